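test_that("smoothing preserves noiseless curves and reproduces constants", {
  cv <- simulate_curve(sim_sample_spec("wt", noise_sd = 0), test_panel())
  sm <- smooth_curve(cv, 7L, 2L)
  amplitude <- max(cv$fluorescence) - min(cv$fluorescence)
  expect_lt(max(abs(sm$fluorescence - cv$fluorescence)), 0.01 * amplitude)

  flat <- melt_curve("c", default_grid(), rep(3.5, 51))
  expect_equal(smooth_curve(flat)$fluorescence, rep(3.5, 51))

  expect_error(smooth_curve(cv, 6L, 2L), "odd")
  expect_error(smooth_curve(cv, 5L, 5L), "poly_order")
  expect_error(smooth_curve(cv, 99L, 2L), "exceeds")
})

test_that("negative derivative reproduces the logistic peak height A/(4w)", {
  grid <- default_grid()
  # single logistic, A = 1, w = 0.4: peak at Tm with height 0.625
  f <- 1 / (1 + exp((grid - 82.2) / 0.4))
  d <- negative_derivative(melt_curve("s", grid, f))
  expect_equal(max(d$minus_dfdt), 1 / (4 * 0.4), tolerance = 0.02)
  expect_equal(grid[which.max(d$minus_dfdt)], 82.2)

  # pure linear baseline: constant trace at -slope
  lin <- melt_curve("l", grid, 30 - 0.3 * (grid - 77))
  dl <- negative_derivative(lin)
  expect_equal(dl$minus_dfdt, rep(0.3, 51), tolerance = 1e-9)

  # superposition of two separated logistics: both heights within 3%
  f2 <- 1.5 / (1 + exp((grid - 79.4) / 0.4)) + 0.8 / (1 + exp((grid - 85.2) / 0.4))
  d2 <- negative_derivative(melt_curve("m", grid, f2))
  h1 <- max(d2$minus_dfdt[abs(grid - 79.4) <= 1.2])
  h2 <- max(d2$minus_dfdt[abs(grid - 85.2) <= 1.2])
  expect_equal(h1, 1.5 / 1.6, tolerance = 0.03)
  expect_equal(h2, 0.8 / 1.6, tolerance = 0.03)
})

test_that("peak detection locates and quantifies the panel's amplicons", {
  panel <- test_panel()
  cv <- simulate_curve(sim_sample_spec("wt", noise_sd = 0), panel)
  ps <- detect_peaks(negative_derivative(cv), panel)
  expect_equal(ps$peaks$gene, c("CLCN7", "HBA1", "HBA2"))
  # peaks at the product Tms, within one grid step
  expect_true(all(abs(ps$peaks$peak_tm - c(79.4, 82.2, 85.2)) <= 0.2))
  # baseline-corrected heights match A/(4w) within 3%
  expect_equal(ps$peaks$height, rep(2 / (4 * 0.2), 3L), tolerance = 0.03)
  expect_false(any(ps$peaks$absent))
})

test_that("an absent target is flagged; an absent reference is fatal", {
  panel <- test_panel()
  cv <- simulate_curve(
    sim_sample_spec("d", c(CLCN7 = 2L, HBA1 = 2L, HBA2 = 0L), noise_sd = 0),
    panel)
  ps <- detect_peaks(negative_derivative(cv), panel)
  expect_true(ps$peaks$absent[ps$peaks$gene == "HBA2"])
  expect_lt(ps$peaks$height[ps$peaks$gene == "HBA2"],
            0.1 * ps$peaks$height[ps$peaks$gene == "CLCN7"])

  set.seed(100)
  noise <- melt_curve("n", default_grid(), abs(rnorm(51, 1, 0.02)))
  expect_error(detect_peaks(negative_derivative(noise), panel),
               "reference.*absent|anchor")
})

test_that("windows auto-place onto the flanking and inter-melt plateaus", {
  run <- noiseless_run(list(c(2, 2)))
  panel <- test_panel()
  w1 <- place_windows(run, panel, stage = 1L)
  expect_gte(w1$pre[1L], 77); expect_lte(w1$pre[2L], 78.4)
  expect_gte(w1$post[1L], 82.2); expect_lte(w1$post[2L], 85.2)
  w2 <- place_windows(run, panel, stage = 2L)
  expect_gte(w2$pre[1L], 79.4); expect_lte(w2$pre[2L], 82.2)
  expect_gte(w2$post[1L], 86); expect_lte(w2$post[2L], 87)
  # invariants hold by construction
  expect_lt(w1$pre[2L], w1$post[1L])
  expect_lt(w2$pre[2L], w2$post[1L])
  expect_error(normalization_windows(c(80, 81), c(79, 82)), "below")
  expect_error(normalization_windows(c(81, 80), c(82, 83)), "increasing")
})

test_that("two-window normalization maps pre to 100 and post to 0", {
  run <- noiseless_run(list(c(2, 1)))
  panel <- test_panel()
  w1 <- place_windows(run, panel, stage = 1L)
  for (cv in run$curves) {
    nc <- normalize_between(cv, w1)
    t <- nc$temperatures_c
    expect_equal(mean(nc$normalized[t >= w1$pre[1L] & t <= w1$pre[2L]]), 100,
                 tolerance = 0.5)
    expect_equal(mean(nc$normalized[t >= w1$post[1L] & t <= w1$post[2L]]), 0,
                 tolerance = 0.5)
    # the inter-melt plateau sits strictly between the rails
    p <- plateau_height(nc, panel, 1L)$plateau_fraction
    expect_gt(p, 0); expect_lt(p, 1)
  }
  flat <- melt_curve("c", default_grid(), rep(2, 51))
  expect_error(normalize_between(flat, w1), "degenerate")
})

test_that("plateau heights equal closed-form amplitude fractions (noiseless)", {
  panel <- test_panel()
  run <- noiseless_run(list(c(2, 2), c(2, 1), c(1, 1), c(2, 0)))
  w1 <- place_windows(run, panel, stage = 1L)
  w2 <- place_windows(run, panel, stage = 2L)
  truth <- list(c(2, 2), c(2, 2), c(2, 1), c(1, 1), c(2, 0))  # control first
  for (i in seq_along(run$curves)) {
    cc <- truth[[i]]
    p1 <- plateau_height(normalize_between(run$curves[[i]], w1), panel, 1L)
    expect_equal(p1$plateau_fraction, cc[1L] / (2 + cc[1L]), tolerance = 0.02)
    p2 <- plateau_height(normalize_between(run$curves[[i]], w2), panel, 2L)
    if (cc[2L] == 0) {
      expect_lte(p2$plateau_fraction, 0.05)
    } else {
      expect_equal(p2$plateau_fraction, cc[2L] / (cc[1L] + cc[2L]),
                   tolerance = 0.02)
    }
  }
})

test_that("plateau measurements are invariant under global scale", {
  panel <- test_panel()
  run <- noiseless_run(list(c(2, 1)))
  w1 <- place_windows(run, panel, stage = 1L)
  cv <- run$curves[["s01"]]
  scaled <- melt_curve(cv$sample_id, cv$temperatures_c, cv$fluorescence * 7.3)
  p <- plateau_height(normalize_between(cv, w1), panel, 1L)$plateau_fraction
  ps <- plateau_height(normalize_between(scaled, w1), panel, 1L)$plateau_fraction
  expect_equal(p, ps, tolerance = 1e-12)
})

test_that("an added linear baseline barely shifts plateau fractions", {
  panel <- test_panel()
  run <- noiseless_run(list(c(2, 1)))
  w1 <- place_windows(run, panel, stage = 1L)
  cv <- run$curves[["s01"]]
  tilted <- melt_curve(cv$sample_id, cv$temperatures_c,
                       cv$fluorescence + 5 + 0.4 * (cv$temperatures_c - 77))
  p <- plateau_height(normalize_between(cv, w1), panel, 1L)$plateau_fraction
  pt <- plateau_height(normalize_between(tilted, w1), panel, 1L)$plateau_fraction
  expect_lt(abs(p - pt), 0.01)
})
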