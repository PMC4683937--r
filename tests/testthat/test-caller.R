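test_that("the normalized peak ratio recovers copy-number fractions", {
  panel <- test_panel()
  run <- noiseless_run(list(c(1, 2), c(2, 1)))
  peaksets <- lapply(run$curves, function(cv) {
    detect_peaks(negative_derivative(smooth_curve(cv)), panel)
  })
  control <- peaksets[["control"]]
  # a sample against itself gives exactly 1
  expect_identical(normalized_peak_ratio(control, control, "HBA1"), 1)
  expect_identical(normalized_peak_ratio(control, control, "HBA2"), 1)
  # one target copy against a two-copy control: ratio 0.5
  expect_equal(normalized_peak_ratio(control, peaksets[["s01"]], "HBA1"), 0.5,
               tolerance = 0.03)
  expect_equal(normalized_peak_ratio(control, peaksets[["s02"]], "HBA2"), 0.5,
               tolerance = 0.03)
  # an absent target returns 0, never divides by zero
  run0 <- noiseless_run(list(c(2, 0)))
  ps0 <- detect_peaks(
    negative_derivative(smooth_curve(run0$curves[["s01"]])), panel)
  expect_identical(normalized_peak_ratio(control, ps0, "HBA2"), 0)
})

test_that("ratios snap to integer copy states with a tolerance band", {
  expect_equal(ratio_to_copies(1.0, 2), list(copies = 2L, ambiguous = FALSE))
  expect_equal(ratio_to_copies(1.5, 2), list(copies = 3L, ambiguous = FALSE))
  # 0.68 * 2 = 1.36: nearest state 1 at distance 0.36 > 0.35 -> ambiguous
  r <- ratio_to_copies(0.68, 2)
  expect_equal(r$copies, 1L)
  expect_true(r$ambiguous)
  expect_equal(ratio_to_copies(0.0, 2)$copies, 0L)
  expect_error(ratio_to_copies(-0.1, 2), ">= 0")
  expect_error(ratio_to_copies(1, 0), "control_copies")
})

test_that("peak calling recovers every cohort copy pair noiselessly", {
  panel <- test_panel()
  run <- noiseless_run(cohort_pairs())
  calls <- call_by_peaks(run, panel)
  truth <- cohort_pairs()
  for (i in seq_along(truth)) {
    row <- calls[calls$sample_id == sprintf("s%02d", i), ]
    expect_equal(c(row$hba1_copies, row$hba2_copies), as.integer(truth[[i]]),
                 info = paste("pair", paste(truth[[i]], collapse = ":")))
  }
  expect_false(any(grepl("ambiguous", calls$flags)))
})

test_that("window calling matches peak calling on every noiseless genotype", {
  panel <- test_panel()
  run <- noiseless_run(cohort_pairs())
  pk <- call_by_peaks(run, panel)
  wd <- call_by_windows(run, panel)
  m <- match(pk$sample_id, wd$sample_id)
  expect_equal(pk$hba1_copies, wd$hba1_copies[m])
  expect_equal(pk$hba2_copies, wd$hba2_copies[m])
})

test_that("window calling resolves sequentially: reference, HBA1, then HBA2", {
  panel <- test_panel()
  run <- noiseless_run(list(c(2, 1), c(2, 0)))
  wd <- call_by_windows(run, panel)
  s1 <- wd[wd$sample_id == "s01", ]
  # control (2,2): stage-2 odds 1; unknown (2,1): odds (1/2) -> ratio 0.5
  expect_equal(s1$stage2_ratio, 0.5, tolerance = 0.05)
  expect_equal(s1$hba2_copies, 1L)
  # stage-2 plateau at the absence floor short-circuits to zero copies
  s2 <- wd[wd$sample_id == "s02", ]
  expect_equal(s2$hba2_copies, 0L)
  expect_match(s2$flags, "absent_target")
})

test_that("both calling methods are invariant under per-sample scale", {
  panel <- test_panel()
  run <- noiseless_run(list(c(2, 1), c(1, 0)))
  scaled_curves <- run$curves
  for (id in c("s01", "s02")) {
    cv <- scaled_curves[[id]]
    scaled_curves[[id]] <- melt_curve(id, cv$temperatures_c,
                                      cv$fluorescence * 3.7)
  }
  scaled <- melt_run(scaled_curves, "control", run_id = "scaled")
  for (caller in list(call_by_peaks, call_by_windows)) {
    a <- caller(run, panel)
    b <- caller(scaled, panel)
    m <- match(a$sample_id, b$sample_id)
    expect_equal(a$hba1_copies, b$hba1_copies[m])
    expect_equal(a$hba2_copies, b$hba2_copies[m])
  }
})

test_that("stage-2 ratio increases strictly with true HBA2 copies", {
  panel <- test_panel()
  run <- noiseless_run(list(c(2, 0), c(2, 1), c(2, 2), c(2, 3)))
  wd <- call_by_windows(run, panel)
  ratios <- wd$stage2_ratio[match(sprintf("s%02d", 1:4), wd$sample_id)]
  expect_true(all(diff(ratios) > 0))
  pk <- call_by_peaks(run, panel)
  pratios <- pk$stage2_ratio[match(sprintf("s%02d", 1:4), pk$sample_id)]
  expect_true(all(diff(pratios) > 0))
})

test_that("a wild-type-only run calls (2,2) everywhere", {
  run <- noiseless_run(list(c(2, 2), c(2, 2)))
  calls <- call_by_peaks(run, test_panel())
  expect_true(all(calls$hba1_copies == 2L))
  expect_true(all(calls$hba2_copies == 2L))
  expect_true(all(!nzchar(calls$flags)))
})

test_that("the improbable_reference flag fires on out-of-range stage-1 ratios", {
  panel <- test_panel()
  # a 'control' with halved reference signal makes unknowns look duplicated:
  # simulate by calling with a panel-allowed but extreme unknown instead
  genes <- c(panel$reference_gene, panel$target_genes)
  copies_hi <- c(2L, 5L, 2L); names(copies_hi) <- genes
  curves <- list(
    simulate_curve(sim_sample_spec("control", noise_sd = 0), panel),
    simulate_curve(sim_sample_spec("s01", copies_hi, noise_sd = 0), panel)
  )
  run <- melt_run(curves, "control")
  calls <- call_by_peaks(run, panel)
  expect_match(calls$flags[calls$sample_id == "s01"], "improbable_reference")
})

test_that("a run whose control fails its wild-type QC gate errors out", {
  panel <- test_panel()
  genes <- c(panel$reference_gene, panel$target_genes)
  # a 'control' that itself lacks HBA2 cannot anchor the run: all ratios are
  # taken against it, so only an absent target can betray it - and must
  copies <- c(2L, 2L, 0L); names(copies) <- genes
  curves <- list(
    simulate_curve(sim_sample_spec("control", copies, noise_sd = 0), panel),
    simulate_curve(sim_sample_spec("s01", noise_sd = 0), panel)
  )
  run <- melt_run(curves, "control")
  expect_error(call_by_peaks(run, panel), "QC|wild type")
  expect_error(call_by_windows(run, panel), "QC|wild type")
})

test_that("copy pairs map to their genotype classes with caveats", {
  expect_match(interpret_copy_pair(2, 2)$label, "normal")
  expect_match(interpret_copy_pair(2, 2)$label, "point mutations")
  expect_match(interpret_copy_pair(2, 1)$label, "single-gene deletion")
  expect_match(interpret_copy_pair(2, 0)$label, "in trans")
  expect_match(interpret_copy_pair(1, 1)$label, "alpha0")
  expect_match(interpret_copy_pair(1, 0)$label, "Hb H")
  expect_match(interpret_copy_pair(2, 3)$label, "duplication")
  expect_match(interpret_copy_pair(0, 0)$label, "four-gene")
  expect_match(interpret_copy_pair(3, 3)$label, "atypical")
  expect_length(interpret_copy_pair(1, 0)$caveats, 3L)
  expect_error(interpret_copy_pair(-1, 0), "nonnegative")
})

test_that("calls survive a CSV round trip", {
  run <- noiseless_run(list(c(2, 1)))
  calls <- call_by_peaks(run, test_panel())
  path <- withr::local_tempfile(fileext = ".csv")
  write_calls_csv(calls, path)
  back <- read_calls_csv(path)
  expect_equal(back$sample_id, calls$sample_id)
  expect_equal(back$hba1_copies, calls$hba1_copies)
  expect_equal(back$hba2_copies, calls$hba2_copies)
  expect_equal(back$flags, calls$flags)
})
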