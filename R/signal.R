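#' Savitzky-Golay smoothing of a melt curve
#'
#' Local-polynomial smoothing on the acquisition grid; endpoints are handled
#' by the filter's truncated polynomial fits. Defaults (7-point window, order
#' 2) suit a 0.2 degrees C grid with modest acquisition noise.
#'
#' @param curve A [melt_curve()].
#' @param window_points Odd window length in points; must exceed `poly_order`
#'   and not exceed the curve length.
#' @param poly_order Polynomial order.
#' @return A smoothed [melt_curve()] on the same grid.
#' @export
smooth_curve <- function(curve, window_points = 7L, poly_order = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  if (window_points %% 2L == 0L) {
    stop("smooth_curve: window_points must be odd", call. = FALSE)
  }
  if (poly_order >= window_points) {
    stop("smooth_curve: poly_order must be < window_points", call. = FALSE)
  }
  if (window_points > length(curve$fluorescence)) {
    stop("smooth_curve: window_points exceeds curve length", call. = FALSE)
  }
  sm <- signal::sgolayfilt(curve$fluorescence, p = poly_order, n = window_points)
  melt_curve(curve$sample_id, curve$temperatures_c, pmax(sm, 0))
}

#' Negative derivative (-dF/dT) of a melt curve
#'
#' Central differences: a 4th-order five-point stencil on interior points, a
#' 3-point central difference at the points adjacent to the boundary, and
#' one-sided differences at the two ends. Each melt transition produces a peak
#' at its Tm; for a logistic transition of amplitude A and width w the peak
#' height is A/(4w), which the tests use as an analytic oracle.
#'
#' @param curve A [melt_curve()].
#' @return An object of class `deriv_trace` with fields `sample_id`,
#'   `temperatures_c` and `minus_dfdt`.
#' @export
negative_derivative <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  y <- curve$fluorescence
  t <- curve$temperatures_c
  n <- length(y)
  h <- (t[n] - t[1L]) / (n - 1L)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / h
  d[n] <- (y[n] - y[n - 1L]) / h
  if (n >= 3L) {
    d[2L] <- (y[3L] - y[1L]) / (2 * h)
    d[n - 1L] <- (y[n] - y[n - 2L]) / (2 * h)
  }
  if (n >= 5L) {
    i <- 3:(n - 2L)
    d[i] <- (-y[i + 2L] + 8 * y[i + 1L] - 8 * y[i - 1L] + y[i - 2L]) / (12 * h)
  }
  structure(
    list(sample_id = curve$sample_id, temperatures_c = t, minus_dfdt = -d),
    class = "deriv_trace"
  )
}

# Flank plateau regions of the panel on a given grid: below the reference
# melt and above the highest melt, clear of the assignment windows. Used for
# the derivative baseline estimate and its noise level.
flank_regions <- function(deriv, panel) {
  amp <- panel$amplicons
  t <- deriv$temperatures_c
  lo <- t < (amp$tm_c[1L] - amp$window_c[1L])
  k <- nrow(amp)
  hi <- t > (amp$tm_c[k] + amp$window_c[k])
  list(lo = lo, hi = hi)
}

#' Detect per-amplicon derivative peaks
#'
#' For each amplicon the peak is the maximum of the baseline-corrected
#' -dF/dT trace within `tm_c +/- window_c`. The baseline is the mean of the
#' trace over the flat flank regions below the first and above the last melt
#' (removing the linear-background slope the instrument software also
#' removes); corrected heights are floored at zero. A target whose height
#' falls below `absence_frac` times the height expected from the sample's own
#' reference peak (scaled by per-copy amplitudes) is flagged absent with
#' height reported as measured. A missing reference peak is a hard error: the
#' run has no quantification anchor.
#'
#' @param deriv A `deriv_trace` from [negative_derivative()].
#' @param panel An [amplicon_panel()].
#' @param baseline Optional fixed baseline in -dF/dT units; if `NULL`
#'   (default), estimated from the flank regions.
#' @param absence_frac Fraction of the expected full-copy height below which a
#'   target peak is flagged absent; default 0.1.
#' @return An object of class `peak_set`: a list with `sample_id` and a tibble
#'   `peaks` (`gene`, `peak_tm`, `height`, `absent`).
#' @export
detect_peaks <- function(deriv, panel, baseline = NULL, absence_frac = 0.1) {
  stopifnot(inherits(deriv, "deriv_trace"), inherits(panel, "amplicon_panel"))
  amp <- panel$amplicons
  t <- deriv$temperatures_c
  v <- deriv$minus_dfdt
  fl <- flank_regions(deriv, panel)
  flank <- fl$lo | fl$hi
  if (sum(flank) < 2L) {
    stop("detect_peaks: derivative trace does not cover the panel's flanks",
         call. = FALSE)
  }
  if (is.null(baseline)) baseline <- mean(v[flank])
  noise <- stats::sd(v[flank])

  res <- lapply(seq_len(nrow(amp)), function(i) {
    win <- abs(t - amp$tm_c[i]) <= amp$window_c[i]
    if (!any(win)) {
      stop("detect_peaks: no grid points in the window of '", amp$gene[i], "'",
           call. = FALSE)
    }
    j <- which(win)[which.max(v[win])]
    tibble::tibble(gene = amp$gene[i], peak_tm = t[j],
                   height = max(v[j] - baseline, 0))
  })
  peaks <- do.call(rbind, res)

  ref <- peaks$height[peaks$gene == panel$reference_gene]
  ref_amp <- amp$per_copy_amplitude[amp$gene == panel$reference_gene]
  # reference must rise clearly above the flank noise floor
  if (ref <= max(5 * noise, 1e-9)) {
    stop("detect_peaks: reference gene '", panel$reference_gene,
         "' peak absent in sample '", deriv$sample_id,
         "' - no quantification anchor", call. = FALSE)
  }
  expected_full <- ref * (amp$per_copy_amplitude * panel$reference_copies) /
    (ref_amp * panel$reference_copies)
  peaks$absent <- peaks$height < absence_frac * expected_full
  peaks$height[peaks$absent] <- peaks$height[peaks$absent] # measured, kept
  structure(list(sample_id = deriv$sample_id, peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Peak set for '", x$sample_id, "':\n", sep = "")
  print(x$peaks)
  invisible(x)
}

#' Normalization windows for two-stage plateau analysis
#'
#' @param pre,post Numeric length-2 vectors `(t_start, t_end)` in degrees C;
#'   `pre` must lie entirely below `post` and each must span at least two grid
#'   points of the run it is applied to.
#' @return An object of class `normalization_windows`.
#' @export
normalization_windows <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != 2L || length(post) != 2L ||
      pre[1L] >= pre[2L] || post[1L] >= post[2L]) {
    stop("normalization_windows: windows must be increasing (start, end) pairs",
         call. = FALSE)
  }
  if (pre[2L] >= post[1L]) {
    stop("normalization_windows: pre window must lie entirely below post window",
         call. = FALSE)
  }
  structure(list(pre = pre, post = post), class = "normalization_windows")
}

#' Automatic placement of normalization windows
#'
#' Mirrors how an analyst sets normalization regions in HRM software, using
#' the control curve's smoothed derivative. Stage 1 (reference vs first
#' target): the pre window sits below the reference melt and the post window
#' in the gap between the two target melts. Stage 2 (first vs second target):
#' the pre window sits in the gap between the reference and first-target
#' melts — i.e. before the first target melts — and the post window above the
#' second-target melt. Each window (default 0.6 degrees C wide) is centred on
#' the flattest position of its eligible region: the minimum mean |dF/dT| of
#' the control trace.
#'
#' @param run A [melt_run()].
#' @param panel An [amplicon_panel()] with exactly two target genes.
#' @param stage 1 or 2.
#' @param width_c Window width in degrees C.
#' @param margin_c Clearance kept from each Tm when defining eligible
#'   regions, degrees C.
#' @param flat_frac Placement fails (with advice to set windows manually) if
#'   the flattest eligible position still has mean |dF/dT| above `flat_frac`
#'   times the control's maximum |dF/dT|.
#' @return A [normalization_windows()].
#' @export
place_windows <- function(run, panel, stage, width_c = 0.6, margin_c = 1.0,
                          flat_frac = 0.10) {
  stopifnot(inherits(run, "melt_run"), inherits(panel, "amplicon_panel"))
  if (length(panel$target_genes) < 2L) {
    stop("place_windows: panel must define two target genes", call. = FALSE)
  }
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) stop("place_windows: stage must be 1 or 2",
                                  call. = FALSE)
  control <- run$curves[[run$control_sample_id]]
  d <- negative_derivative(smooth_curve(control))
  t <- d$temperatures_c
  v <- abs(d$minus_dfdt)
  tm <- function(g) panel$amplicons$tm_c[panel$amplicons$gene == g]
  tm_ref <- tm(panel$reference_gene)
  tm_t1 <- tm(panel$target_genes[1L])
  tm_t2 <- tm(panel$target_genes[2L])

  regions <- if (stage == 1L) {
    list(pre = c(min(t), tm_ref - margin_c),
         post = c(tm_t1 + margin_c, tm_t2 - margin_c))
  } else {
    list(pre = c(tm_ref + margin_c, tm_t1 - margin_c),
         post = c(tm_t2 + margin_c, max(t)))
  }

  flat_limit <- flat_frac * max(v)
  pick <- function(region) {
    elig <- which(t >= region[1L] & t <= region[2L])
    npts <- max(2L, round(width_c / (t[2L] - t[1L])) + 1L)
    if (length(elig) < npts) {
      stop("place_windows: eligible region [", region[1L], ", ", region[2L],
           "] too narrow for a ", width_c, " degrees C window", call. = FALSE)
    }
    starts <- elig[seq_len(length(elig) - npts + 1L)]
    flatness <- vapply(starts, function(s) mean(v[s:(s + npts - 1L)]),
                       numeric(1))
    best <- starts[which.min(flatness)]
    if (min(flatness) > flat_limit) {
      stop("place_windows: no plateau flat enough in [", region[1L], ", ",
           region[2L], "] degrees C; set normalization windows manually",
           call. = FALSE)
    }
    c(t[best], t[best + npts - 1L])
  }
  normalization_windows(pre = pick(regions$pre), post = pick(regions$post))
}

#' Two-window normalization of a melt curve
#'
#' Fits a line to the fluorescence over each window and rescales the curve so
#' the pre-window line maps to 100 and the post-window line to 0:
#' \deqn{n(T) = 100 (F(T) - L_{post}(T)) / (L_{pre}(T) - L_{post}(T))}
#' A linear baseline is absorbed exactly by the two line fits, so the height
#' of an inter-melt plateau on the normalized curve reads out the amplitude
#' fraction of the transitions bracketed by the windows. The two lines share
#' one slope (fitted jointly with separate intercepts): the dye background
#' has a single slope, and estimating two independent slopes from short
#' windows and extrapolating them across the inter-melt region would amplify
#' acquisition noise several-fold. Each window's fitted line still passes
#' through that window's mean, so pre-window values average exactly 100 and
#' post-window values exactly 0.
#'
#' @param curve A [melt_curve()].
#' @param windows A [normalization_windows()].
#' @return An object of class `norm_curve` with fields `sample_id`,
#'   `temperatures_c`, `normalized` (percent units).
#' @export
normalize_between <- function(curve, windows) {
  stopifnot(inherits(curve, "melt_curve"),
            inherits(windows, "normalization_windows"))
  t <- curve$temperatures_c
  f <- curve$fluorescence
  in_pre <- t >= windows$pre[1L] & t <= windows$pre[2L]
  in_post <- t >= windows$post[1L] & t <= windows$post[2L]
  for (w in list(c(sum(in_pre), "pre"), c(sum(in_post), "post"))) {
    if (as.integer(w[1L]) < 2L) {
      stop("normalize_between: ", w[2L], " window spans fewer than 2 grid ",
           "points", call. = FALSE)
    }
  }
  sel <- in_pre | in_post
  x <- cbind(pre = as.numeric(in_pre), post = as.numeric(in_post), t = t)
  cf <- stats::coef(stats::lm.fit(x[sel, , drop = FALSE], f[sel]))
  l_pre <- cf[["pre"]] + cf[["t"]] * t
  l_post <- cf[["post"]] + cf[["t"]] * t
  denom <- l_pre - l_post
  if (mean(abs(denom)) < 1e-6 * max(abs(f), 1)) {
    stop("normalize_between: degenerate fit - pre and post window levels ",
         "coincide (no melt signal between the windows)", call. = FALSE)
  }
  structure(
    list(sample_id = curve$sample_id, temperatures_c = t,
         normalized = 100 * (f - l_post) / denom,
         windows = windows),
    class = "norm_curve"
  )
}

#' Plateau height of a normalized curve
#'
#' Reads the mean normalized value over the central 50% of the inter-melt gap
#' for the stage (stage 1: between the reference and first-target Tms; stage
#' 2: between the two target Tms), avoiding shoulder contamination from the
#' adjacent transitions, and reports it as a fraction of the 100-to-0 span.
#' On noiseless data, stage 1 estimates \eqn{A_{t1}/(A_{ref}+A_{t1})} and
#' stage 2 \eqn{A_{t2}/(A_{t1}+A_{t2})}, the amplitude fractions from which
#' copy-number ratios follow.
#'
#' @param norm_curve A `norm_curve` from [normalize_between()].
#' @param panel An [amplicon_panel()].
#' @param stage 1 or 2.
#' @return An object of class `plateau_measurement`: list with `sample_id`,
#'   `stage`, `plateau_fraction` (clamped to \[0, 1\]).
#' @export
plateau_height <- function(norm_curve, panel, stage) {
  stopifnot(inherits(norm_curve, "norm_curve"), inherits(panel, "amplicon_panel"))
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) stop("plateau_height: stage must be 1 or 2",
                                  call. = FALSE)
  tm <- function(g) panel$amplicons$tm_c[panel$amplicons$gene == g]
  bounds <- if (stage == 1L) {
    c(tm(panel$reference_gene), tm(panel$target_genes[1L]))
  } else {
    c(tm(panel$target_genes[1L]), tm(panel$target_genes[2L]))
  }
  gap <- diff(bounds)
  region <- c(bounds[1L] + 0.25 * gap, bounds[2L] - 0.25 * gap)
  t <- norm_curve$temperatures_c
  i <- t >= region[1L] & t <= region[2L]
  if (!any(i)) {
    stop("plateau_height: plateau read region [", region[1L], ", ", region[2L],
         "] lies outside the grid", call. = FALSE)
  }
  frac <- mean(norm_curve$normalized[i]) / 100
  structure(
    list(sample_id = norm_curve$sample_id, stage = stage,
         plateau_fraction = min(max(frac, 0), 1)),
    class = "plateau_measurement"
  )
}
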