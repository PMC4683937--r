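#' Default melt acquisition grid
#'
#' 77 to 87 degrees C at 0.2 degrees C resolution (51 points), the acquisition
#' range of the assay.
#'
#' @param tmin,tmax Range in degrees C.
#' @param step Grid step in degrees C.
#' @return Numeric temperature grid.
#' @export
default_grid <- function(tmin = 77, tmax = 87, step = 0.2) {
  seq(tmin, tmax, by = step)
}

#' Specification of one simulated sample
#'
#' @param sample_id Sample identifier.
#' @param copies Named integer vector of gene copy numbers. Genes of the panel
#'   that are absent from the vector default to the panel's reference copy
#'   number (so a wild-type spec needs only `sample_id`).
#' @param scale Per-sample global signal factor (> 0); captures pipetting and
#'   amplification efficiency variation between reactions.
#' @param baseline_intercept,baseline_slope Linear background fluorescence:
#'   intercept at the low end of the grid (signal units) and slope per degree C
#'   (<= 0; intercalating-dye background decays slowly with temperature).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added per grid
#'   point (signal units, >= 0).
#' @return An object of class `sim_sample_spec`.
#' @export
sim_sample_spec <- function(sample_id, copies = NULL, scale = 1,
                            baseline_intercept = 2, baseline_slope = -0.02,
                            noise_sd = 0.02) {
  copies <- if (is.null(copies)) integer(0) else copies
  if (length(copies) > 0 && is.null(names(copies))) {
    stop("sim_sample_spec: copies must be a named vector (gene -> copies)",
         call. = FALSE)
  }
  copies_int <- as.integer(copies)
  if (anyNA(copies_int) || any(copies_int < 0L) ||
      any(abs(copies - copies_int) > 0)) {
    stop("sim_sample_spec: copy numbers must be nonnegative integers",
         call. = FALSE)
  }
  names(copies_int) <- names(copies)
  if (!is.numeric(scale) || scale <= 0) {
    stop("sim_sample_spec: scale must be > 0", call. = FALSE)
  }
  if (baseline_slope > 0) {
    stop("sim_sample_spec: baseline_slope must be <= 0", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("sim_sample_spec: noise_sd must be >= 0", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), copies = copies_int,
         scale = scale, baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope, noise_sd = noise_sd),
    class = "sim_sample_spec"
  )
}

#' Simulate one multiplex melt curve
#'
#' The model is a superposition of decreasing logistic melt transitions, one
#' per amplicon, on a linear background:
#' \deqn{F(T) = b_0 + b_1 (T - T_{min}) + \sum_i \frac{A_i}{1 + e^{(T - Tm_i)/w_i}} + \varepsilon(T)}
#' with amplitude \eqn{A_i = scale \cdot per\_copy\_amplitude_i \cdot copies_i}
#' — the proportionality of product amount to input copy number that the
#' limited-cycle multiplex PCR is designed to preserve — and
#' \eqn{\varepsilon \sim N(0, noise\_sd^2)} i.i.d. per point. Fluorescence is
#' clipped at zero. The logistic form yields a closed-form derivative peak of
#' height \eqn{A_i/(4 w_i)} at \eqn{Tm_i}, used as an analytic oracle in the
#' package tests. Randomness is drawn from R's global RNG; seed it (or use
#' [simulate_cohort()], which does) for reproducibility.
#'
#' @param spec A [sim_sample_spec()].
#' @param panel An [amplicon_panel()].
#' @param grid Temperature grid; default [default_grid()].
#' @return A [melt_curve()].
#' @export
simulate_curve <- function(spec, panel, grid = default_grid()) {
  stopifnot(inherits(spec, "sim_sample_spec"), inherits(panel, "amplicon_panel"))
  amp <- panel$amplicons
  copies <- vapply(amp$gene, function(g) {
    if (g %in% names(spec$copies)) spec$copies[[g]] else panel$reference_copies
  }, integer(1))
  f <- spec$baseline_intercept + spec$baseline_slope * (grid - min(grid))
  for (i in seq_len(nrow(amp))) {
    a_i <- spec$scale * amp$per_copy_amplitude[i] * copies[i]
    f <- f + a_i / (1 + exp((grid - amp$tm_c[i]) / amp$width_c[i]))
  }
  if (spec$noise_sd > 0) {
    f <- f + stats::rnorm(length(grid), 0, spec$noise_sd)
  }
  melt_curve(spec$sample_id, grid, pmax(f, 0))
}

#' The development-and-validation cohort composition
#'
#' The 17-genotype cohort used to assess the assay: per-genotype sample counts
#' split into a pre-genotyped set (`n_pcr1`, 105 samples typed beforehand with
#' a commercial reverse-hybridization strip assay) and a prospective set
#' (`n_pcr2`, 62 samples typed afterwards), with the true (HBA1, HBA2) copy
#' pair each genotype presents to the assay. The hybrid gene created by the
#' -a3.7 deletion carries the HBA1-specific 3' primer site and therefore
#' counts as an HBA1 copy; the -(a)20.5 deletion removes HBA2 entirely but
#' spares the HBA1 3' end, so it presents as an HBA2-only deletion; point
#' mutations (rows 12-17) leave copy numbers unchanged.
#'
#' @return A tibble with columns `genotype`, `hba1`, `hba2`, `n_pcr1`,
#'   `n_pcr2`, `n_total`.
#' @export
table2_cohort <- function() {
  x <- tibble::tribble(
    ~genotype,                ~hba1, ~hba2, ~n_pcr1, ~n_pcr2,
    "aa/aa (wild type)",         2L,    2L,     30L,     24L,
    "aa/-a3.7",                  2L,    1L,     29L,     19L,
    "-a3.7/-a3.7",               2L,    0L,     20L,     16L,
    "aa/-a4.2",                  2L,    1L,      2L,      0L,
    "-a4.2/-a4.2",               2L,    0L,      1L,      0L,
    "-a3.7/-a4.2",               2L,    0L,      3L,      0L,
    "-a3.7/--SEA",               1L,    0L,      3L,      3L,
    "aa/--MED",                  1L,    1L,      2L,      0L,
    "aa/--FIL",                  1L,    1L,      2L,      0L,
    "-(a)20.5",                  2L,    1L,      1L,      0L,
    "aa/aaa-anti3.7",            2L,    3L,      2L,      0L,
    "-a3.7/a-Icaria-a",          2L,    1L,      1L,      0L,
    "aa/a-polyA1-a",             2L,    2L,      2L,      0L,
    "aa/a-polyA2-a",             2L,    2L,      1L,      0L,
    "-a3.7/a-polyA1-a",          2L,    1L,      4L,      0L,
    "aa/a-CS-a",                 2L,    2L,      1L,      0L,
    "a-CS-a/a-CS-a",             2L,    2L,      1L,      0L
  )
  x$n_total <- x$n_pcr1 + x$n_pcr2
  x
}

#' Load a cohort specification from YAML
#'
#' The file is a list of entries with keys `genotype`, `hba1`, `hba2`, `count`
#' (or `n_pcr1`/`n_pcr2`, summed into `count`).
#'
#' @param path Path to a YAML cohort file.
#' @return A tibble with columns `genotype`, `hba1`, `hba2`, `count`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("load_cohort: file not found: ", path, call. = FALSE)
  }
  rows <- yaml::read_yaml(path)
  if (length(rows) == 0L) {
    stop("load_cohort: cohort file is empty", call. = FALSE)
  }
  out <- lapply(rows, function(r) {
    count <- if (!is.null(r$count)) r$count else
      (if (is.null(r$n_pcr1)) 0L else r$n_pcr1) +
      (if (is.null(r$n_pcr2)) 0L else r$n_pcr2)
    if (is.null(r$genotype) || is.null(r$hba1) || is.null(r$hba2)) {
      stop("load_cohort: entry missing genotype/hba1/hba2", call. = FALSE)
    }
    tibble::tibble(genotype = r$genotype, hba1 = as.integer(r$hba1),
                   hba2 = as.integer(r$hba2), count = as.integer(count))
  })
  out <- do.call(rbind, out)
  if (any(out$count < 0L)) stop("load_cohort: counts must be >= 0", call. = FALSE)
  out
}

#' Simulate a cohort-scale melt run with known truth
#'
#' Generates one melt curve per sample in `cohort` plus one designated
#' wild-type control curve, with per-sample global scale drawn log-normally
#' (median 1) to mimic reaction-to-reaction amplification variation — which is
#' exactly what control normalization must absorb — and i.i.d. Gaussian
#' acquisition noise per point. All randomness flows from `seed`.
#'
#' @param cohort A data frame with columns `genotype`, `hba1`, `hba2`, and
#'   `count` (or `n_total`), e.g. [table2_cohort()] or [load_cohort()].
#' @param panel An [amplicon_panel()].
#' @param seed Integer seed governing all randomness.
#' @param noise_sd Per-point Gaussian noise sd in signal units.
#' @param scale_sdlog sdlog of the log-normal per-sample scale factor.
#' @param baseline_intercept,baseline_slope Background parameters passed to
#'   every sample.
#' @param control_id Sample id given to the wild-type control.
#' @param grid Temperature grid.
#' @return A list with elements `run` (a [melt_run()]) and `truth` (a tibble
#'   `sample_id`, `genotype`, `hba1`, `hba2`; the control is included with
#'   copies (2, 2)).
#' @export
simulate_cohort <- function(cohort, panel, seed = 1L,
                            noise_sd = 0.02, scale_sdlog = 0.15,
                            baseline_intercept = 2, baseline_slope = -0.02,
                            control_id = "WT_control", grid = default_grid()) {
  stopifnot(inherits(panel, "amplicon_panel"))
  cohort <- tibble::as_tibble(cohort)
  if (!"count" %in% names(cohort)) {
    if ("n_total" %in% names(cohort)) cohort$count <- cohort$n_total
    else stop("simulate_cohort: cohort needs a 'count' (or 'n_total') column",
              call. = FALSE)
  }
  cohort <- cohort[cohort$count > 0L, , drop = FALSE]
  n <- sum(cohort$count)
  if (n < 1L) stop("simulate_cohort: cohort has zero samples", call. = FALSE)

  set.seed(as.integer(seed))
  t1 <- panel$target_genes[1L]
  t2 <- panel$target_genes[2L]

  idx <- rep(seq_len(nrow(cohort)), cohort$count)
  sample_ids <- sprintf("S%03d", seq_len(n))
  truth <- tibble::tibble(
    sample_id = c(control_id, sample_ids),
    genotype = c("wild-type control", cohort$genotype[idx]),
    hba1 = c(panel$reference_copies, cohort$hba1[idx]),
    hba2 = c(panel$reference_copies, cohort$hba2[idx])
  )
  curves <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    copies <- c(panel$reference_copies, truth$hba1[i], truth$hba2[i])
    names(copies) <- c(panel$reference_gene, t1, t2)
    spec <- sim_sample_spec(
      sample_id = truth$sample_id[i],
      copies = copies,
      scale = stats::rlnorm(1, meanlog = 0, sdlog = scale_sdlog),
      baseline_intercept = baseline_intercept,
      baseline_slope = baseline_slope,
      noise_sd = noise_sd
    )
    curves[[i]] <- simulate_curve(spec, panel, grid)
  }
  run <- melt_run(curves, control_sample_id = control_id,
                  run_id = sprintf("sim_seed%d", as.integer(seed)))
  list(run = run, truth = truth)
}

#' Write / read a truth table CSV
#'
#' @param truth A tibble with columns `sample_id`, `hba1`, `hba2` (and
#'   optionally `genotype`).
#' @param path File path.
#' @return `write_truth_csv` invisibly returns `path`; `read_truth_csv`
#'   returns the truth tibble.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_truth_csv: file not found: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "hba1", "hba2")) {
    if (!col %in% names(x)) {
      stop("read_truth_csv: missing column '", col, "'", call. = FALSE)
    }
  }
  x$hba1 <- as.integer(x$hba1)
  x$hba2 <- as.integer(x$hba2)
  tibble::as_tibble(x)
}
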