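#' Confusion counts of copy-number calls against a truth table
#'
#' A sample is a true positive of the screening test when its true copy pair
#' differs from wild type (2, 2) — an abnormal alpha-globin copy number — and
#' the call is likewise abnormal. Flagged-ambiguous calls are handled per
#' `ambiguous`: counted as discordant (default; conservative for a screening
#' claim), taken at their called value, or excluded from the denominators.
#'
#' @param calls A calls tibble ([call_by_peaks()] / [call_by_windows()]).
#' @param truth A tibble with columns `sample_id`, `hba1`, `hba2`.
#' @param ambiguous One of `"as-discordant"`, `"as-called"`, `"excluded"`.
#' @return A list of integer counts: `tp`, `fn`, `tn`, `fp`, `n_excluded`,
#'   `n_total`, `n_positive_truth`, `n_negative_truth`.
#' @export
confusion_counts <- function(calls, truth,
                             ambiguous = c("as-discordant", "as-called",
                                           "excluded")) {
  ambiguous <- match.arg(ambiguous)
  if (is.null(calls) || nrow(calls) == 0L) {
    stop("confusion_counts: empty call list", call. = FALSE)
  }
  missing <- setdiff(calls$sample_id, truth$sample_id)
  if (length(missing) > 0L) {
    stop("confusion_counts: no truth entry for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- match(calls$sample_id, truth$sample_id)
  true_pos <- !(truth$hba1[m] == 2L & truth$hba2[m] == 2L)
  called_pos <- !(calls$hba1_copies == 2L & calls$hba2_copies == 2L)
  is_amb <- grepl("ambiguous", calls$flags)

  excluded <- rep(FALSE, nrow(calls))
  if (ambiguous == "excluded") {
    excluded <- is_amb
  } else if (ambiguous == "as-discordant") {
    # an ambiguous call never counts as a correct result
    called_pos[is_amb] <- !true_pos[is_amb]
  }
  keep <- !excluded
  tp <- sum(keep & true_pos & called_pos)
  fn <- sum(keep & true_pos & !called_pos)
  tn <- sum(keep & !true_pos & !called_pos)
  fp <- sum(keep & !true_pos & called_pos)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       n_excluded = sum(excluded), n_total = sum(keep),
       n_positive_truth = tp + fn, n_negative_truth = tn + fp)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta quantiles: lower bound `qbeta(a/2, k, n-k+1)` (0 when
#' k = 0), upper bound `qbeta(1-a/2, k+1, n-k)` (1 when k = n). For k = n the
#' lower bound reduces to `(a/2)^(1/n)`; with 108/108 and 59/59 at 95%
#' confidence this gives 0.966 and 0.939.
#'
#' @param successes,trials Integer counts, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param confidence Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)` in \[0, 1\].
#' @export
exact_binomial_ci <- function(successes, trials, confidence = 0.95) {
  successes <- as.integer(successes); trials <- as.integer(trials)
  if (is.na(successes) || is.na(trials) || trials < 1L ||
      successes < 0L || successes > trials) {
    stop("exact_binomial_ci: need 0 <= successes <= trials, trials >= 1",
         call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("exact_binomial_ci: confidence must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - confidence
  low <- if (successes == 0L) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1L)
  high <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1L, trials - successes)
  c(low = low, high = high)
}

#' Validate calls against a truth table
#'
#' Composes [confusion_counts()] with exact binomial intervals into a
#' validation report: sensitivity = TP / (TP + FN) over truth-abnormal
#' samples, specificity = TN / (TN + FP) over truth-wild-type samples, each
#' with its Clopper-Pearson interval. A denominator of zero yields `NA`
#' ("not applicable"), never 0.
#'
#' @inheritParams confusion_counts
#' @param confidence Confidence level for the intervals.
#' @return An object of class `validation_report`.
#' @export
run_validation <- function(calls, truth, confidence = 0.95,
                           ambiguous = c("as-discordant", "as-called",
                                         "excluded")) {
  ambiguous <- match.arg(ambiguous)
  cc <- confusion_counts(calls, truth, ambiguous)
  sens <- if (cc$n_positive_truth > 0L) cc$tp / cc$n_positive_truth else NA_real_
  spec <- if (cc$n_negative_truth > 0L) cc$tn / cc$n_negative_truth else NA_real_
  sens_ci <- if (cc$n_positive_truth > 0L) {
    exact_binomial_ci(cc$tp, cc$n_positive_truth, confidence)
  } else c(low = NA_real_, high = NA_real_)
  spec_ci <- if (cc$n_negative_truth > 0L) {
    exact_binomial_ci(cc$tn, cc$n_negative_truth, confidence)
  } else c(low = NA_real_, high = NA_real_)
  structure(
    list(n_total = cc$n_total, n_excluded = cc$n_excluded,
         n_positive_truth = cc$n_positive_truth,
         n_negative_truth = cc$n_negative_truth,
         true_positives = cc$tp, false_negatives = cc$fn,
         true_negatives = cc$tn, false_positives = cc$fp,
         sensitivity = sens, specificity = spec,
         sensitivity_ci95 = unname(sens_ci), specificity_ci95 = unname(spec_ci),
         confidence = confidence, ambiguous_policy = ambiguous),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "n/a" else sprintf("%.1f%%", 100 * p)
  ci <- function(v) if (anyNA(v)) "n/a" else
    sprintf("%.1f-%.1f%%", 100 * v[1L], 100 * v[2L])
  cat("Validation report (", x$n_total, " samples",
      if (x$n_excluded > 0L) paste0(", ", x$n_excluded, " excluded"), ")\n",
      sep = "")
  cat("  abnormal in truth:", x$n_positive_truth,
      " wild type in truth:", x$n_negative_truth, "\n")
  cat("  TP:", x$true_positives, " FN:", x$false_negatives,
      " TN:", x$true_negatives, " FP:", x$false_positives, "\n")
  cat("  sensitivity:", pct(x$sensitivity),
      sprintf("(%.0f%% CI %s)", 100 * x$confidence, ci(x$sensitivity_ci95)), "\n")
  cat("  specificity:", pct(x$specificity),
      sprintf("(%.0f%% CI %s)", 100 * x$confidence, ci(x$specificity_ci95)), "\n")
  invisible(x)
}

#' Write a validation report as CSV
#'
#' One-row CSV with the confusion counts, point estimates and CI bounds.
#'
#' @param report A `validation_report`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_validation_csv <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  row <- data.frame(
    n_total = report$n_total, n_excluded = report$n_excluded,
    n_positive_truth = report$n_positive_truth,
    n_negative_truth = report$n_negative_truth,
    true_positives = report$true_positives,
    false_negatives = report$false_negatives,
    true_negatives = report$true_negatives,
    false_positives = report$false_positives,
    sensitivity = report$sensitivity, specificity = report$specificity,
    sensitivity_ci_low = report$sensitivity_ci95[1L],
    sensitivity_ci_high = report$sensitivity_ci95[2L],
    specificity_ci_low = report$specificity_ci95[1L],
    specificity_ci_high = report$specificity_ci95[2L],
    ambiguous_policy = report$ambiguous_policy
  )
  utils::write.csv(row, path, row.names = FALSE)
  invisible(path)
}
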