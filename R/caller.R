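#' Control-normalized peak-height ratio for one target gene
#'
#' The quantification statistic of the peak-height method:
#' \deqn{ratio = \frac{R_{control}/T_{control}}{R_{unknown}/T_{unknown}}}
#' where R and T are the derivative peak heights of the reference and target
#' amplicons. Under the proportionality model this equals the target copy
#' number of the unknown divided by that of the control; the per-sample scale
#' and the per-copy amplitudes cancel. A target absent in the unknown (height
#' zero or flagged absent) returns 0 by convention — the printed formula would
#' otherwise divide by zero exactly in the homozygous-deletion case it must
#' detect.
#'
#' @param control,unknown `peak_set` objects from [detect_peaks()].
#' @param gene Target gene name.
#' @return A single nonnegative ratio. Zero carries the meaning "target
#'   absent".
#' @export
normalized_peak_ratio <- function(control, unknown, gene) {
  stopifnot(inherits(control, "peak_set"), inherits(unknown, "peak_set"))
  get <- function(ps, g) {
    row <- ps$peaks[ps$peaks$gene == g, ]
    if (nrow(row) != 1L) {
      stop("normalized_peak_ratio: gene '", g, "' not in peak set of '",
           ps$sample_id, "'", call. = FALSE)
    }
    row
  }
  # the reference is the first (lowest-Tm) gene of a peak set by construction
  ref_gene <- control$peaks$gene[1L]
  r_c <- get(control, ref_gene)$height
  t_c <- get(control, gene)$height
  r_u <- get(unknown, ref_gene)$height
  t_u_row <- get(unknown, gene)
  if (r_c <= 0 || r_u <= 0) {
    stop("normalized_peak_ratio: reference peak height is zero", call. = FALSE)
  }
  if (t_c <= 0) {
    stop("normalized_peak_ratio: control target peak height is zero - ",
         "control is not a valid wild type", call. = FALSE)
  }
  if (t_u_row$absent || t_u_row$height <= 0) {
    return(0)
  }
  (r_c / t_c) / (r_u / t_u_row$height)
}

#' Map a copy-number ratio to an integer copy state
#'
#' The candidate copy number is `ratio * control_copies`, snapped to the
#' nearest allowed state. Calls further than `tolerance` (in copy units) from
#' that state are flagged ambiguous — the observed per-state ratio ranges do
#' not overlap in practice, but a batch tool must flag borderline values for
#' confirmatory testing rather than guess silently.
#'
#' @param ratio Nonnegative copy-number ratio.
#' @param control_copies Copy number of the gene in the control (>= 1).
#' @param tolerance Maximum distance, in copies, for an unambiguous call.
#' @param allowed_states Integer vector of assignable copy numbers.
#' @return A list with `copies` (integer) and `ambiguous` (logical).
#' @export
ratio_to_copies <- function(ratio, control_copies, tolerance = 0.35,
                            allowed_states = 0:3) {
  if (ratio < 0) stop("ratio_to_copies: ratio must be >= 0", call. = FALSE)
  if (control_copies < 1) {
    stop("ratio_to_copies: control_copies must be >= 1", call. = FALSE)
  }
  candidate <- ratio * control_copies
  allowed_states <- sort(unique(as.integer(allowed_states)))
  nearest <- allowed_states[which.min(abs(allowed_states - candidate))]
  list(copies = nearest, ambiguous = abs(candidate - nearest) > tolerance)
}

flag_string <- function(...) {
  f <- c(...)
  paste(f[nzchar(f)], collapse = ";")
}

#' Call copy numbers from derivative peak heights
#'
#' For every sample in the run: smooth, differentiate, detect per-amplicon
#' peaks, form the control-normalized peak ratio for each target gene, and
#' snap `ratio * 2` (the control's assumed per-target copy number, equal to
#' the panel's reference copy number) to the nearest allowed state. Absence is
#' decided on the scale-free target/reference height ratio: a target whose
#' ratio falls below `absence_frac` times the control's ratio for the same
#' gene is called 0 copies with an `absent_target` flag. The control's own
#' call must come out wild type — a run whose anchor fails its QC gate raises
#' an error rather than producing silently shifted calls.
#'
#' @param run A [melt_run()].
#' @param panel An [amplicon_panel()].
#' @param tolerance Copy-unit tolerance for unambiguous calls.
#' @param absence_frac Fraction of the control's target/reference height ratio
#'   below which a target is called absent.
#' @param smooth_window,smooth_order Savitzky-Golay parameters applied before
#'   differentiation.
#' @return A tibble of calls: `sample_id`, `method`, `hba1_copies`,
#'   `hba2_copies`, `stage1_ratio`, `stage2_ratio`, `flags`
#'   (semicolon-separated; empty when clean), `interpretation`.
#' @export
call_by_peaks <- function(run, panel, tolerance = 0.35, absence_frac = 0.1,
                          smooth_window = 7L, smooth_order = 2L) {
  stopifnot(inherits(run, "melt_run"), inherits(panel, "amplicon_panel"))
  peaksets <- lapply(run$curves, function(cv) {
    detect_peaks(
      negative_derivative(smooth_curve(cv, smooth_window, smooth_order)),
      panel, absence_frac = absence_frac
    )
  })
  control <- peaksets[[run$control_sample_id]]
  t1 <- panel$target_genes[1L]
  t2 <- panel$target_genes[2L]
  ref_copies <- panel$reference_copies

  ctl_rel <- function(ps, gene) {
    ref_h <- ps$peaks$height[ps$peaks$gene == panel$reference_gene]
    ps$peaks$height[ps$peaks$gene == gene] / ref_h
  }

  call_one <- function(ps) {
    flags <- character(0)
    res <- lapply(c(t1, t2), function(gene) {
      # scale-free absence test against the control's target/reference ratio
      absent <- ctl_rel(ps, gene) < absence_frac * ctl_rel(control, gene)
      ratio <- if (absent) 0 else normalized_peak_ratio(control, ps, gene)
      rc <- ratio_to_copies(ratio, ref_copies, tolerance,
                            panel$allowed_copy_states)
      if (absent) rc <- list(copies = 0L, ambiguous = FALSE)
      list(ratio = ratio, copies = rc$copies, ambiguous = rc$ambiguous,
           absent = absent)
    })
    if (res[[1L]]$ambiguous || res[[2L]]$ambiguous) flags <- c(flags, "ambiguous")
    if (res[[1L]]$absent || res[[2L]]$absent) flags <- c(flags, "absent_target")
    if (!(res[[1L]]$copies %in% panel$allowed_copy_states) ||
        res[[1L]]$ratio > 2.0) {
      flags <- c(flags, "improbable_reference")
    }
    tibble::tibble(
      sample_id = ps$sample_id, method = "peak_ratio",
      hba1_copies = as.integer(res[[1L]]$copies),
      hba2_copies = as.integer(res[[2L]]$copies),
      stage1_ratio = res[[1L]]$ratio, stage2_ratio = res[[2L]]$ratio,
      flags = flag_string(flags),
      interpretation = interpret_copy_pair(res[[1L]]$copies,
                                           res[[2L]]$copies)$label
    )
  }

  calls <- do.call(rbind, lapply(peaksets, call_one))
  ctl_call <- calls[calls$sample_id == run$control_sample_id, ]
  if (ctl_call$hba1_copies != ref_copies || ctl_call$hba2_copies != ref_copies) {
    stop("call_by_peaks: control sample '", run$control_sample_id,
         "' does not call as wild type (", ctl_call$hba1_copies, ", ",
         ctl_call$hba2_copies, ") - run QC failure", call. = FALSE)
  }
  rownames(calls) <- NULL
  calls
}

#' Call copy numbers by two-stage normalization-window analysis
#'
#' The visual method made computable. Stage 1 normalizes every curve between
#' a window below the reference melt and one beyond the first-target melt;
#' the inter-melt plateau then reads \eqn{p_1 = A_{t1}/(A_{ref}+A_{t1})}, so
#' the plateau odds \eqn{p_1/(1-p_1) = A_{t1}/A_{ref}}. The odds ratio of
#' unknown to control cancels per-copy amplitudes, and — because the
#' reference is assumed two-copy, making the wild-type control carry two
#' copies of each target — `odds ratio x 2` is the candidate HBA1 copy
#' number. Stage 2 repeats this between the two target melts: its odds ratio
#' estimates \eqn{(c_{t2}/c_{t1})_{unknown} / (c_{t2}/c_{t1})_{control}}, and
#' with HBA1 already resolved, HBA2 follows sequentially. A stage plateau at
#' or below `absence_threshold` short-circuits to 0 copies; a stage-2 plateau
#' indistinguishable from 1 (degenerate odds, possible only when the
#' first-target amplitude vanishes) is flagged ambiguous.
#'
#' @param run A [melt_run()].
#' @param panel An [amplicon_panel()].
#' @param tolerance Copy-unit tolerance for unambiguous calls.
#' @param absence_threshold Plateau fraction at or below which the stage's
#'   distal gene is called absent (0 copies).
#' @param windows1,windows2 Optional manual [normalization_windows()] for the
#'   two stages; placed automatically from the control when `NULL`.
#' @return A tibble of calls in the same shape as [call_by_peaks()], with
#'   `method = "window_ratio"`; `stage1_ratio`/`stage2_ratio` are the stage
#'   odds ratios.
#' @export
call_by_windows <- function(run, panel, tolerance = 0.35,
                            absence_threshold = 0.05,
                            windows1 = NULL, windows2 = NULL) {
  stopifnot(inherits(run, "melt_run"), inherits(panel, "amplicon_panel"))
  if (is.null(windows1)) windows1 <- place_windows(run, panel, stage = 1L)
  if (is.null(windows2)) windows2 <- place_windows(run, panel, stage = 2L)
  ref_copies <- panel$reference_copies

  plateaus <- lapply(run$curves, function(cv) {
    c(p1 = plateau_height(normalize_between(cv, windows1), panel, 1L)$plateau_fraction,
      p2 = plateau_height(normalize_between(cv, windows2), panel, 2L)$plateau_fraction)
  })
  ctl <- plateaus[[run$control_sample_id]]
  odds <- function(p) p / (1 - p)
  if (ctl[["p1"]] >= 1 || ctl[["p2"]] >= 1) {
    stop("call_by_windows: control plateau is degenerate (fraction 1)",
         call. = FALSE)
  }

  call_one <- function(id) {
    p <- plateaus[[id]]
    flags <- character(0)

    # stage 1: HBA1 against the two-copy reference
    if (p[["p1"]] <= absence_threshold) {
      hba1 <- 0L; amb1 <- FALSE; r1 <- 0
      flags <- c(flags, "absent_target")
    } else if (p[["p1"]] >= 1) {
      r1 <- Inf; hba1 <- max(panel$allowed_copy_states); amb1 <- TRUE
    } else {
      r1 <- odds(p[["p1"]]) / odds(ctl[["p1"]])
      rc <- ratio_to_copies(r1, ref_copies, tolerance, panel$allowed_copy_states)
      hba1 <- rc$copies; amb1 <- rc$ambiguous
    }

    # stage 2: HBA2 from the target:target odds ratio, HBA1 already resolved
    if (p[["p2"]] <= absence_threshold) {
      hba2 <- 0L; amb2 <- FALSE; r2 <- 0
      flags <- c(flags, "absent_target")
    } else if (p[["p2"]] >= 1 || hba1 == 0L) {
      # degenerate odds: no first-target amplitude to ratio against
      r2 <- if (p[["p2"]] >= 1) Inf else odds(p[["p2"]]) / odds(ctl[["p2"]])
      hba2 <- hba1; amb2 <- TRUE
    } else {
      r2 <- odds(p[["p2"]]) / odds(ctl[["p2"]])
      rc <- ratio_to_copies(r2 * hba1, 1, tolerance, panel$allowed_copy_states)
      hba2 <- rc$copies; amb2 <- rc$ambiguous
    }

    if (amb1 || amb2) flags <- c(flags, "ambiguous")
    if (!(hba1 %in% panel$allowed_copy_states) || (is.finite(r1) && r1 > 2.0)) {
      flags <- c(flags, "improbable_reference")
    }
    tibble::tibble(
      sample_id = id, method = "window_ratio",
      hba1_copies = as.integer(hba1), hba2_copies = as.integer(hba2),
      stage1_ratio = r1, stage2_ratio = r2,
      flags = flag_string(unique(flags)),
      interpretation = interpret_copy_pair(hba1, hba2)$label
    )
  }

  calls <- do.call(rbind, lapply(names(run$curves), call_one))
  ctl_call <- calls[calls$sample_id == run$control_sample_id, ]
  if (ctl_call$hba1_copies != ref_copies || ctl_call$hba2_copies != ref_copies) {
    stop("call_by_windows: control sample '", run$control_sample_id,
         "' does not call as wild type - run QC failure", call. = FALSE)
  }
  rownames(calls) <- NULL
  calls
}

#' Interpret an (HBA1, HBA2) copy pair as a genotype class
#'
#' The assay sees copy numbers, not breakpoints, so each pair maps to a
#' deletion/duplication *pattern*; allele-level identity needs confirmatory
#' testing (gap-PCR or MLPA). Every label carries the assay's standing
#' caveats: the hybrid gene of the -a3.7 deletion types as an HBA1 copy, the
#' -(a)20.5 deletion appears as loss of HBA2 only, and point mutations do not
#' change copy numbers.
#'
#' @param hba1,hba2 Nonnegative integer copy numbers.
#' @return A list with `copy_pair`, `label` and `caveats` (character vector).
#' @export
interpret_copy_pair <- function(hba1, hba2) {
  hba1 <- as.integer(hba1); hba2 <- as.integer(hba2)
  if (is.na(hba1) || is.na(hba2) || hba1 < 0L || hba2 < 0L) {
    stop("interpret_copy_pair: copies must be nonnegative integers",
         call. = FALSE)
  }
  key <- paste(hba1, hba2, sep = ":")
  labels <- c(
    "2:2" = "normal alpha-globin copy number (point mutations not excluded)",
    "2:1" = "single-gene deletion pattern (alpha+ heterozygote, e.g. -a3.7/aa or -a4.2/aa)",
    "2:0" = "two-gene deletion in trans pattern (-a/-a)",
    "1:1" = "alpha0 deletion heterozygote pattern (aa/--)",
    "1:0" = "three-gene deletion / Hb H disease pattern (-a/--)",
    "2:3" = "alpha-gene duplication pattern (aa/aaa)",
    "0:0" = "four-gene deletion pattern (--/--)"
  )
  label <- if (key %in% names(labels)) unname(labels[key]) else
    "atypical copy-number pattern - confirm with alternative primers or MLPA"
  caveats <- c(
    "the hybrid gene of the -a3.7 deletion carries the HBA1 primer site and is counted as an HBA1 copy",
    "the -(a)20.5 deletion spares the HBA1 3' end and is detected as loss of HBA2 only",
    "point mutations do not alter copy numbers and are not excluded by this assay"
  )
  list(copy_pair = c(hba1 = hba1, hba2 = hba2), label = label,
       caveats = caveats)
}

#' Write / read a calls CSV
#'
#' @param calls A calls tibble from [call_by_peaks()] or [call_by_windows()].
#' @param path File path.
#' @return `write_calls_csv` invisibly returns `path`; `read_calls_csv` the
#'   calls tibble.
#' @export
write_calls_csv <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_calls_csv
#' @export
read_calls_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_calls_csv: file not found: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$flags[is.na(x$flags)] <- ""
  tibble::as_tibble(x)
}
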