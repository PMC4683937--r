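#' Define an amplicon panel for melt-based copy-number analysis
#'
#' An amplicon panel describes the multiplex assay: one reference amplicon of
#' known copy number (CLCN7 in the bundled alpha-globin panel) and one or more
#' target amplicons whose copy numbers are to be inferred, each with a product
#' melting temperature, a melt transition width (used by the simulator), a
#' per-copy signal amplitude, and a peak-assignment window half-width.
#'
#' @param amplicons A data frame with columns `gene` (character), `tm_c`
#'   (product melting temperature, degrees C), `width_c` (logistic melt
#'   transition width, degrees C; simulator parameter), `per_copy_amplitude`
#'   (dimensionless signal contributed by one gene copy) and `window_c`
#'   (half-width, degrees C, of the window used to assign derivative peaks to
#'   this amplicon). Rows are sorted by `tm_c` on construction.
#' @param reference_gene Name of the reference amplicon; must be the
#'   lowest-melting amplicon, as in the alpha-globin assay design.
#' @param reference_copies Integer copy number assumed for the reference gene
#'   (and for each target gene in the wild-type control); default 2.
#' @param target_genes Character vector of target gene names in resolution
#'   order (first target resolved against the reference, second against the
#'   first, and so on). Defaults to all non-reference amplicons in Tm order.
#' @param allowed_copy_states Integer vector of copy numbers a target gene may
#'   be assigned; default `0:3`.
#'
#' @return An object of class `amplicon_panel`.
#' @examples
#' panel <- default_panel()
#' panel$amplicons$tm_c # 79.4 82.2 85.2
#' @export
amplicon_panel <- function(amplicons,
                           reference_gene,
                           reference_copies = 2L,
                           target_genes = NULL,
                           allowed_copy_states = 0:3) {
  required <- c("gene", "tm_c", "width_c", "per_copy_amplitude", "window_c")
  missing_cols <- setdiff(required, names(amplicons))
  if (length(missing_cols) > 0) {
    stop("panel configuration: amplicons table lacks field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  amplicons <- tibble::as_tibble(amplicons[required])
  amplicons$gene <- as.character(amplicons$gene)
  for (col in c("tm_c", "width_c", "per_copy_amplitude", "window_c")) {
    if (!is.numeric(amplicons[[col]]) || anyNA(amplicons[[col]])) {
      stop("panel configuration: field '", col, "' must be numeric and complete",
           call. = FALSE)
    }
  }
  amplicons <- amplicons[order(amplicons$tm_c), ]

  if (anyDuplicated(amplicons$gene)) {
    stop("panel configuration: duplicate gene names", call. = FALSE)
  }
  if (any(amplicons$width_c <= 0)) {
    stop("panel configuration: field 'width_c' must be > 0", call. = FALSE)
  }
  if (any(amplicons$per_copy_amplitude <= 0)) {
    stop("panel configuration: field 'per_copy_amplitude' must be > 0", call. = FALSE)
  }
  if (any(amplicons$window_c <= 0)) {
    stop("panel configuration: field 'window_c' must be > 0", call. = FALSE)
  }
  if (!reference_gene %in% amplicons$gene) {
    stop("panel configuration: reference gene '", reference_gene,
         "' not among amplicons", call. = FALSE)
  }
  if (amplicons$gene[1L] != reference_gene) {
    stop("panel configuration: reference gene must be the lowest-Tm amplicon",
         call. = FALSE)
  }
  reference_copies <- as.integer(reference_copies)
  if (is.na(reference_copies) || reference_copies < 1L) {
    stop("panel configuration: reference_copies must be a positive integer",
         call. = FALSE)
  }
  if (is.null(target_genes)) {
    target_genes <- setdiff(amplicons$gene, reference_gene)
  }
  if (!all(target_genes %in% amplicons$gene)) {
    stop("panel configuration: unknown target gene(s): ",
         paste(setdiff(target_genes, amplicons$gene), collapse = ", "),
         call. = FALSE)
  }
  allowed_copy_states <- sort(unique(as.integer(allowed_copy_states)))
  if (anyNA(allowed_copy_states) || any(allowed_copy_states < 0L)) {
    stop("panel configuration: allowed_copy_states must be nonnegative integers",
         call. = FALSE)
  }

  # peak assignment windows of distinct amplicons must not overlap
  n <- nrow(amplicons)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      gap <- amplicons$tm_c[i + 1L] - amplicons$tm_c[i]
      if (gap < amplicons$window_c[i] + amplicons$window_c[i + 1L]) {
        stop("panel validation: assignment windows of '", amplicons$gene[i],
             "' and '", amplicons$gene[i + 1L], "' overlap (Tm gap ",
             format(gap), " degrees C)", call. = FALSE)
      }
    }
  }

  structure(
    list(
      amplicons = amplicons,
      reference_gene = reference_gene,
      reference_copies = reference_copies,
      target_genes = as.character(target_genes),
      allowed_copy_states = allowed_copy_states
    ),
    class = "amplicon_panel"
  )
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("Amplicon panel:", nrow(x$amplicons), "amplicons\n")
  cat("  reference:", x$reference_gene, "(", x$reference_copies, "copies )\n")
  cat("  targets:  ", paste(x$target_genes, collapse = ", "), "\n")
  print(x$amplicons)
  invisible(x)
}

#' The bundled alpha-globin panel
#'
#' Three amplicons: the CLCN7 two-copy reference (product Tm 79.4 degrees C)
#' and the HBA1 (82.2 degrees C) and HBA2 (85.2 degrees C) targets, melting
#' roughly 3 degrees C apart so their derivative peaks and inter-melt plateaus
#' are separable on a 0.2 degrees C acquisition grid.
#'
#' @return An `amplicon_panel`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "alpha_globin_panel.yaml",
                         package = "gracepcr", mustWork = TRUE))
}

#' Load an amplicon panel from a YAML configuration file
#'
#' The file has top-level keys `reference`, `reference_copies`, `targets`,
#' optionally `allowed_copy_states`, and `amplicons`: a list of mappings with
#' keys `name`, `tm_c`, `width_c`, `per_copy_amplitude`, `window_c`. Alternate
#' primer panels are supported by supplying a different file; no code changes
#' are needed.
#'
#' @param path Path to a YAML panel configuration.
#' @return An `amplicon_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) {
    stop("panel configuration: file not found: ", path, call. = FALSE)
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("panel configuration: cannot parse '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  for (key in c("reference", "amplicons")) {
    if (is.null(cfg[[key]])) {
      stop("panel configuration: missing field '", key, "' in ", path,
           call. = FALSE)
    }
  }
  amp <- lapply(cfg$amplicons, function(a) {
    for (key in c("name", "tm_c", "width_c", "per_copy_amplitude", "window_c")) {
      if (is.null(a[[key]])) {
        stop("panel configuration: amplicon entry missing field '", key, "'",
             call. = FALSE)
      }
    }
    data.frame(gene = a$name, tm_c = a$tm_c, width_c = a$width_c,
               per_copy_amplitude = a$per_copy_amplitude, window_c = a$window_c)
  })
  amplicon_panel(
    amplicons = do.call(rbind, amp),
    reference_gene = cfg$reference,
    reference_copies = if (is.null(cfg$reference_copies)) 2L else cfg$reference_copies,
    target_genes = if (is.null(cfg$targets)) NULL else unlist(cfg$targets),
    allowed_copy_states = if (is.null(cfg$allowed_copy_states)) 0:3 else
      unlist(cfg$allowed_copy_states)
  )
}
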