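#' A single sample's raw melt curve
#'
#' @param sample_id Sample identifier.
#' @param temperatures_c Strictly increasing temperature grid in degrees C
#'   with a constant step (to 1e-6 degrees C) and at least 20 points.
#' @param fluorescence Nonnegative fluorescence values, one per grid point.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(sample_id, temperatures_c, fluorescence) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) != 1L || is.na(sample_id) || !nzchar(sample_id)) {
    stop("melt_curve: sample_id must be a non-empty string", call. = FALSE)
  }
  temperatures_c <- as.numeric(temperatures_c)
  fluorescence <- as.numeric(fluorescence)
  n <- length(temperatures_c)
  if (n < 20L) {
    stop("melt_curve: grid must have at least 20 points (got ", n, ")",
         call. = FALSE)
  }
  if (length(fluorescence) != n) {
    stop("melt_curve: fluorescence length (", length(fluorescence),
         ") != grid length (", n, ")", call. = FALSE)
  }
  steps <- diff(temperatures_c)
  if (any(steps <= 0)) {
    stop("melt_curve: temperature grid must be strictly increasing",
         call. = FALSE)
  }
  if (max(steps) - min(steps) > 1e-6) {
    stop("melt_curve: temperature grid step must be constant (1e-6 tolerance)",
         call. = FALSE)
  }
  if (anyNA(fluorescence) || any(fluorescence < 0)) {
    stop("melt_curve: fluorescence must be nonnegative and complete",
         call. = FALSE)
  }
  structure(
    list(sample_id = sample_id,
         temperatures_c = temperatures_c,
         fluorescence = fluorescence),
    class = "melt_curve"
  )
}

#' @export
print.melt_curve <- function(x, ...) {
  cat("Melt curve '", x$sample_id, "': ", length(x$temperatures_c),
      " points, ", format(min(x$temperatures_c)), "-",
      format(max(x$temperatures_c)), " degrees C\n", sep = "")
  invisible(x)
}

#' A melt run: a set of curves on one shared grid plus a wild-type control
#'
#' Every per-run quantification is anchored on one designated wild-type
#' control sample, so the control must be present and all curves must share an
#' identical temperature grid (both calling methods compare curves pointwise).
#'
#' @param curves List of `melt_curve` objects.
#' @param control_sample_id Sample id of the designated wild-type control.
#' @param run_id Run identifier.
#' @return An object of class `melt_run`.
#' @export
melt_run <- function(curves, control_sample_id, run_id = "run") {
  if (length(curves) == 0L) {
    stop("melt_run: a run must contain at least one curve", call. = FALSE)
  }
  if (!all(vapply(curves, inherits, logical(1), "melt_curve"))) {
    stop("melt_run: curves must be melt_curve objects", call. = FALSE)
  }
  ids <- vapply(curves, function(x) x$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("melt_run: duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(curves) <- ids
  grid <- curves[[1L]]$temperatures_c
  same <- vapply(curves, function(x) {
    length(x$temperatures_c) == length(grid) &&
      all(abs(x$temperatures_c - grid) <= 1e-9)
  }, logical(1))
  if (!all(same)) {
    stop("melt_run: all curves must share an identical temperature grid ",
         "(offending: ", paste(ids[!same], collapse = ", "), ")",
         call. = FALSE)
  }
  control_sample_id <- as.character(control_sample_id)
  if (!control_sample_id %in% ids) {
    stop("melt_run: control sample '", control_sample_id,
         "' not present in the run", call. = FALSE)
  }
  structure(
    list(run_id = as.character(run_id),
         curves = curves,
         control_sample_id = control_sample_id),
    class = "melt_run"
  )
}

#' @export
print.melt_run <- function(x, ...) {
  cat("Melt run '", x$run_id, "': ", length(x$curves), " samples, control '",
      x$control_sample_id, "'\n", sep = "")
  invisible(x)
}

#' Read a melt run from CSV
#'
#' Dialect: UTF-8, comma-separated, header `temperature_c,<id1>,<id2>,...`,
#' optionally followed by a line `#control=<sample_id>` designating the
#' wild-type control, then one row per temperature point. If no control line
#' is present, `control` must be supplied.
#'
#' @param path Path to a melt CSV file.
#' @param control Control sample id, overriding any `#control=` line.
#' @return A `melt_run`.
#' @export
read_melt_csv <- function(path, control = NULL) {
  if (!file.exists(path)) {
    stop("read_melt_csv: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    stop("read_melt_csv: '", path, "' has no data rows", call. = FALSE)
  }
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "temperature_c" || length(header) < 2L) {
    stop("read_melt_csv: header must be 'temperature_c,<sample ids>' (line 1)",
         call. = FALSE)
  }
  body_start <- 2L
  if (startsWith(lines[2L], "#control=")) {
    if (is.null(control)) control <- sub("^#control=", "", lines[2L])
    body_start <- 3L
  }
  if (is.null(control)) {
    stop("read_melt_csv: no control designated (no '#control=' line and no ",
         "'control' argument)", call. = FALSE)
  }
  body <- lines[seq(body_start, length(lines))]
  body <- body[nzchar(body)]
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop("read_melt_csv: row ", bad + body_start - 1L, " has ", nf[bad],
         " fields, expected ", length(header), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                nrow = length(body), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1L]
    stop("read_melt_csv: non-numeric value in data row ", bad, call. = FALSE)
  }
  temps <- mat[, 1L]
  if (any(diff(temps) <= 0)) {
    stop("read_melt_csv: temperature column must be strictly increasing",
         call. = FALSE)
  }
  ids <- header[-1L]
  curves <- lapply(seq_along(ids), function(j) {
    melt_curve(ids[j], temps, mat[, j + 1L])
  })
  melt_run(curves, control_sample_id = control,
           run_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a melt run to CSV
#'
#' Inverse of [read_melt_csv()]: values survive a round trip to better than
#' 1e-9.
#'
#' @param run A `melt_run`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_melt_csv <- function(run, path) {
  stopifnot(inherits(run, "melt_run"))
  grid <- run$curves[[1L]]$temperatures_c
  num <- function(x) formatC(x, format = "g", digits = 15)
  header <- paste(c("temperature_c", names(run$curves)), collapse = ",")
  control_line <- paste0("#control=", run$control_sample_id)
  cols <- vapply(run$curves, function(cv) num(cv$fluorescence),
                 character(length(grid)))
  rows <- apply(cbind(num(grid), cols), 1L, paste, collapse = ",")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, control_line, rows), con)
  invisible(path)
}
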