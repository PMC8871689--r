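#' Read a time series from a delimited text file
#'
#' Reads one numeric column of a CSV (or TSV) file with a header row into
#' an [FnirsSignal-class]. The sampling rate is declared, never inferred;
#' row order is preserved.
#'
#' @param path path to the file.
#' @param fs sampling rate in Hz.
#' @param column column name to read; defaults to the first column.
#' @param kind signal kind, see [FnirsSignal()].
#' @param sep field separator; default `","`.
#' @return an [FnirsSignal-class].
#' @export
readTimeSeries <- function(path, fs, column = NULL, kind = "hemoglobin",
                           sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop(sprintf("empty file: %s", path))
  if (is.null(column)) column <- colnames(df)[1L]
  if (!(column %in% colnames(df)))
    stop(sprintf("column '%s' not found in %s (have: %s)", column, path,
                 paste(colnames(df), collapse = ", ")))
  raw <- df[[column]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                 raw[bad], column, bad, path))
  }
  FnirsSignal(vals, fs = fs, label = column, kind = kind)
}

#' Write a time series to CSV
#'
#' One sample per row, full double precision (17 significant digits), so a
#' read/write round trip is bit-for-bit lossless.
#'
#' @param path output path.
#' @param x numeric vector or [FnirsSignal-class].
#' @param column column name; defaults to the signal label (or `"value"`).
#' @export
writeTimeSeries <- function(path, x, column = NULL) {
  v <- sigValues(x)
  if (is.null(column))
    column <- if (is(x, "FnirsSignal") && nzchar(sigLabel(x)))
      sigLabel(x) else "value"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(column, con)
  writeLines(formatC(v, digits = 17, format = "g"), con)
  invisible(path)
}

#' Write an artifact annotation to CSV (plus a JSON mirror)
#'
#' One record per segment with `start_seconds`, `end_seconds` (half-open in
#' time: a segment of samples `s..e` maps to `[(s-1)/fs, e/fs)`),
#' `category` and `source`. A machine-readable JSON mirror carrying the
#' same records plus `n_samples` and `fs` is written next to the CSV
#' (extension `.json`).
#'
#' @param path output CSV path.
#' @param annotation an [ArtifactAnnotation-class].
#' @param fs sampling rate in Hz used for the seconds conversion.
#' @return invisibly, the CSV path.
#' @export
writeAnnotation <- function(path, annotation, fs) {
  stopifnot(is(annotation, "ArtifactAnnotation"))
  validObject(annotation)
  df <- annotationToDf(annotation)
  out <- data.frame(start_seconds = (df$start - 1) / fs,
                    end_seconds = df$end / fs,
                    category = df$category, source = df$source,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines("start_seconds,end_seconds,category,source", con)
  if (nrow(out) > 0L)
    writeLines(sprintf("%s,%s,%s,%s",
                       formatC(out$start_seconds, digits = 17, format = "g"),
                       formatC(out$end_seconds, digits = 17, format = "g"),
                       out$category, out$source), con)
  close(con)
  jsonPath <- sub("\\.[^.]*$", "", path)
  jsonlite::write_json(
    list(n_samples = annotation@nSamples, fs = fs, segments = out),
    paste0(jsonPath, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an artifact annotation written by [writeAnnotation()]
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz.
#' @param nSamples length of the annotated signal.
#' @return an [ArtifactAnnotation-class].
#' @export
readAnnotation <- function(path, fs, nSamples) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_seconds", "end_seconds", "category", "source")
  if (!all(need %in% colnames(df)))
    stop(sprintf("annotation file %s lacks columns: %s", path,
                 paste(setdiff(need, colnames(df)), collapse = ", ")))
  ArtifactAnnotation(start = as.integer(round(df$start_seconds * fs)) + 1L,
                     end = as.integer(round(df$end_seconds * fs)),
                     category = df$category, source = df$source,
                     nSamples = nSamples)
}
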