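#' Construct an ArtifactAnnotation
#'
#' @param start,end integer vectors of 1-based closed segment bounds in
#'   samples (may be empty).
#' @param category character vector: `"severe"`, `"slight"` or
#'   `"baseline_shift"`.
#' @param source character vector (or scalar): `"fnirs"` or `"accel"`.
#' @param nSamples length of the annotated signal.
#' @return an [ArtifactAnnotation-class].
#' @examples
#' ArtifactAnnotation(start = 101, end = 150, category = "severe",
#'                    source = "fnirs", nSamples = 1000)
#' @export
ArtifactAnnotation <- function(start = integer(), end = integer(),
                               category = character(), source = character(),
                               nSamples) {
  n <- length(start)
  if (length(source) == 1L) source <- rep(source, n)
  if (length(category) == 1L) category <- rep(category, n)
  seg <- IRanges::IRanges(start = as.integer(start), end = as.integer(end))
  S4Vectors::mcols(seg) <- S4Vectors::DataFrame(
    category = as.character(category), source = as.character(source))
  o <- order(IRanges::start(seg), IRanges::end(seg))
  seg <- seg[o]
  obj <- new("ArtifactAnnotation", segments = seg,
             nSamples = as.integer(nSamples))
  validObject(obj)
  obj
}

#' @describeIn ArtifactAnnotation the segments as an `IRanges` with mcols.
#' @param x an `ArtifactAnnotation`.
#' @export
artifactSegments <- function(x) x@segments

#' @describeIn ArtifactAnnotation number of annotated samples.
#' @export
nSamples <- function(x) x@nSamples

#' @describeIn ArtifactAnnotation segments of one category, as an `IRanges`.
#' @param cat one of `"severe"`, `"slight"`, `"baseline_shift"`.
#' @export
segmentsOfCategory <- function(x, cat) {
  stopifnot(cat %in% .SEGMENT_CATEGORIES)
  x@segments[S4Vectors::mcols(x@segments)$category == cat]
}

#' @describeIn ArtifactAnnotation segments as a data.frame
#'   (`start`, `end`, `category`, `source`, in samples).
#' @export
annotationToDf <- function(x) {
  seg <- x@segments
  data.frame(start = IRanges::start(seg), end = IRanges::end(seg),
             category = S4Vectors::mcols(seg)$category,
             source = S4Vectors::mcols(seg)$source,
             stringsAsFactors = FALSE)
}

setMethod("show", "ArtifactAnnotation", function(object) {
  df <- annotationToDf(object)
  cat(sprintf("ArtifactAnnotation: %d segment(s) over %d samples\n",
              nrow(df), object@nSamples))
  if (nrow(df) > 0) {
    tab <- table(df$category)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(NULL)
})

## logical mask (length nSamples) covered by any segment of given categories
annotationMask <- function(x, categories = c("severe", "slight")) {
  mask <- logical(x@nSamples)
  seg <- x@segments
  keep <- S4Vectors::mcols(seg)$category %in% categories
  seg <- seg[keep]
  for (i in seq_along(seg))
    mask[IRanges::start(seg)[i]:IRanges::end(seg)[i]] <- TRUE
  mask
}
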