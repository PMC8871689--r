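#' Construct an FnirsSignal
#'
#' @param values numeric vector of samples (finite, length >= 1).
#' @param fs sampling rate in Hz.
#' @param label channel name.
#' @param kind signal kind: `"hemoglobin"` (µmol/L), `"optical_density"`,
#'   or `"acceleration"` (g).
#' @return an [FnirsSignal-class] object.
#' @examples
#' FnirsSignal(sin(seq(0, 10, by = 0.1)), fs = 10, label = "hbo2")
#' @export
FnirsSignal <- function(values, fs, label = "", kind = "hemoglobin") {
  obj <- new("FnirsSignal", values = as.numeric(values), fs = as.numeric(fs),
             label = as.character(label), kind = as.character(kind))
  validObject(obj)
  obj
}

#' @describeIn FnirsSignal sample values.
#' @param x an `FnirsSignal` (for `sigValues` and friends, any numeric
#'   vector is also accepted and returned as-is).
#' @export
sigValues <- function(x) {
  if (is(x, "FnirsSignal")) x@values else as.numeric(x)
}

#' @describeIn FnirsSignal sampling rate in Hz.
#' @export
samplingRate <- function(x) x@fs

#' @describeIn FnirsSignal channel label.
#' @export
sigLabel <- function(x) x@label

#' @describeIn FnirsSignal signal kind.
#' @export
signalKind <- function(x) x@kind

#' @describeIn FnirsSignal sample times in seconds, t0 = 0.
#' @export
timePoints <- function(x) (seq_along(x@values) - 1) / x@fs

#' @rdname FnirsSignal
#' @aliases length,FnirsSignal-method
#' @export
setMethod("length", "FnirsSignal", function(x) length(x@values))

setMethod("show", "FnirsSignal", function(object) {
  v <- object@values
  cat(sprintf("FnirsSignal '%s' (%s): %d samples @ %g Hz (%.1f s)\n",
              object@label, object@kind, length(v), object@fs,
              length(v) / object@fs))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g, sd %.4g\n",
              min(v), max(v), mean(v), stats::sd(v)))
  invisible(NULL)
})

## replace the values of a signal, keeping metadata
replaceValues <- function(x, values) {
  new("FnirsSignal", values = as.numeric(values), fs = x@fs,
      label = x@label, kind = x@kind)
}
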