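## Zero-phase Butterworth filtering. Very low cutoffs (0.003 Hz at 10 Hz
## sampling) make unpadded forward-backward filtering bleed long transients
## into the record, so the series is extended on both sides by symmetric
## (even) reflection before filtering; unlike odd reflection, this does not
## extrapolate the local trend, which a low-cutoff high-pass would otherwise
## turn into a large spurious transient.

zeroPhaseFilter <- function(x, fs, cutoff, type = c("high", "low"),
                            order = 3) {
  type <- match.arg(type)
  v <- sigValues(x)
  n <- length(v)
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop(sprintf("cutoff must lie in (0, fs/2) = (0, %g); got %g",
                 fs / 2, cutoff))
  filt <- signal::butter(order, cutoff / (fs / 2), type = type)
  # centring costs nothing (a high-pass rejects DC; a low-pass passes it
  # with unit gain and the mean is restored below) and removes the large
  # start-up transient a constant offset would otherwise excite
  mu <- mean(v)
  v <- v - mu
  pad <- min(n - 1L, as.integer(ceiling(2 * fs / cutoff)))
  if (pad > 0L) {
    pre <- v[(pad + 1L):2L]
    post <- v[(n - 1L):(n - pad)]
    vp <- c(pre, v, post)
  } else vp <- v
  f1 <- signal::filter(filt, vp)
  f2 <- rev(signal::filter(filt, rev(f1)))
  out <- f2[(pad + 1L):(pad + n)]
  if (type == "low") out <- out + mu
  if (is(x, "FnirsSignal")) replaceValues(x, out) else out
}

#' Zero-phase high-pass filter
#'
#' Order-3 Butterworth high-pass, applied forward and backward for zero
#' phase distortion (effective order 6). DC gain is 0; the passband gain is
#' within 5% of unity from about 3x the cutoff upward. Used as the final
#' pipeline stage at 0.003 Hz to keep the hemodynamic band of interest
#' (0.003-0.04 Hz) while discarding residual offsets left after
#' baseline-shift removal.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param fs sampling rate in Hz (taken from `x` if it is a signal object).
#' @param cutoff cutoff frequency in Hz, 0 < cutoff < fs/2.
#' @param order filter order of each pass; default 3.
#' @return filtered series, same type and length as `x`.
#' @examples
#' y <- highpass(rep(1, 500), fs = 10, cutoff = 0.1)  # DC removed
#' max(abs(y)) < 1e-6
#' @export
highpass <- function(x, fs = NULL, cutoff = 0.003, order = 3) {
  if (is(x, "FnirsSignal")) fs <- samplingRate(x)
  if (is.null(fs)) stop("'fs' is required for numeric input")
  zeroPhaseFilter(x, fs, cutoff, type = "high", order = order)
}
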