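#' Robust SD estimate of wavelet coefficients
#'
#' The detail coefficients of an artifact-free signal are modelled as
#' zero-mean Gaussian; artifacts contribute heavy outliers that would
#' inflate a moment estimate. The estimator sorts all coefficients
#' ascending and takes the absolute value at the 1-based index nearest
#' `0.1587 L` (clamped to `[1, L]`): for N(0, sigma^2) the 15.87th
#' percentile is -sigma, so this recovers sigma while ignoring the upper
#' tail where artifacts live.
#'
#' @param coeffs numeric vector of detail coefficients (all levels
#'   concatenated), length >= 1.
#' @return the estimated SD (>= 0).
#' @examples
#' estimateSigma(c(-2, 2))  # index round(0.3174) -> 1, so 2
#' @export
estimateSigma <- function(coeffs) {
  L <- length(coeffs)
  if (L < 1L) stop("empty coefficient vector")
  idx <- min(L, max(1L, as.integer(round(0.1587 * L))))
  abs(sort(coeffs)[idx])
}

#' Dual thresholds from the tail probability alpha
#'
#' `u` is the positive standard-normal deviate with two-sided tail mass
#' `alpha` (`P(|Z| > u) = alpha`, i.e. `u = qnorm(1 - alpha/2)`). The
#' processing threshold is `w2 = u * sigmaHat` and the detecting threshold
#' `w1 = 1.3 * w2`.
#'
#' @param alpha two-sided tail probability in (0, 1).
#' @param sigmaHat coefficient SD estimate from [estimateSigma()].
#' @return a [WaveletThresholds-class].
#' @examples
#' thresholdsFromAlpha(0.05, 1)  # u = 1.959964
#' @export
thresholdsFromAlpha <- function(alpha, sigmaHat) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  u <- qnorm(1 - alpha / 2)
  w2 <- u * abs(sigmaHat)
  obj <- new("WaveletThresholds", alpha = alpha, u = u,
             sigmaHat = abs(sigmaHat), w1 = 1.3 * w2, w2 = w2)
  validObject(obj)
  obj
}

#' Zero outlier runs of wavelet coefficients
#'
#' Scans the coefficients of one level in temporal order. Wherever
#' `|w| > w1` (detecting threshold), the outlier is expanded left and right
#' over every contiguous neighbour with `|w| > w2` (processing threshold),
#' stopping at the first coefficient at or below `w2`; the whole run is set
#' to zero. Coefficients in `(w2, w1]` with no triggering neighbour are
#' left untouched. Approximation coefficients are never passed through this
#' function.
#'
#' @param w numeric vector of one level's detail coefficients.
#' @param w1 detecting threshold (>= `w2`).
#' @param w2 processing threshold (>= 0).
#' @return the modified coefficient vector.
#' @examples
#' zeroOutliers(c(0, 2.1, 3.1, 2.1, 0.2), w1 = 3, w2 = 1)
#' @export
zeroOutliers <- function(w, w1, w2) {
  if (w1 < w2 || w2 < 0) stop("need w1 >= w2 >= 0")
  aw <- abs(w)
  above2 <- aw > w2
  if (!any(aw > w1)) return(w)
  r <- rle(above2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    if (any(aw[starts[i]:ends[i]] > w1))
      w[starts[i]:ends[i]] <- 0
  }
  w
}

#' Dual-threshold wavelet denoising with cyclic averaging
#'
#' For each shift `h = 1 ... K` the signal is circularly shifted, decomposed
#' with the configured mother wavelet, thresholded with [zeroOutliers()]
#' (thresholds from [estimateSigma()] over all detail levels and
#' [thresholdsFromAlpha()]), reconstructed and unshifted; the K results are
#' averaged. Cycle spinning suppresses the pseudo-Gibbs ringing a single
#' shift-variant DWT would leave near the zeroed singularities.
#'
#' The decomposition depth is chosen so the approximation band
#' `[0, fs/2^(M+1)]` still contains `bandTopHz`: the detail levels being
#' thresholded then carry only content above the hemodynamic band, and the
#' globally estimated sigma (whose order statistic would otherwise be
#' dominated by in-band coefficients) cannot trigger zeroing of the signal
#' band itself, which always lives in the untouched approximation.
#'
#' @param x numeric vector or [FnirsSignal-class] (typically after severe
#'   and baseline-shift correction).
#' @param config a [RunConfig-class]; `alpha`, `motherWavelet`, `K`,
#'   `bandTopHz` and `waveletLevel` are used.
#' @param fs sampling rate in Hz (taken from `x` if it is a signal object);
#'   needed for the band-derived depth. If unavailable and no explicit
#'   `waveletLevel` is configured, the deepest supported level is used.
#' @return denoised series, same type and length as `x`.
#' @export
dualThresholdDenoise <- function(x, config = runConfig(), fs = NULL) {
  if (is(x, "FnirsSignal")) fs <- samplingRate(x)
  v <- sigValues(x)
  n <- length(v)
  f <- waveletFilter(config@motherWavelet)
  level <- waveletDepth(n, length(f$lo), config, fs)
  if (level < 1L)
    stop("signal too short for one decomposition level")
  nPad <- as.integer(ceiling(n / 2^level) * 2^level)
  vp <- padBridge(v, nPad)
  acc <- numeric(nPad)
  K <- config@K
  for (h in seq_len(K)) {
    s <- h %% nPad
    vs <- if (s == 0L) vp else c(vp[(s + 1L):nPad], vp[1L:s])
    dec <- dwtDecompose(vs, config@motherWavelet, level = level)
    th <- thresholdsFromAlpha(config@alpha,
                              estimateSigma(unlist(dec@details)))
    dec@details <- lapply(dec@details, zeroOutliers, w1 = th@w1, w2 = th@w2)
    ys <- dwtReconstruct(dec)  # nPad samples (no further padding)
    acc <- acc + if (s == 0L) ys else c(ys[(nPad - s + 1L):nPad],
                                        ys[1L:(nPad - s)])
  }
  out <- (acc / K)[seq_len(n)]
  if (is(x, "FnirsSignal")) replaceValues(x, out) else out
}

#' Run the full correction pipeline
#'
#' Detection (fNIRS strategy) followed by the three correction stages and
#' the final high-pass filter: `x -> x1` (severe-oscillation spline
#' correction), `x1 -> x2` (baseline-shift removal with DC re-anchoring),
#' `x2 -> x3` (dual-threshold wavelet denoising with cyclic averaging),
#' `x3 -> y` (zero-phase high-pass at `hpFinalHz`, default 0.003 Hz). All
#' intermediate stages are retrievable from the returned object.
#'
#' @param x an [FnirsSignal-class].
#' @param config a [RunConfig-class].
#' @param annotation optionally, a precomputed [ArtifactAnnotation-class]
#'   to use instead of running detection.
#' @return a [CorrectionResult-class].
#' @examples
#' ds <- injectArtifacts(generateClean(600, 10, seed = 1), seed = 2)
#' res <- correctPipeline(ds@noised)
#' correctedSignal(res)
#' @export
correctPipeline <- function(x, config = runConfig(), annotation = NULL) {
  stopifnot(is(x, "FnirsSignal"))
  fs <- samplingRate(x)
  if (is.null(annotation))
    annotation <- detectArtifacts(x, strategy = "fnirs", config = config)
  v <- sigValues(x)
  x1 <- correctSevere(v, annotation, p = config@pSevere)
  x2 <- removeBaselineShift(x1, annotation, fs = fs)
  x3 <- dualThresholdDenoise(x2, config = config, fs = fs)
  y <- highpass(x3, fs = fs, cutoff = config@hpFinalHz)
  new("CorrectionResult", input = x, annotation = annotation,
      x1 = x1, x2 = x2, x3 = x3,
      output = replaceValues(x, y), config = config)
}

#' @describeIn correctPipeline the corrected [FnirsSignal-class] y.
#' @param res a [CorrectionResult-class].
#' @export
correctedSignal <- function(res) res@output

#' @describeIn correctPipeline the annotation used for correction.
#' @export
usedAnnotation <- function(res) res@annotation

#' @describeIn correctPipeline an intermediate stage (`"x1"`, `"x2"`,
#'   `"x3"`) as a numeric vector.
#' @param stage stage name.
#' @export
stageSignal <- function(res, stage = c("x1", "x2", "x3")) {
  stage <- match.arg(stage)
  slot(res, stage)
}

setMethod("show", "CorrectionResult", function(object) {
  df <- annotationToDf(object@annotation)
  cat(sprintf("CorrectionResult: %d samples @ %g Hz; %d artifact segment(s)\n",
              length(object@input@values), object@input@fs, nrow(df)))
  invisible(NULL)
})
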