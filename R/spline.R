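#' Cubic smoothing spline (Reinsch form)
#'
#' Fits the natural cubic smoothing spline minimising
#' \deqn{p \sum_n w(n) |x(n) - f(n)|^2 + (1 - p) \int |D^2 f(t)|^2 dt}
#' with unit weights, over the sample-index abscissa (unit spacing), and
#' returns the fitted values at the samples. `p = 1` interpolates,
#' `p = 0` gives the least-squares straight line. For 0 < p < 1 the
#' Reinsch band system `(R + mu Q'Q) g = Q'y` with `mu = (1-p)/p` is solved
#' sparsely and the fit is `f = y - mu Q g`.
#'
#' @param y numeric vector (or [FnirsSignal-class]) of at least 4 samples.
#' @param p smoothing parameter in [0, 1].
#' @param x abscissa values; defaults to the 0-based sample index.
#' @return numeric vector of fitted values, same length as `y`.
#' @examples
#' y <- sin(seq(0, 2 * pi, length.out = 50)) + rnorm(50, sd = 0.1)
#' f <- smoothingSpline(y, p = 0.5)
#' @export
smoothingSpline <- function(y, p, x = NULL) {
  v <- sigValues(y)
  n <- length(v)
  if (n < 4L) stop("smoothing spline needs at least 4 points")
  if (!is.finite(p) || p < 0 || p > 1) stop("'p' must be in [0, 1]")
  if (is.null(x)) x <- seq_len(n) - 1
  if (length(x) != n) stop("'x' and 'y' must have equal length")
  if (p == 1) return(v)
  if (p == 0) return(as.numeric(fitted(lm(v ~ x))))
  h <- diff(x)
  if (any(h <= 0)) stop("'x' must be strictly increasing")
  m <- n - 2L
  i <- seq_len(m)
  Q <- Matrix::sparseMatrix(
    i = c(i, i + 1L, i + 2L), j = rep(i, 3L),
    x = c(1 / h[i], -1 / h[i] - 1 / h[i + 1L], 1 / h[i + 1L]),
    dims = c(n, m))
  diagR <- (h[i] + h[i + 1L]) / 3
  offR <- h[i + 1L][-m] / 6
  R <- Matrix::bandSparse(m, m, k = c(-1L, 0L, 1L),
                          diagonals = list(offR, diagR, offR))
  mu <- (1 - p) / p
  g <- Matrix::solve(R + mu * Matrix::crossprod(Q),
                     Matrix::crossprod(Q, v))
  as.numeric(v - mu * (Q %*% g))
}

#' Correct severe oscillations by spline subtraction
#'
#' Within each severe segment of the annotation, a near-interpolating cubic
#' smoothing spline (`p = 0.99` by default) is fitted to the raw signal and
#' subtracted, flattening the excursion. Samples outside severe segments
#' are returned bit-identical.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param annotation an [ArtifactAnnotation-class].
#' @param p smoothing parameter; default 0.99.
#' @return corrected series, same type and length as `x`.
#' @export
correctSevere <- function(x, annotation, p = 0.99) {
  v <- sigValues(x)
  out <- v
  seg <- segmentsOfCategory(annotation, "severe")
  for (i in seq_along(seg)) {
    idx <- IRanges::start(seg)[i]:IRanges::end(seg)[i]
    if (length(idx) < 4L) { out[idx] <- out[idx] - mean(v[idx]); next }
    out[idx] <- v[idx] - smoothingSpline(v[idx], p)
  }
  if (is(x, "FnirsSignal")) replaceValues(x, out) else out
}

#' Remove baseline shifts by spline subtraction with DC re-anchoring
#'
#' Within each baseline-shift segment, a heavily smoothed spline with
#' `p = 1/fs^3` is fitted and subtracted, and the fitted value at the
#' segment's first sample is added back so the segment rejoins the signal
#' at its pre-shift level. Samples outside baseline-shift segments are
#' unchanged; the residual offset between the segment's end and the
#' following samples is left to the final high-pass filter.
#'
#' @param x numeric vector or [FnirsSignal-class] (typically the output of
#'   [correctSevere()]).
#' @param annotation an [ArtifactAnnotation-class].
#' @param fs sampling rate in Hz (taken from `x` if it is a signal object).
#' @param p smoothing parameter; default `1/fs^3`.
#' @return corrected series, same type and length as `x`.
#' @export
removeBaselineShift <- function(x, annotation, fs = NULL, p = NULL) {
  if (is(x, "FnirsSignal")) fs <- samplingRate(x)
  if (is.null(fs)) stop("'fs' is required for numeric input")
  if (is.null(p)) p <- 1 / fs^3
  v <- sigValues(x)
  out <- v
  seg <- segmentsOfCategory(annotation, "baseline_shift")
  for (i in seq_along(seg)) {
    idx <- IRanges::start(seg)[i]:IRanges::end(seg)[i]
    if (length(idx) < 4L) next
    sS <- smoothingSpline(v[idx], p)
    out[idx] <- v[idx] - sS + sS[1L]
  }
  if (is(x, "FnirsSignal")) replaceValues(x, out) else out
}
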