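#' Signal-to-noise ratio against a known clean reference
#'
#' `10 log10( sum(x^2) / sum((other - x)^2) )` in dB, where `x` is the
#' clean reference and `other` either the noised or the processed signal.
#' A residual of exactly zero returns the `+Inf` sentinel (documented as
#' such in reports, never silently encoded as a number in files).
#'
#' @param clean,other numeric vectors or [FnirsSignal-class] objects of
#'   equal length; `clean` must not be identically zero.
#' @return SNR in dB (possibly `Inf`).
#' @examples
#' snr(sin(1:100), sin(1:100) + 0.1)
#' @export
snr <- function(clean, other) {
  x <- sigValues(clean)
  y <- sigValues(other)
  if (length(x) != length(y)) stop("inputs must have equal length")
  ps <- sum(x^2)
  if (ps == 0) stop("clean reference is identically zero")
  pn <- sum((y - x)^2)
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}

#' Pearson correlation between clean and processed signals
#'
#' @param clean,processed numeric vectors or [FnirsSignal-class] objects of
#'   equal length; both must be non-constant.
#' @return the sample Pearson correlation in [-1, 1].
#' @export
pearsonR <- function(clean, processed) {
  x <- sigValues(clean)
  y <- sigValues(processed)
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input")
  stats::cor(x, y)
}

#' Sliding-median baseline method
#'
#' One-dimensional median filter evaluated on a decimated grid (window
#' `width` samples, every `step` samples) and linearly interpolated back to
#' full length. Robustly removes impulsive artifacts while following the
#' slow baseline; used as a comparison method in [runBenchmark()].
#'
#' @param x numeric vector or [FnirsSignal-class], length >= `width`.
#' @param width window width in samples; default 600.
#' @param step evaluation stride in samples; default 10.
#' @return filtered series, same type and length as `x`.
#' @export
medianFilterBaseline <- function(x, width = 600, step = 10) {
  v <- sigValues(x)
  n <- length(v)
  if (n < width) stop(sprintf("series shorter than the window (%d < %d)",
                              n, width))
  half <- width %/% 2L
  centers <- unique(c(seq.int(1L, n, by = step), n))
  med <- vapply(centers, function(c0)
    median(v[max(1L, c0 - half):min(n, c0 + half)]), numeric(1))
  out <- approx(centers, med, xout = seq_len(n), rule = 2)$y
  if (is(x, "FnirsSignal")) replaceValues(x, out) else out
}

#' Single-threshold wavelet baseline method
#'
#' A reduced wavelet denoiser used as a comparison method: one DWT (no
#' cyclic averaging), a single threshold `w = u * sigmaHat` (so the
#' detecting and processing thresholds coincide), and each coefficient
#' judged independently with no neighbour expansion. Exhibits the known
#' weakness on baseline shifts that the dual-threshold method with spline
#' pre-correction avoids.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param alpha two-sided tail probability; default 0.05.
#' @param config a [RunConfig-class] supplying the mother wavelet.
#' @return processed series, same type and length as `x`.
#' @export
singleThresholdWaveletBaseline <- function(x, alpha = 0.05,
                                           config = runConfig(),
                                           fs = NULL) {
  if (is(x, "FnirsSignal")) fs <- samplingRate(x)
  v <- sigValues(x)
  f <- waveletFilter(config@motherWavelet)
  dec <- dwtDecompose(v, config@motherWavelet,
                      level = waveletDepth(length(v), length(f$lo),
                                           config, fs))
  th <- thresholdsFromAlpha(alpha, estimateSigma(unlist(dec@details)))
  dec@details <- lapply(dec@details, function(w) {
    w[abs(w) > th@w2] <- 0
    w
  })
  out <- dwtReconstruct(dec)
  if (is(x, "FnirsSignal")) replaceValues(x, out) else out
}

.BENCHMARK_METHODS <- c("proposed", "wavelet_single", "median_filter",
                        "spline_only", "identity")

## apply one named correction method to a noised signal
applyMethod <- function(method, noised, config) {
  switch(method,
    proposed = sigValues(correctedSignal(correctPipeline(noised,
                                                         config = config))),
    wavelet_single = sigValues(singleThresholdWaveletBaseline(
      noised, alpha = config@alpha, config = config)),
    median_filter = sigValues(medianFilterBaseline(noised)),
    spline_only = {
      ann <- detectArtifacts(noised, strategy = "fnirs", config = config)
      x1 <- correctSevere(sigValues(noised), ann, p = config@pSevere)
      removeBaselineShift(x1, ann, fs = samplingRate(noised))
    },
    identity = sigValues(noised),
    stop(sprintf("unknown method '%s'; available: %s", method,
                 paste(.BENCHMARK_METHODS, collapse = ", "))))
}

#' Benchmark correction methods on synthetic datasets
#'
#' Runs each method on each dataset's noised signal and scores it against
#' the clean reference with [snr()] and [pearsonR()].
#'
#' @param datasets list of [SyntheticDataset-class] objects, e.g. from
#'   [makeBenchmark()].
#' @param methods character vector of method names among
#'   `"proposed"`, `"wavelet_single"`, `"median_filter"`, `"spline_only"`,
#'   `"identity"`.
#' @param config a [RunConfig-class].
#' @return a data.frame with one row per dataset x method: `segment_id`,
#'   `method`, `snr_noised`, `snr_processed`, `r_noised`, `r` (the
#'   processed-signal correlation).
#' @export
runBenchmark <- function(datasets,
                         methods = c("proposed", "wavelet_single",
                                     "median_filter", "spline_only"),
                         config = runConfig()) {
  if (length(datasets) < 1L) stop("need at least one dataset")
  if (length(methods) < 1L) stop("need at least one method")
  rows <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    stopifnot(is(ds, "SyntheticDataset"))
    clean <- sigValues(ds@clean)
    noised <- sigValues(ds@noised)
    for (m in methods) {
      proc <- applyMethod(m, ds@noised, config)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = i, method = m,
        snr_noised = snr(clean, noised),
        snr_processed = snr(clean, proc),
        r_noised = pearsonR(clean, noised),
        r = pearsonR(clean, proc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarise a benchmark table per method
#'
#' @param tbl a data.frame from [runBenchmark()].
#' @return a data.frame with per-method means and SDs of the SNR and R
#'   columns.
#' @export
summariseBenchmark <- function(tbl) {
  out <- lapply(split(tbl, tbl$method), function(d) {
    data.frame(method = d$method[1L],
               n = nrow(d),
               snr_noised_mean = mean(d$snr_noised),
               snr_processed_mean = mean(d$snr_processed),
               snr_processed_sd = stats::sd(d$snr_processed),
               r_noised_mean = mean(d$r_noised),
               r_mean = mean(d$r),
               r_sd = stats::sd(d$r),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
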