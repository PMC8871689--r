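#' Synthetic artifact specification
#'
#' Parametrises [injectArtifacts()]. Amplitudes are in multiples of the
#' clean signal's SD. Defaults (per 600 s record): 3 spikes of 10 SD over
#' 2 s, 2 slow oscillations of 3 SD over 30 s, 2 baseline shifts of 3 SD
#' with a 1 s rise sustained to the end of the record, 30 s minimum gap.
#'
#' @param nSpikes,nSlow,nBS event counts.
#' @param spikeAmp,slowAmp,bsHeight amplitudes in clean-SD units.
#' @param spikeWidthS,slowWidthS event durations in seconds.
#' @param minGapS minimum spacing between events in seconds.
#' @return a validated [ArtifactSpec-class].
#' @export
artifactSpec <- function(nSpikes = 3L, nSlow = 2L, nBS = 2L,
                         spikeAmp = 10, slowAmp = 3, bsHeight = 3,
                         spikeWidthS = 2, slowWidthS = 30, minGapS = 30) {
  obj <- new("ArtifactSpec", nSpikes = as.integer(nSpikes),
             nSlow = as.integer(nSlow), nBS = as.integer(nBS),
             spikeAmp = spikeAmp, slowAmp = slowAmp, bsHeight = bsHeight,
             spikeWidthS = spikeWidthS, slowWidthS = slowWidthS,
             minGapS = minGapS)
  validObject(obj)
  obj
}

#' Generate a clean fNIRS-like signal
#'
#' A zero-mean unit-SD Gaussian process spectrally confined to the
#' hemodynamic band of interest (0.003-0.04 Hz), built by band-masking
#' white noise in the frequency domain, optionally with small cardiac
#' (~1.1 Hz) and respiratory (~0.3 Hz) sinusoids on top. Reproducible from
#' the seed.
#'
#' @param durationS duration in seconds; `durationS * fs >= 100`.
#' @param fs sampling rate in Hz; default 10.
#' @param seed integer seed, or `NA` to use the current RNG state.
#' @param band two-element numeric, pass band in Hz.
#' @param cardiacAmp,respAmp amplitudes (in SD units) of the physiological
#'   sinusoids; set to 0 to disable. Defaults 0.05 and 0.08.
#' @return an [FnirsSignal-class] of kind `"hemoglobin"`.
#' @examples
#' generateClean(300, 10, seed = 1)
#' @export
generateClean <- function(durationS, fs = 10, seed = NA_integer_,
                          band = c(0.003, 0.04),
                          cardiacAmp = 0.05, respAmp = 0.08) {
  n <- as.integer(round(durationS * fs))
  if (n < 100L) stop("need durationS * fs >= 100")
  withSeed(seed, {
    white <- rnorm(n)
    F <- fft(white)
    freq <- (seq_len(n) - 1L) * fs / n
    freq <- pmin(freq, fs - freq)  # two-sided
    keep <- freq >= band[1] & freq <= band[2]
    F[!keep] <- 0
    v <- Re(fft(F, inverse = TRUE)) / n
    v <- (v - mean(v)) / stats::sd(v)
    tt <- (seq_len(n) - 1L) / fs
    if (cardiacAmp > 0 && fs / 2 > 1.1)
      v <- v + cardiacAmp * sin(2 * pi * 1.1 * tt + runif(1, 0, 2 * pi))
    if (respAmp > 0 && fs / 2 > 0.3)
      v <- v + respAmp * sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi))
    FnirsSignal(v, fs = fs, label = "clean", kind = "hemoglobin")
  })
}

## place event windows of the given widths (samples) with at least gap
## samples between them and to the record edges; error if infeasible
placeEvents <- function(n, widths, gap) {
  k <- length(widths)
  if (k == 0L) return(integer())
  # draw in the gap-compressed space, then expand: exact and rejection-free
  nc <- n - sum(widths) - (k + 1L) * gap
  if (nc < k)
    stop("artifact spec infeasible for this duration: events and gaps do not fit")
  cpos <- sort(sample.int(nc, k))
  cw <- c(0L, cumsum(widths))[seq_len(k)]
  cpos + seq_len(k) * gap + cw
}

#' Inject synthetic artifacts into a clean signal
#'
#' Adds three artifact families to a clean record, with ground truth:
#' spikes (Gaussian-windowed 1-3 Hz bursts; severe), slow oscillations
#' (Hann-windowed 0.05-0.1 Hz excursions; slight), and baseline shifts
#' (a smoothed step with a 1 s rise, sustained to the end of the record;
#' the rise is annotated both as an oscillation and as a baseline_shift
#' segment). Injection is purely additive, so `noised - clean` is exactly
#' the injected noise.
#'
#' @param clean an [FnirsSignal-class], e.g. from [generateClean()].
#' @param spec an [ArtifactSpec-class].
#' @param seed integer seed, or `NA`.
#' @return a [SyntheticDataset-class].
#' @export
injectArtifacts <- function(clean, spec = artifactSpec(),
                            seed = NA_integer_) {
  stopifnot(is(clean, "FnirsSignal"))
  v <- sigValues(clean)
  fs <- samplingRate(clean)
  n <- length(v)
  sdClean <- stats::sd(v)
  withSeed(seed, {
    widths <- c(rep(as.integer(round(spec@spikeWidthS * fs)), spec@nSpikes),
                rep(as.integer(round(spec@slowWidthS * fs)), spec@nSlow),
                rep(as.integer(round(fs)), spec@nBS))  # BS truth = the rise
    types <- c(rep("spike", spec@nSpikes), rep("slow", spec@nSlow),
               rep("bs", spec@nBS))
    ord <- sample.int(length(widths))  # randomise placement order
    starts <- placeEvents(n, widths[ord], as.integer(round(spec@minGapS * fs)))
    types <- types[ord]; widths <- widths[ord]
    noise <- numeric(n)
    segStart <- integer(); segEnd <- integer(); segCat <- character()
    for (i in seq_along(starts)) {
      s <- starts[i]; w <- widths[i]
      idx <- s:(s + w - 1L)
      tt <- (idx - s) / fs
      if (types[i] == "spike") {
        env <- exp(-0.5 * ((tt - max(tt) / 2) / (max(tt) / 6))^2)
        carrier <- sin(2 * pi * runif(1, 1, 3) * tt + runif(1, 0, 2 * pi))
        noise[idx] <- noise[idx] + spec@spikeAmp * sdClean * env * carrier
        segStart <- c(segStart, s); segEnd <- c(segEnd, s + w - 1L)
        segCat <- c(segCat, "severe")
      } else if (types[i] == "slow") {
        # carrier above the hemodynamic band, well below the spike band
        env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1)))
        carrier <- sin(2 * pi * runif(1, 0.1, 0.3) * tt + runif(1, 0, 2 * pi))
        noise[idx] <- noise[idx] + spec@slowAmp * sdClean * env * carrier
        segStart <- c(segStart, s); segEnd <- c(segEnd, s + w - 1L)
        segCat <- c(segCat, "slight")
      } else {
        # smoothed step: raised-cosine rise over ~1 s, then sustained
        h <- sample(c(-1, 1), 1L) * spec@bsHeight * sdClean
        rise <- 0.5 * (1 - cos(pi * seq_along(idx) / length(idx)))
        noise[idx] <- noise[idx] + h * rise
        if (s + w <= n) noise[(s + w):n] <- noise[(s + w):n] + h
        segStart <- c(segStart, s, s); segEnd <- c(segEnd, s + w - 1L,
                                                   s + w - 1L)
        segCat <- c(segCat, "slight", "baseline_shift")
      }
    }
    truth <- ArtifactAnnotation(start = segStart, end = segEnd,
                                category = segCat, source = "fnirs",
                                nSamples = n)
    new("SyntheticDataset",
        clean = clean,
        noised = replaceValues(clean, v + noise),
        truth = truth,
        seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Generate a benchmark of independent synthetic datasets
#'
#' Draws `nSegments` independent clean records and artifact injections with
#' per-segment seeds derived from `seed`, reproducibly. The default
#' configuration (20 segments of 600 s at 10 Hz) is the package's
#' desk-scale stand-in for long-duration semi-simulated evaluation data.
#'
#' @param nSegments number of datasets; default 20.
#' @param durationS record duration in seconds; default 600.
#' @param fs sampling rate in Hz; default 10.
#' @param spec an [ArtifactSpec-class].
#' @param seed integer master seed.
#' @param ... further arguments passed to [generateClean()].
#' @return a list of [SyntheticDataset-class] objects.
#' @export
makeBenchmark <- function(nSegments = 20L, durationS = 600, fs = 10,
                          spec = artifactSpec(), seed = 1L, ...) {
  if (nSegments < 1L) stop("'nSegments' must be >= 1")
  seeds <- withSeed(seed, matrix(sample.int(2147483646L, 2L * nSegments),
                                 ncol = 2L))
  lapply(seq_len(nSegments), function(i) {
    clean <- generateClean(durationS, fs, seed = seeds[i, 1L], ...)
    injectArtifacts(clean, spec = spec, seed = seeds[i, 2L])
  })
}

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d samples @ %g Hz, %d truth segment(s), seed %s\n",
              length(object@clean@values), object@clean@fs,
              length(object@truth@segments),
              if (is.na(object@seed)) "NA" else object@seed))
  invisible(NULL)
})
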