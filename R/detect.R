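#' Two-sided moving standard deviation
#'
#' Per-sample SD of `x` over a centred window of `W = 2k + 1` samples with
#' `k = round(3 fs)`, i.e. a window of about six seconds. The population
#' form is used (division by `W`). The window is only defined for interior
#' samples `k+1 ... N-k`; the first and last `k` samples replicate the
#' nearest interior value so the returned series has full length.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param fs sampling rate in Hz (taken from `x` if it is a signal object).
#' @return numeric vector of per-sample moving SDs, same length as `x`.
#' @examples
#' movingSD(sin(seq(0, 20, by = 0.1)), fs = 10)
#' @export
movingSD <- function(x, fs = NULL) {
  if (is(x, "FnirsSignal")) fs <- samplingRate(x)
  if (is.null(fs)) stop("'fs' is required for numeric input")
  v <- sigValues(x)
  N <- length(v)
  k <- as.integer(round(3 * fs))
  W <- 2L * k + 1L
  if (N < W)
    stop(sprintf("series too short for the moving-SD window: need >= %d samples (W = 2*round(3*fs)+1), got %d",
                 W, N))
  if (k == 0L) return(rep(0, N))
  # centring first keeps the sum-of-squares update numerically benign
  vc <- v - mean(v)
  c1 <- c(0, cumsum(vc))
  c2 <- c(0, cumsum(vc * vc))
  ctr <- seq.int(k + 1L, N - k)
  s1 <- c1[ctr + k + 1L] - c1[ctr - k]
  s2 <- c2[ctr + k + 1L] - c2[ctr - k]
  varw <- pmax(0, s2 / W - (s1 / W)^2)
  ti <- sqrt(varw)
  c(rep(ti[1L], k), ti, rep(ti[length(ti)], k))
}

#' Dynamic detection threshold from the moving-SD series
#'
#' Builds the per-sample threshold A(n) that the oscillation classifier
#' compares the moving SD against. With `p` the moving-SD series sorted
#' ascending and `N` its length, the anchors are the order statistics
#' `T1 = p[floor(0.3 N)]`, `T2 = p[floor(0.5 N)]`, `T3 = p[floor(0.7 N)]`
#' (index floored, minimum 1). The series is clipped into `[T1, T3]`,
#' filtered with a zero-phase order-3 Butterworth filter at
#' `cutoffHz` (high-pass by default; see `filter`), floored at `T2`, and
#' offset by `3 (T3 - T1)`.
#'
#' @param t moving-SD series from [movingSD()].
#' @param fs sampling rate in Hz.
#' @param cutoffHz filter cutoff applied to the clipped series; default 0.02.
#' @param filter `"highpass"` (default) or `"lowpass"`.
#' @return a [ThresholdSeries-class].
#' @export
dynamicThreshold <- function(t, fs, cutoffHz = 0.02,
                             filter = c("highpass", "lowpass")) {
  filter <- match.arg(filter)
  N <- length(t)
  if (N < 10L) stop("need at least 10 samples for the quantile anchors")
  p <- sort(t)
  qat <- function(f) p[max(1L, floor(f * N))]
  T1 <- qat(0.3); T2 <- qat(0.5); T3 <- qat(0.7)
  clipped <- pmin(pmax(t, T1), T3)
  filt <- zeroPhaseFilter(clipped, fs, cutoffHz,
                          type = if (filter == "highpass") "high" else "low")
  A <- pmax(filt, T2) + 3 * (T3 - T1)
  obj <- new("ThresholdSeries", t = as.numeric(t), A = A,
             T1 = T1, T2 = T2, T3 = T3)
  validObject(obj)
  obj
}

#' Classify samples against the dynamic threshold
#'
#' The oscillation criterion: `t > 2A` is a suspected severe oscillation,
#' `A < t <= 2A` a slight oscillation, `t <= A` none. Both boundaries are
#' inclusive on the lower class.
#'
#' @param t moving-SD series (or a [ThresholdSeries-class], in which case
#'   `A` is ignored).
#' @param A dynamic-threshold series of the same length.
#' @return character vector of labels in
#'   `{"none", "slight", "severe_suspected"}`.
#' @examples
#' classifySamples(c(1, 2, 2.1), c(1, 1, 1))
#' @export
classifySamples <- function(t, A = NULL) {
  if (is(t, "ThresholdSeries")) { A <- t@A; t <- t@t }
  if (length(t) != length(A)) stop("'t' and 'A' must have equal length")
  out <- rep("none", length(t))
  out[t > A] <- "slight"
  out[t > 2 * A] <- "severe_suspected"
  out
}

#' Split a region into single-peak segments at its troughs
#'
#' Boundaries are placed at local minima of `x` within `[start, end]` so
#' that each sub-segment contains exactly one peak and the junctions sit at
#' the troughs. A flat valley (plateau) resolves to its first sample.
#' Regions shorter than 3 samples are returned as a single segment.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param start,end 1-based closed bounds of the region.
#' @return an [IRanges::IRanges] of sub-segments partitioning the region.
#' @export
segmentBySlope <- function(x, start, end) {
  v <- sigValues(x)
  stopifnot(start >= 1, end <= length(v), start <= end)
  seg <- v[start:end]
  n <- length(seg)
  if (n < 3L) return(IRanges::IRanges(start, end))
  d <- diff(seg)
  nz <- which(d != 0)
  troughs <- integer()
  if (length(nz) >= 2L) {
    s <- sign(d[nz])
    tr <- which(s[-length(s)] < 0 & s[-1L] > 0)
    troughs <- nz[tr] + 1L  # first sample of the valley
  }
  bounds <- unique(c(troughs[troughs > 1L & troughs < n]))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  IRanges::IRanges(start = starts + start - 1L, end = ends + start - 1L)
}

#' Confirm suspected severe oscillations
#'
#' A suspected severe region is split into single-peak segments with
#' [segmentBySlope()]; each segment whose signal range `(xmax - xmin)`
#' reaches at least six times the SD of `x` over the whole suspected region
#' is confirmed severe, the rest are demoted to slight.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param start,end bounds of the suspected region (samples, closed).
#' @return list with `IRanges` components `severe` and `slight` (adjacent
#'   same-category segments merged).
#' @export
confirmSevere <- function(x, start, end) {
  v <- sigValues(x)
  sdReg <- stats::sd(v[start:end])
  if (is.na(sdReg)) sdReg <- 0
  sub <- segmentBySlope(v, start, end)
  rng <- vapply(seq_along(sub), function(i) {
    s <- v[IRanges::start(sub)[i]:IRanges::end(sub)[i]]
    max(s) - min(s)
  }, numeric(1))
  isSevere <- rng >= 6 * sdReg
  list(severe = IRanges::reduce(sub[isSevere]),
       slight = IRanges::reduce(sub[!isSevere]))
}

#' Detect baseline shifts around oscillation regions
#'
#' For each merged oscillation run flanked on both sides by quiet
#' (non-oscillation) runs lasting at least `quietSeconds`, the means of the
#' full quiet flanks (`avebefore`, `aveafter`) are compared with the signal
#' range over the run: a baseline shift is marked over the run iff
#' `|avebefore - aveafter| > (xmax - xmin)/2`. Runs without both quiet
#' flanks are not eligible. The record edges bound the first and last
#' flanks.
#'
#' @param x numeric vector or [FnirsSignal-class].
#' @param oscRuns `IRanges` of merged oscillation (severe or slight) runs.
#' @param fs sampling rate in Hz.
#' @param quietSeconds minimum flank duration in seconds; default 5.
#' @return `IRanges` of baseline-shift segments (a subset of `oscRuns`).
#' @export
detectBaselineShift <- function(x, oscRuns, fs, quietSeconds = 5) {
  v <- sigValues(x)
  N <- length(v)
  need <- quietSeconds * fs
  keep <- logical(length(oscRuns))
  st <- IRanges::start(oscRuns); en <- IRanges::end(oscRuns)
  for (i in seq_along(oscRuns)) {
    prevEnd <- if (i == 1L) 0L else en[i - 1L]
    nextStart <- if (i == length(oscRuns)) N + 1L else st[i + 1L]
    beforeLen <- st[i] - 1L - prevEnd
    afterLen <- nextStart - 1L - en[i]
    if (beforeLen < need || afterLen < need) next
    aveBefore <- mean(v[(prevEnd + 1L):(st[i] - 1L)])
    aveAfter <- mean(v[(en[i] + 1L):(nextStart - 1L)])
    run <- v[st[i]:en[i]]
    if (abs(aveBefore - aveAfter) > (max(run) - min(run)) / 2)
      keep[i] <- TRUE
  }
  oscRuns[keep]
}

#' Integrate 3-axis acceleration into one magnitude trace
#'
#' `acc(n) = sqrt((ax^2 + ay^2 + az^2) / 3)`, the root-mean-square over the
#' three axes, in g.
#'
#' @param ax,ay,az the axis traces, numeric vectors or
#'   [FnirsSignal-class] objects of equal length (and equal fs).
#' @param fs sampling rate in Hz, required when the inputs are numeric.
#' @return an [FnirsSignal-class] of kind `"acceleration"`.
#' @export
integrateAcceleration <- function(ax, ay, az, fs = NULL) {
  rates <- c()
  for (a in list(ax, ay, az))
    if (is(a, "FnirsSignal")) rates <- c(rates, samplingRate(a))
  if (length(rates) > 0) {
    if (length(unique(rates)) > 1L) stop("axis sampling rates differ")
    if (is.null(fs)) fs <- rates[1]
    else if (fs != rates[1]) stop("'fs' conflicts with the axis traces")
  }
  if (is.null(fs)) stop("'fs' is required for numeric input")
  vx <- sigValues(ax); vy <- sigValues(ay); vz <- sigValues(az)
  if (length(vx) != length(vy) || length(vy) != length(vz))
    stop("axis traces must have equal length")
  FnirsSignal(sqrt((vx^2 + vy^2 + vz^2) / 3), fs = fs,
              label = "acc", kind = "acceleration")
}

#' Dynamic threshold for the acceleration strategy
#'
#' With `T` the order statistic of the moving SD `d` of the integrated
#' acceleration at 1-based index `floor(0.3 N)` (minimum 1), `d` is clipped
#' into `[T/2, T]` and doubled: `B = 2 d'`.
#'
#' @param d moving-SD series of the integrated acceleration.
#' @return numeric vector `B`, the per-sample threshold.
#' @export
accelThreshold <- function(d) {
  N <- length(d)
  if (N < 1L) stop("empty input")
  T <- sort(d)[max(1L, floor(0.3 * N))]
  2 * pmin(pmax(d, 0.5 * T), T)
}

## contiguous TRUE runs of a logical mask as an IRanges
maskToRanges <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' Detect motion artifacts in an fNIRS signal
#'
#' Full detection: moving SD, dynamic threshold (fNIRS strategy:
#' [dynamicThreshold()]; accel strategy: [accelThreshold()] on the
#' integrated acceleration), per-sample classification, severe confirmation
#' on the fNIRS signal, and baseline-shift detection on the fNIRS signal.
#' Oscillation runs separated by less than one second of unlabelled samples
#' are merged before confirmation and baseline-shift analysis.
#'
#' @param x the fNIRS signal, an [FnirsSignal-class].
#' @param accel optional list of three axis traces (required for
#'   `strategy = "accel"`).
#' @param strategy `"fnirs"` (default) or `"accel"`.
#' @param config a [RunConfig-class].
#' @return an [ArtifactAnnotation-class].
#' @examples
#' ds <- injectArtifacts(generateClean(600, 10, seed = 1), seed = 2)
#' detectArtifacts(ds@noised)
#' @export
detectArtifacts <- function(x, accel = NULL,
                            strategy = c("fnirs", "accel"),
                            config = runConfig()) {
  strategy <- match.arg(strategy)
  stopifnot(is(x, "FnirsSignal"))
  v <- sigValues(x)
  fs <- samplingRate(x)
  N <- length(v)
  if (strategy == "fnirs") {
    t <- movingSD(v, fs)
    th <- dynamicThreshold(t, fs, cutoffHz = config@hpThresholdHz,
                           filter = config@thresholdFilter)
    labels <- classifySamples(th)
  } else {
    if (is.null(accel) || length(accel) != 3L)
      stop("strategy 'accel' requires a list of three axis traces")
    acc <- integrateAcceleration(accel[[1]], accel[[2]], accel[[3]], fs = fs)
    if (length(acc@values) != N)
      stop("acceleration traces must match the fNIRS signal length")
    d <- movingSD(acc@values, fs)
    labels <- classifySamples(d, accelThreshold(d))
  }

  runs <- IRanges::reduce(maskToRanges(labels != "none"),
                          min.gapwidth = as.integer(round(fs)))
  sevAll <- IRanges::IRanges()
  sliAll <- IRanges::IRanges()
  for (i in seq_along(runs)) {
    rs <- IRanges::start(runs)[i]; re <- IRanges::end(runs)[i]
    susp <- maskToRanges(labels == "severe_suspected")
    susp <- IRanges::restrict(susp, start = rs, end = re)
    susp <- susp[IRanges::width(susp) > 0L]
    sevRun <- IRanges::IRanges()
    for (j in seq_along(susp)) {
      conf <- confirmSevere(v, IRanges::start(susp)[j],
                            IRanges::end(susp)[j])
      sevRun <- c(sevRun, conf$severe)
    }
    sevRun <- IRanges::reduce(sevRun)
    sliRun <- IRanges::setdiff(IRanges::IRanges(rs, re), sevRun)
    sevAll <- c(sevAll, sevRun)
    sliAll <- c(sliAll, sliRun)
  }
  bs <- detectBaselineShift(v, runs, fs, quietSeconds = config@quietSeconds)

  ArtifactAnnotation(
    start = c(IRanges::start(sevAll), IRanges::start(sliAll),
              IRanges::start(bs)),
    end = c(IRanges::end(sevAll), IRanges::end(sliAll), IRanges::end(bs)),
    category = c(rep("severe", length(sevAll)),
                 rep("slight", length(sliAll)),
                 rep("baseline_shift", length(bs))),
    source = if (strategy == "fnirs") "fnirs" else "accel",
    nSamples = N)
}
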