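## Central S4 containers. Validity methods enforce the invariants the
## detection/correction stages rely on, so downstream code can assume them.

.SIGNAL_KINDS <- c("hemoglobin", "optical_density", "acceleration")
.SEGMENT_CATEGORIES <- c("severe", "slight", "baseline_shift")
.SEGMENT_SOURCES <- c("fnirs", "accel")

#' FnirsSignal: a uniformly sampled channel
#'
#' Holds one uniformly sampled time series: hemoglobin concentration change
#' (µmol/L), optical density change, or acceleration (g), together with its
#' sampling rate. Sampling is implicitly uniform; sample n (1-based) is at
#' time (n-1)/fs seconds.
#'
#' @slot values numeric vector of samples; all finite, length >= 1.
#' @slot fs sampling rate in Hz (> 0).
#' @slot label free-text channel name.
#' @slot kind one of `"hemoglobin"`, `"optical_density"`, `"acceleration"`.
#' @exportClass FnirsSignal
setClass("FnirsSignal",
  representation(values = "numeric", fs = "numeric",
                 label = "character", kind = "character"))

setValidity("FnirsSignal", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive finite number")
  if (length(object@values) < 1L)
    return("'values' must have length >= 1")
  if (!all(is.finite(object@values)))
    return("'values' must be all finite")
  if (length(object@kind) != 1L || !(object@kind %in% .SIGNAL_KINDS))
    return(sprintf("'kind' must be one of: %s",
                   paste(.SIGNAL_KINDS, collapse = ", ")))
  TRUE
})

#' ArtifactAnnotation: typed artifact intervals over a signal
#'
#' Segments are 1-based closed [IRanges::IRanges] over sample indices, with
#' per-segment metadata columns `category` (severe / slight / baseline_shift)
#' and `source` (fnirs / accel). Invariants: segments lie within
#' `[1, nSamples]`, are sorted by start, severe and slight segments are
#' mutually disjoint, and every baseline_shift segment spans exactly one
#' merged oscillation (severe or slight) region.
#'
#' @slot segments an `IRanges` with mcols `category` and `source`.
#' @slot nSamples length of the annotated signal.
#' @exportClass ArtifactAnnotation
setClass("ArtifactAnnotation",
  representation(segments = "IRanges", nSamples = "integer"))

setValidity("ArtifactAnnotation", function(object) {
  seg <- object@segments
  mc <- S4Vectors::mcols(seg)
  if (is.null(mc) || !all(c("category", "source") %in% colnames(mc)))
    return("segments must carry 'category' and 'source' metadata columns")
  if (length(object@nSamples) != 1L || is.na(object@nSamples) ||
      object@nSamples < 0L)
    return("'nSamples' must be a single non-negative integer")
  if (length(seg) == 0L) return(TRUE)
  if (!all(mc$category %in% .SEGMENT_CATEGORIES))
    return("unknown segment category")
  if (!all(mc$source %in% .SEGMENT_SOURCES))
    return("unknown segment source")
  if (any(IRanges::start(seg) < 1L) ||
      any(IRanges::end(seg) > object@nSamples))
    return("segments must lie within [1, nSamples]")
  if (is.unsorted(IRanges::start(seg)))
    return("segments must be sorted by start")
  sev <- seg[mc$category == "severe"]
  sli <- seg[mc$category == "slight"]
  if (sum(IRanges::width(IRanges::intersect(
        IRanges::reduce(sev), IRanges::reduce(sli)))) > 0)
    return("severe and slight segments must be disjoint")
  bs <- seg[mc$category == "baseline_shift"]
  if (length(bs) > 0L) {
    osc <- IRanges::reduce(c(sev, sli))
    key <- paste(IRanges::start(osc), IRanges::end(osc))
    bskey <- paste(IRanges::start(bs), IRanges::end(bs))
    if (!all(bskey %in% key))
      return("each baseline_shift segment must span one oscillation region")
  }
  TRUE
})

#' ThresholdSeries: moving SD and its dynamic threshold
#'
#' Result of [dynamicThreshold()]: the moving SD series `t`, its 30/50/70%
#' order statistics `T1 <= T2 <= T3`, and the per-sample dynamic threshold
#' `A = max(filtered clipped SD, T2) + 3 (T3 - T1)`, so `A >= T2` everywhere.
#'
#' @slot t numeric, moving SD per sample (signal units).
#' @slot A numeric, dynamic threshold per sample, same length as `t`.
#' @slot T1,T2,T3 numeric scalars, the quantile anchors.
#' @exportClass ThresholdSeries
setClass("ThresholdSeries",
  representation(t = "numeric", A = "numeric",
                 T1 = "numeric", T2 = "numeric", T3 = "numeric"))

setValidity("ThresholdSeries", function(object) {
  if (length(object@t) != length(object@A))
    return("'t' and 'A' must have equal length")
  if (!(object@T1 <= object@T2 && object@T2 <= object@T3))
    return("need T1 <= T2 <= T3")
  if (any(object@A < object@T2 - 1e-12 * max(object@T2, 1)))
    return("'A' must be >= T2 everywhere")
  TRUE
})

#' WaveletThresholds: the dual detecting/processing thresholds
#'
#' Governs coefficient zeroing in the dual-threshold wavelet stage:
#' `u` is the positive standard-normal deviate with two-sided tail mass
#' `alpha`, `sigmaHat` the robust coefficient-SD estimate, and
#' `w2 = u * sigmaHat` (processing threshold), `w1 = 1.3 * w2` (detecting
#' threshold).
#'
#' @slot alpha two-sided tail probability in (0, 1).
#' @slot u standard-normal deviate (>= 0).
#' @slot sigmaHat estimated coefficient SD (>= 0).
#' @slot w1 detecting threshold.
#' @slot w2 processing threshold.
#' @exportClass WaveletThresholds
setClass("WaveletThresholds",
  representation(alpha = "numeric", u = "numeric", sigmaHat = "numeric",
                 w1 = "numeric", w2 = "numeric"))

setValidity("WaveletThresholds", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must be in (0, 1)")
  if (object@u < 0 || object@sigmaHat < 0)
    return("'u' and 'sigmaHat' must be >= 0")
  tol <- 1e-9 * max(1, object@w2)
  if (abs(object@w2 - object@u * object@sigmaHat) > tol)
    return("w2 must equal u * sigmaHat")
  if (abs(object@w1 - 1.3 * object@w2) > tol)
    return("w1 must equal 1.3 * w2")
  TRUE
})

#' WaveletDecomposition: periodized orthogonal DWT coefficients
#'
#' Detail coefficients per level (level 1 = finest) plus the final
#' approximation, for a signal padded to a multiple of `2^level`.
#' Reconstructing an unmodified decomposition reproduces the input to
#' better than 1e-8 relative error.
#'
#' @slot details list of numeric vectors, finest level first.
#' @slot approx numeric, approximation coefficients at the coarsest level.
#' @slot wavelet mother-wavelet name (e.g. `"db4"`).
#' @slot nOrig original (unpadded) signal length.
#' @slot nPadded padded length actually transformed.
#' @exportClass WaveletDecomposition
setClass("WaveletDecomposition",
  representation(details = "list", approx = "numeric", wavelet = "character",
                 nOrig = "integer", nPadded = "integer"))

#' MBLLCoefficients: mixing coefficients of the modified Beer-Lambert law
#'
#' The linear map from dual-wavelength optical-density changes to hemoglobin
#' concentration changes: dHbO2 = (a1 dOD1 + a2 dOD2)/L and
#' dHb = (b1 dOD1 + b2 dOD2)/L.
#'
#' @slot a1,a2,b1,b2 mixing coefficients (µmol/L per unit OD at L = 1).
#' @slot L path/depth term (> 0), same length unit throughout.
#' @slot lambda1,lambda2 wavelengths in nm.
#' @exportClass MBLLCoefficients
setClass("MBLLCoefficients",
  representation(a1 = "numeric", a2 = "numeric", b1 = "numeric",
                 b2 = "numeric", L = "numeric",
                 lambda1 = "numeric", lambda2 = "numeric"))

setValidity("MBLLCoefficients", function(object) {
  if (object@L <= 0) return("'L' must be > 0")
  if (abs(object@a1 * object@b2 - object@a2 * object@b1) <
      1e-12 * max(abs(c(object@a1, object@a2, object@b1, object@b2, 1))))
    return("coefficient matrix is singular (a1*b2 - a2*b1 = 0)")
  TRUE
})

#' ExtinctionParams: extinction coefficients and path factors
#'
#' Spectroscopic parameters of the forward Beer-Lambert map at two
#' wavelengths, used by [coefficientsFromExtinction()] to derive the
#' inverse mixing coefficients for wavelength pairs other than the packaged
#' 735/850 nm default.
#'
#' @slot epsHbL1,epsHbL2 extinction coefficients of deoxy-hemoglobin.
#' @slot epsHbO2L1,epsHbO2L2 extinction coefficients of oxy-hemoglobin.
#' @slot dpf1,dpf2 differential path factors (> 0).
#' @exportClass ExtinctionParams
setClass("ExtinctionParams",
  representation(epsHbL1 = "numeric", epsHbL2 = "numeric",
                 epsHbO2L1 = "numeric", epsHbO2L2 = "numeric",
                 dpf1 = "numeric", dpf2 = "numeric"))

setValidity("ExtinctionParams", function(object) {
  if (object@dpf1 <= 0 || object@dpf2 <= 0)
    return("differential path factors must be > 0")
  det <- object@epsHbO2L1 * object@epsHbL2 -
    object@epsHbO2L2 * object@epsHbL1
  scale <- max(abs(c(object@epsHbL1, object@epsHbL2,
                     object@epsHbO2L1, object@epsHbO2L2, 1)))
  if (abs(det) < 1e-12 * scale)
    return("extinction matrix is singular")
  TRUE
})

#' RunConfig: pipeline parameters
#'
#' Bundles the tunable parameters of the detection/correction pipeline.
#' Defaults follow the method's reference settings: alpha = 0.05, db4
#' mother wavelet, K = 16 cyclic shifts, p = 0.99 for severe-oscillation
#' splines, 0.003 Hz final and 0.02 Hz threshold-filter cutoffs, 5 s
#' minimum quiet duration.
#'
#' @slot alpha two-sided tail probability in (0, 1) for wavelet thresholds.
#' @slot motherWavelet mother-wavelet name, see [waveletFilter()].
#' @slot K number of cyclic shifts for cycle spinning (>= 1).
#' @slot pSevere smoothing parameter for severe-oscillation splines, [0, 1].
#' @slot hpFinalHz final high-pass cutoff (Hz).
#' @slot hpThresholdHz cutoff of the filter applied to the clipped moving-SD
#'   series when building the dynamic threshold (Hz).
#' @slot thresholdFilter `"highpass"` (reference behaviour) or `"lowpass"`
#'   (alternative reading; see the vignette).
#' @slot quietSeconds minimum quiet-flank duration for baseline-shift
#'   eligibility (s).
#' @slot bandTopHz upper edge of the hemodynamic band of interest (Hz); the
#'   wavelet decomposition depth is chosen so the approximation band still
#'   contains it, keeping the signal band out of the thresholded details.
#' @slot waveletLevel explicit decomposition depth, or `NA` to derive it
#'   from `bandTopHz` and the sampling rate.
#' @slot seed integer seed or `NA` for unseeded.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(alpha = "numeric", motherWavelet = "character",
                 K = "integer", pSevere = "numeric",
                 hpFinalHz = "numeric", hpThresholdHz = "numeric",
                 thresholdFilter = "character", quietSeconds = "numeric",
                 bandTopHz = "numeric", waveletLevel = "integer",
                 seed = "integer"))

setValidity("RunConfig", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must be in (0, 1)")
  if (object@pSevere < 0 || object@pSevere > 1)
    return("'pSevere' must be in [0, 1]")
  if (object@K < 1L) return("'K' must be >= 1")
  if (object@hpFinalHz <= 0 || object@hpThresholdHz <= 0)
    return("cutoff frequencies must be > 0")
  if (!(object@thresholdFilter %in% c("highpass", "lowpass")))
    return("'thresholdFilter' must be 'highpass' or 'lowpass'")
  if (object@quietSeconds < 0) return("'quietSeconds' must be >= 0")
  if (object@bandTopHz <= 0) return("'bandTopHz' must be > 0")
  if (!is.na(object@waveletLevel) && object@waveletLevel < 1L)
    return("'waveletLevel' must be >= 1 (or NA for automatic)")
  TRUE
})

#' ArtifactSpec: parameters of the synthetic artifact generator
#'
#' Counts, amplitudes (in multiples of the clean signal's SD), durations and
#' spacing of the artifacts injected by [injectArtifacts()].
#'
#' @slot nSpikes,nSlow,nBS event counts (>= 0).
#' @slot spikeAmp,slowAmp,bsHeight amplitudes in clean-signal SD units.
#' @slot spikeWidthS,slowWidthS durations in seconds (> 0).
#' @slot minGapS minimum spacing between events in seconds.
#' @exportClass ArtifactSpec
setClass("ArtifactSpec",
  representation(nSpikes = "integer", nSlow = "integer", nBS = "integer",
                 spikeAmp = "numeric", slowAmp = "numeric",
                 bsHeight = "numeric", spikeWidthS = "numeric",
                 slowWidthS = "numeric", minGapS = "numeric"))

setValidity("ArtifactSpec", function(object) {
  if (object@nSpikes < 0L || object@nSlow < 0L || object@nBS < 0L)
    return("counts must be >= 0")
  if (object@spikeAmp < 0 || object@slowAmp < 0 || object@bsHeight < 0)
    return("amplitudes must be >= 0")
  if (object@spikeWidthS <= 0 || object@slowWidthS <= 0)
    return("durations must be > 0")
  TRUE
})

#' SyntheticDataset: clean/noised signal pair with ground truth
#'
#' @slot clean,noised [FnirsSignal] objects of equal length; `noised - clean`
#'   is exactly the injected noise.
#' @slot truth ground-truth [ArtifactAnnotation] covering every injection.
#' @slot seed integer seed the dataset was generated from.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(clean = "FnirsSignal", noised = "FnirsSignal",
                 truth = "ArtifactAnnotation", seed = "integer"))

setValidity("SyntheticDataset", function(object) {
  if (length(object@clean@values) != length(object@noised@values))
    return("clean and noised must have equal length")
  if (object@truth@nSamples != length(object@clean@values))
    return("truth annotation length must match the signals")
  TRUE
})

#' CorrectionResult: full pipeline output with retrievable stages
#'
#' @slot input the input [FnirsSignal] x.
#' @slot annotation the [ArtifactAnnotation] used for correction.
#' @slot x1 numeric, after severe-oscillation correction.
#' @slot x2 numeric, after baseline-shift removal.
#' @slot x3 numeric, after dual-threshold wavelet denoising.
#' @slot output the final [FnirsSignal] y, after the final high-pass.
#' @slot config the [RunConfig] used.
#' @exportClass CorrectionResult
setClass("CorrectionResult",
  representation(input = "FnirsSignal", annotation = "ArtifactAnnotation",
                 x1 = "numeric", x2 = "numeric", x3 = "numeric",
                 output = "FnirsSignal", config = "RunConfig"))
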