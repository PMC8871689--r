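#' Build a pipeline configuration
#'
#' Collects the tunable parameters of the detection/correction pipeline.
#' The defaults are the method's reference settings and are deliberately
#' insensitive choices: performance is flat across alpha in 0.005-0.1 and
#' across the orthogonal mother wavelets (see the vignette).
#'
#' @param alpha two-sided tail probability in (0, 1) controlling the wavelet
#'   thresholds; default 0.05.
#' @param motherWavelet mother wavelet for the DWT; one of
#'   [availableWavelets()]; default `"db4"`.
#' @param K number of unit-sample cyclic shifts averaged in the wavelet
#'   stage; default 16.
#' @param pSevere smoothing parameter of the severe-oscillation spline in
#'   [0, 1]; default 0.99 (near-interpolating).
#' @param hpFinalHz final high-pass cutoff in Hz; default 0.003, the lower
#'   edge of the hemodynamic band of interest.
#' @param hpThresholdHz cutoff of the zero-phase filter applied to the
#'   clipped moving-SD series inside [dynamicThreshold()]; default 0.02.
#' @param thresholdFilter `"highpass"` (default, literal reading) or
#'   `"lowpass"` (alternative reading) for that filter.
#' @param quietSeconds minimum duration of the quiet flanks required for
#'   baseline-shift eligibility; default 5 s.
#' @param bandTopHz upper edge of the hemodynamic band of interest; default
#'   0.04. The wavelet depth is chosen as the deepest level whose
#'   approximation band `[0, fs/2^(M+1)]` still contains it, so the
#'   globally thresholded detail levels carry only supra-band content.
#' @param waveletLevel explicit decomposition depth overriding the
#'   band-derived default, or `NA`.
#' @param seed integer seed for stochastic stages, or `NA`.
#' @return a validated [RunConfig-class].
#' @examples
#' runConfig(alpha = 0.01, motherWavelet = "sym4")
#' @export
runConfig <- function(alpha = 0.05, motherWavelet = "db4", K = 16L,
                      pSevere = 0.99, hpFinalHz = 0.003,
                      hpThresholdHz = 0.02,
                      thresholdFilter = c("highpass", "lowpass"),
                      quietSeconds = 5, bandTopHz = 0.04,
                      waveletLevel = NA_integer_, seed = NA_integer_) {
  thresholdFilter <- match.arg(thresholdFilter)
  obj <- new("RunConfig", alpha = alpha, motherWavelet = motherWavelet,
             K = as.integer(K), pSevere = pSevere, hpFinalHz = hpFinalHz,
             hpThresholdHz = hpThresholdHz, thresholdFilter = thresholdFilter,
             quietSeconds = quietSeconds, bandTopHz = bandTopHz,
             waveletLevel = as.integer(waveletLevel),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(paste0(
    "RunConfig: alpha=%g, wavelet=%s, K=%d, pSevere=%g,\n",
    "  hpFinal=%g Hz, hpThreshold=%g Hz (%s), quiet=%g s, seed=%s\n"),
    object@alpha, object@motherWavelet, object@K, object@pSevere,
    object@hpFinalHz, object@hpThresholdHz, object@thresholdFilter,
    object@quietSeconds,
    if (is.na(object@seed)) "NA" else as.character(object@seed)))
  invisible(NULL)
})

#' Read a RunConfig from a YAML file
#'
#' Keys mirror the arguments of [runConfig()]; missing keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a [RunConfig-class].
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

## run expr with a temporary RNG state seeded from `seed` (if not NA),
## restoring the caller's state afterwards
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
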