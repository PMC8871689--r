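## Periodized orthogonal discrete wavelet transform.
##
## Analysis uses the circular pyramid
##   a[k] = sum_m lo[m] x[(2k + m) mod N],   d[k] = sum_m hi[m] x[(2k + m) mod N]
## whose row vectors form an orthonormal basis of R^N when N is even and at
## least the filter length, so synthesis is the exact transpose and
## reconstruction is exact to machine precision. Signals whose length is not
## a multiple of 2^level are extended with a linear bridge from the last
## sample back to the first (keeping the circular seam continuous) and
## truncated after reconstruction.

# Standard orthonormal scaling (low-pass decomposition) filters.
.WAVELET_LO <- list(
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999,
          -0.0062414902127982744, 0.077571493840045719, -0.032244869584638375,
          -0.24229488706638203, 0.13842814590132074, 0.72430852843777294,
          0.60382926979718965, 0.16010239797419293),
  sym3 = c(0.035226291882100656, -0.085441273882241486, -0.13501102001039084,
           0.45987750211933132, 0.80689150931333875, 0.33267055295095688),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.72340769040242059, 0.63397896345821192,
           0.016602105764522319, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  coif3 = c(-3.4599773197272781e-05, -7.0983302506379004e-05,
            0.00046621695982040288, 0.0011175187708306303,
            -0.0025745176881367972, -0.0090079761367306242,
            0.015880544863669452, 0.034555027573297738, -0.082301927106299827,
            -0.071799821619154838, 0.42848347637737, 0.79377722262608719,
            0.40517690240911824, -0.061123390002972552, -0.065771911281469364,
            0.023452696142077168, 0.0077825964256727463,
            -0.0037935128643808019),
  coif4 = c(-1.7849909144933469e-06, -3.259647940030751e-06,
            3.1229861599195265e-05, 6.2338854312787192e-05,
            -0.00025997433712225682, -0.00058902022463321654,
            0.0012665610789256603, 0.0037514346971460866,
            -0.0056582838001308835, -0.015211728187697211,
            0.025082253337949612, 0.039334422605589149, -0.096220424535952642,
            -0.066627472366817167, 0.43438603311435653, 0.78223893442428261,
            0.41530842700068227, -0.056077319603569258, -0.081266710249193727,
            0.02668230466960483, 0.016068947131575029, -0.0073461679362680507,
            -0.001629492425226786, 0.00089231390253700297),
  coif5 = c(-9.6040101127678941e-08, -1.6237995172048338e-07,
            2.0612203985788783e-06, 3.7007277113394796e-06,
            -2.1270221672515614e-05, -4.1219861924265501e-05,
            0.00014035632812373243, 0.00030185794166824478,
            -0.00063755892612588115, -0.0016616273039298788,
            0.0024315754425382886, 0.0067615202206204169,
            -0.0091595073386761625, -0.019758391600965465,
            0.032674799467057355, 0.041287530472117834, -0.10556315130733723,
            -0.06203775157498196, 0.43798230665916338, 0.77429362286032744,
            0.42157126673075435, -0.052046670253554764, -0.091921588060086087,
            0.028169744270532353, 0.023408322118927783, -0.010131584846900276,
            -0.0041593126275786402, 0.0021782943778456947,
            0.00035857774116175768, -0.000212081862067494))

#' Available mother wavelets
#'
#' The orthogonal Daubechies, Symlet and Coiflet family members supported by
#' the DWT stage.
#'
#' @return character vector of wavelet names.
#' @export
availableWavelets <- function() names(.WAVELET_LO)

#' Decomposition filter pair of a mother wavelet
#'
#' @param name wavelet name, one of [availableWavelets()].
#' @return list with the low-pass (`lo`) and high-pass (`hi`) decomposition
#'   filters; `hi` is the quadrature mirror `hi[k] = (-1)^(k+1) lo[L+1-k]`.
#' @export
waveletFilter <- function(name) {
  lo <- .WAVELET_LO[[name]]
  if (is.null(lo))
    stop(sprintf("unknown wavelet '%s'; available: %s", name,
                 paste(availableWavelets(), collapse = ", ")))
  L <- length(lo)
  k <- seq_len(L)
  list(lo = lo, hi = (-1)^k * rev(lo))
}

# one circular analysis step; N even, N >= filter length
dwtStep <- function(x, lo, hi) {
  N <- length(x)
  half <- N %/% 2L
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (m in seq_along(lo)) {
    idx <- base + m
    idx[idx > N] <- idx[idx > N] - N
    xm <- x[idx]
    a <- a + lo[m] * xm
    d <- d + hi[m] * xm
  }
  list(a = a, d = d)
}

# exact transpose of dwtStep
idwtStep <- function(a, d, lo, hi) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(lo)) {
    idx <- base + m
    idx[idx > N] <- idx[idx > N] - N
    x[idx] <- x[idx] + lo[m] * a + hi[m] * d
  }
  x
}

# deepest level keeping every analysed length >= filter length
dwtMaxLevel <- function(n, filterLength) {
  if (n < 2L * filterLength) return(0L)
  max(1L, floor(log2(n / (filterLength - 1))))
}

# depth used by the denoising stages: deepest level whose approximation
# band [0, fs/2^(M+1)] still contains config@bandTopHz, capped by length
waveletDepth <- function(n, filterLength, config, fs = NULL) {
  maxLev <- dwtMaxLevel(n, filterLength)
  if (!is.na(config@waveletLevel)) return(min(maxLev, config@waveletLevel))
  if (is.null(fs)) return(maxLev)
  byBand <- floor(log2(fs / (2 * config@bandTopHz)))
  max(1L, min(maxLev, as.integer(byBand)))
}

# extend to length nPad with a linear bridge from x[N] towards x[1]
padBridge <- function(x, nPad) {
  n <- length(x)
  if (nPad == n) return(x)
  bridge <- seq(x[n], x[1L], length.out = nPad - n + 2L)
  c(x, bridge[-c(1L, length(bridge))])
}

#' Periodized orthogonal wavelet decomposition
#'
#' Decomposes a signal into `level` detail bands plus a final approximation
#' using the circular orthonormal pyramid. Signals whose length is not a
#' multiple of `2^level` are first extended with a linear bridge from last
#' to first sample; [dwtReconstruct()] truncates back to the original
#' length, so an unmodified round trip reproduces the input to machine
#' precision.
#'
#' @param x numeric vector or [FnirsSignal-class], length >= 2.
#' @param wavelet mother-wavelet name; default `"db4"`.
#' @param level decomposition depth; default the deepest level supported by
#'   the signal length and filter length.
#' @return a [WaveletDecomposition-class].
#' @examples
#' x <- rnorm(1000)
#' dec <- dwtDecompose(x, "db4")
#' max(abs(dwtReconstruct(dec) - x))  # ~ 1e-15
#' @export
dwtDecompose <- function(x, wavelet = "db4", level = NULL) {
  v <- sigValues(x)
  n <- length(v)
  f <- waveletFilter(wavelet)
  Lf <- length(f$lo)
  maxLev <- dwtMaxLevel(n, Lf)
  if (maxLev < 1L)
    stop(sprintf("signal too short for one '%s' decomposition level (need >= %d samples)",
                 wavelet, 2L * Lf))
  if (is.null(level)) level <- maxLev
  level <- as.integer(level)
  if (level < 1L || level > maxLev)
    stop(sprintf("'level' must be in [1, %d] for this signal", maxLev))
  nPad <- as.integer(ceiling(n / 2^level) * 2^level)
  a <- padBridge(v, nPad)
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- dwtStep(a, f$lo, f$hi)
    details[[j]] <- st$d
    a <- st$a
  }
  new("WaveletDecomposition", details = details, approx = a,
      wavelet = wavelet, nOrig = n, nPadded = nPad)
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' @param dec a [WaveletDecomposition-class], possibly with modified detail
#'   coefficients.
#' @return numeric vector of length `nOrig`.
#' @export
dwtReconstruct <- function(dec) {
  stopifnot(is(dec, "WaveletDecomposition"))
  f <- waveletFilter(dec@wavelet)
  a <- dec@approx
  for (j in rev(seq_along(dec@details)))
    a <- idwtStep(a, dec@details[[j]], f$lo, f$hi)
  a[seq_len(dec@nOrig)]
}

setMethod("show", "WaveletDecomposition", function(object) {
  cat(sprintf("WaveletDecomposition (%s): %d level(s), %d -> %d samples\n",
              object@wavelet, length(object@details), object@nOrig,
              object@nPadded))
  invisible(NULL)
})
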