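#' Modified Beer-Lambert conversion of optical density to hemoglobin
#'
#' The modified Beer-Lambert law (MBLL) maps optical-density changes
#' measured at two near-infrared wavelengths to concentration changes of
#' oxygenated and deoxygenated hemoglobin:
#' \deqn{\Delta[HbO_2] = (a_1 \Delta OD_{\lambda 1} + a_2 \Delta OD_{\lambda 2})/L,}
#' \deqn{\Delta[Hb]   = (b_1 \Delta OD_{\lambda 1} + b_2 \Delta OD_{\lambda 2})/L.}
#' The packaged default coefficients are for the 735/850 nm wavelength pair:
#' a1 = 330.1717, a2 = -131.3958, b1 = -127.6967, b2 = 184.5598 with L = 1.
#'
#' @param dod1,dod2 optical-density changes at the two wavelengths (scalars
#'   or equal-length numeric vectors; `FnirsSignal` also accepted).
#' @param coeffs an [MBLLCoefficients-class]; defaults to the packaged
#'   735/850 nm values.
#' @return a list with numeric components `HbO2` and `Hb` (µmol/L).
#' @examples
#' odToHemo(1, 1)   # about 200 and 60 µmol/L per unit OD
#' odToHemo(1, -1)  # opposite-sign inputs diverge: about 460 and -310
#' @export
odToHemo <- function(dod1, dod2, coeffs = defaultMBLLCoefficients()) {
  stopifnot(is(coeffs, "MBLLCoefficients"))
  validObject(coeffs)
  d1 <- sigValues(dod1)
  d2 <- sigValues(dod2)
  if (length(d1) != length(d2))
    stop("'dod1' and 'dod2' must have equal length")
  if (!all(is.finite(d1)) || !all(is.finite(d2)))
    stop("optical-density inputs must be finite")
  list(HbO2 = (coeffs@a1 * d1 + coeffs@a2 * d2) / coeffs@L,
       Hb   = (coeffs@b1 * d1 + coeffs@b2 * d2) / coeffs@L)
}

#' @describeIn odToHemo the packaged 735/850 nm coefficients.
#' @export
defaultMBLLCoefficients <- function() {
  new("MBLLCoefficients", a1 = 330.1717, a2 = -131.3958,
      b1 = -127.6967, b2 = 184.5598, L = 1,
      lambda1 = 735, lambda2 = 850)
}

#' Construct MBLLCoefficients directly
#'
#' @param a1,a2,b1,b2 mixing coefficients.
#' @param L path/depth term (> 0).
#' @param lambda1,lambda2 wavelengths in nm.
#' @return a validated [MBLLCoefficients-class].
#' @export
MBLLCoefficients <- function(a1, a2, b1, b2, L = 1,
                             lambda1 = NA_real_, lambda2 = NA_real_) {
  obj <- new("MBLLCoefficients", a1 = a1, a2 = a2, b1 = b1, b2 = b2, L = L,
             lambda1 = lambda1, lambda2 = lambda2)
  validObject(obj)
  obj
}

#' Construct ExtinctionParams
#'
#' @param epsHbO2L1,epsHbO2L2 extinction coefficients of oxy-hemoglobin at
#'   the two wavelengths.
#' @param epsHbL1,epsHbL2 extinction coefficients of deoxy-hemoglobin.
#' @param dpf1,dpf2 differential path factors (> 0).
#' @return a validated [ExtinctionParams-class].
#' @export
ExtinctionParams <- function(epsHbO2L1, epsHbO2L2, epsHbL1, epsHbL2,
                             dpf1 = 1, dpf2 = 1) {
  obj <- new("ExtinctionParams", epsHbL1 = epsHbL1, epsHbL2 = epsHbL2,
             epsHbO2L1 = epsHbO2L1, epsHbO2L2 = epsHbO2L2,
             dpf1 = dpf1, dpf2 = dpf2)
  validObject(obj)
  obj
}

#' Derive MBLL mixing coefficients from extinction parameters
#'
#' Inverts the forward MBLL system
#' \deqn{\Delta OD_{\lambda i} = DPF_{\lambda i}
#'   (\epsilon_{HbO_2,\lambda i} \Delta[HbO_2] +
#'    \epsilon_{Hb,\lambda i} \Delta[Hb]) L}
#' by solving the 2x2 linear system, so that [odToHemo()] with the returned
#' coefficients recovers the concentrations from the optical densities.
#'
#' @param ext an [ExtinctionParams-class].
#' @param L path/depth term carried into the returned coefficients.
#' @param lambda1,lambda2 wavelengths in nm (annotation only).
#' @return an [MBLLCoefficients-class].
#' @examples
#' ext <- ExtinctionParams(epsHbO2L1 = 0, epsHbO2L2 = 1,
#'                         epsHbL1 = 1, epsHbL2 = 0)
#' co <- coefficientsFromExtinction(ext)
#' odToHemo(1, 0, co)  # HbO2 = 0, Hb = 1
#' @export
coefficientsFromExtinction <- function(ext, L = 1,
                                       lambda1 = NA_real_,
                                       lambda2 = NA_real_) {
  stopifnot(is(ext, "ExtinctionParams"))
  validObject(ext)
  fwd <- matrix(c(ext@dpf1 * ext@epsHbO2L1, ext@dpf1 * ext@epsHbL1,
                  ext@dpf2 * ext@epsHbO2L2, ext@dpf2 * ext@epsHbL2),
                nrow = 2, byrow = TRUE)
  inv <- solve(fwd)  # rows: (a1 a2), (b1 b2)
  MBLLCoefficients(a1 = inv[1, 1], a2 = inv[1, 2],
                   b1 = inv[2, 1], b2 = inv[2, 2], L = L,
                   lambda1 = lambda1, lambda2 = lambda2)
}
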