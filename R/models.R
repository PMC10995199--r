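#' @include AllClasses.R
NULL

#' Forward response models
#'
#' The noiseless response curves underlying both the synthetic assay
#' generator and the fitters.
#'
#' \describe{
#'   \item{\code{michaelisMenten}}{v = Vmax S / (Km + S).}
#'   \item{\code{hillActivation}}{v = v_basal + (v_max - v_basal)
#'     S^n / (K_act^n + S^n). At S = K_act the response is exactly midway
#'     between the basal and maximal rates; with n = 1 and v_basal = 0 it
#'     reduces to the Michaelis-Menten form.}
#'   \item{\code{thermalSigmoid}}{a logistic between two plateaus with
#'     inflection (midpoint) at Tm: v = low + (high - low) /
#'     (1 + exp((Tm - T)/slope)).}
#' }
#'
#' @param S substrate or activator concentration (same units as Km/Kact)
#' @param Vmax,Km Michaelis-Menten parameters (> 0)
#' @param vBasal,vMax,Kact,nHill Hill activation parameters
#' @param T_ temperature (Celsius)
#' @param low,high plateau rates
#' @param Tm midpoint temperature (Celsius)
#' @param slope transition width (Celsius, > 0)
#' @return numeric response vector
#' @name forwardModels
NULL

#' @rdname forwardModels
#' @export
michaelisMenten <- function(S, Vmax, Km) Vmax * S / (Km + S)

#' @rdname forwardModels
#' @export
hillActivation <- function(S, vBasal, vMax, Kact, nHill) {
  f <- ifelse(S > 0, S^nHill / (Kact^nHill + S^nHill), 0)
  vBasal + (vMax - vBasal) * f
}

#' @rdname forwardModels
#' @export
thermalSigmoid <- function(T_, low, high, Tm, slope)
  low + (high - low) / (1 + exp((Tm - T_) / slope))
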