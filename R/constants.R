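# Physical constants (CODATA where applicable). Electron rest energy is kept
# at 0.511 MeV, the value used throughout the Compton kinematics here.
ELECTRON_REST_MEV <- 0.511
CLASSICAL_ELECTRON_RADIUS_CM <- 2.8179403262e-13
AVOGADRO <- 6.02214076e23
FINE_STRUCTURE <- 1 / 137.035999084
THOMSON_XS_CM2 <- 6.6524587321e-25
MEV_PER_G_TO_GY <- 1.602176634e-10   # 1 MeV/g = 1.602176634e-10 J/kg
PAIR_THRESHOLD_MEV <- 2 * ELECTRON_REST_MEV

#' Convert absorbed dose from MeV/g to gray
#'
#' @param dose_mev_g Numeric vector of doses in MeV per gram.
#' @return Dose in Gy (J/kg).
#' @export
to_gray <- function(dose_mev_g) {
  if (any(!is.finite(dose_mev_g)) || any(dose_mev_g < 0))
    stop("dose must be finite and non-negative")
  dose_mev_g * MEV_PER_G_TO_GY
}

#' Express a dose in attogray
#'
#' Convenience display scale for per-source-photon doses (1 aGy = 1e-18 Gy).
#'
#' @param dose_gy Numeric vector of doses in Gy.
#' @return Dose in aGy.
#' @export
format_attogray <- function(dose_gy) {
  if (any(!is.finite(dose_gy)) || any(dose_gy < 0))
    stop("dose must be finite and non-negative")
  dose_gy * 1e18
}
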