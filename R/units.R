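#' Physical constants used throughout
#'
#' Planck constant (J s), speed of light (m s^-1), Avogadro constant (mol^-1),
#' Angstrom^2 per m^2 and per cm^2.
#' @keywords internal
.const <- list(
  h        = 6.62607015e-34,
  c        = 2.99792458e8,
  avogadro = 6.02214076e23,
  A2_per_m2  = 1e20,
  A2_per_cm2 = 1e16
)

#' Photon flux of an optical beam from its power density
#'
#' Converts a power density (W cm^-2) at a given wavelength into a photon
#' flux in photons per square Angstrom per second, the unit in which the
#' product with sigmaPSII (in A^2) gives PSII excitation hits per second.
#'
#' @param power_W_cm2 Power density, W cm^-2 (>= 0).
#' @param wavelength_nm Wavelength, nm (> 0). Flux is linear in the
#'   wavelength (one photon carries hc/lambda joules).
#' @return Photon flux, photons A^-2 s^-1.
#' @examples
#' photon_flux_from_power(1, 450)  # ~226.5 photons A^-2 s^-1
#' @export
photon_flux_from_power <- function(power_W_cm2, wavelength_nm) {
  if (!is.numeric(power_W_cm2) || any(power_W_cm2 < 0)) {
    stop("`power_W_cm2` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(wavelength_nm) || any(wavelength_nm <= 0)) {
    stop("`wavelength_nm` must be > 0", call. = FALSE)
  }
  e_photon <- .const$h * .const$c / (wavelength_nm * 1e-9)  # J per photon
  power_W_cm2 / e_photon / .const$A2_per_cm2
}

#' Photon flux from a quantum irradiance
#'
#' Converts the usual PAR-style irradiance (umol photons m^-2 s^-1) into
#' photons per square Angstrom per second.
#'
#' @param E Irradiance, umol photons m^-2 s^-1 (>= 0).
#' @return Photon flux, photons A^-2 s^-1.
#' @examples
#' photon_flux_from_quanta(100)  # 0.602214
#' @export
photon_flux_from_quanta <- function(E) {
  if (!is.numeric(E) || any(E < 0)) {
    stop("`E` must be >= 0", call. = FALSE)
  }
  E * 1e-6 * .const$avogadro / .const$A2_per_m2
}
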