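#' @keywords internal
"_PACKAGE"

## Physical constants used throughout. Cross-sections are expressed in units
## of the squared classical electron radius r_e^2: the tail fit supplies the
## global scale of the scatter estimate, so absolute normalisation constants
## cancel and are never needed.
.mec2_kev <- 511          # electron rest energy, keV
.c_mm_per_ps <- 0.299792458  # speed of light, mm/ps
.fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))

#' Energy of a Compton-scattered photon
#'
#' Compton kinematics: a photon of energy `E_kev` scattered through angle
#' `theta` leaves with energy `E / (1 + (E/511)(1 - cos theta))` (energies in
#' keV). For 511 keV annihilation photons the backscatter limit is 511/3 keV.
#'
#' @param E_kev Incident photon energy in keV (> 0). Vectorised.
#' @param theta Scattering angle in radians, in `[0, pi]`. Vectorised.
#' @return Scattered photon energy in keV.
#' @examples
#' scattered_energy(511, pi)      # 511/3
#' scattered_energy(511, pi / 2)  # 255.5
#' @export
scattered_energy <- function(E_kev, theta) {
  stopifnot(all(E_kev > 0), all(theta >= 0), all(theta <= pi + 1e-12))
  E_kev / (1 + (E_kev / .mec2_kev) * (1 - cos(theta)))
}

#' Klein-Nishina differential cross-section
#'
#' Differential cross-section of Compton scattering per unit solid angle,
#' `dsigma/dOmega = 1/2 r_e^2 (lambda/lambda')^2
#' [lambda/lambda' + lambda'/lambda - sin^2 theta]`, where
#' `lambda/lambda' = E'/E` is the Compton energy ratio. Returned in units of
#' `r_e^2` (set `re2` to get absolute values).
#'
#' @inheritParams scattered_energy
#' @param re2 Unit of the result; defaults to 1 so values are in `r_e^2`.
#' @return Differential cross-section, strictly positive.
#' @examples
#' klein_nishina_dcs(511, 0)      # 1  (forward scatter, in r_e^2)
#' klein_nishina_dcs(511, pi / 2) # 0.1875
#' @export
klein_nishina_dcs <- function(E_kev, theta, re2 = 1) {
  ratio <- scattered_energy(E_kev, theta) / E_kev  # = lambda/lambda'
  0.5 * re2 * ratio^2 * (ratio + 1 / ratio - sin(theta)^2)
}

#' Total Klein-Nishina cross-section
#'
#' Closed-form angle-integrated Klein-Nishina cross-section, in units of
#' `r_e^2`. Decreasing in energy; tends to the Thomson limit `8 pi / 3 r_e^2`
#' as `E -> 0`. Used to scale linear attenuation coefficients with photon
#' energy in a Compton-dominated medium.
#'
#' @inheritParams klein_nishina_dcs
#' @return Total cross-section in units of `r_e^2`.
#' @export
total_kn_cross_section <- function(E_kev, re2 = 1) {
  stopifnot(all(E_kev > 0))
  x <- E_kev / .mec2_kev
  2 * pi * re2 * (
    (1 + x) / x^2 * (2 * (1 + x) / (1 + 2 * x) - log1p(2 * x) / x) +
      log1p(2 * x) / (2 * x) - (1 + 3 * x) / (1 + 2 * x)^2
  )
}

#' Scale a 511 keV attenuation coefficient to another photon energy
#'
#' Treats the medium as Compton-dominated (Rayleigh and photoelectric
#' contributions neglected, a standard approximation for soft tissue at
#' annihilation energies): `mu(E) = mu(511) * sigma_KN(E) / sigma_KN(511)`.
#'
#' @param mu_511 Linear attenuation coefficient at 511 keV (1/mm), `>= 0`.
#' @param E_kev Photon energy in keV.
#' @return Attenuation coefficient at `E_kev`, same shape as `mu_511`.
#' @export
mu_at_energy <- function(mu_511, E_kev) {
  stopifnot(all(mu_511 >= 0))
  mu_511 * (total_kn_cross_section(E_kev) / total_kn_cross_section(.mec2_kev))
}

## FWHM (keV) of the detector energy response at energy E, from the fractional
## FWHM at 511 keV. Default statistical scintillator model: FWHM(E)/E ~
## 1/sqrt(E), i.e. FWHM(E) = f511 * sqrt(511 * E). The constant-relative
## alternative FWHM(E) = f511 * E is kept as an option.
energy_fwhm_kev <- function(E_kev, fwhm_frac_511,
                            model = c("sqrt", "constant")) {
  model <- match.arg(model)
  switch(model,
    sqrt = fwhm_frac_511 * sqrt(.mec2_kev * E_kev),
    constant = fwhm_frac_511 * E_kev
  )
}

#' Photon detection efficiency of the energy window
#'
#' Probability that a photon depositing energy `E_kev` is accepted by the
#' energy discriminators, under a Gaussian energy response whose FWHM at
#' 511 keV is `specs$energy_resolution_fwhm` (fractional) and scales with
#' energy per `resolution_model`. With no upper-level discriminator the
#' efficiency at `E = lld` is exactly 0.5 by symmetry.
#'
#' @param E_kev Deposited photon energy in keV. Vectorised.
#' @param specs List with `energy_resolution_fwhm` (fraction of 511 keV),
#'   `energy_lld_kev`, and optional finite `energy_uld_kev`.
#' @param resolution_model `"sqrt"` (default, FWHM(E)/E proportional to
#'   1/sqrt(E)) or `"constant"` (constant fractional FWHM).
#' @return Acceptance probability in `[0, 1]`.
#' @export
detection_efficiency <- function(E_kev, specs,
                                 resolution_model = c("sqrt", "constant")) {
  lld <- specs$energy_lld_kev
  uld <- specs$energy_uld_kev
  if (is.null(uld) || !is.finite(uld)) uld <- Inf
  if (lld >= uld) stop("energy_lld_kev must be below energy_uld_kev")
  sigma <- energy_fwhm_kev(E_kev, specs$energy_resolution_fwhm,
                           match.arg(resolution_model)) * .fwhm_to_sigma
  p <- stats::pnorm((uld - E_kev) / sigma) - stats::pnorm((lld - E_kev) / sigma)
  pmin(pmax(p, 0), 1)
}
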