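#' Chromophore library: melanin and hemoglobin extinction spectra
#'
#' Loads the effective extinction curves used by the absorption model. The
#' hemoglobin curve is a fixed oxy/deoxy mixture. Effective extinction means
#' absorption per unit chromophore volume fraction (units 1/mm), so the
#' absorption coefficient is simply `vf * extinction` -- concentration is
#' folded into the curve, since the tissue model parameterizes skin solely
#' through volume-fraction ranges.
#'
#' The shipped default curves are smooth synthetic approximations to
#' published eumelanin and oxy-/deoxyhemoglobin data (see the files'
#' headers); users may supply their own two-column files.
#'
#' @param oxygenation_fraction fraction of hemoglobin that is oxygenated,
#'   in \[0, 1\]. Default 0.75 (typical cutaneous mixed arterio-venous blood).
#' @param melanin,hemoglobin_oxy,hemoglobin_deoxy optional paths to
#'   two-column spectral files overriding the shipped curves.
#' @param wavelengths_nm grid the curves are resampled onto.
#' @return an object of class `chromophore_library` with `spectral_curve`
#'   fields `melanin` and `hemoglobin` (the oxy/deoxy mix) and the
#'   `oxygenation_fraction` used.
#' @export
chromophore_library <- function(oxygenation_fraction = 0.75,
                                melanin = NULL,
                                hemoglobin_oxy = NULL,
                                hemoglobin_deoxy = NULL,
                                wavelengths_nm = spectral_grid()) {
  if (oxygenation_fraction < 0 || oxygenation_fraction > 1)
    stop("oxygenation_fraction must be in [0, 1]")
  pkgfile <- function(f) system.file("extdata", f, package = "chromaderm",
                                     mustWork = TRUE)
  mel <- read_spectral_curve(melanin %||% pkgfile("extinction_eumelanin_synthetic.txt"))
  oxy <- read_spectral_curve(hemoglobin_oxy %||% pkgfile("extinction_hemoglobin_oxy_synthetic.txt"))
  deo <- read_spectral_curve(hemoglobin_deoxy %||% pkgfile("extinction_hemoglobin_deoxy_synthetic.txt"))
  mel <- resample_spectral(mel, wavelengths_nm, warn_extrapolate = FALSE)
  oxy <- resample_spectral(oxy, wavelengths_nm, warn_extrapolate = FALSE)
  deo <- resample_spectral(deo, wavelengths_nm, warn_extrapolate = FALSE)
  hb <- spectral_curve(wavelengths_nm,
                       oxygenation_fraction * oxy$values +
                         (1 - oxygenation_fraction) * deo$values)
  if (any(mel$values <= 0) || any(hb$values <= 0))
    stop("extinction curves must be strictly positive across the band")
  structure(list(melanin = mel, hemoglobin = hb,
                 oxygenation_fraction = oxygenation_fraction),
            class = "chromophore_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduced-scattering model parameters
#'
#' The reduced scattering coefficient is modelled as a Rayleigh/Mie mixture
#' `a * (f_Ray * (lambda/lambda0)^-4 + (1 - f_Ray) * (lambda/lambda0)^-b)`.
#' Defaults are representative soft-tissue values; all are configurable.
#'
#' @param amplitude_a scattering amplitude at the reference wavelength, 1/mm.
#' @param power_b Mie scattering power (dimensionless).
#' @param f_rayleigh fraction of Rayleigh scattering events, in \[0, 1\].
#' @param lambda0_nm reference wavelength, nm.
#' @return an object of class `scattering_params`.
#' @export
scattering_params <- function(amplitude_a = 4.0, power_b = 1.3,
                              f_rayleigh = 0.4, lambda0_nm = 500) {
  stopifnot(is.finite(amplitude_a), amplitude_a > 0,
            is.finite(power_b), power_b > 0,
            is.finite(lambda0_nm), lambda0_nm > 0)
  if (f_rayleigh < 0 || f_rayleigh > 1) stop("f_rayleigh must be in [0, 1]")
  structure(list(amplitude_a = amplitude_a, power_b = power_b,
                 f_rayleigh = f_rayleigh, lambda0_nm = lambda0_nm),
            class = "scattering_params")
}

#' Tissue-layer parameters
#'
#' Physiological volume-fraction ranges for melanin (epidermis) and
#' hemoglobin (dermis), and the epidermis thickness used by the
#' Beer-Lambert transmittance. Normalized map values in \[0, 1\] are mapped
#' affinely onto these ranges.
#'
#' @param melanin_vf_range melanin volume-fraction range, default 1.3%--43%.
#' @param hemoglobin_vf_range hemoglobin (blood) volume-fraction range,
#'   default 2%--7%.
#' @param epidermis_thickness_mm epidermis thickness in mm (default 0.06).
#' @return an object of class `tissue_params`.
#' @export
tissue_params <- function(melanin_vf_range = c(0.013, 0.43),
                          hemoglobin_vf_range = c(0.02, 0.07),
                          epidermis_thickness_mm = 0.06) {
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] >= r[2] || r[1] < 0 || r[2] > 1)
      stop(nm, " must be an increasing pair within [0, 1]")
  }
  chk(melanin_vf_range, "melanin_vf_range")
  chk(hemoglobin_vf_range, "hemoglobin_vf_range")
  stopifnot(is.finite(epidermis_thickness_mm), epidermis_thickness_mm > 0)
  structure(list(melanin_vf_range = melanin_vf_range,
                 hemoglobin_vf_range = hemoglobin_vf_range,
                 epidermis_thickness_mm = epidermis_thickness_mm,
                 dermis_semi_infinite = TRUE),
            class = "tissue_params")
}

#' Absorption coefficient of skin chromophores
#'
#' `mu_a(lambda) = vm * eps_mel(lambda) + vh * eps_hb(lambda)`, linear in
#' each volume fraction. Units 1/mm.
#'
#' @param lambda_nm wavelength(s) in nm, within the library support.
#' @param vm melanin volume fraction (scalar or vector), >= 0.
#' @param vh hemoglobin volume fraction (scalar or vector), >= 0.
#' @param lib a [chromophore_library()].
#' @return absorption coefficient(s), 1/mm.
#' @export
absorption_coefficient <- function(lambda_nm, vm, vh, lib) {
  if (any(vm < 0) || any(vh < 0)) stop("volume fractions must be nonnegative")
  vm * eval_spectral(lib$melanin, lambda_nm) +
    vh * eval_spectral(lib$hemoglobin, lambda_nm)
}

#' Reduced scattering coefficient
#'
#' Rayleigh/Mie mixture, strictly decreasing in wavelength. Units 1/mm.
#'
#' @inheritParams absorption_coefficient
#' @param p a [scattering_params()].
#' @return reduced scattering coefficient(s), 1/mm.
#' @export
reduced_scattering <- function(lambda_nm, p) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  x <- lambda_nm / p$lambda0_nm
  p$amplitude_a * (p$f_rayleigh * x^(-4) + (1 - p$f_rayleigh) * x^(-p$power_b))
}

#' Epidermis transmittance
#'
#' Beer-Lambert single-pass transmission through a finite epidermis with
#' melanin as the sole absorber: `T = exp(-vm * eps_mel(lambda) * d)`.
#' Strictly decreasing in `vm`; equals 1 at `vm = 0`.
#'
#' @inheritParams absorption_coefficient
#' @param t a [tissue_params()].
#' @return transmitted fraction(s) in (0, 1\].
#' @export
epidermis_transmittance <- function(lambda_nm, vm, t, lib) {
  if (any(vm < 0)) stop("melanin volume fraction must be nonnegative")
  mu <- vm * eval_spectral(lib$melanin, lambda_nm)
  exp(-mu * t$epidermis_thickness_mm)
}

#' Dermis reflectance (semi-infinite Kubelka-Munk)
#'
#' Two-flux reflectance of a semi-infinite scattering dermis with hemoglobin
#' as absorber: `R_inf = 1 + K/S - sqrt((K/S)^2 + 2 K/S)` with the
#' `K = 2 mu_a`, `S = mu_s'` convention. Bounded in \[0, 1\], decreasing in
#' K/S, and 1 for a lossless medium.
#'
#' @inheritParams absorption_coefficient
#' @param t a [tissue_params()].
#' @param s a [scattering_params()].
#' @return reflected fraction(s) in \[0, 1\].
#' @export
dermis_reflectance <- function(lambda_nm, vh, t, s, lib) {
  if (any(vh < 0)) stop("hemoglobin volume fraction must be nonnegative")
  S <- reduced_scattering(lambda_nm, s)
  if (any(S <= 0)) stop("Kubelka-Munk reflectance undefined without scattering")
  K <- 2 * vh * eval_spectral(lib$hemoglobin, lambda_nm)
  km_rinf(K / S)
}

# semi-infinite Kubelka-Munk reflectance as a function of the K/S ratio
km_rinf <- function(ks) {
  if (any(ks < 0)) stop("K/S must be nonnegative")
  1 + ks - sqrt(ks^2 + 2 * ks)
}

#' Two-layer skin reflectance
#'
#' `R(lambda) = T_epidermis(lambda)^2 * R_dermis(lambda)`: light crosses the
#' melanin-bearing epidermis, diffusely reflects off the hemoglobin-bearing
#' dermis, and crosses the epidermis again. Non-increasing in both volume
#' fractions at every wavelength.
#'
#' @inheritParams dermis_reflectance
#' @param vm melanin volume fraction.
#' @return reflectance fraction(s) in \[0, 1\].
#' @export
skin_reflectance <- function(lambda_nm, vm, vh, t, s, lib) {
  epidermis_transmittance(lambda_nm, vm, t, lib)^2 *
    dermis_reflectance(lambda_nm, vh, t, s, lib)
}

#' Full reflectance spectrum for one (vm, vh) pair
#'
#' @inheritParams skin_reflectance
#' @param wavelengths_nm sampling grid.
#' @return a [spectral_curve()] of reflectance.
#' @export
reflectance_spectrum <- function(vm, vh, t, s, lib,
                                 wavelengths_nm = spectral_grid()) {
  spectral_curve(wavelengths_nm,
                 skin_reflectance(wavelengths_nm, vm, vh, t, s, lib))
}
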