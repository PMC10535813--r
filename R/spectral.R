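#' Sampled spectral curve
#'
#' A spectral curve is a function of wavelength sampled on a strictly
#' increasing grid inside the visible band used throughout the package,
#' 450--750 nm. All spectral quantities (chromophore extinction, illuminant
#' power, sensor quantum efficiency, reflectance) are carried as
#' `spectral_curve` objects.
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths
#'   in nanometres, within \[450, 750\].
#' @param values nonnegative finite numeric vector, same length.
#' @return an object of class `spectral_curve` with fields `wavelengths_nm`
#'   and `values`.
#' @export
spectral_curve <- function(wavelengths_nm, values) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths_nm) < 2L)
    stop("a spectral curve needs at least two samples")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and nonnegative")
  if (min(wavelengths_nm) < 450 - 1e-9 || max(wavelengths_nm) > 750 + 1e-9)
    stop("wavelengths must lie within [450, 750] nm")
  structure(list(wavelengths_nm = wavelengths_nm, values = values),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %d samples, %g-%g nm, values %.4g-%.4g\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), min(x$values), max(x$values)))
  invisible(x)
}

#' Read a spectral curve from a two-column text file
#'
#' The file dialect is two whitespace-separated columns (wavelength_nm,
#' value) with `#` comment lines; the same dialect is used for all shipped
#' chromophore, illuminant and sensor data.
#'
#' @param path file path.
#' @return a [spectral_curve()].
#' @export
read_spectral_curve <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", col.names = c("wl", "value"))
  spectral_curve(tab$wl, tab$value)
}

#' Evaluate a spectral curve at arbitrary wavelengths
#'
#' Linear interpolation on the sample grid. Wavelengths outside the curve's
#' support raise an error (the optical model is only defined on the band the
#' data cover).
#'
#' @param curve a [spectral_curve()].
#' @param lambda_nm numeric vector of wavelengths in nm.
#' @return numeric vector of interpolated values.
#' @export
eval_spectral <- function(curve, lambda_nm) {
  rng <- range(curve$wavelengths_nm)
  if (any(lambda_nm < rng[1] - 1e-9) || any(lambda_nm > rng[2] + 1e-9))
    stop(sprintf("wavelength outside curve support [%g, %g] nm", rng[1], rng[2]))
  stats::approx(curve$wavelengths_nm, curve$values, xout = lambda_nm,
                rule = 2)$y
}

#' Resample a spectral curve onto a new grid
#'
#' @inheritParams eval_spectral
#' @param wavelengths_nm target grid (strictly increasing, inside the band).
#' @param warn_extrapolate warn if the target grid extends beyond the curve's
#'   support (end values are clamped).
#' @return a [spectral_curve()] on the new grid.
#' @export
resample_spectral <- function(curve, wavelengths_nm, warn_extrapolate = TRUE) {
  rng <- range(curve$wavelengths_nm)
  outside <- wavelengths_nm < rng[1] - 1e-9 | wavelengths_nm > rng[2] + 1e-9
  if (any(outside) && warn_extrapolate)
    warning("resampling extrapolates beyond curve support; end values clamped")
  v <- stats::approx(curve$wavelengths_nm, curve$values,
                     xout = wavelengths_nm, rule = 2)$y
  spectral_curve(wavelengths_nm, v)
}

#' Default wavelength grid: 5-nm steps over 450--750 nm (61 samples)
#' @param step_nm grid step in nm.
#' @return numeric vector of wavelengths.
#' @export
spectral_grid <- function(step_nm = 5) seq(450, 750, by = step_nm)

# trapezoid quadrature weights for a (possibly non-uniform) grid
trapz_weights <- function(wl) {
  n <- length(wl)
  w <- numeric(n)
  d <- diff(wl)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}
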