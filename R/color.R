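# Spectral-to-RGB rendering configuration and color-space conversions:
# camera integration under an illuminant, white balance, camera->XYZ->RGB
# matrices, the sRGB transfer function, and CIELAB.

# standard linear-sRGB <-> XYZ (D65) matrices, full IEC precision so the
# white point round-trips exactly
.XYZ_TO_RGB <- matrix(c(3.2409699419, -1.5373831776, -0.4986107603,
                        -0.9692436363, 1.8759675015, 0.0415550574,
                        0.0556300797, -0.2039769589, 1.0569715142),
                      3, 3, byrow = TRUE)
.RGB_TO_XYZ <- matrix(c(0.4123907993, 0.3575843394, 0.1804807884,
                        0.2126390059, 0.7151686788, 0.0721923154,
                        0.0193308187, 0.1191947798, 0.9505321522),
                      3, 3, byrow = TRUE)
# reference white = the sRGB matrix white (row sums), so the achromatic
# axis maps exactly to a* = b* = 0
.D65_WHITE <- c(X = sum(.RGB_TO_XYZ[1, ]), Y = sum(.RGB_TO_XYZ[2, ]),
                Z = sum(.RGB_TO_XYZ[3, ]))

#' CIE 1931 color matching functions (analytic approximation)
#'
#' Multi-Gaussian analytic fit to the 2-degree standard observer
#' (piecewise-sigma Gaussian lobes). Adequate for sensor-matrix fitting;
#' not a replacement for tabulated CMFs in colorimetric-grade work.
#'
#' @param lambda_nm wavelengths in nm.
#' @return matrix with columns x, y, z.
#' @export
cie_cmf <- function(lambda_nm) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  x <- 1.056 * g(lambda_nm, 599.8, 37.9, 31.0) +
    0.362 * g(lambda_nm, 442.0, 16.0, 26.7) -
    0.065 * g(lambda_nm, 501.1, 20.4, 26.2)
  y <- 0.821 * g(lambda_nm, 568.8, 46.9, 40.5) +
    0.286 * g(lambda_nm, 530.9, 16.3, 31.1)
  z <- 1.217 * g(lambda_nm, 437.0, 11.8, 36.0) +
    0.681 * g(lambda_nm, 459.0, 26.0, 13.8)
  cbind(x = x, y = y, z = z)
}

#' Rendering configuration: illuminant, sensor and color matrices
#'
#' Bundles everything needed to project a reflectance spectrum to
#' white-balanced linear RGB: the illuminant SPD `L(lambda)`, the three
#' sensor quantum-efficiency curves, the camera-RGB-to-XYZ matrix, the
#' XYZ-to-linear-RGB matrix, and the white-balance factors.
#'
#' The camera matrix is fitted at construction by least squares, mapping the
#' white-balanced monochromatic sensor responses onto the CIE observer
#' responses under the same illuminant, and is then adjusted so that the
#' combined matrix chain maps camera white (1,1,1) to linear-RGB white
#' exactly (white-point preservation). White-balance factors are the
#' reciprocal camera response to a perfect reflector, so the full chain maps
#' a perfect reflector to (1,1,1).
#'
#' @param illuminant,qe_r,qe_g,qe_b optional [spectral_curve()]s (or paths to
#'   two-column files) overriding the shipped synthetic D65 and idealized
#'   Gaussian sensor curves.
#' @param wavelengths_nm integration grid (default 5-nm steps, 450--750 nm).
#' @return an object of class `render_config`.
#' @export
render_config <- function(illuminant = NULL, qe_r = NULL, qe_g = NULL,
                          qe_b = NULL, wavelengths_nm = spectral_grid()) {
  pkgfile <- function(f) system.file("extdata", f, package = "chromaderm",
                                     mustWork = TRUE)
  as_curve <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.character(x)) x <- read_spectral_curve(x)
    resample_spectral(x, wavelengths_nm, warn_extrapolate = FALSE)
  }
  L <- as_curve(illuminant, pkgfile("illuminant_d65_synthetic.txt"))
  qr_ <- as_curve(qe_r, pkgfile("sensor_qe_r_synthetic.txt"))
  qg_ <- as_curve(qe_g, pkgfile("sensor_qe_g_synthetic.txt"))
  qb_ <- as_curve(qe_b, pkgfile("sensor_qe_b_synthetic.txt"))
  qe <- cbind(r = qr_$values, g = qg_$values, b = qb_$values)
  w <- trapz_weights(wavelengths_nm)

  # camera response to a perfect reflector -> white balance factors
  cam_white <- as.numeric(crossprod(qe, w * L$values))
  if (any(cam_white <= 0)) stop("sensor channel with zero response to the illuminant")
  wb <- 1 / cam_white

  # least-squares fit of white-balanced monochromatic camera responses to
  # the CIE observer responses (both under L), scaled so white has Y = 1
  cmf <- cie_cmf(wavelengths_nm)
  Q <- (w * L$values) * qe          # rows: wavelengths, cols: camera channels
  Qwb <- sweep(Q, 2, wb, `*`)
  X <- (w * L$values) * cmf
  Yw <- sum(X[, "y"])
  X <- X / Yw
  cam_to_xyz <- t(qr.solve(Qwb, X))            # XYZ ~ cam_to_xyz %*% wb_cam
  # white-point preservation: force the combined chain to map camera white
  # (after wb this is (1,1,1)) exactly onto linear-RGB white
  M <- .XYZ_TO_RGB %*% cam_to_xyz
  v <- as.numeric(M %*% c(1, 1, 1))
  if (any(abs(v) < 1e-12)) stop("degenerate camera matrix fit")
  cam_to_xyz <- solve(.XYZ_TO_RGB) %*% (M / v)
  structure(list(wavelengths_nm = wavelengths_nm,
                 illuminant = L,
                 qe = qe,
                 wb_factors = wb,
                 cam_rgb_to_xyz = cam_to_xyz,
                 xyz_to_rgb = .XYZ_TO_RGB,
                 quad_weights = w),
            class = "render_config")
}

#' White balance factors of a rendering configuration
#'
#' Reciprocal of the camera response to a perfect reflector (`R(lambda) = 1`,
#' unit shading) under the configured illuminant.
#'
#' @param cfg a [render_config()].
#' @return positive numeric triple.
#' @export
white_balance_factors <- function(cfg) cfg$wb_factors

#' Integrate a reflectance spectrum to camera RGB
#'
#' Per channel m: `I_m = integral L(lambda) R(lambda) M_shading C_m(lambda)
#' dlambda` (trapezoid rule on the configuration grid). Linear in shading.
#' Reflectance sampled on a different grid is resampled with a warning when
#' that requires extrapolation.
#'
#' @param reflectance a [spectral_curve()] with values in \[0, 1\], or a
#'   numeric vector already on the configuration grid.
#' @param shading nonnegative multiplicative shading scalar.
#' @param cfg a [render_config()].
#' @return camera-RGB triple (not yet white balanced).
#' @export
spectral_to_camera_rgb <- function(reflectance, shading = 1, cfg) {
  if (shading < 0) stop("shading must be nonnegative")
  if (inherits(reflectance, "spectral_curve")) {
    if (!isTRUE(all.equal(reflectance$wavelengths_nm, cfg$wavelengths_nm)))
      reflectance <- resample_spectral(reflectance, cfg$wavelengths_nm)
    refl <- reflectance$values
  } else refl <- as.numeric(reflectance)
  if (length(refl) != length(cfg$wavelengths_nm))
    stop("reflectance sampling does not match the configuration grid")
  as.numeric(crossprod(cfg$qe, cfg$quad_weights * cfg$illuminant$values *
                         refl * shading))
}

#' Convert camera RGB to linear RGB
#'
#' Applies white balance, the fitted camera-to-XYZ matrix and the
#' XYZ-to-linear-RGB matrix, then clips to \[0, 1\]. The fraction of clipped
#' values is attached as attribute `clip_fraction` (and reported via
#' `message()` when nonzero and `verbose`).
#'
#' @param cam_rgb numeric triple or N x 3 matrix of camera RGB.
#' @param cfg a [render_config()].
#' @param clip clip the result into \[0, 1\] (default TRUE).
#' @param verbose report the clipped fraction.
#' @return linear-RGB values, same shape as input.
#' @export
camera_to_linear_rgb <- function(cam_rgb, cfg, clip = TRUE, verbose = FALSE) {
  v <- if (is.matrix(cam_rgb)) cam_rgb else matrix(cam_rgb, ncol = 3)
  M <- cfg$xyz_to_rgb %*% cfg$cam_rgb_to_xyz
  out <- sweep(v, 2, cfg$wb_factors, `*`) %*% t(M)
  frac <- 0
  if (clip) {
    frac <- mean(out < 0 | out > 1)
    if (frac > 0 && verbose)
      message(sprintf("camera_to_linear_rgb: clipped %.2f%% of values", 100 * frac))
    out <- pmin(pmax(out, 0), 1)
  }
  if (!is.matrix(cam_rgb)) out <- as.numeric(out)
  attr(out, "clip_fraction") <- frac
  out
}

#' sRGB transfer function and its inverse
#'
#' Standard piecewise linear + power transfer (thresholds 0.0031308 /
#' 0.04045). `linear_to_srgb()` encodes linear intensities to sRGB;
#' `srgb_to_linear()` is the inverse gamma correction restoring linear
#' attributes of color. Mutual inverses on \[0, 1\].
#'
#' When given a [skin_image()], the color-space tag is checked (encoding an
#' already-sRGB image is an error) and the returned image is retagged.
#'
#' @param x numeric vector/array in \[0, 1\], or a [skin_image()].
#' @return same shape as input.
#' @export
linear_to_srgb <- function(x) {
  if (inherits(x, "skin_image")) {
    if (x$color_space != "linear") stop("image is not tagged linear")
    x$data <- linear_to_srgb(x$data)
    x$color_space <- "srgb"
    return(x)
  }
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' @rdname linear_to_srgb
#' @export
srgb_to_linear <- function(x) {
  if (inherits(x, "skin_image")) {
    if (x$color_space != "srgb") stop("image is not tagged srgb")
    x$data <- srgb_to_linear(x$data)
    x$color_space <- "linear"
    return(x)
  }
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' Convert sRGB to CIE L*a*b* (D65 white)
#'
#' @param rgb sRGB triple in \[0, 1\] or N x 3 matrix.
#' @param white_point XYZ of the reference white (default D65).
#' @return named triple (L, a, b) or N x 3 matrix.
#' @export
rgb_to_lab <- function(rgb, white_point = .D65_WHITE) {
  v <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  xyz <- srgb_to_linear(v) %*% t(.RGB_TO_XYZ)
  xyz <- sweep(xyz, 2, white_point, `/`)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1]); fy <- f(xyz[, 2]); fz <- f(xyz[, 3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (!is.matrix(rgb)) out <- stats::setNames(as.numeric(out), c("L", "a", "b"))
  out
}

#' Convert CIE L*a*b* (D65 white) to sRGB
#'
#' Inverse of [rgb_to_lab()]; out-of-gamut results are clipped to \[0, 1\].
#'
#' @param lab triple (L, a, b) or N x 3 matrix.
#' @param white_point XYZ of the reference white (default D65).
#' @return sRGB values in \[0, 1\].
#' @export
lab_to_srgb <- function(lab, white_point = .D65_WHITE) {
  v <- if (is.matrix(lab)) lab else matrix(lab, ncol = 3)
  fy <- (v[, 1] + 16) / 116
  fx <- fy + v[, 2] / 500
  fz <- fy - v[, 3] / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, white_point, `*`)
  lin <- pmin(pmax(xyz %*% t(.XYZ_TO_RGB), 0), 1)
  out <- linear_to_srgb(lin)
  if (!is.matrix(lab)) out <- as.numeric(out)
  out
}
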