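#' Per-pixel pigment maps
#'
#' Melanin, hemoglobin and shading fields in normalized \[0, 1\] units on a
#' common H x W grid. A normalized value v maps affinely onto the
#' physiological volume-fraction range: `vf = lo + v * (hi - lo)`.
#'
#' @param melanin,hemoglobin,shading numeric H x W matrices in \[0, 1\].
#' @return an object of class `pigment_maps`.
#' @export
pigment_maps <- function(melanin, hemoglobin, shading) {
  dims <- dim(melanin)
  if (is.null(dims)) stop("maps must be matrices")
  for (m in list(melanin, hemoglobin, shading)) {
    if (!all(dim(m) == dims)) stop("all maps must share the same shape")
    if (any(m < -1e-9) || any(m > 1 + 1e-9))
      stop("map values must lie in [0, 1]")
  }
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  structure(list(melanin = clip01(melanin), hemoglobin = clip01(hemoglobin),
                 shading = clip01(shading)),
            class = "pigment_maps")
}

#' @export
print.pigment_maps <- function(x, ...) {
  d <- dim(x$melanin)
  cat(sprintf("<pigment_maps> %d x %d; melanin %.2f-%.2f, hemoglobin %.2f-%.2f, shading %.2f-%.2f\n",
              d[1], d[2], min(x$melanin), max(x$melanin),
              min(x$hemoglobin), max(x$hemoglobin),
              min(x$shading), max(x$shading)))
  invisible(x)
}

#' Map normalized pigment values to volume fractions
#'
#' Affine rescale of the normalized \[0, 1\] melanin and hemoglobin maps into
#' the declared physiological ranges: 0 maps to the lower bound, 1 to the
#' upper bound. Values outside \[0, 1\] are clipped with a warning.
#'
#' @param maps a [pigment_maps()].
#' @param t a [tissue_params()].
#' @return list with matrices `vm` and `vh` of volume fractions.
#' @export
maps_to_volume_fractions <- function(maps, t = tissue_params()) {
  resc <- function(m, r) {
    if (any(m < 0) || any(m > 1)) {
      warning("map values outside [0, 1] clipped before rescaling")
      m <- pmin(pmax(m, 0), 1)
    }
    r[1] + m * (r[2] - r[1])
  }
  list(vm = resc(maps$melanin, t$melanin_vf_range),
       vh = resc(maps$hemoglobin, t$hemoglobin_vf_range))
}

#' Render pigment maps to a linear-RGB image
#'
#' The differentiable forward model: per pixel, the melanin and hemoglobin
#' maps are rescaled to volume fractions on the LUT's ranges, looked up by
#' bilinear interpolation, and multiplied by the shading map. Output values
#' stay in \[0, 1\] because the table entries do. With `grad = TRUE` the
#' partial derivatives of every output channel with respect to the three
#' (normalized) map values are returned as well, enabling backpropagation
#' into the maps.
#'
#' @param maps a [pigment_maps()].
#' @param lut a [build_reflectance_lut()] result (its grids define the
#'   volume-fraction ranges used in the rescale).
#' @param grad also return per-pixel gradients.
#' @return an H x W x 3 linear-RGB array; with `grad`, a list with `rgb`
#'   plus H x W x 3 arrays `d_melanin`, `d_hemoglobin`, `d_shading`.
#' @export
render_maps <- function(maps, lut, grad = FALSE) {
  stopifnot(inherits(maps, "pigment_maps"), inherits(lut, "reflectance_lut"))
  d <- dim(maps$melanin)
  vm_rng <- range(lut$vm_grid); vh_rng <- range(lut$vh_grid)
  vm <- vm_rng[1] + as.vector(maps$melanin) * diff(vm_rng)
  vh <- vh_rng[1] + as.vector(maps$hemoglobin) * diff(vh_rng)
  s <- as.vector(maps$shading)
  lk <- lut_lookup(lut, vm, vh, grad = grad)
  rgb <- array(lk$rgb * s, c(d, 3))
  if (!grad) return(rgb)
  list(rgb = rgb,
       d_melanin = array(lk$d_vm * s * diff(vm_rng), c(d, 3)),
       d_hemoglobin = array(lk$d_vh * s * diff(vh_rng), c(d, 3)),
       d_shading = array(lk$rgb, c(d, 3)))
}

#' Masked reconstruction-quality metrics
#'
#' Mean squared error and peak signal-to-noise ratio between two equally
#' shaped images, restricted to masked pixels (all pixels when `mask` is
#' NULL). PSNR uses peak 1.0 (normalized intensities) and returns `Inf` for
#' identical images.
#'
#' @param img_a,img_b numeric arrays of identical shape.
#' @param mask optional H x W binary matrix; must select at least one pixel.
#' @return `mse()`: nonnegative scalar; `psnr()`: value in dB.
#' @export
mse <- function(img_a, img_b, mask = NULL) {
  if (!all(dim(img_a) == dim(img_b))) stop("image shapes differ")
  d2 <- (img_a - img_b)^2
  if (is.null(mask)) return(mean(d2))
  keep <- mask != 0
  if (!any(keep)) stop("mask selects no pixels")
  if (length(dim(d2)) == 3) {
    sel <- matrix(d2, ncol = dim(d2)[3])[as.vector(keep), , drop = FALSE]
    mean(sel)
  } else mean(d2[keep])
}

#' @rdname mse
#' @export
psnr <- function(img_a, img_b, mask = NULL) {
  e <- mse(img_a, img_b, mask)
  if (e == 0) return(Inf)
  10 * log10(1 / e)
}
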