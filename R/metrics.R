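# Skin tone and pigmentation quantification: individual typology angle
# (ITA), optical density, melanin index, two erythema indices, and
# region-versus-surround contrast.
#
# Index convention: optical densities are computed on white-balanced linear
# RGB with reference intensity I0 = 1 (white-balanced reflectance is its
# own reference), so sRGB inputs are linearized first.

#' Individual typology angle (ITA)
#'
#' Mean sRGB over the masked skin area is converted to CIE L*a*b* (D65) and
#' the angle of the (L*, b*) coordinate relative to L = 50 is returned in
#' degrees: `atan2(L - 50, b) * 180 / pi`. Higher angles correspond to
#' lighter skin tone. The two-argument arctangent handles b = 0.
#'
#' @param img a [skin_image()] tagged srgb, or an H x W x 3 sRGB array.
#' @param mask optional binary matrix restricting the average (defaults to
#'   the image's own mask, or all pixels); must select at least one pixel.
#' @return ITA in degrees, in (-90, 90\].
#' @export
ita <- function(img, mask = NULL) {
  x <- as_srgb_array(img)
  mask <- resolve_mask(img, mask, dim(x)[1:2])
  rgb <- mean_masked_rgb(x, mask)
  lab <- rgb_to_lab(rgb)
  atan2(lab[["L"]] - 50, lab[["b"]]) * 180 / pi
}

as_srgb_array <- function(img) {
  if (inherits(img, "skin_image")) {
    if (img$color_space != "srgb") stop("ITA expects an sRGB-tagged image")
    img$data
  } else img
}

as_linear_array <- function(img) {
  if (inherits(img, "skin_image")) {
    if (img$color_space == "srgb") srgb_to_linear(img$data) else img$data
  } else img
}

resolve_mask <- function(img, mask, shape) {
  if (is.null(mask) && inherits(img, "skin_image")) mask <- img$mask
  if (is.null(mask)) mask <- matrix(1, shape[1], shape[2])
  if (!all(dim(mask) == shape)) stop("mask shape does not match image")
  if (!any(mask != 0)) stop("mask selects no pixels")
  mask
}

mean_masked_rgb <- function(x, mask) {
  keep <- as.vector(mask != 0)
  flat <- matrix(x, ncol = 3)[keep, , drop = FALSE]
  colMeans(flat)
}

#' Optical density
#'
#' `OD = -log10(I / I0)`; zero when the detected intensity equals the
#' reference. Zero intensities are capped at `od_max` with a warning (the
#' logarithm diverges).
#'
#' @param intensity nonnegative intensity (scalar, vector or array).
#' @param i0 positive reference intensity (default 1: white-balanced
#'   reflectance convention).
#' @param od_max cap applied where `intensity` is 0 (default 4).
#' @return optical density, same shape as `intensity`.
#' @export
optical_density <- function(intensity, i0 = 1, od_max = 4) {
  if (i0 <= 0) stop("reference intensity must be positive")
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  zero <- intensity == 0
  if (any(zero)) warning("zero intensity: optical density capped at od_max")
  od <- -log10(pmax(intensity, i0 * 10^(-od_max)) / i0)
  od[zero] <- od_max
  od
}

#' Melanin index (red-channel optical density)
#'
#' The optical-density slope in the red band is dominated by melanin, so the
#' OD of the red channel of a white-balanced linear image serves as a
#' simplified melanin index: `M.I = OD_R`.
#'
#' @param img a [skin_image()] (sRGB images are linearized first) or an
#'   H x W x 3 linear-RGB array.
#' @param mask optional binary matrix. When supplied (or present in the
#'   image) the mask-averaged scalar index is returned; with `mask = NA` a
#'   per-pixel index map is returned instead.
#' @param od_max cap for zero intensities, see [optical_density()].
#' @return scalar index, or an H x W map when `mask = NA`.
#' @export
melanin_index <- function(img, mask = NULL, od_max = 4) {
  x <- as_linear_array(img)
  m <- suppressWarnings(optical_density(x[, , 1], od_max = od_max))
  index_reduce(m, img, mask, dim(x)[1:2])
}

index_reduce <- function(map, img, mask, shape) {
  if (length(mask) == 1 && is.na(mask)) return(map)
  mask <- resolve_mask(img, mask, shape)
  mean(map[mask != 0])
}

#' Erythema indices
#'
#' Two hemoglobin-sensitive indices on white-balanced linear RGB:
#' `erythema_diffey()` is the optical-density difference between the green
#' and red channels, `E.I1 = OD_G - OD_R` (zero on achromatic pixels);
#' `erythema_jacovels()` combines all three channel intensities,
#' `E.I2 = I_B * I_R / I_G`, which compensates melanin interference. Pixels
#' with zero green intensity are excluded from E.I2 with a warning.
#'
#' @inheritParams melanin_index
#' @return scalar index, or an H x W map when `mask = NA` (excluded E.I2
#'   pixels are NA in the map).
#' @export
erythema_diffey <- function(img, mask = NULL, od_max = 4) {
  x <- as_linear_array(img)
  m <- suppressWarnings(optical_density(x[, , 2], od_max = od_max) -
                          optical_density(x[, , 1], od_max = od_max))
  index_reduce(m, img, mask, dim(x)[1:2])
}

#' @rdname erythema_diffey
#' @export
erythema_jacovels <- function(img, mask = NULL) {
  x <- as_linear_array(img)
  g <- x[, , 2]
  bad <- g == 0
  if (any(bad)) warning("pixels with zero green intensity excluded from E.I2")
  m <- x[, , 3] * x[, , 1] / g
  m[bad] <- NA_real_
  if (length(mask) == 1 && !is.null(mask) && is.na(mask)) return(m)
  mask <- resolve_mask(img, mask, dim(x)[1:2])
  mean(m[mask != 0], na.rm = TRUE)
}

#' Disjoint pigmented-region / surround mask pair
#'
#' @param region_mask binary matrix marking the pigmented area.
#' @param surround_mask binary matrix marking adjacent normal skin.
#' @return an object of class `region_pair`.
#' @export
region_pair <- function(region_mask, surround_mask) {
  if (!all(dim(region_mask) == dim(surround_mask)))
    stop("mask shapes differ")
  if (!any(region_mask != 0) || !any(surround_mask != 0))
    stop("both masks must be nonempty")
  if (any(region_mask != 0 & surround_mask != 0))
    stop("region and surround masks overlap")
  structure(list(region_mask = region_mask, surround_mask = surround_mask),
            class = "region_pair")
}

#' Region-versus-surround index contrast
#'
#' Difference of the mean pigment index over the pigmented region and over
#' the surrounding normal skin.
#'
#' @param index_map per-pixel index map (e.g. `melanin_index(img, mask = NA)`).
#' @param pair a [region_pair()].
#' @return scalar contrast (region mean minus surround mean).
#' @export
region_contrast <- function(index_map, pair) {
  stopifnot(inherits(pair, "region_pair"))
  mean(index_map[pair$region_mask != 0], na.rm = TRUE) -
    mean(index_map[pair$surround_mask != 0], na.rm = TRUE)
}

#' All pigment indices for one image
#'
#' Convenience report: ITA, melanin index and both erythema indices, plus
#' region contrasts when a [region_pair()] is supplied.
#'
#' @param img a [skin_image()] tagged srgb.
#' @param mask optional skin mask.
#' @param pair optional [region_pair()].
#' @return named list of indices.
#' @export
pigment_indices <- function(img, mask = NULL, pair = NULL) {
  lin <- as_linear_array(img)
  out <- list(ita_deg = ita(img, mask),
              mi = melanin_index(lin, resolve_mask(img, mask, dim(lin)[1:2])),
              ei1 = erythema_diffey(lin, resolve_mask(img, mask, dim(lin)[1:2])),
              ei2 = erythema_jacovels(lin, resolve_mask(img, mask, dim(lin)[1:2])))
  if (!is.null(pair)) {
    out$mi_contrast <- region_contrast(melanin_index(lin, mask = NA), pair)
    out$ei1_contrast <- region_contrast(erythema_diffey(lin, mask = NA), pair)
    out$ei2_contrast <- region_contrast(erythema_jacovels(lin, mask = NA), pair)
  }
  out
}

#' ITA skin-tone category bands
#'
#' Conventional ITA category bounds, exposed as a lookup only -- no
#' computation in the package depends on the labels.
#'
#' @param ita_deg ITA value(s) in degrees.
#' @return character vector of categories.
#' @export
ita_category <- function(ita_deg) {
  cut(ita_deg, breaks = c(-Inf, -30, 10, 28, 41, 55, Inf),
      labels = c("dark", "brown", "tan", "intermediate", "light", "very light"),
      right = FALSE)
}
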