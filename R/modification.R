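# Numerically controlled pigment modification: additive shifts of whole
# maps change overall skin tone; multiplicative scaling changes the
# contrast of pigmented regions against their surround. Modified maps are
# re-rendered through the forward model into sRGB images.

#' Modification specification
#'
#' Exactly one mode is active. Additive deltas act on the normalized
#' \[0, 1\] maps, so the conventional -1 to +1 range spans the full
#' physiological range and saturates exactly at its ends. Multiplicative
#' factors conventionally span 0.8--1.4 for melanin and 0.6--1.4 for
#' hemoglobin. An optional region mask restricts scaling to a region
#' (extension, off by default -- the reference procedure scales whole maps
#' and measures contrast against the surround).
#'
#' @param mode `"additive"` or `"multiplicative"`.
#' @param delta_melanin,delta_hemoglobin additive shifts in normalized
#'   units (additive mode).
#' @param factor_melanin,factor_hemoglobin positive scale factors
#'   (multiplicative mode).
#' @param region_mask optional binary matrix restricting a multiplicative
#'   modification.
#' @return an object of class `modification_spec`.
#' @export
modification_spec <- function(mode = c("additive", "multiplicative"),
                              delta_melanin = 0, delta_hemoglobin = 0,
                              factor_melanin = 1, factor_hemoglobin = 1,
                              region_mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "multiplicative" &&
      (factor_melanin <= 0 || factor_hemoglobin <= 0))
    stop("scale factors must be positive")
  structure(list(mode = mode, delta_melanin = delta_melanin,
                 delta_hemoglobin = delta_hemoglobin,
                 factor_melanin = factor_melanin,
                 factor_hemoglobin = factor_hemoglobin,
                 region_mask = region_mask),
            class = "modification_spec")
}

clip_report <- function(m) {
  frac <- mean(m < 0 | m > 1)
  list(map = pmin(pmax(m, 0), 1), frac = frac)
}

#' Additive skin-tone shift of pigment maps
#'
#' `melanin' = clip(melanin + delta_m, 0, 1)` and likewise for hemoglobin;
#' the shading map is untouched. The fraction of clipped (saturated)
#' pixels per map is attached as attribute `clip_fraction` -- large
#' negative shifts drive many pixels to saturation near 0.
#'
#' @param maps a [pigment_maps()].
#' @param spec an additive [modification_spec()].
#' @return modified [pigment_maps()] with attribute `clip_fraction`.
#' @export
shift_maps <- function(maps, spec) {
  stopifnot(inherits(maps, "pigment_maps"), inherits(spec, "modification_spec"))
  if (spec$mode != "additive") stop("shift_maps needs an additive spec")
  mel <- clip_report(maps$melanin + spec$delta_melanin)
  hem <- clip_report(maps$hemoglobin + spec$delta_hemoglobin)
  out <- pigment_maps(mel$map, hem$map, maps$shading)
  attr(out, "clip_fraction") <- c(melanin = mel$frac, hemoglobin = hem$frac)
  out
}

#' Multiplicative scaling of pigment maps
#'
#' `map' = clip(map * factor, 0, 1)`, applied to the whole map or, when the
#' spec carries a region mask, only inside it.
#'
#' @inheritParams shift_maps
#' @param spec a multiplicative [modification_spec()].
#' @return modified [pigment_maps()] with attribute `clip_fraction`.
#' @export
scale_maps <- function(maps, spec) {
  stopifnot(inherits(maps, "pigment_maps"), inherits(spec, "modification_spec"))
  if (spec$mode != "multiplicative") stop("scale_maps needs a multiplicative spec")
  apply_factor <- function(m, f) {
    scaled <- if (is.null(spec$region_mask)) m * f
    else m * ifelse(spec$region_mask != 0, f, 1)
    clip_report(scaled)
  }
  mel <- apply_factor(maps$melanin, spec$factor_melanin)
  hem <- apply_factor(maps$hemoglobin, spec$factor_hemoglobin)
  out <- pigment_maps(mel$map, hem$map, maps$shading)
  attr(out, "clip_fraction") <- c(melanin = mel$frac, hemoglobin = hem$frac)
  out
}

#' Apply a modification spec (dispatch on mode)
#' @inheritParams shift_maps
#' @return modified [pigment_maps()].
#' @export
modify_maps <- function(maps, spec) {
  if (spec$mode == "additive") shift_maps(maps, spec) else scale_maps(maps, spec)
}

#' Generate a pigment-modified sRGB image
#'
#' Full pipeline: decompose the input into pigment maps, modify the melanin
#' and hemoglobin maps per the spec, re-render through the reflectance LUT,
#' and gamma-encode back to sRGB. An identity spec reproduces the model's
#' plain reconstruction exactly. (Rendering is per-pixel, so rendering the
#' blended full-resolution maps equals blending per-patch renderings.)
#'
#' @inheritParams decompose_image
#' @param spec a [modification_spec()].
#' @param lut the reflectance LUT the model was trained against.
#' @return a [skin_image()] tagged srgb with the input mask attached.
#' @export
generate_modified_image <- function(img, mask = NULL, model, spec, lut,
                                    grid = NULL) {
  x <- as_srgb_array(img)
  if (is.null(mask) && inherits(img, "skin_image")) mask <- img$mask
  if (is.null(mask)) mask <- matrix(1, dim(x)[1], dim(x)[2])
  maps <- decompose_image(img, mask, model, grid)
  maps <- modify_maps(maps, spec)
  lin <- render_maps(maps, lut)
  srgb <- linear_to_srgb(lin)
  skin_image(srgb, "srgb", mask)
}

#' Sweep a modification grid and collect skin-tone / contrast responses
#'
#' Convenience for validation plots: applies each additive delta (to one
#' pigment at a time) or each multiplicative factor and records the mean
#' ITA or the region contrast of the relevant index.
#'
#' @param img,mask,model,lut,grid as in [generate_modified_image()].
#' @param deltas additive grid (e.g. `seq(-1, 1, by = 0.2)`).
#' @param pigment `"melanin"` or `"hemoglobin"`.
#' @return data frame with the grid values and mean ITA.
#' @export
sweep_skin_tone <- function(img, mask = NULL, model, lut,
                            deltas = seq(-1, 1, by = 0.2),
                            pigment = c("melanin", "hemoglobin"),
                            grid = NULL) {
  pigment <- match.arg(pigment)
  maps <- decompose_image(img, mask, model, grid)
  if (is.null(mask) && inherits(img, "skin_image")) mask <- img$mask
  ita_vals <- vapply(deltas, function(d) {
    spec <- if (pigment == "melanin")
      modification_spec("additive", delta_melanin = d)
    else modification_spec("additive", delta_hemoglobin = d)
    mod <- modify_maps(maps, spec)
    out <- skin_image(linear_to_srgb(render_maps(mod, lut)), "srgb")
    ita(out, mask)
  }, numeric(1))
  data.frame(delta = deltas, ita_deg = ita_vals)
}
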