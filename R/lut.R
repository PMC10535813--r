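#' Precompute a (melanin, hemoglobin) -> linear-RGB reflectance table
#'
#' Evaluates the full spectral pipeline -- two-layer Kubelka-Munk
#' reflectance, illuminant/sensor integration, white balance and color
#' matrices (no shading, no gamma) -- on a regular grid of melanin and
#' hemoglobin volume fractions spanning the physiological ranges. The table
#' is what makes per-pixel rendering (and its gradients) cheap enough to
#' train against.
#'
#' @param t a [tissue_params()].
#' @param s a [scattering_params()].
#' @param lib a [chromophore_library()].
#' @param cfg a [render_config()].
#' @param grid_sizes integer pair: number of melanin and hemoglobin grid
#'   nodes (default 64 x 64; each must be >= 2).
#' @return an object of class `reflectance_lut` with fields `vm_grid`,
#'   `vh_grid` and `rgb_table` (array `n_vm x n_vh x 3` of white-balanced
#'   linear-RGB reflectance in \[0, 1\]).
#' @export
build_reflectance_lut <- function(t = tissue_params(), s = scattering_params(),
                                  lib = chromophore_library(),
                                  cfg = render_config(),
                                  grid_sizes = c(64, 64)) {
  if (length(grid_sizes) != 2 || any(grid_sizes < 2))
    stop("grid_sizes must be two integers >= 2")
  vm_grid <- seq(t$melanin_vf_range[1], t$melanin_vf_range[2],
                 length.out = grid_sizes[1])
  vh_grid <- seq(t$hemoglobin_vf_range[1], t$hemoglobin_vf_range[2],
                 length.out = grid_sizes[2])
  wl <- cfg$wavelengths_nm
  # camera integrals accumulated over wavelengths; R(lambda) separates into
  # T_epi(vm)^2 (outer) R_derm(vh) so each wavelength adds a rank-1 term
  cam <- array(0, c(length(vm_grid), length(vh_grid), 3))
  wLq <- cfg$quad_weights * cfg$illuminant$values   # length n_wl
  for (k in seq_along(wl)) {
    Te2 <- epidermis_transmittance(wl[k], vm_grid, t, lib)^2
    Rd <- dermis_reflectance(wl[k], vh_grid, t, s, lib)
    Rk <- outer(Te2, Rd)
    for (m in 1:3) cam[, , m] <- cam[, , m] + wLq[k] * cfg$qe[k, m] * Rk
  }
  flat <- matrix(cam, ncol = 3)
  rgb <- camera_to_linear_rgb(flat, cfg, clip = TRUE)
  structure(list(vm_grid = vm_grid, vh_grid = vh_grid,
                 rgb_table = array(rgb, c(length(vm_grid), length(vh_grid), 3))),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf("<reflectance_lut> %d x %d nodes, vm %.3f-%.3f, vh %.3f-%.3f\n",
              length(x$vm_grid), length(x$vh_grid), min(x$vm_grid),
              max(x$vm_grid), min(x$vh_grid), max(x$vh_grid)))
  invisible(x)
}

#' Bilinear lookup in a reflectance table
#'
#' Vectorized bilinear interpolation at arbitrary (vm, vh) volume-fraction
#' pairs; inputs are clipped to the grid ranges before lookup. Optionally
#' returns the partial derivatives of each channel with respect to vm and
#' vh (piecewise constant per grid cell), which is what backpropagation
#' through the renderer consumes.
#'
#' @param lut a [build_reflectance_lut()] result.
#' @param vm,vh numeric vectors (same length) of volume fractions.
#' @param grad also return `d_vm` and `d_vh` (N x 3 each).
#' @return list with `rgb` (N x 3) and, if `grad`, `d_vm`, `d_vh`.
#' @export
lut_lookup <- function(lut, vm, vh, grad = FALSE) {
  vmg <- lut$vm_grid; vhg <- lut$vh_grid
  vm <- pmin(pmax(vm, vmg[1]), vmg[length(vmg)])
  vh <- pmin(pmax(vh, vhg[1]), vhg[length(vhg)])
  i <- findInterval(vm, vmg, all.inside = TRUE)
  j <- findInterval(vh, vhg, all.inside = TRUE)
  dvm <- vmg[i + 1] - vmg[i]
  dvh <- vhg[j + 1] - vhg[j]
  u <- (vm - vmg[i]) / dvm
  v <- (vh - vhg[j]) / dvh
  n <- length(vm)
  rgb <- matrix(0, n, 3)
  if (grad) { gvm <- matrix(0, n, 3); gvh <- matrix(0, n, 3) }
  for (m in 1:3) {
    tab <- lut$rgb_table[, , m]
    c00 <- tab[cbind(i, j)]; c10 <- tab[cbind(i + 1, j)]
    c01 <- tab[cbind(i, j + 1)]; c11 <- tab[cbind(i + 1, j + 1)]
    rgb[, m] <- (1 - u) * (1 - v) * c00 + u * (1 - v) * c10 +
      (1 - u) * v * c01 + u * v * c11
    if (grad) {
      gvm[, m] <- ((c10 - c00) * (1 - v) + (c11 - c01) * v) / dvm
      gvh[, m] <- ((c01 - c00) * (1 - u) + (c11 - c10) * u) / dvh
    }
  }
  if (grad) list(rgb = rgb, d_vm = gvm, d_vh = gvh) else list(rgb = rgb)
}
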