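#' Load a pipeline configuration from YAML (or JSON)
#'
#' Recognized top-level keys (all optional; defaults shown in the
#' constructors): `tissue` (melanin_vf_range, hemoglobin_vf_range,
#' epidermis_thickness_mm), `scattering` (amplitude_a, power_b, f_rayleigh,
#' lambda0_nm), `grid` (lut_melanin, lut_hemoglobin node counts),
#' `wavelength_step_nm`, and `chromophores` (oxygenation_fraction plus
#' optional spectral file paths).
#'
#' @param path YAML or JSON file.
#' @return list with `tissue`, `scattering`, `library`, `render`,
#'   `grid_sizes` -- ready to hand to [build_reflectance_lut()].
#' @export
load_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  step <- raw$wavelength_step_nm %||% 5
  wl <- spectral_grid(step)
  t_args <- raw$tissue %||% list()
  if (!is.null(t_args$melanin_vf_range))
    t_args$melanin_vf_range <- as.numeric(t_args$melanin_vf_range)
  if (!is.null(t_args$hemoglobin_vf_range))
    t_args$hemoglobin_vf_range <- as.numeric(t_args$hemoglobin_vf_range)
  tissue <- do.call(tissue_params, t_args)
  scat <- do.call(scattering_params, raw$scattering %||% list())
  ch <- raw$chromophores %||% list()
  lib <- chromophore_library(
    oxygenation_fraction = ch$oxygenation_fraction %||% 0.75,
    melanin = ch$melanin, hemoglobin_oxy = ch$hemoglobin_oxy,
    hemoglobin_deoxy = ch$hemoglobin_deoxy, wavelengths_nm = wl)
  render <- render_config(wavelengths_nm = wl)
  g <- raw$grid %||% list()
  grid_sizes <- c(g$lut_melanin %||% 64, g$lut_hemoglobin %||% 64)
  list(tissue = tissue, scattering = scat, library = lib, render = render,
       grid_sizes = grid_sizes)
}

#' Build the default reflectance LUT from a pipeline configuration
#' @param config a [load_pipeline_config()] result (default configuration
#'   when NULL).
#' @return a [build_reflectance_lut()] result.
#' @export
default_lut <- function(config = NULL) {
  cfgs <- config %||% load_pipeline_config()
  build_reflectance_lut(cfgs$tissue, cfgs$scattering, cfgs$library,
                        cfgs$render, cfgs$grid_sizes)
}
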