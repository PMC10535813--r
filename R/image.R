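# Raster containers and plain-file IO: tagged sRGB/linear images with an
# optional binary skin mask, PNG/TIFF readers and writers with a JSON
# sidecar recording the color-space tag, and 16-bit persistence of pigment
# maps.

#' Tagged skin image
#'
#' An H x W x 3 raster of RGB values in \[0, 1\] with an explicit color-space
#' tag (`"srgb"` or `"linear"`) and an optional binary skin mask.
#'
#' @param data numeric H x W x 3 array in \[0, 1\].
#' @param color_space `"srgb"` or `"linear"`.
#' @param mask optional H x W binary (0/1 or logical) matrix.
#' @return an object of class `skin_image`.
#' @export
skin_image <- function(data, color_space = c("srgb", "linear"), mask = NULL) {
  color_space <- match.arg(color_space)
  if (length(dim(data)) != 3 || dim(data)[3] != 3)
    stop("data must be an H x W x 3 array")
  if (any(data < -1e-9) || any(data > 1 + 1e-9))
    stop("pixel values must lie in [0, 1]")
  data <- pmin(pmax(data, 0), 1)
  if (!is.null(mask)) {
    mask <- as_mask(mask, dim(data)[1:2])
  }
  structure(list(data = data, color_space = color_space, mask = mask),
            class = "skin_image")
}

#' @export
print.skin_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<skin_image> %d x %d, %s%s\n", d[1], d[2], x$color_space,
              if (is.null(x$mask)) "" else
                sprintf(", mask (%.0f%% skin)", 100 * mean(x$mask))))
  invisible(x)
}

as_mask <- function(mask, shape) {
  m <- matrix(as.numeric(mask != 0), shape[1], shape[2])
  if (!all(dim(mask) == shape)) stop("mask shape does not match image")
  m
}

#' Read / write a skin image (PNG or TIFF) with a color-space sidecar
#'
#' 8-bit PNG and 8/16-bit TIFF are supported. The color-space tag is stored
#' in a `<file>.json` sidecar on write and read back when present;
#' otherwise `color_space` must be supplied.
#'
#' @param path image file path (`.png`, `.tif`, `.tiff`).
#' @param color_space tag used when no sidecar exists.
#' @param mask optional binary mask (matrix, or path to a mask PNG).
#' @return a [skin_image()].
#' @export
read_skin_image <- function(path, color_space = NULL, mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  data <- switch(ext,
                 png = png::readPNG(path),
                 tif = ,
                 tiff = tiff::readTIFF(path),
                 stop("unsupported image format: ", ext))
  if (length(dim(data)) == 2) data <- array(rep(data, 3), c(dim(data), 3))
  if (dim(data)[3] > 3) data <- data[, , 1:3, drop = FALSE]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    color_space <- color_space %||% meta$color_space
  }
  if (is.null(color_space))
    stop("no sidecar found; supply color_space explicitly")
  if (is.character(mask)) mask <- png::readPNG(mask)
  if (!is.null(mask) && length(dim(mask)) == 3) mask <- mask[, , 1]
  skin_image(data, color_space, mask)
}

#' @rdname read_skin_image
#' @param img a [skin_image()].
#' @param bits bit depth for TIFF output (8 or 16; PNG is 8-bit).
#' @export
write_skin_image <- function(img, path, bits = 8) {
  stopifnot(inherits(img, "skin_image"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img$data, path),
         tif = ,
         tiff = tiff::writeTIFF(img$data, path, bits.per.sample = bits),
         stop("unsupported image format: ", ext))
  jsonlite::write_json(list(color_space = img$color_space), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Persist pigment maps as 16-bit grayscale TIFFs with a JSON sidecar
#'
#' Writes `<prefix>_melanin.tif`, `<prefix>_hemoglobin.tif`,
#' `<prefix>_shading.tif` (values are the normalized \[0, 1\] maps) plus
#' `<prefix>_maps.json` recording the volume-fraction ranges the normalized
#' units refer to.
#'
#' @param maps a [pigment_maps()].
#' @param prefix output path prefix.
#' @param tissue a [tissue_params()] whose ranges are recorded.
#' @return invisibly, the sidecar path.
#' @export
write_pigment_maps <- function(maps, prefix, tissue = tissue_params()) {
  stopifnot(inherits(maps, "pigment_maps"))
  for (nm in c("melanin", "hemoglobin", "shading"))
    tiff::writeTIFF(maps[[nm]], sprintf("%s_%s.tif", prefix, nm),
                    bits.per.sample = 16)
  sidecar <- sprintf("%s_maps.json", prefix)
  jsonlite::write_json(list(melanin_vf_range = tissue$melanin_vf_range,
                            hemoglobin_vf_range = tissue$hemoglobin_vf_range),
                       sidecar, auto_unbox = FALSE)
  invisible(sidecar)
}

#' @rdname write_pigment_maps
#' @export
read_pigment_maps <- function(prefix) {
  g <- function(nm) {
    m <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, nm))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  }
  pigment_maps(g("melanin"), g("hemoglobin"), g("shading"))
}
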