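# Synthetic cross-polarized skin generator.
#
# Stands in for clinical data: smooth stationary random fields of melanin
# and hemoglobin around subject-level base values, a low-frequency shading
# field, optional smooth-edged hyperpigmented blobs with an annular
# "normal skin" surround, rendered to sRGB through the spectral forward
# model. Every draw is fixed by the subject seed.

#' Synthetic subject specification
#'
#' Parameters of one synthetic subject. `field_smoothness` is the spatial
#' correlation length in pixels at which the field autocorrelation falls to
#' 1/e (the generating Gaussian kernel has sigma = smoothness / 2, since
#' smoothing white noise with a Gaussian of sigma gives a Gaussian
#' correlogram with sigma * sqrt(2)).
#'
#' @param base_melanin,base_hemoglobin subject-level mean normalized map
#'   values in \[0, 1\].
#' @param field_smoothness correlation length, px.
#' @param noise_amplitude standard deviation of the pigment fields around
#'   their base values (normalized units).
#' @param n_blobs number of hyperpigmented blobs.
#' @param blob_radius_px range (min, max) of blob radii, px.
#' @param blob_gain range (min, max) of blob amplitude in normalized units.
#' @param blob_pigment which map(s) the blobs raise: "melanin",
#'   "hemoglobin" or "both".
#' @param shading_smoothness correlation length of the shading field, px.
#' @param shading_range range of the multiplicative shading field.
#' @param seed integer seed fixing every draw for this subject.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(base_melanin = 0.35, base_hemoglobin = 0.5,
                         field_smoothness = 8, noise_amplitude = 0.08,
                         n_blobs = 0, blob_radius_px = c(6, 12),
                         blob_gain = c(0.1, 0.3),
                         blob_pigment = c("melanin", "hemoglobin", "both"),
                         shading_smoothness = 32,
                         shading_range = c(0.5, 1), seed = 1L) {
  blob_pigment <- match.arg(blob_pigment)
  stopifnot(base_melanin >= 0, base_melanin <= 1,
            base_hemoglobin >= 0, base_hemoglobin <= 1,
            field_smoothness > 0, noise_amplitude >= 0, n_blobs >= 0,
            blob_radius_px[1] <= blob_radius_px[2],
            blob_gain[1] <= blob_gain[2],
            shading_range[1] >= 0, shading_range[2] <= 1,
            shading_range[1] < shading_range[2])
  structure(as.list(environment()), class = "subject_spec")
}

# smooth stationary Gaussian random field via circular FFT convolution of
# white noise with a Gaussian kernel; unit marginal variance
smooth_field <- function(shape, sigma_px) {
  h <- shape[1]; w <- shape[2]
  noise <- matrix(stats::rnorm(h * w), h, w)
  if (sigma_px <= 0) return(noise)
  gk <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-0.5 * (d / sigma_px)^2)
  }
  ker <- outer(gk(h), gk(w))
  ker <- ker / sum(ker)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(ker), inverse = TRUE)) / (h * w)
  f / sqrt(sum(ker^2))   # restore unit variance after smoothing
}

#' Generate smooth pigment and shading fields for one subject
#'
#' Low-pass-filtered Gaussian noise around the subject's base levels,
#' clipped to \[0, 1\]; the shading map is an independent low-frequency
#' field scaled into `shading_range`. Deterministic under the spec seed.
#'
#' @param spec a [subject_spec()].
#' @param shape integer pair (rows, cols).
#' @return a [pigment_maps()].
#' @export
generate_pigment_fields <- function(spec, shape = c(256, 256)) {
  stopifnot(inherits(spec, "subject_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  sig <- spec$field_smoothness / 2
  mel <- spec$base_melanin + spec$noise_amplitude * smooth_field(shape, sig)
  hem <- spec$base_hemoglobin + spec$noise_amplitude * smooth_field(shape, sig)
  sh <- smooth_field(shape, spec$shading_smoothness / 2)
  # map the shading field smoothly into its range via a logistic squash
  sh <- spec$shading_range[1] + diff(spec$shading_range) * stats::plogis(sh)
  pigment_maps(pmin(pmax(mel, 0), 1), pmin(pmax(hem, 0), 1), sh)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# raised-cosine-edged plateau blob profile: 1 inside core_frac * R, cosine
# taper to 0 at R
blob_profile <- function(shape, center, radius, core_frac = 0.6) {
  r <- sqrt(outer((seq_len(shape[1]) - center[1])^2,
                  (seq_len(shape[2]) - center[2])^2, `+`))
  core <- core_frac * radius
  p <- matrix(0, shape[1], shape[2])
  p[r <= core] <- 1
  band <- r > core & r < radius
  p[band] <- 0.5 * (1 + cos(pi * (r[band] - core) / (radius - core)))
  p
}

#' Add hyperpigmented blobs and build region/surround masks
#'
#' Adds `n_blobs` smooth-edged plateau blobs to the targeted pigment
#' map(s). The region mask covers the blob plateaus (where the full gain
#' applies); the surround mask is an annulus of adjacent unmodified skin,
#' so the targeted map's region mean exceeds its surround mean by
#' construction.
#'
#' @param maps a [pigment_maps()].
#' @param spec a [subject_spec()] with `n_blobs >= 1`.
#' @return list with elements `maps` (modified [pigment_maps()]), `pair`
#'   (a [region_pair()]) and `gain` (the drawn blob gains).
#' @export
add_pigmented_region <- function(maps, spec) {
  stopifnot(inherits(maps, "pigment_maps"), inherits(spec, "subject_spec"))
  shape <- dim(maps$melanin)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed + 104729L)   # independent stream from the fields
  region <- matrix(0, shape[1], shape[2])
  surround <- matrix(0, shape[1], shape[2])
  mel <- maps$melanin; hem <- maps$hemoglobin
  gains <- numeric(0)
  n <- max(1L, spec$n_blobs)
  for (b in seq_len(n)) {
    radius <- stats::runif(1, spec$blob_radius_px[1], spec$blob_radius_px[2])
    # shrink the blob if the canvas cannot hold it with its surround annulus
    radius <- min(radius, (min(shape) / 2 - 1) / 1.9)
    gain <- stats::runif(1, spec$blob_gain[1], spec$blob_gain[2])
    # draw the center inside the box where the blob plus its surround
    # annulus fits entirely in the image
    lo <- 1.8 * radius
    if (shape[1] - lo <= lo || shape[2] - lo <= lo)
      stop("could not place blob inside the image")
    ctr <- c(stats::runif(1, lo, shape[1] - lo),
             stats::runif(1, lo, shape[2] - lo))
    prof <- blob_profile(shape, ctr, radius)
    if (spec$blob_pigment %in% c("melanin", "both")) mel <- mel + gain * prof
    if (spec$blob_pigment %in% c("hemoglobin", "both")) hem <- hem + gain * prof
    r <- sqrt(outer((seq_len(shape[1]) - ctr[1])^2,
                    (seq_len(shape[2]) - ctr[2])^2, `+`))
    region[r <= 0.6 * radius] <- 1
    surround[r > 1.1 * radius & r <= 1.8 * radius] <- 1
    gains <- c(gains, gain)
  }
  surround[region != 0] <- 0
  list(maps = pigment_maps(pmin(mel, 1), pmin(hem, 1), maps$shading),
       pair = region_pair(region, surround),
       gain = gains)
}

#' Render one synthetic subject to an sRGB image
#'
#' Fields (plus blobs when `n_blobs > 0`) are rendered through the
#' reflectance LUT and gamma-encoded. The skin mask is all-true by default
#' or an inscribed ellipse when `face_mask = TRUE`.
#'
#' @param spec a [subject_spec()].
#' @param lut a [build_reflectance_lut()] result.
#' @param shape canvas size (default one 256 x 256 patch).
#' @param face_mask use an elliptical face-like mask instead of all-skin.
#' @return list with `image` (a [skin_image()] tagged srgb, mask attached),
#'   `truth` (the ground-truth [pigment_maps()]), and when blobs were
#'   requested, `pair` (a [region_pair()]).
#' @export
generate_subject <- function(spec, lut, shape = c(256, 256),
                             face_mask = FALSE) {
  maps <- generate_pigment_fields(spec, shape)
  pair <- NULL
  if (spec$n_blobs >= 1) {
    reg <- add_pigmented_region(maps, spec)
    maps <- reg$maps
    pair <- reg$pair
  }
  lin <- render_maps(maps, lut)
  srgb <- linear_to_srgb(lin)
  mask <- if (face_mask) {
    cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
    el <- outer(((seq_len(shape[1]) - cy) / (0.45 * shape[1]))^2,
                ((seq_len(shape[2]) - cx) / (0.4 * shape[2]))^2, `+`)
    matrix(as.numeric(el <= 1), shape[1], shape[2])
  } else matrix(1, shape[1], shape[2])
  out <- list(image = skin_image(srgb, "srgb", mask), truth = maps)
  if (!is.null(pair)) out$pair <- pair
  out
}

#' Draw a random subject specification
#'
#' The default population emulates a non-patient study cohort whose
#' rendered skin tones are concentrated around ITA 30 degrees with a full
#' light-to-dark spread (roughly -30 to +55 degrees). Under the default
#' forward model (including the shading field) this corresponds to base
#' melanin normal with mean 0.16, sd 0.10, clipped to \[0.05, 0.55\];
#' blood content varies as base hemoglobin normal with mean 0.45, sd
#' 0.15, clipped to \[0.10, 0.90\]. Field statistics are fixed; blobs are
#' optional.
#'
#' @param seed integer seed for this subject.
#' @param n_blobs number of pigmented blobs (default 0).
#' @param blob_pigment which map the blobs raise.
#' @param ... further overrides passed to [subject_spec()].
#' @return a [subject_spec()].
#' @export
random_subject_spec <- function(seed, n_blobs = 0,
                                blob_pigment = "melanin", ...) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  subject_spec(base_melanin = clamp(stats::rnorm(1, 0.16, 0.10), 0.05, 0.55),
               base_hemoglobin = clamp(stats::rnorm(1, 0.45, 0.15), 0.10, 0.90),
               n_blobs = n_blobs, blob_pigment = blob_pigment,
               seed = seed, ...)
}

#' Generate and write a labelled synthetic dataset
#'
#' For each subject: draw a specification from the population, render the
#' image, and write the sRGB image (8-bit PNG), ground-truth maps (16-bit
#' TIFF), skin mask and any region/surround masks (PNG), plus a manifest
#' JSON listing files and seeds. Fully reproducible under the master seed.
#'
#' @param n_subjects number of subjects.
#' @param lut a [build_reflectance_lut()] result.
#' @param out_dir output directory (created if missing).
#' @param master_seed integer; subject seeds are derived from it.
#' @param shape canvas size.
#' @param n_blobs,blob_pigment forwarded to [random_subject_spec()].
#' @param face_mask use elliptical masks.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
generate_dataset <- function(n_subjects, lut, out_dir, master_seed = 1L,
                             shape = c(256, 256), n_blobs = 0,
                             blob_pigment = "melanin", face_mask = FALSE) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory")
  subjects <- list()
  for (i in seq_len(n_subjects)) {
    seed_i <- as.integer((master_seed * 1000L + i) %% .Machine$integer.max)
    spec <- random_subject_spec(seed_i, n_blobs = n_blobs,
                                blob_pigment = blob_pigment)
    subj <- generate_subject(spec, lut, shape, face_mask)
    id <- sprintf("subject_%03d", i)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    write_skin_image(subj$image, img_path)
    png::writePNG(subj$image$mask, file.path(out_dir, paste0(id, "_mask.png")))
    write_pigment_maps(subj$truth, file.path(out_dir, id))
    entry <- list(id = id, seed = seed_i, image = basename(img_path),
                  base_melanin = spec$base_melanin,
                  base_hemoglobin = spec$base_hemoglobin)
    if (!is.null(subj$pair)) {
      png::writePNG(subj$pair$region_mask,
                    file.path(out_dir, paste0(id, "_region.png")))
      png::writePNG(subj$pair$surround_mask,
                    file.path(out_dir, paste0(id, "_surround.png")))
      entry$region <- paste0(id, "_region.png")
      entry$surround <- paste0(id, "_surround.png")
    }
    subjects[[i]] <- entry
  }
  manifest <- list(n_subjects = n_subjects, master_seed = master_seed,
                   shape = shape, subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
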