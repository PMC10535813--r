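# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fix_lib <- function() memo("lib", chromophore_library)
fix_tissue <- function() memo("tissue", tissue_params)
fix_scatter <- function() memo("scatter", scattering_params)
fix_render <- function() memo("render", render_config)
fix_lut <- function() memo("lut", function()
  build_reflectance_lut(fix_tissue(), fix_scatter(), fix_lib(), fix_render()))

# direct spectral-pipeline evaluation of one (vm, vh) pair -- the brute-force
# oracle the LUT is checked against (no shading, no gamma)
spectral_oracle_rgb <- function(vm, vh) {
  refl <- reflectance_spectrum(vm, vh, fix_tissue(), fix_scatter(), fix_lib())
  cam <- spectral_to_camera_rgb(refl, 1, fix_render())
  as.numeric(camera_to_linear_rgb(cam, fix_render()))
}

# one rendered synthetic 64 x 64 patch with its ground truth
gen_patch <- function(seed, shape = c(64, 64), n_blobs = 0,
                      blob_pigment = "melanin") {
  spec <- random_subject_spec(seed, n_blobs = n_blobs,
                              blob_pigment = blob_pigment)
  subj <- generate_subject(spec, fix_lut(), shape = shape)
  subj$linear <- srgb_to_linear(subj$image$data)
  subj
}

# the trained desk-scale model shared by the training-dependent tests:
# 200 synthetic training patches, 20 held-out, fixed seeds
trained_fixture <- function() {
  memo("trained", function() {
    lut <- fix_lut()
    train <- lapply(1:200, function(i) gen_patch(1000 + i)$linear)
    held <- lapply(1:20, function(i) gen_patch(9000 + i))
    cfg <- model_config(seed = 7, steps = 1500)
    tr <- train_self_supervised(train, lut, cfg)
    list(model = tr$model, state = tr$state, held = held, cfg = cfg)
  })
}
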