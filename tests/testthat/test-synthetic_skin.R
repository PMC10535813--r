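test_that("pigment fields are seeded, smooth and base-centred", {
  spec <- subject_spec(base_melanin = 0.4, base_hemoglobin = 0.5, seed = 77)
  a <- generate_pigment_fields(spec, c(64, 64))
  b <- generate_pigment_fields(spec, c(64, 64))
  expect_identical(a, b)
  # zero noise gives constant pigment maps at the base levels
  flat <- generate_pigment_fields(subject_spec(base_melanin = 0.4,
                                               base_hemoglobin = 0.5,
                                               noise_amplitude = 0, seed = 1),
                                  c(32, 32))
  expect_equal(max(abs(flat$melanin - 0.4)), 0)
  expect_equal(max(abs(flat$hemoglobin - 0.5)), 0)
  expect_true(all(a$shading >= 0.5 & a$shading <= 1))
  expect_true(abs(mean(a$melanin) - 0.4) < 0.05)
})

test_that("field autocorrelation length tracks the smoothness parameter", {
  L <- 10
  spec <- subject_spec(field_smoothness = L, noise_amplitude = 0.2,
                       base_melanin = 0.5, seed = 5)
  f <- generate_pigment_fields(spec, c(256, 256))$melanin
  z <- f - mean(f)
  # circular empirical correlogram via the FFT (matches the generator's
  # periodic construction)
  ac <- Re(stats::fft(Mod(stats::fft(z))^2, inverse = TRUE))
  rho <- ac[1:40, 1] / ac[1, 1]
  lag_e <- which(rho < exp(-1))[1] - 1
  expect_gt(lag_e, 0.8 * L)
  expect_lt(lag_e, 1.2 * L)
})

test_that("pigmented blobs create the designed region contrast", {
  base <- subject_spec(base_melanin = 0.3, base_hemoglobin = 0.4,
                       noise_amplitude = 0, n_blobs = 1,
                       blob_gain = c(0.2, 0.2), seed = 9)
  maps <- generate_pigment_fields(base, c(64, 64))
  out <- add_pigmented_region(maps, base)
  # plateau construction: region mean minus surround mean equals the gain
  expect_equal(region_contrast(out$maps$melanin, out$pair), 0.2,
               tolerance = 1e-6)
  # hemoglobin untouched by a melanin-only blob
  expect_identical(out$maps$hemoglobin, maps$hemoglobin)
  # zero gain leaves the maps unchanged
  zg <- base; zg$blob_gain <- c(0, 0)
  out0 <- add_pigmented_region(maps, zg)
  expect_equal(max(abs(out0$maps$melanin - maps$melanin)), 0)
  # hemoglobin-only blobs leave melanin unchanged
  hspec <- subject_spec(base_melanin = 0.3, base_hemoglobin = 0.4,
                        n_blobs = 1, blob_pigment = "hemoglobin", seed = 9)
  outh <- add_pigmented_region(maps, hspec)
  expect_identical(outh$maps$melanin, maps$melanin)
  expect_gt(region_contrast(outh$maps$hemoglobin, outh$pair), 0)
})

test_that("darker synthetic subjects have lower ITA", {
  lut <- fix_lut()
  mk <- function(mel) generate_subject(
    subject_spec(base_melanin = mel, base_hemoglobin = 0.5,
                 noise_amplitude = 0.05, seed = 3),
    lut, shape = c(32, 32))
  expect_gt(ita(mk(0.1)$image), ita(mk(0.3)$image))
  expect_gt(ita(mk(0.3)$image), ita(mk(0.6)$image))
})

test_that("generated volume fractions stay inside the physiological ranges", {
  t <- fix_tissue()
  for (seed in 1:5) {
    subj <- gen_patch(400 + seed, n_blobs = 1)
    vf <- maps_to_volume_fractions(subj$truth, t)
    expect_true(all(vf$vm >= t$melanin_vf_range[1] - 1e-12 &
                      vf$vm <= t$melanin_vf_range[2] + 1e-12))
    expect_true(all(vf$vh >= t$hemoglobin_vf_range[1] - 1e-12 &
                      vf$vh <= t$hemoglobin_vf_range[2] + 1e-12))
  }
})

test_that("dataset generation is reproducible and complete on disk", {
  lut <- fix_lut()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(3, lut, d1, master_seed = 11, shape = c(32, 32),
                         n_blobs = 1)
  m2 <- generate_dataset(3, lut, d2, master_seed = 11, shape = c(32, 32),
                         n_blobs = 1)
  expect_equal(length(m1$subjects), 3)
  for (s in m1$subjects) {
    expect_true(file.exists(file.path(d1, s$image)))
    expect_true(file.exists(file.path(d1, paste0(s$id, "_mask.png"))))
    expect_true(file.exists(file.path(d1, paste0(s$id, "_melanin.tif"))))
    expect_true(file.exists(file.path(d1, s$region)))
  }
  # identical master seed gives bit-identical outputs
  for (f in c("subject_001.png", "subject_002_melanin.tif", "manifest.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
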