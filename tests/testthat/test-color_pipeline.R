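test_that("white balance closes the chain on a perfect reflector", {
  cfg <- fix_render()
  wb <- white_balance_factors(cfg)
  expect_true(all(wb > 0))
  cam_white <- spectral_to_camera_rgb(rep(1, length(cfg$wavelengths_nm)), 1, cfg)
  expect_equal(wb * cam_white, c(1, 1, 1), tolerance = 1e-14)
  # full chain: perfect reflector -> (1,1,1) linear RGB
  lin <- camera_to_linear_rgb(cam_white, cfg)
  expect_equal(as.numeric(lin), c(1, 1, 1), tolerance = 1e-12)
  # factors under the shipped D65-like illuminant differ across channels
  expect_gt(diff(range(wb)) / min(wb), 0.1)
})

test_that("camera integration is linear in shading and reflectance", {
  cfg <- fix_render()
  refl <- skin_reflectance(cfg$wavelengths_nm, 0.1, 0.04, fix_tissue(),
                           fix_scatter(), fix_lib())
  expect_equal(spectral_to_camera_rgb(refl, 0, cfg), c(0, 0, 0))
  one <- spectral_to_camera_rgb(refl, 1, cfg)
  expect_equal(spectral_to_camera_rgb(refl, 2, cfg), 2 * one)
  expect_equal(spectral_to_camera_rgb(0.5 * refl, 1, cfg), 0.5 * one)
  expect_error(spectral_to_camera_rgb(refl, -1, cfg), "nonnegative")
})

test_that("camera-to-linear conversion is the expected matrix product", {
  cfg <- fix_render()
  # identity matrices and unit white balance pass values through
  id_cfg <- cfg
  id_cfg$cam_rgb_to_xyz <- solve(cfg$xyz_to_rgb)
  id_cfg$wb_factors <- c(1, 1, 1)
  v <- c(0.2, 0.5, 0.7)
  expect_equal(as.numeric(camera_to_linear_rgb(v, id_cfg)), v)
  # positive homogeneity before clipping
  x <- c(0.1, 0.2, 0.15)
  expect_equal(as.numeric(camera_to_linear_rgb(0.5 * x, cfg, clip = FALSE)),
               0.5 * as.numeric(camera_to_linear_rgb(x, cfg, clip = FALSE)))
  # scalar oracle for the shipped matrices
  M <- cfg$xyz_to_rgb %*% cfg$cam_rgb_to_xyz
  expect_equal(as.numeric(camera_to_linear_rgb(x, cfg, clip = FALSE)),
               as.numeric(M %*% (cfg$wb_factors * x)))
})

test_that("the sRGB transfer pair is the standard and mutually inverse", {
  expect_equal(linear_to_srgb(0), 0)
  expect_equal(linear_to_srgb(1), 1)
  expect_equal(srgb_to_linear(0), 0)
  expect_equal(srgb_to_linear(1), 1)
  expect_equal(linear_to_srgb(0.5), 1.055 * 0.5^(1 / 2.4) - 0.055,
               tolerance = 1e-12)
  expect_equal(linear_to_srgb(0.5), 0.735357, tolerance = 1e-5)
  set.seed(8)
  v <- runif(1000)
  expect_lt(max(abs(srgb_to_linear(linear_to_srgb(v)) - v)), 1e-7)
  expect_lt(max(abs(linear_to_srgb(srgb_to_linear(v)) - v)), 1e-7)
  # color-space tags are enforced on images
  img <- skin_image(array(0.5, c(2, 2, 3)), "srgb")
  expect_error(linear_to_srgb(img), "not tagged linear")
  lin <- srgb_to_linear(img)
  expect_identical(lin$color_space, "linear")
})

test_that("Lab conversion hits the achromatic anchors", {
  w <- rgb_to_lab(c(1, 1, 1))
  expect_equal(w[["L"]], 100, tolerance = 1e-3)
  expect_lt(abs(w[["a"]]), 0.01)
  expect_lt(abs(w[["b"]]), 0.01)
  expect_equal(rgb_to_lab(c(0, 0, 0))[["L"]], 0, tolerance = 1e-6)
  g <- rgb_to_lab(c(0.5, 0.5, 0.5))
  # independent scalar evaluation of the CIE formula for the gray axis
  y <- srgb_to_linear(0.5)
  expect_equal(g[["L"]], 116 * y^(1 / 3) - 16, tolerance = 1e-3)
  expect_lt(abs(g[["a"]]), 0.01)
  expect_lt(abs(g[["b"]]), 0.01)
  # lab -> sRGB -> lab round trip inside the gamut
  lab <- c(60, 5, 12)
  expect_equal(as.numeric(rgb_to_lab(lab_to_srgb(lab))), lab, tolerance = 1e-3)
})

test_that("image files round-trip with their color-space sidecar", {
  dir <- withr::local_tempdir()
  arr <- array(runif(12 * 10 * 3), c(12, 10, 3))
  img <- skin_image(arr, "linear", mask = matrix(1, 12, 10))
  p <- file.path(dir, "x.tif")
  write_skin_image(img, p, bits = 16)
  back <- read_skin_image(p)
  expect_identical(back$color_space, "linear")
  expect_equal(back$data, arr, tolerance = 2e-5)  # 16-bit quantization
  maps <- pigment_maps(matrix(runif(30), 6, 5), matrix(runif(30), 6, 5),
                       matrix(runif(30), 6, 5))
  write_pigment_maps(maps, file.path(dir, "subj"))
  back2 <- read_pigment_maps(file.path(dir, "subj"))
  expect_equal(back2$melanin, maps$melanin, tolerance = 2e-5)
  expect_equal(back2$hemoglobin, maps$hemoglobin, tolerance = 2e-5)
})
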