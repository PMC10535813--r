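test_that("spectral curves validate their invariants", {
  expect_error(spectral_curve(c(500, 500), c(1, 1)), "increasing")
  expect_error(spectral_curve(c(500, 600), c(1, -1)), "nonnegative")
  expect_error(spectral_curve(c(400, 600), c(1, 1)), "450")
  sc <- spectral_curve(c(450, 600, 750), c(1, 2, 3))
  expect_equal(eval_spectral(sc, 525), 1.5)
  expect_error(eval_spectral(sc, 760), "outside")
})

test_that("absorption is linear and additive in the volume fractions", {
  lib <- fix_lib()
  expect_equal(absorption_coefficient(550, 0, 0, lib), 0)
  x <- 0.07
  expect_equal(absorption_coefficient(550, 2 * x, 0, lib),
               2 * absorption_coefficient(550, x, 0, lib))
  # term-by-term oracle straight from the curves
  mel_term <- 0.1 * stats::approx(lib$melanin$wavelengths_nm,
                                  lib$melanin$values, 620)$y
  hb_term <- 0.04 * stats::approx(lib$hemoglobin$wavelengths_nm,
                                  lib$hemoglobin$values, 620)$y
  expect_equal(absorption_coefficient(620, 0.1, 0.04, lib),
               mel_term + hb_term, tolerance = 1e-12)
  # linearity across the whole sampled band, both chromophores
  for (alpha in c(0.5, 3)) {
    wl <- spectral_grid()
    expect_equal(absorption_coefficient(wl, alpha * 0.1, alpha * 0.03, lib),
                 alpha * absorption_coefficient(wl, 0.1, 0.03, lib))
  }
  expect_error(absorption_coefficient(550, -1, 0, lib), "nonnegative")
})

test_that("reduced scattering has the Rayleigh/Mie closed forms", {
  p <- scattering_params(amplitude_a = 3.7, power_b = 1.0, f_rayleigh = 0.25,
                         lambda0_nm = 500)
  expect_equal(reduced_scattering(500, p), 3.7)          # both terms are 1
  p_mie <- scattering_params(amplitude_a = 2, power_b = 1, f_rayleigh = 0)
  expect_equal(reduced_scattering(1000, p_mie), 1)       # a/2 at 2*lambda0
  p_ray <- scattering_params(amplitude_a = 2, f_rayleigh = 1)
  expect_equal(reduced_scattering(1000, p_ray), 2 / 16)  # lambda^-4
  # strictly decreasing in wavelength
  wl <- spectral_grid()
  expect_true(all(diff(reduced_scattering(wl, scattering_params())) < 0))
  expect_error(reduced_scattering(-5, p), "positive")
})

test_that("epidermis transmittance follows the exponential law", {
  lib <- fix_lib(); t <- fix_tissue()
  expect_equal(epidermis_transmittance(550, 0, t, lib), 1)
  vm <- c(0.013, 0.1, 0.2, 0.43)
  tv <- epidermis_transmittance(650, vm, t, lib)
  expect_true(all(diff(tv) < 0))
  # scalar oracle: read the shipped curve and apply Beer-Lambert by hand
  f <- system.file("extdata", "extinction_eumelanin_synthetic.txt",
                   package = "chromaderm")
  tab <- read.table(f, comment.char = "#")
  eps650 <- stats::approx(tab[[1]], tab[[2]], 650)$y
  expect_equal(epidermis_transmittance(650, 0.1, t, lib),
               exp(-0.1 * eps650 * t$epidermis_thickness_mm),
               tolerance = 1e-12)
})

test_that("dermis reflectance matches the semi-infinite Kubelka-Munk form", {
  lib <- fix_lib(); t <- fix_tissue(); s <- scattering_params()
  expect_equal(dermis_reflectance(500, 0, t, s, lib), 1)  # lossless medium
  # closed form at K/S = 4: at lambda0 S = a, so choose vh giving K = 4a
  eps500 <- stats::approx(lib$hemoglobin$wavelengths_nm,
                          lib$hemoglobin$values, 500)$y
  vh <- 4 * s$amplitude_a / (2 * eps500)
  expect_equal(dermis_reflectance(500, vh, t, s, lib), 5 - sqrt(24),
               tolerance = 1e-12)
  # bounds and monotone decrease in K/S over a sweep
  vhs <- seq(0, 5, length.out = 50)
  rv <- dermis_reflectance(560, vhs, t, s, lib)
  expect_true(all(rv >= 0 & rv <= 1))
  expect_true(all(diff(rv) < 0))
  # K/S -> infinity limit
  expect_lt(dermis_reflectance(560, 1e6, t, s, lib), 1e-3)
})

test_that("skin reflectance composes the two layers and is monotone", {
  lib <- fix_lib(); t <- fix_tissue(); s <- fix_scatter()
  expect_equal(skin_reflectance(500, 0, 0, t, s, lib), 1)
  set.seed(11)
  for (k in 1:200) {
    wl <- runif(1, 450, 750)
    vm <- runif(1, 0, 0.43); vh <- runif(1, 0, 0.07)
    expect_equal(skin_reflectance(wl, vm, vh, t, s, lib),
                 epidermis_transmittance(wl, vm, t, lib)^2 *
                   dermis_reflectance(wl, vh, t, s, lib))
  }
  # dense numeric monotonicity sweep in both volume fractions
  set.seed(12)
  wl <- runif(1000, 450, 750)
  vm <- runif(1000, 0.013, 0.42); vh <- runif(1000, 0.02, 0.069)
  base <- skin_reflectance(wl, vm, vh, t, s, lib)
  expect_true(all(skin_reflectance(wl, vm + 0.01, vh, t, s, lib) <= base))
  expect_true(all(skin_reflectance(wl, vm, vh + 0.001, t, s, lib) <= base))
  expect_true(all(skin_reflectance(wl, 0.43, vh, t, s, lib) <
                    skin_reflectance(wl, 0.013, vh, t, s, lib)))
})

test_that("the reflectance LUT reproduces the spectral pipeline", {
  lut <- fix_lut()
  expect_true(all(lut$rgb_table >= 0 & lut$rgb_table <= 1))
  # monotone non-increasing in melanin along every channel
  for (m in 1:3) expect_true(all(apply(lut$rgb_table[, , m], 2, diff) <= 0))
  # grid nodes match brute-force spectral integration
  set.seed(4)
  for (k in 1:12) {
    i <- sample(length(lut$vm_grid), 1); j <- sample(length(lut$vh_grid), 1)
    expect_equal(lut$rgb_table[i, j, ],
                 spectral_oracle_rgb(lut$vm_grid[i], lut$vh_grid[j]),
                 tolerance = 1e-9)
  }
  # bilinear interpolation reproduces nodes exactly
  lk <- lut_lookup(lut, lut$vm_grid[c(1, 30, 64)], lut$vh_grid[c(5, 40, 64)])
  for (q in 1:3)
    expect_equal(lk$rgb[q, ],
                 lut$rgb_table[c(1, 30, 64)[q], c(5, 40, 64)[q], ])
  expect_error(build_reflectance_lut(fix_tissue(), fix_scatter(), fix_lib(),
                                     fix_render(), grid_sizes = c(1, 8)),
               "grid_sizes")
})

test_that("LUT interpolation error off the nodes stays small", {
  lut <- fix_lut()
  set.seed(5)
  vm <- runif(40, 0.013, 0.43); vh <- runif(40, 0.02, 0.07)
  lk <- lut_lookup(lut, vm, vh)$rgb
  for (q in 1:40)
    expect_lt(max(abs(lk[q, ] - spectral_oracle_rgb(vm[q], vh[q]))), 1e-3)
})
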