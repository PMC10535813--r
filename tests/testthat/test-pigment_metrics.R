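# uniform sRGB image with the given Lab color
lab_image <- function(L, a, b, shape = c(4, 4)) {
  rgb <- lab_to_srgb(c(L, a, b))
  skin_image(array(rep(rgb, each = prod(shape)), c(shape, 3)), "srgb")
}

test_that("ITA hits its analytic anchor angles", {
  expect_equal(ita(lab_image(50, 0, 10)), 0, tolerance = 0.1)
  expect_equal(ita(lab_image(60, 0, 10)), 45, tolerance = 0.1)
  expect_equal(ita(lab_image(40, 0, 10)), -45, tolerance = 0.1)
  # invariant to mask size on a uniform image
  img <- lab_image(65, 8, 14, shape = c(10, 10))
  m1 <- matrix(0, 10, 10); m1[1:3, 1:3] <- 1
  expect_equal(ita(img, m1), ita(img), tolerance = 1e-6)
  # strictly decreasing in L at fixed positive b
  Ls <- seq(20, 80, by = 5)
  vals <- vapply(Ls, function(L) ita(lab_image(L, 0, 15)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(ita(img, matrix(0, 10, 10)), "no pixels")
})

test_that("optical density follows the log law with a capped zero", {
  expect_equal(optical_density(1), 0)
  expect_equal(optical_density(0.1), 1)
  expect_equal(optical_density(0.5), log10(2), tolerance = 1e-12)
  expect_equal(optical_density(0.05, i0 = 0.5), 1)
  expect_warning(od0 <- optical_density(0), "capped")
  expect_equal(od0, 4)
  expect_error(optical_density(1, i0 = 0), "positive")
})

test_that("melanin and erythema indices have their channel closed forms", {
  mk <- function(r, g, b) array(rep(c(r, g, b), each = 4), c(2, 2, 3))
  expect_equal(melanin_index(mk(1, 0.3, 0.3)), 0)
  expect_equal(melanin_index(mk(0.5, 0.3, 0.3)), log10(2), tolerance = 1e-12)
  # achromatic pixels: E.I1 exactly zero, E.I2 equals the intensity
  for (c_ in c(0.2, 0.5, 0.9)) {
    expect_identical(erythema_diffey(mk(c_, c_, c_)), 0)
    expect_equal(erythema_jacovels(mk(c_, c_, c_)), c_, tolerance = 1e-12)
  }
  # M.I is additive under multiplicative darkening of the red channel
  x <- mk(0.8, 0.4, 0.3)
  xk <- x; xk[, , 1] <- 0.25 * xk[, , 1]
  expect_equal(melanin_index(xk), melanin_index(x) - log10(0.25),
               tolerance = 1e-12)
  # raising hemoglobin at fixed melanin raises E.I1 (forward-model oracle)
  lut <- fix_lut()
  lo <- render_maps(pigment_maps(matrix(0.3, 2, 2), matrix(0.2, 2, 2),
                                 matrix(1, 2, 2)), lut)
  hi <- render_maps(pigment_maps(matrix(0.3, 2, 2), matrix(0.9, 2, 2),
                                 matrix(1, 2, 2)), lut)
  expect_gt(erythema_diffey(hi), erythema_diffey(lo))
  # darker subject (higher melanin) has the larger melanin index
  dk <- render_maps(pigment_maps(matrix(0.7, 2, 2), matrix(0.5, 2, 2),
                                 matrix(1, 2, 2)), lut)
  lt <- render_maps(pigment_maps(matrix(0.1, 2, 2), matrix(0.5, 2, 2),
                                 matrix(1, 2, 2)), lut)
  expect_gt(melanin_index(dk), melanin_index(lt))
})

test_that("region contrast is the difference of region and surround means", {
  reg <- matrix(0, 6, 6); reg[2:3, 2:3] <- 1
  sur <- matrix(0, 6, 6); sur[5:6, ] <- 1
  pair <- region_pair(reg, sur)
  idx <- matrix(0.1, 6, 6)
  expect_equal(region_contrast(idx, pair), 0)
  idx[reg != 0] <- 0.3
  expect_equal(region_contrast(idx, pair), 0.2, tolerance = 1e-12)
  expect_error(region_pair(reg, reg), "overlap")
  expect_error(region_pair(reg, matrix(0, 6, 6)), "nonempty")
})

test_that("the index report gathers all metrics consistently", {
  lut <- fix_lut()
  subj <- gen_patch(301, n_blobs = 1)
  rep_ <- pigment_indices(subj$image, pair = subj$pair)
  expect_named(rep_, c("ita_deg", "mi", "ei1", "ei2", "mi_contrast",
                       "ei1_contrast", "ei2_contrast"))
  expect_true(all(vapply(rep_, is.finite, logical(1))))
  # a melanin blob raises the melanin-index contrast above zero
  expect_gt(rep_$mi_contrast, 0)
  expect_s3_class(ita_category(c(-40, 35)), "factor")
})
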