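test_that("model construction is seeded and emits bounded maps", {
  cfg <- model_config(base_channels = 8, depth = 2, patch_size = 16,
                      seed = 42, steps = 1)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(model_config(base_channels = 8, depth = 2,
                                 patch_size = 16, seed = 43, steps = 1))
  expect_false(identical(m1$params, m3$params))
  set.seed(1)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out <- model_forward(m1, x)$out
  expect_equal(dim(out), c(16, 16, 3))
  expect_true(all(out >= 0 & out <= 1))
  # fully convolutional: larger inputs work at inference time
  x2 <- array(runif(32 * 48 * 3), c(32, 48, 3))
  expect_equal(dim(model_forward(m1, x2)$out), c(32, 48, 3))
  expect_error(model_config(patch_size = 60, depth = 3), "divisible")
})

test_that("backpropagation matches finite differences through the renderer", {
  lut <- fix_lut()
  cfg <- model_config(base_channels = 4, depth = 2, patch_size = 8,
                      seed = 3, steps = 1)
  m <- build_model(cfg)
  set.seed(9)
  x <- array(runif(8 * 8 * 3, 0.05, 0.6), c(8, 8, 3))
  mask <- matrix(1, 8, 8)
  lossfn <- function(params) {
    m2 <- m; m2$params <- params
    fw <- chromaderm:::model_forward(m2, x)
    chromaderm:::recon_loss_grad(fw$out, x, mask, lut)$loss
  }
  fw <- chromaderm:::model_forward(m, x, want_cache = TRUE)
  lg <- chromaderm:::recon_loss_grad(fw$out, x, mask, lut)
  gr <- chromaderm:::model_backward(m, fw$cache, lg$d_out)
  eps <- 1e-6
  leaves <- list(
    list(function(p) p$stem$W, function(p, v) { p$stem$W <- v; p }),
    list(function(p) p$enc[[3]]$conv_b$W, function(p, v) { p$enc[[3]]$conv_b$W <- v; p }),
    list(function(p) p$down[[1]]$W, function(p, v) { p$down[[1]]$W <- v; p }),
    list(function(p) p$up[[2]]$W, function(p, v) { p$up[[2]]$W <- v; p }),
    list(function(p) p$fuse[[1]]$W, function(p, v) { p$fuse[[1]]$W <- v; p }),
    list(function(p) p$head$W, function(p, v) { p$head$W <- v; p }))
  for (lv in leaves) {
    g <- lv[[1]](gr); idx <- which.max(abs(g))
    bump <- function(h) {
      v <- lv[[1]](m$params); v[idx] <- v[idx] + h
      lossfn(lv[[2]](m$params, v))
    }
    fd <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})

test_that("the optional shading smoothness penalty has a correct gradient", {
  set.seed(14)
  s <- matrix(runif(49), 7, 7)
  tv <- chromaderm:::tv_penalty(s)
  eps <- 1e-7
  for (k in 1:6) {
    i <- sample(7, 1); j <- sample(7, 1)
    s1 <- s; s1[i, j] <- s1[i, j] + eps
    s2 <- s; s2[i, j] <- s2[i, j] - eps
    fd <- (chromaderm:::tv_penalty(s1)$value -
             chromaderm:::tv_penalty(s2)$value) / (2 * eps)
    expect_equal(tv$grad[i, j], fd, tolerance = 1e-5)
  }
})

test_that("training is deterministic under a fixed seed", {
  lut <- fix_lut()
  imgs <- lapply(1:3, function(i) gen_patch(600 + i)$linear)
  cfg <- model_config(seed = 5, steps = 25, eval_every = 25)
  t1 <- train_self_supervised(imgs, lut, cfg)
  t2 <- train_self_supervised(imgs, lut, cfg)
  expect_identical(t1$state$running_mse, t2$state$running_mse)
  expect_identical(t1$model$params, t2$model$params)
})

test_that("a single patch can be overfit to high reconstruction fidelity", {
  lut <- fix_lut()
  x <- gen_patch(660)$linear
  cfg <- model_config(seed = 11, steps = 500)
  tr <- train_self_supervised(list(x), lut, cfg)
  maps <- predict_maps(tr$model, x)
  expect_gt(psnr(render_maps(maps, lut), x), 40)
  # the checkpoint log only records states above the saving threshold
  if (length(tr$state$checkpoints) > 0)
    expect_true(all(vapply(tr$state$checkpoints, `[[`, numeric(1),
                           "psnr_db") > 35))
})

test_that("decomposition respects the skin mask", {
  fx <- trained_fixture()
  subj <- fx$held[[1]]
  # all-zero mask yields all-zero maps
  z <- decompose_image(subj$image, matrix(0, 64, 64), fx$model)
  expect_equal(max(abs(z$melanin)), 0)
  expect_equal(max(abs(z$hemoglobin)), 0)
  # pixels outside the mask cannot influence maps inside it
  mask <- matrix(1, 64, 64); mask[, 33:64] <- 0
  m1 <- decompose_image(subj$image, mask, fx$model)
  pert <- subj$image$data
  pert[, 33:64, ] <- 0.99   # arbitrary perturbation of non-skin pixels
  m2 <- decompose_image(skin_image(pert, "srgb"), mask, fx$model)
  expect_identical(m1$melanin[, 1:32], m2$melanin[, 1:32])
  expect_identical(m1$hemoglobin[, 1:32], m2$hemoglobin[, 1:32])
})

test_that("checkpoints round-trip through the JSON archive", {
  cfg <- model_config(base_channels = 4, depth = 1, patch_size = 8,
                      seed = 2, steps = 1)
  m <- build_model(cfg)
  p <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  set.seed(4)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(model_forward(m2, x)$out, model_forward(m, x)$out,
               tolerance = 1e-12)
})
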