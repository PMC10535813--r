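#' Configuration of the pigment discrimination model
#'
#' A residual encoder-decoder with skip connections (a lightweight relative
#' of ResUNet++-style architectures) mapping a 3-channel linear-RGB patch
#' to three single-channel maps (melanin, hemoglobin, shading) bounded to
#' \[0, 1\] by a sigmoid head. The default is the desk scale used
#' throughout: 16 base channels, 4 resolution levels, 64 x 64 patches --
#' small enough to train on one CPU while exercising the full
#' self-supervised framework.
#'
#' @param base_channels channels at full resolution (default 16).
#' @param depth number of 2x downsamplings (default 4); the patch size must
#'   be divisible by `2^depth`.
#' @param channel_cap maximum channel multiple of `base_channels` (default 8).
#' @param patch_size training patch side length (default 64).
#' @param seed integer seed fixing parameter initialization and the
#'   training-stream order.
#' @param steps optimizer step budget (default 1500).
#' @param lr peak Adam learning rate (default 1e-3).
#' @param lr_schedule `"cosine"` (default) anneals the learning rate from
#'   `lr` to `lr_min` over the step budget, which settles the
#'   single-patch gradient noise late in training; `"constant"` keeps `lr`.
#' @param lr_min floor of the cosine schedule (default 5e-5).
#' @param augment_crop_from when > patch_size, training patches are random
#'   crops of this size down to `patch_size` (default 78, mirroring a
#'   310-to-256 crop at full scale). Images exactly `patch_size` wide are
#'   used as-is.
#' @param tv_shading weight of an optional total-variation penalty on the
#'   shading map (default 0: disabled -- the shading head is otherwise
#'   unsupervised).
#' @param checkpoint_psnr_db running masked PSNR above which checkpoints are
#'   recorded (default 35 dB).
#' @param eval_every steps between checkpoint evaluations (default 50).
#' @return an object of class `model_config`.
#' @export
model_config <- function(base_channels = 16, depth = 4, channel_cap = 8,
                         patch_size = 64, seed = 1L, steps = 1500,
                         lr = 1e-3, lr_schedule = c("cosine", "constant"),
                         lr_min = 5e-5, augment_crop_from = 78,
                         tv_shading = 0, checkpoint_psnr_db = 35,
                         eval_every = 50) {
  lr_schedule <- match.arg(lr_schedule)
  if (patch_size %% (2^depth) != 0)
    stop("patch_size must be divisible by 2^depth")
  stopifnot(base_channels >= 1, depth >= 1, steps >= 1, lr > 0)
  structure(as.list(environment()), class = "model_config")
}

level_channels <- function(cfg) {
  pmin(cfg$base_channels * 2^(0:cfg$depth),
       cfg$base_channels * cfg$channel_cap)
}

#' Build the pigment discrimination model
#'
#' Deterministic He initialization under `cfg$seed`. The network is fully
#' convolutional: any input whose sides are divisible by `2^depth` is
#' accepted at inference time.
#'
#' @param cfg a [model_config()].
#' @return an object of class `pigment_model` (parameters + config).
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  ch <- level_channels(cfg)
  D <- cfg$depth
  params <- list(stem = conv3_init(3, ch[1]))
  params$enc <- lapply(seq_len(D + 1), function(l) resblock_init(ch[l]))
  params$down <- lapply(seq_len(D), function(l) conv1_init(ch[l], ch[l + 1]))
  params$up <- lapply(seq_len(D), function(l) conv1_init(ch[l + 1], ch[l]))
  params$fuse <- lapply(seq_len(D), function(l) conv3_init(2 * ch[l], ch[l]))
  params$head <- conv1_init(ch[1], 3, gain = 1)
  structure(list(params = params, cfg = cfg), class = "pigment_model")
}

#' @export
print.pigment_model <- function(x, ...) {
  n <- sum(unlist(nl_map(length, x$params)))
  cat(sprintf("<pigment_model> depth %d, base %d channels, %s parameters\n",
              x$cfg$depth, x$cfg$base_channels, format(n, big.mark = ",")))
  invisible(x)
}

model_forward <- function(model, x, want_cache = FALSE) {
  p <- model$params
  D <- model$cfg$depth
  d <- dim(x)
  if (any(d[1:2] %% 2^D != 0))
    stop("input sides must be divisible by 2^depth")
  cc <- if (want_cache) list() else NULL
  st <- conv3_fwd(x, p$stem); r0 <- relu_fwd(st$out)
  if (want_cache) { cc$stem <- st$cache; cc$stem_relu <- r0$cache }
  e <- vector("list", D + 1)
  eb <- resblock_fwd(r0$out, p$enc[[1]])
  e[[1]] <- eb$out
  if (want_cache) cc$enc <- list(eb$cache)
  for (l in seq_len(D)) {
    pl <- avgpool2_fwd(e[[l]])
    dn <- conv1_fwd(pl$out, p$down[[l]]); rn <- relu_fwd(dn$out)
    rb <- resblock_fwd(rn$out, p$enc[[l + 1]])
    e[[l + 1]] <- rb$out
    if (want_cache) {
      cc$pool[[l]] <- pl$cache; cc$down[[l]] <- dn$cache
      cc$down_relu[[l]] <- rn$cache; cc$enc[[l + 1]] <- rb$cache
    }
  }
  u <- e[[D + 1]]
  for (l in D:1) {
    us <- upsample2_fwd(u)
    uc <- conv1_fwd(us$out, p$up[[l]]); ur <- relu_fwd(uc$out)
    cat_ <- concat_ch(ur$out, e[[l]])
    fs <- conv3_fwd(cat_, p$fuse[[l]]); fr <- relu_fwd(fs$out)
    u <- fr$out
    if (want_cache) {
      cc$upsz[[l]] <- us$cache; cc$up[[l]] <- uc$cache
      cc$up_relu[[l]] <- ur$cache; cc$fuse[[l]] <- fs$cache
      cc$fuse_relu[[l]] <- fr$cache
    }
  }
  hd <- conv1_fwd(u, p$head)
  sg <- sigmoid_fwd(hd$out)
  if (want_cache) { cc$head <- hd$cache; cc$sigmoid <- sg$cache }
  list(out = sg$out, cache = cc)
}

model_backward <- function(model, cache, d_out) {
  p <- model$params
  D <- model$cfg$depth
  ch <- level_channels(model$cfg)
  g <- list(enc = vector("list", D + 1), down = vector("list", D),
            up = vector("list", D), fuse = vector("list", D))
  dz <- sigmoid_bwd(d_out, cache$sigmoid)
  hb <- conv1_bwd(dz, p$head, cache$head)
  g$head <- hb$grads
  du <- hb$dx
  de <- vector("list", D + 1)   # gradient flowing into each encoder output
  for (l in 1:D) {
    dfr <- relu_bwd(du, cache$fuse_relu[[l]])
    fb <- conv3_bwd(dfr, p$fuse[[l]], cache$fuse[[l]])
    g$fuse[[l]] <- fb$grads
    sp <- split_ch(fb$dx, ch[l])
    de[[l]] <- sp[[2]]
    dur <- relu_bwd(sp[[1]], cache$up_relu[[l]])
    ub <- conv1_bwd(dur, p$up[[l]], cache$up[[l]])
    g$up[[l]] <- ub$grads
    du <- upsample2_bwd(ub$dx, cache$upsz[[l]])
  }
  de[[D + 1]] <- du
  dprev <- NULL
  for (l in (D + 1):1) {
    dl <- de[[l]]
    if (!is.null(dprev)) dl <- dl + dprev
    rb <- resblock_bwd(dl, p$enc[[l]], cache$enc[[l]])
    g$enc[[l]] <- rb$grads
    if (l > 1) {
      drn <- relu_bwd(rb$dx, cache$down_relu[[l - 1]])
      db <- conv1_bwd(drn, p$down[[l - 1]], cache$down[[l - 1]])
      g$down[[l - 1]] <- db$grads
      dprev <- avgpool2_bwd(db$dx, cache$pool[[l - 1]])
    } else {
      dr0 <- relu_bwd(rb$dx, cache$stem_relu)
      sb <- conv3_bwd(dr0, p$stem, cache$stem)
      g$stem <- sb$grads
    }
  }
  g[c("stem", "enc", "down", "up", "fuse", "head")]
}

#' Apply the model to one linear-RGB patch
#'
#' @param model a [build_model()] result (usually trained).
#' @param patch H x W x 3 linear-RGB array, sides divisible by `2^depth`.
#' @return a [pigment_maps()] at the patch resolution.
#' @export
predict_maps <- function(model, patch) {
  out <- model_forward(model, patch)$out
  pigment_maps(out[, , 1], out[, , 2], out[, , 3])
}

# smoothed isotropic total variation of a map and its gradient
tv_penalty <- function(s, eps = 1e-8) {
  d <- dim(s)
  dx <- s[-1, , drop = FALSE] - s[-d[1], , drop = FALSE]
  dy <- s[, -1, drop = FALSE] - s[, -d[2], drop = FALSE]
  # pad the forward differences back to full size
  dxf <- rbind(dx, 0); dyf <- cbind(dy, 0)
  mag <- sqrt(dxf^2 + dyf^2 + eps)
  g <- matrix(0, d[1], d[2])
  gx <- dxf / mag; gy <- dyf / mag
  g <- g - gx - gy
  g[-1, ] <- g[-1, ] + gx[-d[1], ]
  g[, -1] <- g[, -1] + gy[, -d[2]]
  n <- prod(d)
  list(value = sum(mag) / n, grad = g / n)
}

# masked reconstruction loss and its gradient w.r.t. the model output maps
recon_loss_grad <- function(out, x, mask, lut) {
  maps <- pigment_maps(out[, , 1], out[, , 2], out[, , 3])
  rd <- render_maps(maps, lut, grad = TRUE)
  n_eff <- 3 * sum(mask)
  w <- array(rep(mask, 3), dim(x))
  resid <- (rd$rgb - x) * w
  loss <- sum(resid^2) / n_eff
  dr <- 2 * resid / n_eff
  sum3 <- function(a) a[, , 1] + a[, , 2] + a[, , 3]
  d_out <- array(c(sum3(dr * rd$d_melanin),
                   sum3(dr * rd$d_hemoglobin),
                   sum3(dr * rd$d_shading)), dim(out))
  list(loss = loss, d_out = d_out, recon = rd$rgb)
}

#' Self-supervised training against the differentiable renderer
#'
#' Minimizes the masked mean squared error between each input patch and the
#' rendering of its predicted pigment maps -- no pigment ground truth is
#' used. One Adam step per patch, patches visited in a seeded shuffled
#' order, reshuffled each epoch. A running (exponentially averaged) masked
#' PSNR is tracked; whenever its periodic evaluation exceeds the checkpoint
#' threshold the step and PSNR are recorded and the best-so-far parameters
#' retained. Fully reproducible under `cfg$seed`.
#'
#' @param images list of H x W x 3 linear-RGB patches (H = W =
#'   `cfg$patch_size`, or `cfg$augment_crop_from` for random-crop
#'   augmentation).
#' @param lut a [build_reflectance_lut()] result.
#' @param cfg a [model_config()].
#' @param masks optional list of binary skin masks matching `images`
#'   (default: all-skin).
#' @param model optional pre-built model to continue training.
#' @param verbose print progress every `cfg$eval_every` steps.
#' @return list with `model` (trained), and `state`: step count, final
#'   running MSE/PSNR, checkpoint log, and best checkpoint parameters.
#' @export
train_self_supervised <- function(images, lut, cfg = model_config(),
                                  masks = NULL, model = NULL,
                                  verbose = FALSE) {
  if (length(images) == 0) stop("empty training set")
  if (is.null(model)) model <- build_model(cfg)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed + 1L)
  opt <- adam_init(model$params)
  n <- length(images)
  order_ <- sample.int(n)
  pos <- 0L
  ema <- NA_real_
  checkpoints <- list()
  best <- list(psnr = -Inf, params = NULL, step = NA_integer_)
  P <- cfg$patch_size
  for (step in seq_len(cfg$steps)) {
    pos <- pos + 1L
    if (pos > n) { order_ <- sample.int(n); pos <- 1L }
    i <- order_[pos]
    x <- images[[i]]
    m <- if (is.null(masks)) matrix(1, dim(x)[1], dim(x)[2]) else masks[[i]]
    if (dim(x)[1] > P || dim(x)[2] > P) {   # random-crop augmentation
      r0 <- sample.int(dim(x)[1] - P + 1L, 1L)
      c0 <- sample.int(dim(x)[2] - P + 1L, 1L)
      x <- x[r0:(r0 + P - 1L), c0:(c0 + P - 1L), , drop = FALSE]
      m <- m[r0:(r0 + P - 1L), c0:(c0 + P - 1L), drop = FALSE]
    }
    lr_t <- if (cfg$lr_schedule == "cosine")
      cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
        (1 + cos(pi * (step - 1) / cfg$steps))
    else cfg$lr
    fw <- model_forward(model, x, want_cache = TRUE)
    lg <- recon_loss_grad(fw$out, x, m, lut)
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite loss at step %d (running MSE %.3g): aborting",
                   step, ema))
    if (cfg$tv_shading > 0) {
      tv <- tv_penalty(fw$out[, , 3])
      lg$d_out[, , 3] <- lg$d_out[, , 3] + cfg$tv_shading * tv$grad
    }
    grads <- model_backward(model, fw$cache, lg$d_out)
    up <- adam_step(model$params, grads, opt, lr = lr_t)
    model$params <- up$params
    opt <- up$state
    ema <- if (is.na(ema)) lg$loss else 0.98 * ema + 0.02 * lg$loss
    if (step %% cfg$eval_every == 0L || step == cfg$steps) {
      run_psnr <- 10 * log10(1 / ema)
      if (verbose)
        message(sprintf("step %5d  running MSE %.3e  PSNR %.2f dB",
                        step, ema, run_psnr))
      if (run_psnr > cfg$checkpoint_psnr_db) {
        checkpoints[[length(checkpoints) + 1L]] <-
          list(step = step, psnr_db = run_psnr)
        if (run_psnr > best$psnr)
          best <- list(psnr = run_psnr, params = model$params, step = step)
      }
    }
  }
  state <- list(steps = cfg$steps, running_mse = ema,
                running_psnr_db = 10 * log10(1 / ema),
                checkpoints = checkpoints, best = best)
  list(model = model, state = state)
}

#' Decompose a full image into pigment maps
#'
#' Inference pipeline: overlay the skin mask (non-skin pixels zeroed),
#' inverse gamma to linear RGB, split into overlapping patches, run the
#' model on each patch, and blend each output map with the crossfade
#' weights. Non-skin pixels of the returned maps are zero. Because non-skin
#' input is zeroed before the network sees it, pixels outside the mask
#' cannot influence maps inside it.
#'
#' @param img a [skin_image()] tagged srgb (or H x W x 3 sRGB array).
#' @param mask binary skin mask (defaults to the image's own mask).
#' @param model a trained [build_model()] result.
#' @param grid optional [patch_grid()]; defaults to the model's patch size
#'   with a 15-px overlap.
#' @return a [pigment_maps()] at full image resolution.
#' @export
decompose_image <- function(img, mask = NULL, model, grid = NULL) {
  x <- as_srgb_array(img)
  shape <- dim(x)[1:2]
  if (is.null(mask) && inherits(img, "skin_image")) mask <- img$mask
  if (is.null(mask)) mask <- matrix(1, shape[1], shape[2])
  if (!all(dim(mask) == shape)) stop("mask shape does not match image")
  if (is.null(grid))
    grid <- patch_grid(shape, patch_size = model$cfg$patch_size, overlap = 15)
  lin <- srgb_to_linear(x * array(rep(mask, 3), dim(x)))
  patches <- split_into_patches(lin, grid)
  outs <- lapply(patches, function(pp) model_forward(model, pp)$out)
  blend1 <- function(k) {
    blend_patches(lapply(outs, function(o) o[, , k]), grid, shape) * mask
  }
  pigment_maps(blend1(1), blend1(2), blend1(3))
}

#' Reconstruct an image from its own decomposition
#'
#' Convenience wrapper: [decompose_image()] then [render_maps()], returning
#' the linear-RGB reconstruction (what the training loss compares against
#' the linearized input).
#'
#' @inheritParams decompose_image
#' @param lut the reflectance LUT the model was trained against.
#' @return H x W x 3 linear-RGB array.
#' @export
reconstruct_image <- function(img, mask = NULL, model, lut, grid = NULL) {
  maps <- decompose_image(img, mask, model, grid)
  render_maps(maps, lut)
}

#' Save / load a model checkpoint
#'
#' Self-describing plain-JSON archive: the configuration plus all parameter
#' tensors (flattened with dimensions recorded).
#'
#' @param model a `pigment_model`.
#' @param path output `.json` file.
#' @export
save_checkpoint <- function(model, path) {
  ser <- nl_map(function(x) list(dim = dim(x) %||% length(x),
                                 data = as.numeric(x)), model$params)
  jsonlite::write_json(list(cfg = unclass(model$cfg), params = ser), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg_args <- raw$cfg[names(raw$cfg) %in% names(formals(model_config))]
  cfg <- do.call(model_config, lapply(cfg_args, function(v)
    if (is.list(v)) unlist(v) else v))
  deser <- function(x) {
    if (is.list(x) && setequal(names(x), c("dim", "data"))) {
      dims <- unlist(x$dim)
      vals <- as.numeric(unlist(x$data))
      if (length(dims) > 1) array(vals, dims) else vals
    } else lapply(x, deser)
  }
  structure(list(params = deser(raw$params), cfg = cfg),
            class = "pigment_model")
}
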