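# Minimal CPU neural-network layer kit used by the pigment discrimination
# model: 3x3 same-padding convolution via im2col + BLAS matmul, 1x1
# convolution, ReLU / sigmoid, 2x2 average pooling, nearest-neighbour
# upsampling, channel concatenation, and an Adam optimizer over nested
# parameter lists. Forward functions return a cache consumed by the
# matching backward function; all tensors are H x W x C arrays.

conv3_init <- function(cin, cout, gain = 2) {
  list(W = matrix(stats::rnorm(9 * cin * cout) * sqrt(gain / (9 * cin)),
                  9 * cin, cout),
       b = numeric(cout))
}

conv1_init <- function(cin, cout, gain = 2) {
  list(W = matrix(stats::rnorm(cin * cout) * sqrt(gain / cin), cin, cout),
       b = numeric(cout))
}

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  Xc <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    Xc[, k * C + seq_len(C)] <- xp[di + seq_len(H), dj + seq_len(W), ]
    k <- k + 1L
  }
  Xc
}

conv3_fwd <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Xc <- im2col3(x)
  cout <- ncol(p$W)
  Y <- Xc %*% p$W + rep(p$b, each = H * W)
  list(out = array(Y, c(H, W, cout)), cache = list(Xc = Xc, dims = d))
}

conv3_bwd <- function(dy, p, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  dY <- matrix(dy, H * W, ncol(p$W))
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, p$W)
  dxp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    ri <- di + seq_len(H); ci <- dj + seq_len(W)
    blk <- dXc[, k * C + seq_len(C)]
    dim(blk) <- c(H, W, C)
    dxp[ri, ci, ] <- dxp[ri, ci, ] + blk
    k <- k + 1L
  }
  list(dx = dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

conv1_fwd <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Xm <- matrix(x, H * W, d[3])
  Y <- Xm %*% p$W + rep(p$b, each = H * W)
  list(out = array(Y, c(H, W, ncol(p$W))), cache = list(Xm = Xm, dims = d))
}

conv1_bwd <- function(dy, p, cache) {
  d <- cache$dims
  dY <- matrix(dy, d[1] * d[2], ncol(p$W))
  list(dx = array(tcrossprod(dY, p$W), d),
       grads = list(W = crossprod(cache$Xm, dY), b = colSums(dY)))
}

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}
relu_bwd <- function(dy, cache) dy * cache

sigmoid_fwd <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, cache = out)
}
sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

avgpool2_fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], by = 2L); o2 <- o1 + 1L
  e1 <- seq(1L, d[2], by = 2L); e2 <- e1 + 1L
  out <- 0.25 * (x[o1, e1, , drop = FALSE] + x[o2, e1, , drop = FALSE] +
                   x[o1, e2, , drop = FALSE] + x[o2, e2, , drop = FALSE])
  list(out = out, cache = d)
}

avgpool2_bwd <- function(dy, cache) {
  d <- cache
  dx <- array(0, d)
  q <- 0.25 * dy
  o1 <- seq(1L, d[1], by = 2L); o2 <- o1 + 1L
  e1 <- seq(1L, d[2], by = 2L); e2 <- e1 + 1L
  dx[o1, e1, ] <- q; dx[o2, e1, ] <- q; dx[o1, e2, ] <- q; dx[o2, e2, ] <- q
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
               drop = FALSE],
       cache = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- dim(dy)
  o1 <- seq(1L, d[1], by = 2L); o2 <- o1 + 1L
  e1 <- seq(1L, d[2], by = 2L); e2 <- e1 + 1L
  dy[o1, e1, , drop = FALSE] + dy[o2, e1, , drop = FALSE] +
    dy[o1, e2, , drop = FALSE] + dy[o2, e2, , drop = FALSE]
}

# channel-last concatenation is contiguous in column-major storage
concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), drop = FALSE],
       x[, , (c1 + 1L):d[3], drop = FALSE])
}

# residual block: y = relu(x + conv_b(relu(conv_a(x))))
resblock_fwd <- function(x, p) {
  a <- conv3_fwd(x, p$conv_a)
  r <- relu_fwd(a$out)
  b <- conv3_fwd(r$out, p$conv_b)
  y <- relu_fwd(x + b$out)
  list(out = y$out, cache = list(a = a$cache, r = r$cache, b = b$cache,
                                 y = y$cache))
}

resblock_bwd <- function(dy, p, cache) {
  d1 <- relu_bwd(dy, cache$y)
  bb <- conv3_bwd(d1, p$conv_b, cache$b)
  d2 <- relu_bwd(bb$dx, cache$r)
  aa <- conv3_bwd(d2, p$conv_a, cache$a)
  list(dx = aa$dx + d1,
       grads = list(conv_a = aa$grads, conv_b = bb$grads))
}

resblock_init <- function(ch) {
  list(conv_a = conv3_init(ch, ch), conv_b = conv3_init(ch, ch))
}

# --- Adam over nested parameter lists ------------------------------------

nl_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) nl_map(f, x)) else f(a)
}
nl_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nl_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = nl_map(function(x) x * 0, params),
       v = nl_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nl_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nl_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- nl_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                 state$m, state$v)
  params <- nl_map2(`-`, params, upd)
  list(params = params, state = state)
}
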