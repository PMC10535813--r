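# Overlapping patch decomposition and seam-free recombination.
#
# Full images are processed in fixed-size patches that share a small
# overlap; per-patch outputs are recombined with distance-to-border
# crossfade weights ("inverse gradient"), normalized per pixel so the
# weights form an exact partition of unity. Across a standard overlap band
# between two patches the normalized weight profile is an exactly linear
# ramp.

#' Patch geometry for a full image
#'
#' Computes row-major patch origins covering an image. Interior patches
#' advance by `patch_size - overlap`; the final patch along each axis is
#' anchored to the image border (its overlap may exceed the nominal value).
#' Images smaller than the patch size are reflect-padded by
#' [split_into_patches()]; the padding is recorded in the grid.
#'
#' @param shape integer pair (rows, cols) of the full image.
#' @param patch_size patch side length in pixels (default 256).
#' @param overlap nominal overlap between adjacent patches (default 15);
#'   must be smaller than `patch_size`.
#' @return an object of class `patch_grid` with 1-based `row_starts`,
#'   `col_starts`, the padded working shape and the original shape.
#' @export
patch_grid <- function(shape, patch_size = 256, overlap = 15) {
  if (overlap >= patch_size) stop("overlap must be smaller than patch_size")
  if (overlap < 0) stop("overlap must be nonnegative")
  pad <- pmax(0, patch_size - shape)
  work <- shape + pad
  starts <- function(n) {
    s <- seq(1L, max(1L, n - patch_size + 1L), by = patch_size - overlap)
    if (s[length(s)] + patch_size - 1L < n) s <- c(s, n - patch_size + 1L)
    s[length(s)] <- n - patch_size + 1L   # anchor last patch to the border
    unique(s)
  }
  structure(list(patch_size = as.integer(patch_size),
                 overlap = as.integer(overlap),
                 row_starts = starts(work[1]), col_starts = starts(work[2]),
                 shape = shape, work_shape = work, pad = pad),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d image, %d patches of %d px (overlap %d)\n",
              x$shape[1], x$shape[2],
              length(x$row_starts) * length(x$col_starts),
              x$patch_size, x$overlap))
  invisible(x)
}

#' Patch geometry as a plain list (for JSON debugging dumps)
#' @param grid a [patch_grid()].
#' @return list of 0-based (row, col) origins plus the geometry scalars.
#' @export
patch_grid_json <- function(grid) {
  org <- expand.grid(col = grid$col_starts - 1L, row = grid$row_starts - 1L)
  list(patch_size = grid$patch_size, overlap = grid$overlap,
       shape = grid$shape,
       origins = lapply(seq_len(nrow(org)),
                        function(i) c(org$row[i], org$col[i])))
}

reflect_pad <- function(x, pad) {
  ridx <- seq_len(dim(x)[1]); cidx <- seq_len(dim(x)[2])
  if (pad[1] > 0) ridx <- c(ridx, rev(ridx))[seq_len(dim(x)[1] + pad[1])]
  if (pad[2] > 0) cidx <- c(cidx, rev(cidx))[seq_len(dim(x)[2] + pad[2])]
  if (length(dim(x)) == 3) x[ridx, cidx, , drop = FALSE] else x[ridx, cidx, drop = FALSE]
}

#' Split an image into overlapping patches
#'
#' Deterministic row-major ordering; every pixel is covered by at least one
#' patch. Inputs smaller than the patch size are reflect-padded first (the
#' grid records the padding so [blend_patches()] can crop it away).
#'
#' @param img matrix (H x W) or array (H x W x C).
#' @param grid a [patch_grid()] built for `dim(img)[1:2]`.
#' @return list of patches in row-major order.
#' @export
split_into_patches <- function(img, grid) {
  if (!all(dim(img)[1:2] == grid$shape)) stop("grid was built for a different shape")
  if (any(grid$pad > 0)) img <- reflect_pad(img, grid$pad)
  P <- grid$patch_size
  out <- vector("list", length(grid$row_starts) * length(grid$col_starts))
  k <- 1L
  for (r in grid$row_starts) for (c in grid$col_starts) {
    out[[k]] <- if (length(dim(img)) == 3)
      img[r:(r + P - 1L), c:(c + P - 1L), , drop = FALSE]
    else img[r:(r + P - 1L), c:(c + P - 1L), drop = FALSE]
    k <- k + 1L
  }
  out
}

# 1-D tent weight: distance to the nearest patch border (>= 1 inside)
tent_weight <- function(start, P) {
  i <- seq_len(P)
  pmin(i, P - i + 1L)
}

#' Recombine per-patch outputs into a full image
#'
#' Per-pixel weighted average with separable distance-to-border crossfade
#' weights, normalized so they sum to one everywhere. Feeding the patches
#' produced by [split_into_patches()] straight back reproduces the input
#' exactly, and constant patches blend to the same constant (partition of
#' unity).
#'
#' @param patches list of patches, ordered as produced by the split.
#' @param grid the same [patch_grid()].
#' @param out_shape optional output shape (defaults to the grid's original
#'   image shape).
#' @return matrix or array of shape `out_shape`.
#' @export
blend_patches <- function(patches, grid, out_shape = grid$shape) {
  np <- length(grid$row_starts) * length(grid$col_starts)
  if (length(patches) != np)
    stop(sprintf("expected %d patches, got %d", np, length(patches)))
  P <- grid$patch_size
  nch <- if (length(dim(patches[[1]])) == 3) dim(patches[[1]])[3] else 1L
  work <- grid$work_shape
  num <- array(0, c(work, nch))
  den <- matrix(0, work[1], work[2])
  w2 <- outer(tent_weight(1L, P), tent_weight(1L, P))
  k <- 1L
  for (r in grid$row_starts) for (c in grid$col_starts) {
    ri <- r:(r + P - 1L); ci <- c:(c + P - 1L)
    p <- patches[[k]]
    if (is.null(dim(p)) || !all(dim(p)[1:2] == c(P, P)))
      stop("patch ", k, " has the wrong shape")
    pv <- array(p, c(P, P, nch))
    for (m in seq_len(nch))
      num[ri, ci, m] <- num[ri, ci, m] + w2 * pv[, , m]
    den[ri, ci] <- den[ri, ci] + w2
    k <- k + 1L
  }
  for (m in seq_len(nch)) num[, , m] <- num[, , m] / den
  out <- num[seq_len(out_shape[1]), seq_len(out_shape[2]), , drop = FALSE]
  if (nch == 1L) dim(out) <- out_shape
  out
}

#' Normalized blend weight fields, one per patch
#'
#' Mainly for validation: returns each patch's per-pixel contribution
#' weight on the full canvas; the fields sum to one at every pixel.
#'
#' @param grid a [patch_grid()].
#' @return list of `work_shape` matrices.
#' @export
blend_weight_fields <- function(grid) {
  P <- grid$patch_size
  work <- grid$work_shape
  den <- matrix(0, work[1], work[2])
  w2 <- outer(tent_weight(1L, P), tent_weight(1L, P))
  for (r in grid$row_starts) for (c in grid$col_starts)
    den[r:(r + P - 1L), c:(c + P - 1L)] <-
      den[r:(r + P - 1L), c:(c + P - 1L)] + w2
  fields <- list()
  k <- 1L
  for (r in grid$row_starts) for (c in grid$col_starts) {
    f <- matrix(0, work[1], work[2])
    ri <- r:(r + P - 1L); ci <- c:(c + P - 1L)
    f[ri, ci] <- w2 / den[ri, ci]
    fields[[k]] <- f
    k <- k + 1L
  }
  fields
}
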