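#' Logistic blending weight over an overlap coordinate
#'
#' `omega(r) = 1 / (1 + exp(-k (r - r_c)))`: strictly increasing, 0.5 at the
#' overlap midpoint `r_c`, and symmetric in the sense
#' `omega(r_c + d) + omega(r_c - d) = 1`, which is what makes pairwise
#' blending a partition of unity.
#'
#' @param r overlap coordinate (pixels; scalar or vector)
#' @param r_c sigmoid centre (inflection point), the overlap midpoint
#' @param k_slope slope constant in 1/raw-pixel (default 0.05); when blending
#'   on an upsampled grid the caller scales it by the upsampling factor
#' @return weights in (0, 1)
#' @export
sigmoid_weight <- function(r, r_c, k_slope = 0.05) {
  if (!(k_slope > 0)) stop("k_slope must be positive")
  1 / (1 + exp(-k_slope * (r - r_c)))
}

#' Blend two overlapping tiles along one axis
#'
#' Convex combination `F = (1 - omega) I1 + omega I2` with the logistic
#' weight varying along the stitch axis: `I1` dominates the low-coordinate
#' side of the overlap, `I2` the high side.
#'
#' @param i1,i2 overlapping regions (matrices or `[z, y, x]` arrays of equal
#'   shape)
#' @param axis `"x"` (columns) or `"y"` (rows): axis along which the tiles
#'   abut
#' @param k_slope logistic slope constant (per pixel of the supplied grid)
#' @return blended array, same shape
#' @export
fuse_pair <- function(i1, i2, axis = c("x", "y"), k_slope = 0.05) {
  axis <- match.arg(axis)
  if (!identical(dim(i1), dim(i2))) stop("overlap extents differ")
  d <- dim(i1)
  arr3 <- length(d) == 3
  len <- if (arr3) (if (axis == "x") d[3] else d[2]) else (if (axis == "x") d[2] else d[1])
  w <- sigmoid_weight(seq_len(len), (len + 1) / 2, k_slope)
  if (arr3) {
    wa <- if (axis == "x") aperm(array(w, c(d[3], d[1], d[2])), c(2, 3, 1))
          else aperm(array(w, c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    wa <- if (axis == "x") matrix(w, d[1], d[2], byrow = TRUE) else matrix(w, d[1], d[2])
  }
  (1 - wa) * i1 + wa * i2
}

# per-tile separable weight profile along one axis of the fused field:
# ascending logistic over the left overlap, 1 in the core, descending over
# the right overlap; border tiles keep weight 1 at the field edge.
tile_weight_profile <- function(pos, n_side, tile_len, overlap, k_slope) {
  w <- rep(1, tile_len)
  idx <- seq_len(overlap)
  centre <- (overlap + 1) / 2
  if (pos > 1) w[idx] <- sigmoid_weight(idx, centre, k_slope)
  if (pos < n_side) {
    w[tile_len - overlap + idx] <- 1 - sigmoid_weight(idx, centre, k_slope)
  }
  w
}

#' Fuse reconstructed tiles into the full-field volume
#'
#' Stitches per-tile super-resolution volumes on the upsampled grid using
#' separable products of logistic weight profiles. Adjacent profiles are
#' complementary (`omega` and `1 - omega`) over each overlap, so the
#' effective weights form a partition of unity everywhere, including the
#' four-fold corner overlaps where the x/y products multiply out to 1.
#'
#' @param tiles list of `[z, y', x']` arrays in row-major tile order
#'   (matching `grid$bounds`), each of lateral side `upsample * 2m`
#' @param grid the [tile_grid()] used to cut the raw stack
#' @param upsample lateral upsampling factor of the tiles relative to the
#'   raw grid (default 2)
#' @param k_slope logistic slope constant per pixel of the fused
#'   (upsampled) grid; with the default 0.05 the weight 64 SR pixels past
#'   the overlap midpoint is `1/(1+exp(-3.2))`
#' @return fused `[z, upsample*N, upsample*N]` array
#' @export
fuse_grid <- function(tiles, grid, upsample = 2, k_slope = 0.05) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tiles) != grid$n_tiles) {
    missing_ids <- setdiff(seq_len(grid$n_tiles), seq_along(tiles))
    stop("missing reconstructed tiles: ", paste(missing_ids, collapse = ", "))
  }
  ts <- grid$tile_size * upsample
  ov <- grid$stride * upsample
  nz <- dim(tiles[[1]])[1]
  nfull <- grid$n * upsample
  out <- array(0, c(nz, nfull, nfull))
  wsum <- matrix(0, nfull, nfull)
  for (t in seq_len(grid$n_tiles)) {
    stopifnot(all(dim(tiles[[t]]) == c(nz, ts, ts)))
    i <- grid$ij[t, "i"]; j <- grid$ij[t, "j"]
    wy <- tile_weight_profile(i, grid$n_side, ts, ov, k_slope)
    wx <- tile_weight_profile(j, grid$n_side, ts, ov, k_slope)
    wmat <- outer(wy, wx)
    b <- grid$bounds[t, ] * upsample
    ys <- (b[1] + 1):b[2]; xs <- (b[3] + 1):b[4]
    for (z in seq_len(nz)) {
      out[z, ys, xs] <- out[z, ys, xs] + wmat * tiles[[t]][z, , ]
    }
    wsum[ys, xs] <- wsum[ys, xs] + wmat
  }
  attr(out, "weight_sum") <- wsum
  out
}
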