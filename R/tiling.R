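#' Half-overlapping tile segmentation of a square field
#'
#' Splits an `n x n` field into `(n/m - 1)^2` tiles of size `2m x 2m` at
#' stride `m`, so each tile shares half its pixels with each lateral
#' neighbour, the union of tiles covers the field exactly, and interior
#' pixels are covered by exactly four tiles. `n` must be divisible by `m`
#' and at least `2m`.
#'
#' The adaptive pipeline segments on the 2x-upsampled lateral grid: a raw
#' stack of side `N` is tiled as `tile_grid(2 * N, m)`, giving the
#' `(2N/m - 1)^2` tiles of `2m x 2m` (128 x 128 for the default `m = 64`)
#' that the tiled reconstruction operates on — equivalent to raw-grid
#' windows of `m x m` at stride `m/2`.
#'
#' @param n field side length (pixels of the segmentation grid)
#' @param m half-tile size (pixels, default 64 giving 128 x 128 tiles)
#' @return object of class `tile_grid`: `n`, `m`, `tile_size`, `stride`,
#'   `n_side`, `n_tiles`, and `bounds`, a `n_tiles x 4` integer matrix of
#'   0-based half-open `(y0, y1, x0, x1)` windows in row-major tile order
#' @export
tile_grid <- function(n, m = 64) {
  if (n %% m != 0)
    stop("field size ", n, " is not divisible by half-tile size ", m,
         "; crop or pad the stack (see config) before tiling")
  if (n < 2 * m) stop("field must be at least one full tile (2m) wide")
  n_side <- as.integer(n %/% m - 1L)
  idx <- expand.grid(j = seq_len(n_side), i = seq_len(n_side))  # j (cols) fastest
  bounds <- cbind(y0 = (idx$i - 1L) * m, y1 = (idx$i + 1L) * m,
                  x0 = (idx$j - 1L) * m, x1 = (idx$j + 1L) * m)
  structure(list(n = as.integer(n), m = as.integer(m),
                 tile_size = 2L * as.integer(m), stride = as.integer(m),
                 n_side = n_side, n_tiles = n_side^2,
                 ij = cbind(i = idx$i, j = idx$j),
                 bounds = bounds),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %d x %d field, %d tiles of %d x %d at stride %d\n",
              x$n, x$n, x$n_tiles, x$tile_size, x$tile_size, x$stride))
  invisible(x)
}

#' Number of tiles covering each pixel of the field
#'
#' @param grid a [tile_grid()]
#' @return integer matrix `n x n`
#' @export
tile_coverage <- function(grid) {
  cov <- matrix(0L, grid$n, grid$n)
  for (t in seq_len(grid$n_tiles)) {
    b <- grid$bounds[t, ]
    cov[(b[1] + 1):b[2], (b[3] + 1):b[4]] <- cov[(b[1] + 1):b[2], (b[3] + 1):b[4]] + 1L
  }
  cov
}

#' Partition layers into direct and merged sets by modulation quality
#'
#' Layers whose normalized MCNR exceeds the threshold carry enough modulation
#' for their own parameter estimates; the rest share parameters estimated
#' from one merged composite slice. An empty direct set is legal.
#'
#' @param quality a `slice_quality` (from [normalize_scores()] or
#'   [stack_mcnr()])
#' @param threshold modulation threshold `M_t`; defaults to the one stored in
#'   `quality`
#' @return list `direct` and `merged`: integer layer indices
#' @export
select_slices <- function(quality, threshold = quality$threshold) {
  direct <- which(quality$mcnr_norm > threshold)
  merged <- setdiff(seq_along(quality$mcnr_norm), direct)
  list(direct = direct, merged = merged)
}

#' MCNR-weighted composite slice of a tile sub-stack
#'
#' Weighted merge of the pre-filtered layers of a tile: layer weights are the
#' normalized MCNR scores re-normalized to sum to one over the retained
#' layers. Layers below `prefilter` (deep defocus) are excluded from the
#' composite; if nothing survives the pre-filter, an unweighted mean over all
#' layers is returned with a warning.
#'
#' @param tile_substack array `[..., z, y, x]` or `[z, y, x]`: any leading
#'   dimensions are preserved while z is collapsed
#' @param quality a `slice_quality` for the tile
#' @param prefilter minimum normalized MCNR for a layer to enter the
#'   composite (default 0.2)
#' @return array with the z dimension collapsed (composite image per leading
#'   index)
#' @export
merge_block <- function(tile_substack, quality, prefilter = 0.2) {
  d <- dim(tile_substack)
  nd <- length(d)
  stopifnot(nd >= 3)
  zdim <- nd - 2L
  nz <- d[zdim]
  stopifnot(length(quality$mcnr_norm) == nz)
  w <- quality$mcnr_norm
  keep <- w >= prefilter
  if (!any(keep) || sum(w[keep]) <= 0) {
    warning("no layers pass the MCNR pre-filter; using an unweighted mean")
    w <- rep(1, nz); keep <- rep(TRUE, nz)
  }
  w[!keep] <- 0
  w <- w / sum(w)
  perm <- c(zdim, seq_len(nd)[-zdim])
  a <- aperm(tile_substack, perm)             # z first
  dim(a) <- c(nz, prod(d[-zdim]))
  comp <- as.vector(w %*% a)
  out_dim <- d[-zdim]
  array(comp, out_dim)
}

#' Resolve the per-tile parameter field with anomaly fallback
#'
#' Non-anomalous tiles keep their own estimates; tiles whose orientation
#' triple fails the prior check are replaced by the full-field estimate of
#' the corresponding layer (or composite reference). Every substitution is
#' recorded in a ledger.
#'
#' @param tile_estimates nested list `[[tile]][[z_key]][[orientation]]` of
#'   `param_estimate`s; `z_key` is a layer index as character or `"merged"`
#' @param layer_estimates list `[[z_key]][[orientation]]` of full-field
#'   fallback estimates, with the same z keys
#' @param checks list `[[tile]][[z_key]]` of `orientation_check`s
#' @return object of class `param_field`: `estimates` (same nesting, with
#'   anomalous entries substituted and tagged `source = "layer"`), `ledger`
#'   (data frame of substitutions)
#' @export
resolve_params <- function(tile_estimates, layer_estimates, checks) {
  ledger <- data.frame(tile = integer(), z = character(),
                       sd_wv = numeric(), sd_ang = numeric())
  out <- tile_estimates
  for (t in seq_along(tile_estimates)) {
    for (zk in names(tile_estimates[[t]])) {
      chk <- checks[[t]][[zk]]
      low <- any(vapply(tile_estimates[[t]][[zk]],
                        function(e) isTRUE(e$low_confidence), TRUE))
      if (isTRUE(chk$anomalous) || low) {
        if (is.null(layer_estimates[[zk]]))
          stop("no full-field fallback estimate for layer ", zk)
        sub <- lapply(layer_estimates[[zk]], function(e) {
          e$source <- "layer"
          e
        })
        out[[t]][[zk]] <- sub
        ledger <- rbind(ledger, data.frame(
          tile = t, z = zk,
          sd_wv = if (!is.null(chk)) chk$sd_wv else NA_real_,
          sd_ang = if (!is.null(chk)) chk$sd_ang else NA_real_))
      }
    }
  }
  structure(list(estimates = out, ledger = ledger), class = "param_field")
}

#' @export
print.param_field <- function(x, ...) {
  n_sub <- nrow(x$ledger)
  cat(sprintf("parameter field: %d tiles, %d anomalous entr%s replaced by layer estimates\n",
              length(x$estimates), n_sub, if (n_sub == 1) "y" else "ies"))
  invisible(x)
}
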