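#' Per-pixel modulation contrast-to-noise ratio
#'
#' For each pixel the five phase-stepped intensities follow the cosine model
#' `N(n) = A0 + A1 cos(2 pi n / 5 + alpha1) + A2 cos(4 pi n / 5 + alpha2)`.
#' The amplitudes are read off the length-5 DFT along the phase axis with the
#' convention `A0 = |sum N| / 5`, `Au = 2 |sum N exp(-2i pi u n / 5)| / 5`
#' (u = 1, 2), so that a pure signal `c + b cos(2 pi n / 5)` yields exactly
#' `A0 = c, A1 = b`. The contrast-to-noise ratio is
#' `MCNR = 2 sqrt(A1^2 + A2^2) / sqrt(A0^2)`: the numerator is twice the mean
#' modulation amplitude, the denominator the shot-noise level.
#'
#' @param phase_images 3-D array `[5, y, x]` (or list of 5 matrices): the five
#'   phase-stepped images of one orientation and layer
#' @return object of class `mcnr_map`: list with `per_pixel` (MCNR matrix),
#'   `amp` (list A0, A1, A2) and `phase` (list alpha1, alpha2)
#' @export
mcnr_map <- function(phase_images) {
  if (is.list(phase_images)) {
    phase_images <- aperm(simplify2array(phase_images), c(3, 1, 2))
  }
  d <- dim(phase_images)
  if (length(d) != 3 || d[1] != 5) stop("exactly 5 phase images are required")
  ny <- d[2]; nx <- d[3]
  m <- matrix(phase_images, 5, ny * nx)       # DFT along the phase axis
  co <- stats::mvfft(m)
  a0 <- abs(co[1, ]) / 5
  a1 <- 2 * abs(co[2, ]) / 5
  a2 <- 2 * abs(co[3, ]) / 5
  al1 <- Arg(co[2, ]); al2 <- Arg(co[3, ])
  mc <- rep(0, ny * nx)
  pos <- a0 > 0
  mc[pos] <- 2 * sqrt(a1[pos]^2 + a2[pos]^2) / a0[pos]
  structure(list(per_pixel = matrix(mc, ny, nx),
                 amp = list(A0 = matrix(a0, ny, nx),
                            A1 = matrix(a1, ny, nx),
                            A2 = matrix(a2, ny, nx)),
                 phase = list(alpha1 = matrix(al1, ny, nx),
                              alpha2 = matrix(al2, ny, nx))),
            class = "mcnr_map")
}

#' Average MCNR maps over the three illumination orientations
#'
#' @param maps list of 3 `mcnr_map` objects (or plain matrices) of equal shape
#' @return matrix: per-pixel arithmetic mean
#' @export
mcnr_orientation_mean <- function(maps) {
  stopifnot(length(maps) == 3)
  mats <- lapply(maps, function(m) if (inherits(m, "mcnr_map")) m$per_pixel else m)
  if (!all(vapply(mats, function(m) identical(dim(m), dim(mats[[1]])), TRUE)))
    stop("MCNR maps have mismatched shapes")
  (mats[[1]] + mats[[2]] + mats[[3]]) / 3
}

# percentile with linear interpolation between order statistics
# (the "inclusive" definition, i.e. stats::quantile type 7)
prctile <- function(x, p) {
  unname(stats::quantile(x, p / 100, type = 7, names = FALSE))
}

#' Layer quality score from an orientation-averaged MCNR map
#'
#' Mean of the 100th and (100 - a)th percentiles of the map: the highest and
#' nearby-second-highest MCNR values, robust to single hot pixels.
#'
#' @param mean_map matrix (orientation-averaged MCNR)
#' @param a percentile constant, must lie strictly in (5, 10); default 7
#' @return scalar average MCNR for the layer
#' @export
slice_score <- function(mean_map, a = 7) {
  if (!(a > 5 && a < 10)) stop("percentile constant a must lie in (5, 10)")
  (prctile(mean_map, 100) + prctile(mean_map, 100 - a)) / 2
}

#' Normalize per-layer scores so the best layer scores exactly 1
#'
#' @param avg_mcnr numeric vector of per-layer scores (at least one positive)
#' @param a percentile constant used to compute the scores (carried along)
#' @param threshold modulation-quality threshold `M_t` (default 0.85)
#' @return object of class `slice_quality`: list with `avg_mcnr`,
#'   `mcnr_norm`, `percentile_a`, `threshold`
#' @export
normalize_scores <- function(avg_mcnr, a = 7, threshold = 0.85) {
  stopifnot(length(avg_mcnr) >= 1)
  mx <- max(avg_mcnr)
  if (!(mx > 0)) stop("degenerate stack: all layer MCNR scores are zero")
  structure(list(avg_mcnr = avg_mcnr,
                 mcnr_norm = avg_mcnr / mx,
                 percentile_a = a,
                 threshold = threshold),
            class = "slice_quality")
}

#' MCNR quality summary of a raw stack
#'
#' Computes the per-layer orientation-averaged MCNR scores for a whole stack
#' (or a lateral sub-window of it).
#'
#' @param stack a [raw_stack()]
#' @param a percentile constant for [slice_score()]
#' @param threshold modulation threshold `M_t`
#' @param bounds optional `(y0, y1, x0, x1)` 0-based half-open lateral window
#' @return a `slice_quality` object (plus `mean_maps`: per-layer averaged maps)
#' @export
stack_mcnr <- function(stack, a = 7, threshold = 0.85, bounds = NULL) {
  stopifnot(inherits(stack, "raw_stack"))
  ys <- if (is.null(bounds)) seq_len(stack$n) else (bounds[1] + 1):bounds[2]
  xs <- if (is.null(bounds)) seq_len(stack$n) else (bounds[3] + 1):bounds[4]
  scores <- numeric(stack$nz)
  maps <- vector("list", stack$nz)
  for (z in seq_len(stack$nz)) {
    per_or <- lapply(1:3, function(d) {
      mcnr_map(stack$data[d, , z, ys, xs, drop = TRUE])
    })
    maps[[z]] <- mcnr_orientation_mean(per_or)
    scores[z] <- slice_score(maps[[z]], a)
  }
  q <- normalize_scores(scores, a, threshold)
  q$mean_maps <- maps
  q
}

#' @export
print.slice_quality <- function(x, ...) {
  cat("per-layer MCNR quality (normalized, threshold ",
      x$threshold, "):\n", sep = "")
  cat(sprintf("  z%02d: %.3f%s\n", seq_along(x$mcnr_norm), x$mcnr_norm,
              ifelse(x$mcnr_norm > x$threshold, "  *direct*", "")), sep = "")
  invisible(x)
}
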