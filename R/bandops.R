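#' Separate the five frequency bands from phase-stepped images
#'
#' Each raw frame is a known mixture of the five band components,
#' `I_n(k) = sum_m C_m(k) exp(i m n dphi)` for `m = -2..2`; with five phase
#' steps the 5x5 mixing matrix is invertible and the bands are recovered by a
#' direct linear solve. Inputs may be spatial images (transformed here) or
#' pre-computed lateral spectra.
#'
#' @param phase_images `[5, y, x]` array (or list of 5 matrices) of one
#'   orientation/layer, or `[5, ky, kx]` complex spectra if `spectra = TRUE`
#' @param delta_phi nominal phase step (radians), default `2 pi / 5`
#' @param spectra set to TRUE if `phase_images` already holds lateral spectra
#' @return object of class `band_set`: list `bands` of complex spectra indexed
#'   by order `m = -2..2` (names "-2".."2", unshifted FFT layout) and `orders`
#' @export
separate_bands <- function(phase_images, delta_phi = 2 * pi / 5, spectra = FALSE) {
  if (is.list(phase_images)) {
    phase_images <- aperm(simplify2array(phase_images), c(3, 1, 2))
  }
  d <- dim(phase_images)
  if (length(d) != 3 || d[1] != 5) stop("exactly 5 phase images are required")
  orders <- -2:2
  mix <- outer(0:4, orders, function(n, m) exp(1i * m * n * delta_phi))
  if (min(svd(mix)$d) < 1e-8) stop("degenerate phase step: mixing matrix is singular")
  inv <- solve(mix)
  specs <- lapply(1:5, function(n) {
    s <- phase_images[n, , ]
    if (spectra) s else fft2(s + 0i)
  })
  bands <- lapply(seq_along(orders), function(j) {
    acc <- inv[j, 1] * specs[[1]]
    for (n in 2:5) acc <- acc + inv[j, n] * specs[[n]]
    acc
  })
  names(bands) <- as.character(orders)
  structure(list(bands = bands, orders = orders), class = "band_set")
}

#' Remix separated bands into phase-stepped spectra (inverse of separation)
#'
#' @param bandset a `band_set`
#' @param delta_phi nominal phase step
#' @return `[5, ky, kx]` complex array of remixed spectra
#' @export
remix_bands <- function(bandset, delta_phi = 2 * pi / 5) {
  orders <- bandset$orders
  dd <- dim(bandset$bands[[1]])
  out <- array(0i, c(5, dd))
  for (n in 0:4) {
    acc <- array(0i, dd)
    for (j in seq_along(orders)) {
      acc <- acc + bandset$bands[[j]] * exp(1i * orders[j] * n * delta_phi)
    }
    out[n + 1, , ] <- acc
  }
  out
}

#' Locate the integer-pixel spectral peak of a side band
#'
#' Finds the frequency bin with maximal modulus outside a DC exclusion
#' region. Ties are broken toward smaller radius, then lexicographically on
#' the signed bin pair.
#'
#' @param band complex lateral spectrum (unshifted layout)
#' @param exclude_radius DC exclusion radius as a fraction of Nyquist
#'   (default 0.2); bins with `|k| <= r * N/2` are ignored
#' @param near optional signed bin pair `(kx, ky)`: restrict the search to a
#'   window around this expected location. Used to localize the weakly
#'   transmitted second-harmonic peak near twice the first-harmonic one.
#' @param search_radius half-width (bins) of the restricted search window
#' @return integer length-2 signed bin vector `(kx, ky)` — note x first, to
#'   match wave-vector component order
#' @export
locate_integer_peak <- function(band, exclude_radius = 0.2,
                                near = NULL, search_radius = 3) {
  d <- dim(band)
  ky <- fft_bins(d[1]); kx <- fft_bins(d[2])
  r2 <- outer(ky^2, kx^2, `+`)
  rmin2 <- (exclude_radius * min(d) / 2)^2
  mag <- abs(band)
  mag[r2 <= rmin2] <- -Inf
  if (!is.null(near)) {
    circ_dist <- function(b, centre, n) abs((b - centre + n / 2) %% n - n / 2)
    iny <- circ_dist(ky, near[2], d[1]) <= search_radius
    inx <- circ_dist(kx, near[1], d[2]) <= search_radius
    mag[!outer(iny, inx)] <- -Inf
  }
  best <- max(mag)
  if (!is.finite(best) || best <= 0)
    stop("no spectral peak outside the DC exclusion region")
  cand <- which(mag >= best - 1e-300, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    key <- cbind(r2[cand], ky[cand[, 1]], kx[cand[, 2]])
    cand <- cand[order(key[, 1], key[, 2], key[, 3]), , drop = FALSE]
  }
  c(kx[cand[1, 2]], ky[cand[1, 1]])
}

#' Build the unit-modulus phasor field of a band
#'
#' Rolls the spectrum so the located integer peak sits at DC, inverse
#' transforms, and keeps only the per-pixel unit phasor. For an ideal single
#' harmonic the result is `exp(i (2 pi p_sub . r / N + phase0))`: a perfect
#' phase plane whose slope is the sub-pixel wave-vector residual.
#'
#' @param band complex lateral spectrum (unshifted layout) or a 3-D
#'   `[ky, kx, z]` stack of spectra sharing one peak
#' @param p_int integer signed bin vector `(kx, ky)` from
#'   [locate_integer_peak()]
#' @return object of class `phasor_field`: `values` (unit-modulus complex
#'   array, `[y, x]` or `[y, x, z]`), `p_int`
#' @export
build_phasor <- function(band, p_int) {
  d <- dim(band)
  if (max(abs(p_int)) > max(d) / 2) stop("integer peak outside the grid")
  sh <- if (length(d) == 2) c(-p_int[2], -p_int[1]) else c(-p_int[2], -p_int[1], 0)
  centred <- roll(band, sh)
  sp <- if (length(d) == 2) ifft2(centred) else ifft2(centred)
  mag <- abs(sp)
  ph <- sp
  nz <- mag > 0
  ph[nz] <- sp[nz] / mag[nz]
  ph[!nz] <- 1 + 0i
  structure(list(values = ph, p_int = as.integer(p_int)), class = "phasor_field")
}

#' Frequency-domain masking of a phasor field
#'
#' The spectrum of an ideal phasor is a sampled Dirichlet kernel whose energy
#' concentrates in a small window around its peak; zeroing everything outside
#' a `(2w+1)^2` window suppresses the broadband noise floor while keeping the
#' phase-plane information. Applied slice-wise for 3-D phasor tensors.
#'
#' By default the masked field keeps its smoothed magnitudes, which act as
#' SNR weights in the subsequent principal-component fit; with
#' `renormalize = TRUE` each pixel is rescaled to unit modulus (the ideal
#' phasor's form), which is equivalent on noise-free fields but re-amplifies
#' pure-noise pixels on low-signal tiles.
#'
#' @param phasor a `phasor_field`
#' @param half_width window half-width `w` in bins (default 7, a 15x15 window)
#' @param renormalize rescale every pixel to unit modulus after masking
#' @return a masked `phasor_field`
#' @export
mask_phasor <- function(phasor, half_width = 7, renormalize = FALSE) {
  stopifnot(inherits(phasor, "phasor_field"), half_width >= 1)
  v <- phasor$values
  d <- dim(v)
  if (half_width >= min(d[1], d[2]) / 2) {
    if (2 * half_width + 1 > min(d[1], d[2]))
      warning("mask window larger than grid; clipping to grid Nyquist")
    return(phasor)  # window covers everything: identity
  }
  arr3 <- length(d) == 3
  vv <- if (arr3) v else array(v, c(d, 1))
  spec <- fft2(vv)
  # common peak from the energy summed over slices (robust for thin tensors)
  pw <- abs(spec)^2
  psum <- if (dim(vv)[3] > 1) apply(pw, c(1, 2), sum) else pw[, , 1]
  pk <- which(psum == max(psum), arr.ind = TRUE)[1, ]
  ky <- fft_bins(d[1]); kx <- fft_bins(d[2])
  keep_y <- abs((fft_bins(d[1]) - ky[pk[1]] + d[1] / 2) %% d[1] - d[1] / 2) <= half_width
  keep_x <- abs((fft_bins(d[2]) - kx[pk[2]] + d[2] / 2) %% d[2] - d[2] / 2) <= half_width
  mask <- outer(keep_y, keep_x)
  spec <- spec * array(mask, dim(vv))
  out <- ifft2(spec)
  if (renormalize) {
    mag <- abs(out)
    nzm <- mag > 0
    out[nzm] <- out[nzm] / mag[nzm]
    out[!nzm] <- 1 + 0i
  }
  res <- phasor
  res$values <- if (arr3) out else out[, , 1]
  res$mask_window <- half_width
  res
}
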