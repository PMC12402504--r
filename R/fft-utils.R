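# Fourier conventions used throughout:
#  * spectra are stored in "unshifted" FFT layout (DC at index [1,1,...]),
#  * frequency bins are addressed by signed integers k in (-N/2, N/2],
#    where bin k lives at array index (k mod N) + 1,
#  * wave vectors are expressed in cycles/pixel; bin spacing is 1/N.

#' Signed frequency bins of an N-point DFT (unshifted layout)
#'
#' @param n grid length
#' @return integer vector of length `n`: 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1
#' @keywords internal
fft_bins <- function(n) {
  k <- 0:(n - 1)
  k - n * (k > n / 2)
}

#' Circularly shift an array by an integer offset per dimension
#'
#' Positive offsets move content toward higher indices (wrapping).
#'
#' @param x array
#' @param shift integer vector, one entry per dimension of `x`
#' @keywords internal
roll <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    s <- ((shift[1] %% n) + n) %% n
    if (s == 0) return(x)
    return(c(x[(n - s + 1):n], x[1:(n - s)]))
  }
  stopifnot(length(shift) == length(d))
  idx <- lapply(seq_along(d), function(i) {
    s <- ((shift[i] %% d[i]) + d[i]) %% d[i]
    if (s == 0) seq_len(d[i]) else c((d[i] - s + 1):d[i], seq_len(d[i] - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' fftshift / ifftshift for 2-D slices (dims 1 and 2 of an array)
#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  roll(x, c(floor(d[1] / 2), floor(d[2] / 2), rep(0L, length(d) - 2)))
}

#' @rdname fftshift2
#' @keywords internal
ifftshift2 <- function(x) {
  d <- dim(x)
  roll(x, c(ceiling(d[1] / 2), ceiling(d[2] / 2), rep(0L, length(d) - 2)))
}

# Batched 2-D FFT over dims (1,2) of a 2-D or 3-D array, via two mvfft passes.
# Much faster than slice-wise fft() loops for thin 3-D arrays.
#' @keywords internal
fft2 <- function(x, inverse = FALSE) {
  d <- dim(x)
  n1 <- d[1]; n2 <- d[2]; rest <- prod(d[-(1:2)])
  y <- stats::mvfft(matrix(x, n1, n2 * rest), inverse = inverse)
  dim(y) <- d
  y <- aperm(y, c(2, 1, seq_along(d)[-(1:2)]))
  y <- stats::mvfft(matrix(y, n2, n1 * rest), inverse = inverse)
  dim(y) <- d[c(2, 1, seq_along(d)[-(1:2)])]
  y <- aperm(y, c(2, 1, seq_along(d)[-(1:2)]))
  if (inverse) y / (n1 * n2) else y
}

#' @keywords internal
ifft2 <- function(x) fft2(x, inverse = TRUE)

# FFT along the third dimension of a 3-D array.
#' @keywords internal
fftz <- function(x, inverse = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  y <- aperm(x, c(3, 1, 2))
  y <- stats::mvfft(matrix(y, d[3], d[1] * d[2]), inverse = inverse)
  dim(y) <- c(d[3], d[1], d[2])
  y <- aperm(y, c(2, 3, 1))
  if (inverse) y / d[3] else y
}

#' @keywords internal
ifftz <- function(x) fftz(x, inverse = TRUE)

#' Full 3-D FFT (lateral batched + axial pass)
#' @keywords internal
fft3 <- function(x, inverse = FALSE) fftz(fft2(x, inverse = inverse), inverse = inverse)

#' @keywords internal
ifft3 <- function(x) fft3(x, inverse = TRUE)

# Embed an N x N (x Nz) unshifted lateral spectrum into the centre of a
# 2N x 2N (x Nz) grid (frequency-domain zero padding = 2x lateral upsampling).
# Values are scaled by 4 so that image-domain mean intensity is preserved.
#' @keywords internal
fourier_pad2 <- function(spec) {
  d <- dim(spec)
  n <- d[1]
  stopifnot(d[2] == n)
  nz <- if (length(d) == 3) d[3] else 1L
  out <- array(0i, c(2L * n, 2L * n, nz))
  s <- fftshift2(array(spec, c(n, n, nz)))
  out[(n / 2 + 1):(n / 2 + n), (n / 2 + 1):(n / 2 + n), ] <- s
  out <- ifftshift2(out) * 4
  if (length(d) == 2) out[, , 1] else out
}

# Inverse of fourier_pad2: centred lateral crop 2N -> N, scaled by 1/4 so the
# image-domain mean is preserved (proper band-limited downsampling).
#' @keywords internal
fourier_crop2 <- function(spec) {
  d <- dim(spec)
  n2 <- d[1]
  stopifnot(d[2] == n2, n2 %% 2 == 0)
  n <- n2 / 2L
  nz <- if (length(d) == 3) d[3] else 1L
  s <- fftshift2(array(spec, c(n2, n2, nz)))
  out <- s[(n / 2 + 1):(n / 2 + n), (n / 2 + 1):(n / 2 + n), , drop = FALSE]
  out <- ifftshift2(out) / 4
  if (length(d) == 2) out[, , 1] else out
}

# 1-D phase unwrap (radians): removes 2*pi jumps sequentially.
#' @keywords internal
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  phi + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

# Map an angle to (-pi, pi].
#' @keywords internal
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
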