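#' Structural similarity index (SSIM) between two images
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5) and
#' the usual stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. For 3-D
#' inputs (`[z, y, x]`) the per-layer mean SSIM is returned.
#'
#' @param x,y real matrices or `[z, y, x]` arrays of identical shape
#' @param dynamic_range data range `L`; defaults to the range of `x`
#' @return scalar mean SSIM
#' @export
ssim <- function(x, y, dynamic_range = NULL) {
  if (!identical(dim(x), dim(y))) stop("images have different shapes")
  if (length(dim(x)) == 3) {
    L <- if (is.null(dynamic_range)) diff(range(x)) else dynamic_range
    return(mean(vapply(seq_len(dim(x)[1]), function(z) {
      ssim(x[z, , ], y[z, , ], dynamic_range = L)
    }, 0)))
  }
  L <- if (is.null(dynamic_range)) diff(range(x)) else dynamic_range
  if (L <= 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- stats::dnorm(-5:5, sd = 1.5)
  g <- g / sum(g)
  blur <- function(m) {
    # separable Gaussian filtering via row/col convolution (replicated edges)
    pad <- 5
    mp <- m[c(rep(1, pad), 1:nrow(m), rep(nrow(m), pad)),
            c(rep(1, pad), 1:ncol(m), rep(ncol(m), pad))]
    mp <- apply(mp, 2, function(col) stats::filter(col, g, sides = 2))
    mp <- t(apply(mp, 1, function(row) stats::filter(row, g, sides = 2)))
    mp[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))]
  }
  mx <- blur(x); my <- blur(y)
  sxx <- blur(x * x) - mx^2
  syy <- blur(y * y) - my^2
  sxy <- blur(x * y) - mx * my
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
       ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}

#' Peak signal-to-noise ratio
#'
#' @param x reference image/volume
#' @param y test image/volume, same shape
#' @param peak reference peak value; defaults to `max(x)`
#' @return PSNR in dB
#' @export
psnr <- function(x, y, peak = max(x)) {
  if (!identical(dim(x), dim(y))) stop("images have different shapes")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
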