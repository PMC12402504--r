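# shared fixtures and independent oracles for the test suite

tiny_cfg <- function() sim_config()

# closed-form planar phasor matrix exp(i(2 pi (px x + py y)/n + c))
planar_phasor <- function(n, p_bins, const = 0) {
  x <- 0:(n - 1)
  outer(exp(2i * pi * p_bins[2] * x / n), exp(2i * pi * p_bins[1] * x / n)) *
    exp(1i * const)
}

# rank-one 3-D phasor tensor with optional per-layer phase jitter
planar_phasor_tensor <- function(n, nz, p_bins, const = 0, z_jitter = rep(0, nz)) {
  arr <- array(0i, c(n, n, nz))
  base <- planar_phasor(n, p_bins, const)
  for (z in seq_len(nz)) arr[, , z] <- base * exp(1i * z_jitter[z])
  arr
}

as_phasor_field <- function(values, p_int = c(0L, 0L)) {
  structure(list(values = values, p_int = as.integer(p_int)),
            class = "phasor_field")
}

# least-squares oracle for the five-point cosine model
# N(n) = A0 + A1 cos(2 pi n/5 + a1) + A2 cos(4 pi n/5 + a2), n = 0..4
mcnr_ls_oracle <- function(nvec) {
  n <- 0:4
  X <- cbind(1, cos(2 * pi * n / 5), sin(2 * pi * n / 5),
             cos(4 * pi * n / 5), sin(4 * pi * n / 5))
  beta <- solve(crossprod(X), crossprod(X, nvec))
  a0 <- abs(beta[1])
  a1 <- sqrt(beta[2]^2 + beta[3]^2)
  a2 <- sqrt(beta[4]^2 + beta[5]^2)
  if (a0 == 0) 0 else 2 * sqrt(a1^2 + a2^2) / a0
}

# sort-based percentile oracle (linear interpolation between order stats)
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# least-squares plane fit residual of a phasor's phase: rows are unwrapped
# along x, then row offsets are unwrapped along y so the whole surface is
# continuous before the plane fit
plane_fit_residual <- function(phasor_values) {
  ph <- Arg(phasor_values)
  phu <- t(apply(ph, 1, sim3dr:::unwrap_phase))
  col1 <- sim3dr:::unwrap_phase(phu[, 1])
  phu <- phu + (col1 - phu[, 1])
  x <- as.vector(col(ph)) - 1
  y <- as.vector(row(ph)) - 1
  fit <- stats::lm(as.vector(phu) ~ x + y)
  sqrt(mean(stats::resid(fit)^2))
}

# small default simulation shared by the heavier tests (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_sim3d(n = 128, nz = 8, cfg = tiny_cfg(), seed = 3)
    }
    cache
  }
})

# angular difference in degrees, wrapped to [0, 180)
ang_err_deg <- function(a, b) {
  abs((a - b + pi) %% (2 * pi) - pi) * 180 / pi
}
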