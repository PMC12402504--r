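# First principal pair of a complex matrix via the Hermitian cross-product:
# cheaper than a full SVD for the wide unfoldings used here, and only the
# dominant singular triplet is ever needed.
principal_pair <- function(A) {
  G <- A %*% Conj(t(A))
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(Re(e$values), 0)
  u <- e$vectors[, 1]
  s1 <- sqrt(ev[1])
  s2 <- if (length(ev) > 1) sqrt(ev[2]) else 0
  vh <- if (s1 > 0) (Conj(u) %*% A) / s1 else matrix(0i, 1, ncol(A))  # v^H row
  list(u = u, vh = as.vector(vh), s1 = s1, s2 = s2)
}

# phase slope (radians/sample) of a near-exponential vector.
# Default "hybrid": the argument of the lag-1 autocorrelation gives a
# wrap-proof initial slope (exact for a clean exponential, immune to the
# catastrophic 2*pi failures of sequential unwrapping on noisy vectors);
# the vector is then demodulated by it and the slowly varying residual
# phase is unwrapped and fitted by weighted least squares for precision.
# method = "unwrap" is the plain sequential-unwrap + regression variant.
phase_slope <- function(vec, weighted = TRUE,
                        method = c("hybrid", "unwrap")) {
  method <- match.arg(method)
  n <- length(vec)
  s0 <- 0
  if (method == "hybrid") {
    s0 <- Arg(sum(Conj(vec[-n]) * vec[-1]))
    vec <- vec * exp(-1i * s0 * (seq_len(n) - 1))
  }
  ph <- unwrap_phase(Arg(vec))
  w <- if (weighted) abs(vec) else rep(1, n)
  x <- seq_len(n) - 1
  wm <- sum(w)
  xb <- sum(w * x) / wm
  yb <- sum(w * ph) / wm
  s0 + sum(w * (x - xb) * (ph - yb)) / sum(w * (x - xb)^2)
}

#' Sub-pixel wave vector and initial phase from a 2-D phasor matrix
#'
#' The ideal phasor matrix of the second-harmonic band factorizes as a
#' rank-one outer product of two complex exponentials; the slopes of the
#' unwrapped phases of the first left/right singular vectors give the
#' sub-pixel residual of the band wave vector, and the phase of the rank-one
#' reconstruction at the tile origin carries twice the initial phase. This
#' routine folds in the halving in exactly one place: it reports the
#' illumination first-harmonic wave vector `p_lateral = (p_int + p_sub) / 2`
#' and `phi0 = phase(origin) / 2` for a second-harmonic input
#' (`harmonic = 2`), or the unhalved values for a first-harmonic input.
#'
#' `phi0` from the second harmonic is only determined modulo pi; see
#' [resolve_phi0_ambiguity()].
#'
#' @param phasor a 2-D `phasor_field` (typically masked)
#' @param p_int integer peak `(kx, ky)` carried by the phasor
#' @param harmonic which illumination harmonic the band represents (2 for the
#'   +/-2-order band, 1 for the +/-1-order band)
#' @param weighted magnitude-weight the phase regression (default TRUE)
#' @param quality_floor flag the estimate when `sigma1/sigma2` falls below
#'   this ratio (default 3)
#' @return object of class `param_estimate`: `p_lateral` (cycles/pixel),
#'   `p_sub` (sub-pixel bin residual of the band vector, `(x, y)`), `phi0`
#'   (radians, in (-pi, pi]), `quality` (sigma1/sigma2), `low_confidence`,
#'   `source`
#' @export
estimate_2d <- function(phasor, p_int = phasor$p_int, harmonic = 2,
                        weighted = TRUE, quality_floor = 3) {
  stopifnot(inherits(phasor, "phasor_field"))
  v <- phasor$values
  stopifnot(length(dim(v)) == 2)
  ny <- nrow(v); nx <- ncol(v)
  pp <- principal_pair(v)                  # v[y, x]: u over y, vh over x
  # A[y,x] ~ u[y] * vh[x]; phase of u rises with y at 2*pi*py_sub/ny,
  # phase of vh rises with x at 2*pi*px_sub/nx
  sy <- phase_slope(pp$u, weighted)
  sx <- phase_slope(pp$vh, weighted)
  py_sub <- sy * ny / (2 * pi)
  px_sub <- sx * nx / (2 * pi)
  # origin phase by matched filtering the rank-one factors with the fitted
  # plane: more robust than reading the (noisy) first entries directly
  origin_phase <- Arg(sum(pp$u * exp(-1i * sy * (0:(ny - 1)))) *
                      sum(pp$vh * exp(-1i * sx * (0:(nx - 1)))))
  quality <- if (pp$s2 > 0) pp$s1 / pp$s2 else Inf
  p_band <- c(p_int[1] + px_sub, p_int[2] + py_sub)   # bins of the analysis grid
  p_lat <- p_band / c(nx, ny) / harmonic              # cycles/pixel, first harmonic
  structure(list(p_lateral = p_lat,
                 p_band_bins = p_band,
                 p_sub = c(px_sub, py_sub),
                 phi0 = wrap_pi(origin_phase / harmonic),
                 quality = quality,
                 low_confidence = quality < quality_floor,
                 grid = c(nx, ny),
                 harmonic = harmonic,
                 source = "tile"),
            class = "param_estimate")
}

#' Wave vector and phase from a 3-D phasor tensor by HOSVD
#'
#' The ideal phasor tensor is Tucker-rank-one in every mode; the first
#' singular vectors of the x-mode and y-mode unfoldings are complex
#' exponentials whose phase slopes give the two lateral sub-pixel components,
#' while constant per-layer phases live entirely in the (y,z)/(x,z) factors.
#' The initial phase is read from the rank-one reconstruction at the origin
#' of the first layer.
#'
#' @param phasor a 3-D `phasor_field` (`values[y, x, z]`)
#' @inheritParams estimate_2d
#' @return a `param_estimate` with `source = "volume-hosvd"`
#' @export
estimate_3d_hosvd <- function(phasor, p_int = phasor$p_int, harmonic = 2,
                              weighted = TRUE, quality_floor = 3) {
  stopifnot(inherits(phasor, "phasor_field"))
  v <- phasor$values
  d <- dim(v)
  stopifnot(length(d) == 3)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  unf_y <- matrix(v, ny, nx * nz)                       # y-mode unfolding
  unf_x <- matrix(aperm(v, c(2, 1, 3)), nx, ny * nz)    # x-mode unfolding
  py_pp <- principal_pair(unf_y)
  px_pp <- principal_pair(unf_x)
  sy <- phase_slope(py_pp$u, weighted)
  sx <- phase_slope(px_pp$u, weighted)
  py_sub <- sy * ny / (2 * pi)
  px_sub <- sx * nx / (2 * pi)
  # origin phase by matched filtering the y-mode rank-one factors; the
  # (x,z)-factor is demodulated with the x-slope replicated over layers
  xz_ramp <- rep(exp(-1i * sx * (0:(nx - 1))), nz)
  origin_phase <- Arg(sum(py_pp$u * exp(-1i * sy * (0:(ny - 1)))) *
                      sum(py_pp$vh * xz_ramp))
  quality <- min(if (py_pp$s2 > 0) py_pp$s1 / py_pp$s2 else Inf,
                 if (px_pp$s2 > 0) px_pp$s1 / px_pp$s2 else Inf)
  p_band <- c(p_int[1] + px_sub, p_int[2] + py_sub)
  p_lat <- p_band / c(nx, ny) / harmonic
  structure(list(p_lateral = p_lat,
                 p_band_bins = p_band,
                 p_sub = c(px_sub, py_sub),
                 phi0 = wrap_pi(origin_phase / harmonic),
                 quality = quality,
                 low_confidence = quality < quality_floor,
                 grid = c(nx, ny),
                 harmonic = harmonic,
                 source = "volume-hosvd"),
            class = "param_estimate")
}

#' @export
print.param_estimate <- function(x, ...) {
  cat(sprintf("p = (%.5f, %.5f) cyc/px, phi0 = %.4f rad, quality %.3g (%s)%s\n",
              x$p_lateral[1], x$p_lateral[2], x$phi0, x$quality, x$source,
              if (isTRUE(x$low_confidence)) "  [low confidence]" else ""))
  invisible(x)
}

#' Resolve the pi ambiguity of a second-harmonic phase estimate
#'
#' The second-harmonic band carries `2 phi0`, so `phi0` is known only modulo
#' pi. Given an independent (coarser) first-harmonic phase reading, pick the
#' candidate `phi0` or `phi0 +/- pi` circularly closest to it.
#'
#' @param phi0_2 phase from the second-harmonic band (radians)
#' @param phi0_1 phase from the first-harmonic band (radians)
#' @return resolved phase in (-pi, pi]
#' @export
resolve_phi0_ambiguity <- function(phi0_2, phi0_1) {
  cands <- wrap_pi(c(phi0_2, phi0_2 + pi))
  d <- abs(wrap_pi(cands - phi0_1))
  cands[which.min(d)]
}

#' Axial wave vector from the beam geometry
#'
#' For three-beam interference the axial modulation frequency follows from
#' the angle `beta` between the centre and side beams:
#' `p_z / p_lateral = (1 - cos beta) / sin beta = tan(beta / 2)`.
#'
#' @param p_lateral_mag magnitude of the lateral first-harmonic wave vector
#'   in cycles/pixel (on the raw grid)
#' @param cfg a [sim_config()]; `cfg$beam_angle_beta` supplies beta
#' @param beta optional override of the beam half-angle (radians, in
#'   (0, pi/2]); when beta is not known it can be derived from the measured
#'   pattern frequency as `asin(lambda_exc * f / n_imm)`
#' @return axial wave vector in cycles per z-step
#' @export
axial_wavevector <- function(p_lateral_mag, cfg, beta = cfg$beam_angle_beta) {
  if (!(beta > 0 && beta <= pi / 2)) stop("beam angle beta out of range (0, pi/2]")
  p_nm <- p_lateral_mag / cfg$pixel_size_nm       # cycles/nm
  pz_nm <- p_nm * (1 - cos(beta)) / sin(beta)
  pz_nm * cfg$z_step_nm                           # cycles per z-step
}

#' Beam half-angle implied by a measured pattern frequency
#'
#' @param p_lateral_mag lateral wave-vector magnitude (cycles/pixel)
#' @param cfg a [sim_config()]
#' @return beta (radians)
#' @export
beta_from_wavevector <- function(p_lateral_mag, cfg) {
  s <- cfg$wavelength_exc_nm * p_lateral_mag / cfg$pixel_size_nm / cfg$n_imm
  if (s <= 0 || s >= 1) stop("measured wave vector incompatible with beam geometry")
  asin(s)
}

#' Orientation-prior anomaly check of a parameter triple
#'
#' The three pattern wave vectors should be numerically close in magnitude
#' and 120 degrees apart in direction. `sd_wv` is the population standard
#' deviation of the three magnitudes (in frequency bins of the analysis
#' window); `sd_ang` the population SD of the pairwise angular deviations
#' from 120 degrees. A triple is anomalous when `sd_wv > 0.5` or
#' `sd_ang > 5`.
#'
#' Estimated wave vectors carry a sign ambiguity (either of the conjugate
#' side-band peaks may be picked); directions are therefore canonicalized by
#' trying both signs of the second and third vector and keeping the
#' assignment with the smallest deviation spread.
#'
#' @param p_list list of 3 wave vectors, either in cycles/pixel with
#'   `grid_n` given (converted to bins) or already in bins
#' @param grid_n analysis window size used to convert cycles/pixel to bins;
#'   set to 1 if `p_list` is already in bins
#' @param sd_wv_max,sd_ang_max anomaly thresholds (0.5 bins, 5 degrees)
#' @return object of class `orientation_check`: `sd_wv`, `sd_ang`, `anomalous`
#' @export
check_orientation_set <- function(p_list, grid_n = 1,
                                  sd_wv_max = 0.5, sd_ang_max = 5) {
  stopifnot(length(p_list) == 3)
  pb <- lapply(p_list, function(p) p * grid_n)
  mags <- vapply(pb, function(p) sqrt(sum(p^2)), 0)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_wv <- pop_sd(mags)
  angs <- vapply(pb, function(p) atan2(p[2], p[1]) * 180 / pi, 0)
  dev_for <- function(a) {
    pd <- c(a[2] - a[1], a[3] - a[2], a[1] - a[3])
    pd <- abs(((pd + 180) %% 360) - 180)   # pairwise separation in [0, 180]
    pd - 120
  }
  best <- NULL
  for (s2 in c(0, 180)) for (s3 in c(0, 180)) {
    dev <- dev_for(c(angs[1], angs[2] + s2, angs[3] + s3))
    if (is.null(best) || pop_sd(dev) < pop_sd(best)) best <- dev
  }
  sd_ang <- pop_sd(best)
  structure(list(sd_wv = sd_wv, sd_ang = sd_ang,
                 anomalous = (sd_wv > sd_wv_max) || (sd_ang > sd_ang_max)),
            class = "orientation_check")
}

#' @export
print.orientation_check <- function(x, ...) {
  cat(sprintf("orientation prior: sd_wv = %.3f bins, sd_ang = %.2f deg -> %s\n",
              x$sd_wv, x$sd_ang, if (x$anomalous) "ANOMALOUS" else "ok"))
  invisible(x)
}

#' Full PCA parameter estimate for one orientation from one lateral slice
#'
#' Chains the per-slice estimation steps: band separation (unless a
#' `band_set` is supplied), integer localization of the strongly transmitted
#' first-harmonic peak, a restricted search for the second-harmonic peak near
#' twice that location, phasor construction, frequency-domain masking, SVD
#' phase-slope regression on the second-harmonic phasor (which carries twice
#' the wave vector and phase, maximizing slope leverage), and resolution of
#' the resulting pi phase ambiguity against the first-harmonic phasor.
#'
#' @param x either a `[5, y, x]` array of phase images or a `band_set`
#' @param mask_half_width mask window half-width (bins), see [mask_phasor()]
#' @param near_p1 optional expected first-harmonic peak `(kx, ky)` in bins of
#'   this grid (e.g. from a full-field estimate when analysing small tiles)
#' @param search_radius restricted-search half-width used with `near_p1`
#' @param exclude_radius DC exclusion for the unrestricted peak search
#' @param weighted,quality_floor passed to [estimate_2d()]
#' @return a `param_estimate` (first-harmonic `p_lateral` in cycles/pixel,
#'   disambiguated `phi0`), with the first-harmonic estimate in `$band1`
#' @export
estimate_slice_params <- function(x, mask_half_width = 7,
                                  near_p1 = NULL, search_radius = 3,
                                  exclude_radius = 0.2,
                                  weighted = TRUE, quality_floor = 3) {
  bs <- if (inherits(x, "band_set")) x else separate_bands(x)
  n_grid <- dim(bs$bands[["1"]])
  pk1 <- locate_integer_peak(bs$bands[["1"]], exclude_radius,
                             near = near_p1, search_radius = search_radius)
  ph1 <- mask_phasor(build_phasor(bs$bands[["1"]], pk1), mask_half_width)
  est1 <- estimate_2d(ph1, pk1, harmonic = 1,
                      weighted = weighted, quality_floor = quality_floor)
  near2 <- round(2 * est1$p_band_bins)
  near2 <- pmax(pmin(near2, floor(n_grid / 2) - 1), -(floor(n_grid / 2) - 1))
  pk2 <- tryCatch(
    locate_integer_peak(bs$bands[["2"]], exclude_radius,
                        near = near2, search_radius = 2),
    error = function(e) near2)   # degenerate window: fall back to the prior
  ph2 <- mask_phasor(build_phasor(bs$bands[["2"]], pk2), mask_half_width)
  est <- estimate_2d(ph2, pk2, harmonic = 2,
                     weighted = weighted, quality_floor = quality_floor)
  est$phi0 <- resolve_phi0_ambiguity(est$phi0, est1$phi0)
  est$band1 <- est1
  est
}

#' Whole-volume parameter estimate for one orientation by HOSVD
#'
#' Assembles the second-harmonic band spectra of every layer into a phasor
#' tensor and extracts the single principal component of its mode unfoldings.
#' Layer spectra are stacked as supplied (use in-focus layers, or all).
#'
#' @param band_stacks list with elements `b1`, `b2`: complex `[ky, kx, z]`
#'   arrays of first/second-harmonic band spectra per layer
#' @param focus_layer layer index used to disambiguate `phi0` from the
#'   first-harmonic band. Away from focus the axial envelope of the
#'   first-harmonic band can be negative (a pi flip), so the in-focus layer
#'   (e.g. the MCNR-best one) must be used; defaults to the layer with the
#'   strongest first-harmonic peak.
#' @inheritParams estimate_slice_params
#' @return a `param_estimate` with `source = "volume-hosvd"`
#' @export
estimate_volume_params <- function(band_stacks, mask_half_width = 7,
                                   near_p1 = NULL, search_radius = 3,
                                   exclude_radius = 0.2, focus_layer = NULL,
                                   weighted = TRUE, quality_floor = 3) {
  b1 <- band_stacks$b1; b2 <- band_stacks$b2
  sum1 <- apply(abs(b1), c(1, 2), sum)
  pk1 <- locate_integer_peak(sum1, exclude_radius,
                             near = near_p1, search_radius = search_radius)
  ph1 <- mask_phasor(build_phasor(b1, pk1), mask_half_width)
  est1 <- estimate_3d_hosvd(ph1, pk1, harmonic = 1,
                            weighted = weighted, quality_floor = quality_floor)
  sum2 <- apply(abs(b2), c(1, 2), sum)
  pk2 <- locate_integer_peak(sum2, exclude_radius,
                             near = round(2 * est1$p_band_bins), search_radius = 2)
  ph2 <- mask_phasor(build_phasor(b2, pk2), mask_half_width)
  est <- estimate_3d_hosvd(ph2, pk2, harmonic = 2,
                           weighted = weighted, quality_floor = quality_floor)
  if (is.null(focus_layer)) {
    iy <- (pk1[2] %% dim(b1)[1]) + 1L
    ix <- (pk1[1] %% dim(b1)[2]) + 1L
    focus_layer <- which.max(abs(b1[iy, ix, ]))
  }
  ph1f <- mask_phasor(build_phasor(b1[, , focus_layer], pk1), mask_half_width)
  est1f <- estimate_2d(ph1f, pk1, harmonic = 1,
                       weighted = weighted, quality_floor = quality_floor)
  est$phi0 <- resolve_phi0_ambiguity(est$phi0, est1f$phi0)
  est$band1 <- est1
  est$focus_layer <- focus_layer
  est
}

#' Relative modulation depths from overlapping band spectra
#'
#' After the side bands have been shifted to a common origin, the m-order
#' band and the 0-order band observe the same object spectrum through
#' different OTFs; over the region where both OTFs carry signal the complex
#' gain of band m relative to band 0 is estimated by least squares:
#' `g_m = sum(conj(B0 O_m) B_m O0) / sum(|B0 O_m|^2)`. Magnitudes are the
#' relative modulation depths `a_m / a_0`; the residual phase is returned for
#' use as a per-band phase correction during recombination.
#'
#' @param band_m,band_0 centred complex spectra of band m and band 0 (same
#'   grid, any dimensionality)
#' @param otf_m,otf_0 matching real OTF arrays for the two bands
#' @param otf_floor both OTFs must exceed this fraction of their maximum for
#'   a frequency to enter the fit (default 0.1)
#' @param min_overlap minimum number of usable frequencies; below it the
#'   routine warns and returns the fallback
#' @param fallback complex gain returned when the overlap is too small
#' @return list `gain` (complex), `a_rel` (its modulus), `phase` (its
#'   argument), `n_overlap`
#' @export
estimate_modulation_depth <- function(band_m, band_0, otf_m, otf_0,
                                      otf_floor = 0.1, min_overlap = 50,
                                      fallback = 0.5 + 0i) {
  w <- (otf_m > otf_floor * max(otf_m)) & (otf_0 > otf_floor * max(otf_0))
  n_overlap <- sum(w)
  if (n_overlap < min_overlap) {
    warning("OTF overlap region too small; falling back to default modulation depth")
    return(list(gain = fallback, a_rel = Mod(fallback), phase = Arg(fallback),
                n_overlap = n_overlap))
  }
  x <- band_0[w] * otf_m[w]
  y <- band_m[w] * otf_0[w]
  g <- sum(Conj(x) * y) / sum(Mod(x)^2)
  # trimmed refits: windowing leakage of the incommensurate pattern carrier
  # (and any interference) shows up as gross outliers in the per-bin ratios
  for (it in 1:2) {
    r <- Mod(y - g * x)
    keep <- r <= stats::quantile(r, 0.9)
    g <- sum(Conj(x[keep]) * y[keep]) / sum(Mod(x[keep])^2)
  }
  list(gain = g, a_rel = Mod(g), phase = Arg(g), n_overlap = n_overlap)
}
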