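#' Spatial distortion description for the simulator
#'
#' Describes how the illumination deviates from an ideal uniform pattern:
#' a lateral wave-vector perturbation that grows linearly across the field
#' along one axis, a per-layer axial displacement sequence applied as lateral
#' pattern jitter, and additive Gaussian noise.
#'
#' @param wv_error_px length-2 numeric `(min, max)`: wave-vector error in
#'   frequency bins of the full-field DFT ("pixels"), ramped linearly across
#'   the field along `axis`. `c(0, 0)` disables the perturbation.
#' @param axis `"x"` or `"y"`: axis along which the wave-vector error ramps
#' @param z_displacement_nm numeric vector (recycled/ramped to `nz` at use
#'   time) of per-layer stage displacement errors in nm, applied as lateral
#'   phase jitter of the pattern; length-2 input is interpreted as the
#'   `(min, max)` of a linear ramp over layers
#' @param noise_power_dbw additive Gaussian noise power in dBW on the
#'   simulated count scale (variance `10^(dbw/10)` counts^2, with the
#'   noiseless stack normalized to a mean of 100 counts); `-Inf` disables
#'   noise
#' @param seed RNG seed used for the noise draw
#' @return an object of class `distortion_field`
#' @export
distortion_field <- function(wv_error_px = c(0, 0),
                             axis = c("x", "y"),
                             z_displacement_nm = c(0, 0),
                             noise_power_dbw = -Inf,
                             seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(length(wv_error_px) == 2, is.numeric(z_displacement_nm))
  structure(list(wv_error_px = as.numeric(wv_error_px),
                 axis = axis,
                 z_displacement_nm = as.numeric(z_displacement_nm),
                 noise_power_dbw = noise_power_dbw,
                 seed = as.integer(seed)),
            class = "distortion_field")
}

# per-layer displacement sequence (nm) for nz layers
z_displacements <- function(distortion, nz) {
  zd <- distortion$z_displacement_nm
  if (length(zd) == 2 && nz > 1) seq(zd[1], zd[2], length.out = nz)
  else rep_len(zd, nz)
}

# wave-vector error profile (bins of the n-point full-field DFT) at lateral
# coordinates u (raw-pixel units along the distortion axis)
wv_error_profile <- function(distortion, u, n) {
  e <- distortion$wv_error_px
  if (n > 1) e[1] + (e[2] - e[1]) * u / (n - 1) else rep(mean(e), length(u))
}

#' True tile-averaged wave vector under a distortion field
#'
#' Mean local first-harmonic wave vector (cycles/pixel) of the distorted
#' pattern over a lateral window, used as ground truth when validating the
#' tiled estimator.
#'
#' @param params [illum_params()] of the undistorted pattern
#' @param distortion a [distortion_field()]
#' @param n full-field side length (raw pixels)
#' @param bounds length-4 integer `(y0, y1, x0, x1)`, 0-based half-open
#'   half-open pixel window; defaults to the full field
#' @return length-2 numeric wave vector (cycles/pixel)
#' @export
local_wavevector <- function(params, distortion, n, bounds = c(0, n, 0, n)) {
  u <- if (distortion$axis == "x") seq(bounds[3], bounds[4] - 1)
       else seq(bounds[1], bounds[2] - 1)
  dp <- mean(wv_error_profile(distortion, u, n)) / n   # bins -> cycles/pixel
  p <- params$p_lateral
  if (distortion$axis == "x") p + c(dp, 0) else p + c(0, dp)
}

# Lateral phase field (radians) of the illumination first harmonic over an
# n x n raw-pixel grid sampled at `step` pixel spacing (step = 0.5 for the
# fine simulation grid), including the wave-vector distortion.
lateral_phase_field <- function(params, distortion, n, step) {
  m <- round(n / step)
  u <- (seq_len(m) - 1) * step                     # raw-pixel coordinates
  p <- params$p_lateral
  base_x <- 2 * pi * p[1] * u
  base_y <- 2 * pi * p[2] * u
  dp <- wv_error_profile(distortion, u, n) / n     # cycles/pixel perturbation
  # integrate the local wave-vector offset along the ramp axis
  dphi <- 2 * pi * (cumsum(dp) - dp[1]) * step
  if (distortion$axis == "x") {
    outer(base_y, base_x + dphi, `+`)              # [y, x]
  } else {
    outer(base_y + dphi, base_x, `+`)
  }
}

#' Generate a three-beam interference illumination stack
#'
#' Intensity of the interference of one centre beam (amplitude `E0`) and two
#' side beams (amplitude `E1` each):
#' `I = a0 + 2 a1 cos(theta) cos(2 pi p_z (z - z_focus)) + a2 cos(2 theta)`
#' with `theta = 2 pi p.r + phi0 + n * 2 pi / 5`, `a0 = E0^2 + 2 E1^2`,
#' `a1 = 2 E0 E1`, `a2 = 2 E1^2`; non-negativity is automatic because the
#' intensity is a squared field modulus. Phase steps are the nominal
#' `2 pi / 5`. The wave vector and per-layer jitter are perturbed per the
#' distortion field.
#'
#' @param params_list list of 3 [illum_params()], one per orientation (each
#'   must carry a finite `p_z`)
#' @param distortion a [distortion_field()]
#' @param n full-field side length in raw pixels
#' @param nz number of layers
#' @param cfg a [sim_config()] (pixel size converts nm displacements to phase)
#' @param step lateral sampling in raw-pixel units (0.5 = the 2x fine grid)
#' @param z_focus layer index (1-based, may be fractional) where the axial
#'   envelope peaks; defaults to the stack centre
#' @return 5-D array `[orientation, phase, z, y, x]` of illumination intensity
#' @export
make_illumination <- function(params_list, distortion, n, nz, cfg,
                              step = 1, z_focus = (nz + 1) / 2) {
  stopifnot(length(params_list) == 3)
  m <- round(n / step)
  out <- array(0, c(3, 5, nz, m, m))
  zd <- z_displacements(distortion, nz)
  for (d in 1:3) {
    pr <- params_list[[d]]
    if (!is.finite(pr$p_z)) stop("params for orientation ", d, " lack p_z")
    a0 <- pr$a[1]; a1 <- pr$a[2]; a2 <- pr$a[3]
    if (a0 + a2 < 2 * a1)   # |E0 - ...|^2 >= 0 always holds for field-derived depths
      stop("modulation depths would make the interference intensity negative")
    phase_xy <- lateral_phase_field(pr, distortion, n, step)
    pmag <- sqrt(sum(pr$p_lateral^2))
    jitter <- 2 * pi * zd * pmag / cfg$pixel_size_nm
    for (z in seq_len(nz)) {
      axial <- cos(2 * pi * pr$p_z * (z - z_focus))
      for (ph in 1:5) {
        theta <- phase_xy + pr$phi0 + (ph - 1) * 2 * pi / 5 + jitter[z]
        out[d, ph, z, , ] <- a0 + 2 * a1 * cos(theta) * axial + a2 * cos(2 * theta)
      }
    }
  }
  out
}

#' Procedural ground-truth volumes
#'
#' Generates a non-negative ground-truth volume on the 2x-upsampled lateral
#' grid. Structures are confined to a central axial slab so that defocused
#' layers genuinely carry less in-focus signal.
#'
#' @param kind `"beads"` (random diffraction-limited-scale spots),
#'   `"point-pairs"` (axis-aligned pairs at a fixed separation), or
#'   `"filaments"` (smooth random-walk curves)
#' @param n raw-pixel side length (volume is `2n x 2n` laterally)
#' @param nz number of layers
#' @param seed RNG seed
#' @param density structures per 1000 SR pixels of one layer (beads/filaments)
#' @param pair_sep_px separation of point pairs in SR pixels
#' @param z_frac fraction of layers (centred) that carry structure
#' @param background diffuse fluorescence level added to every structured
#'   layer (fraction of the unit structure amplitude). Real specimens carry
#'   out-of-focus haze and unbound fluorophores; this low-frequency mass is
#'   also what lets spectral-peak parameter estimators see the pattern
#'   carrier, so `background = 0` makes an adversarial, purely sparse object.
#' @return `[z, y, x]` array, `nz x 2n x 2n`, non-negative
#' @export
ground_truth <- function(kind = c("beads", "point-pairs", "filaments"),
                         n, nz, seed = 1L, density = 0.3,
                         pair_sep_px = 4, z_frac = 0.5, background = 0.3) {
  kind <- match.arg(kind)
  set.seed(seed)
  m <- 2L * n
  vol <- array(0, c(nz, m, m))
  zlo <- max(1L, floor((nz + 1) / 2 - z_frac * nz / 2))
  zhi <- min(nz, ceiling((nz + 1) / 2 + z_frac * nz / 2))
  zset <- zlo:zhi
  sigma <- 1.2   # SR pixels; slightly sub-diffraction marks
  spot <- function(cy, cx) {
    yy <- pmax(1, cy - 4):pmin(m, cy + 4)
    xx <- pmax(1, cx - 4):pmin(m, cx + 4)
    outer(exp(-(yy - cy)^2 / (2 * sigma^2)), exp(-(xx - cx)^2 / (2 * sigma^2)))
  }
  add_spot <- function(z, cy, cx, amp = 1) {
    yy <- pmax(1, cy - 4):pmin(m, cy + 4)
    xx <- pmax(1, cx - 4):pmin(m, cx + 4)
    vol[z, yy, xx] <<- vol[z, yy, xx] + amp * spot(cy, cx)
  }
  if (kind == "beads") {
    nb <- max(8, round(density * m * m / 1000))
    for (z in zset) {
      cy <- sample(5:(m - 5), nb, replace = TRUE)
      cx <- sample(5:(m - 5), nb, replace = TRUE)
      amp <- stats::runif(nb, 0.5, 1)
      for (i in seq_len(nb)) add_spot(z, cy[i], cx[i], amp[i])
    }
  } else if (kind == "point-pairs") {
    np <- max(4, round(density * m * m / 2000))
    half <- round(pair_sep_px / 2)
    for (z in zset) {
      cy <- sample(10:(m - 10), np, replace = TRUE)
      cx <- sample(10:(m - 10), np, replace = TRUE)
      for (i in seq_len(np)) {
        add_spot(z, cy[i], cx[i] - half)
        add_spot(z, cy[i], cx[i] + half)
      }
    }
  } else if (kind == "filaments") {
    nf <- max(3, round(density * m / 20))
    for (z in zset) {
      for (f in seq_len(nf)) {
        y <- stats::runif(1, 10, m - 10); x <- stats::runif(1, 10, m - 10)
        ang <- stats::runif(1, 0, 2 * pi)
        for (s in seq_len(3 * m)) {
          ang <- ang + stats::rnorm(1, 0, 0.08)
          y <- y + sin(ang); x <- x + cos(ang)
          if (y < 6 || y > m - 5 || x < 6 || x > m - 5) break
          add_spot(z, round(y), round(x), 0.25)
        }
      }
    }
  }
  if (background > 0) {
    # smooth diffuse haze: constant level plus a gentle large-scale mottle
    fy <- stats::runif(1, 0.5, 1.5) / m
    fx <- stats::runif(1, 0.5, 1.5) / m
    mot <- outer(sin(2 * pi * fy * (1:m) + stats::runif(1, 0, 2 * pi)),
                 cos(2 * pi * fx * (1:m) + stats::runif(1, 0, 2 * pi)))
    haze <- background * (1 + 0.3 * mot)
    for (z in zset) vol[z, , ] <- vol[z, , ] + haze
  }
  vol
}

#' Simulate a raw 3DSIM acquisition
#'
#' Modulates a ground-truth volume by the three-beam illumination on the fine
#' (2x) lateral grid, attenuates with the 3-D widefield OTF, performs
#' band-limited lateral downsampling to the camera grid, normalizes the
#' noiseless stack to a mean of `mean_counts` (a typical fluorescence signal
#' level on an sCMOS detector), and adds Gaussian noise of the configured
#' power in counts^2 (negative intensities are clamped to zero, as for
#' photon counts). Deterministic given the distortion's seed.
#'
#' @param gt `[z, y, x]` ground-truth volume on the 2x lateral grid
#' @param params_list list of 3 [illum_params()] with `p_z` set
#' @param cfg a [sim_config()]
#' @param distortion a [distortion_field()]
#' @param otf optional precomputed fine-grid [make_otf3d()] (with
#'   `pixel_size_nm = cfg$pixel_size_nm / 2` and matching shape)
#' @param z_focus focal layer of the illumination axial envelope
#' @param mean_counts mean intensity (counts) of the noiseless stack; the
#'   dBW noise power is referenced to this count scale
#' @return a [raw_stack()]
#' @export
simulate_acquisition <- function(gt, params_list, cfg, distortion = distortion_field(),
                                 otf = NULL, z_focus = floor((dim(gt)[1] + 1) / 2),
                                 mean_counts = 100) {
  nz <- dim(gt)[1]; mfine <- dim(gt)[2]
  stopifnot(dim(gt)[3] == mfine, mfine %% 2 == 0)
  n <- mfine %/% 2L
  if (is.null(otf)) {
    otf <- make_otf3d(cfg, mfine, nz, pixel_size_nm = cfg$pixel_size_nm / 2)
  }
  stopifnot(all(dim(otf$values) == c(mfine, mfine, nz)))
  illum <- make_illumination(params_list, distortion, n, nz, cfg,
                             step = 0.5, z_focus = z_focus)
  gtzyx <- aperm(gt, c(2, 3, 1))                 # [y, x, z] for lateral-batched FFTs
  out <- array(0, c(3, 5, nz, n, n))
  for (d in 1:3) for (ph in 1:5) {
    il <- aperm(illum[d, ph, , , , drop = TRUE], c(2, 3, 1))
    if (nz == 1) dim(il) <- c(mfine, mfine, 1)
    em <- gtzyx * il
    spec <- fft3(em) * otf$values
    img <- Re(ifft3(fourier_crop2(spec)))
    out[d, ph, , , ] <- aperm(img, c(3, 1, 2))
  }
  scale <- mean(out)
  if (scale <= 0) stop("simulated stack has non-positive mean; check ground truth")
  out <- out / scale * mean_counts
  if (is.finite(distortion$noise_power_dbw)) {
    set.seed(distortion$seed)
    sdn <- sqrt(10^(distortion$noise_power_dbw / 10))
    out <- out + array(stats::rnorm(length(out), 0, sdn), dim(out))
  }
  out[out < 0] <- 0
  raw_stack(out, cfg)
}

#' Default per-orientation illumination parameters for simulations
#'
#' Three orientations 60 degrees apart with equal pattern frequency set by
#' the beam geometry (`|p| = n_imm sin(beta) / lambda_exc`), fixed distinct
#' initial phases, and modulation depths derived from beam amplitudes
#' `E0 = 1, E1 = 0.5` (`a = (1.5, 1, 0.5)`). The axial wave vector follows
#' from the beam half-angle via [axial_wavevector()].
#'
#' @param cfg a [sim_config()]
#' @param angles_deg pattern orientations in degrees
#' @param phi0 initial phases (radians), one per orientation
#' @param e0,e1 centre/side beam field amplitudes
#' @return list of 3 [illum_params()]
#' @export
default_sim_params <- function(cfg, angles_deg = c(15, 75, 135),
                               phi0 = c(0.5, 1.2, -0.9),
                               e0 = 1, e1 = 0.5) {
  pmag_nm <- cfg$n_imm * sin(cfg$beam_angle_beta) / cfg$wavelength_exc_nm
  pmag <- pmag_nm * cfg$pixel_size_nm            # cycles/pixel
  a <- c(e0^2 + 2 * e1^2, 2 * e0 * e1, 2 * e1^2)
  lapply(1:3, function(d) {
    ang <- angles_deg[d] * pi / 180
    pr <- illum_params(pmag * c(cos(ang), sin(ang)), phi0[d], a)
    pr$p_z <- axial_wavevector(pmag, cfg)
    pr
  })
}

#' One-call synthetic 3DSIM study
#'
#' Convenience wrapper tying together ground truth, illumination and
#' acquisition; returns everything a test harness needs, including the true
#' parameters ("sidecar").
#'
#' @param n raw lateral size; `nz` layers
#' @param cfg a [sim_config()]
#' @param distortion a [distortion_field()]
#' @param kind ground-truth structure kind, see [ground_truth()]
#' @param seed seed for the ground-truth draw (noise uses the distortion seed)
#' @param params_list optional list of 3 [illum_params()]
#' @param ... passed on to [ground_truth()]
#' @return list with `stack` ([raw_stack()]), `gt`, `params` (true
#'   [illum_params()] per orientation), `distortion`, `z_focus`
#' @export
simulate_sim3d <- function(n = 128, nz = 8, cfg = sim_config(),
                           distortion = distortion_field(),
                           kind = "beads", seed = 1L,
                           params_list = default_sim_params(cfg), ...) {
  gt <- ground_truth(kind, n, nz, seed = seed, ...)
  z_focus <- floor((nz + 1) / 2)
  stack <- simulate_acquisition(gt, params_list, cfg, distortion, z_focus = z_focus)
  list(stack = stack, gt = gt, params = params_list,
       distortion = distortion, z_focus = z_focus)
}
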