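test_that("2-D SVD estimation recovers a constructed phasor exactly", {
  n <- 64
  p_sub <- c(0.137, -0.291)
  phi0 <- 0.6
  ph <- as_phasor_field(planar_phasor(n, p_sub, const = 2 * phi0))
  est <- estimate_2d(ph, c(0, 0), harmonic = 2)
  expect_lt(max(abs(est$p_sub - p_sub)), 1e-6)
  expect_lt(abs(est$phi0 - phi0), 1e-6)
  expect_gt(est$quality, 1e6)                 # numerically rank-one
})

test_that("zero slopes and zero phase are recovered as zeros", {
  ph <- as_phasor_field(matrix(1 + 0i, 32, 32))
  est <- estimate_2d(ph, c(0, 0))
  expect_equal(est$p_sub, c(0, 0), tolerance = 1e-10)
  expect_equal(est$phi0, 0, tolerance = 1e-10)
})

test_that("conjugating the phasor negates wave vector and phase", {
  n <- 48
  ph <- planar_phasor(n, c(0.21, 0.33), const = 0.8)
  e1 <- estimate_2d(as_phasor_field(ph), c(0, 0))
  e2 <- estimate_2d(as_phasor_field(Conj(ph)), c(0, 0))
  expect_equal(e2$p_sub, -e1$p_sub, tolerance = 1e-8)
  expect_equal(e2$phi0, -e1$phi0, tolerance = 1e-8)
})

test_that("the second-harmonic wave vector and phase are halved in one place", {
  n <- 64
  p_int <- c(11, -6)
  p_sub <- c(0.2, 0.1)
  phi0 <- 0.5
  ph <- as_phasor_field(planar_phasor(n, p_sub, const = 2 * phi0), p_int)
  est <- estimate_2d(ph, p_int, harmonic = 2)
  expect_equal(est$p_lateral, (p_int + p_sub) / 2 / n, tolerance = 1e-9)
  expect_equal(est$phi0, phi0, tolerance = 1e-8)
  est1 <- estimate_2d(ph, p_int, harmonic = 1)
  expect_equal(est1$p_lateral, (p_int + p_sub) / n, tolerance = 1e-9)
})

test_that("HOSVD recovers a rank-one tensor exactly and every slice is rank-one", {
  n <- 32; nz <- 6
  p_sub <- c(-0.23, 0.31)
  phi0 <- 0.45
  tens <- planar_phasor_tensor(n, nz, p_sub, const = 2 * phi0)
  est <- estimate_3d_hosvd(as_phasor_field(tens), c(0, 0))
  expect_lt(max(abs(est$p_sub - p_sub)), 1e-6)
  expect_lt(abs(est$phi0 - phi0), 1e-6)
  for (z in seq_len(nz)) {
    sv <- svd(tens[, , z])$d
    expect_lt(sv[2] / sv[1], 1e-6)
  }
  # mode unfoldings are rank-one too
  for (unf in list(matrix(tens, n, n * nz),
                   matrix(aperm(tens, c(2, 1, 3)), n, n * nz))) {
    sv <- svd(unf)$d
    expect_lt(sv[2] / sv[1], 1e-6)
  }
})

test_that("per-layer global phase jitter does not disturb HOSVD slopes", {
  set.seed(31)
  n <- 32; nz <- 8
  p_sub <- c(0.17, -0.12)
  jit <- runif(nz, -pi, pi)
  tens <- planar_phasor_tensor(n, nz, p_sub, const = 0.3, z_jitter = jit)
  est <- estimate_3d_hosvd(as_phasor_field(tens), c(0, 0))
  expect_lt(max(abs(est$p_sub - p_sub)), 1e-3)
})

test_that("axial wave vector follows the beam geometry identity", {
  cfg <- tiny_cfg()
  # beta = 90 degrees: p_z equals the (unit-converted) lateral wave vector
  p <- 0.15
  pz90 <- axial_wavevector(p, cfg, beta = pi / 2)
  expect_equal(pz90, p / cfg$pixel_size_nm * cfg$z_step_nm, tolerance = 1e-12)
  # small-angle limit: p_z ~ p * beta / 2
  beta <- 1e-3
  expect_equal(axial_wavevector(p, cfg, beta = beta),
               p / cfg$pixel_size_nm * cfg$z_step_nm * beta / 2, tolerance = 1e-6)
  # two algebraic forms agree to 1e-12
  set.seed(32)
  for (i in 1:20) {
    pp <- runif(1, 0.05, 0.3); bb <- runif(1, 0.1, pi / 2)
    lhs <- axial_wavevector(pp, cfg, beta = bb)
    rhs <- pp / cfg$pixel_size_nm * (1 - cos(bb)) / sin(bb) * cfg$z_step_nm
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_equal(lhs, pp / cfg$pixel_size_nm * tan(bb / 2) * cfg$z_step_nm,
                 tolerance = 1e-12)
  }
  expect_error(axial_wavevector(p, cfg, beta = -0.1), "beta")
})

test_that("beam angle can be recovered from the measured pattern frequency", {
  cfg <- tiny_cfg()
  p <- cfg$n_imm * sin(cfg$beam_angle_beta) / cfg$wavelength_exc_nm * cfg$pixel_size_nm
  expect_equal(beta_from_wavevector(p, cfg), cfg$beam_angle_beta, tolerance = 1e-12)
})

test_that("orientation prior flags rotated triples and passes equilateral ones", {
  mk <- function(angles_deg, mag = 10) {
    lapply(angles_deg, function(a) mag * c(cos(a * pi / 180), sin(a * pi / 180)))
  }
  ok <- check_orientation_set(mk(c(0, 120, 240)))
  expect_equal(ok$sd_wv, 0)
  expect_equal(ok$sd_ang, 0, tolerance = 1e-10)
  expect_false(ok$anomalous)
  rot <- check_orientation_set(mk(c(20, 120, 240)))
  expect_gt(rot$sd_ang, 5)
  expect_true(rot$anomalous)
  # population-SD oracle on magnitudes (10, 10, 11)
  mags <- check_orientation_set(list(c(10, 0),
                                     10 * c(cos(2 * pi / 3), sin(2 * pi / 3)),
                                     11 * c(cos(4 * pi / 3), sin(4 * pi / 3))))
  expect_equal(mags$sd_wv, sqrt(mean((c(10, 10, 11) - mean(c(10, 10, 11)))^2)),
               tolerance = 1e-12)
  # sign flips of individual vectors do not change the verdict
  flipped <- check_orientation_set(list(mk(c(0, 120, 240))[[1]],
                                        -mk(c(0, 120, 240))[[2]],
                                        mk(c(0, 120, 240))[[3]]))
  expect_equal(flipped$sd_ang, 0, tolerance = 1e-10)
})

test_that("modulation-depth ratios are recovered on simulated data", {
  sim <- shared_sim()
  cfg <- sim$stack$config
  otf <- make_otf3d(cfg, 256, 8, pixel_size_nm = cfg$pixel_size_nm / 2)
  rec <- reconstruct_subset(sim$stack$data, sim$params, cfg, otf, z_ref = 4)
  a <- sim$params[[1]]$a
  for (d in 1:3) {
    g <- Mod(rec$gains[[d]])
    expect_equal(2 * g[1], a[3] / a[1], tolerance = 0.05)  # +2 band: a2/a0
    expect_equal(2 * g[2], a[3] / a[1], tolerance = 0.05)  # -2 band
    expect_equal(2 * mean(g[3:6]), a[2] / a[1], tolerance = 0.10)  # 1-order copies
  }
})

test_that("side band of zero yields zero modulation gain", {
  n <- 16
  b0 <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), c(n, n, n))
  O <- array(1, c(n, n, n))
  g <- estimate_modulation_depth(array(0i, c(n, n, n)), b0, O, O)
  expect_equal(Mod(g$gain), 0)
  # scaling both bands by the same factor leaves the ratio invariant
  bm <- 0.4 * b0
  g1 <- estimate_modulation_depth(bm, b0, O, O)
  g2 <- estimate_modulation_depth(5 * bm, 5 * b0, O, O)
  expect_equal(g1$gain, g2$gain, tolerance = 1e-12)
  expect_equal(Mod(g1$gain), 0.4, tolerance = 1e-12)
})

test_that("tiny OTF overlap falls back with a warning", {
  n <- 8
  b <- array(1 + 0i, c(n, n, 2))
  O <- array(0, c(n, n, 2)); O[1, 1, 1] <- 1
  expect_warning(g <- estimate_modulation_depth(b, b, O, O, min_overlap = 50),
                 "overlap")
  expect_equal(g$gain, 0.5 + 0i)
})

test_that("full estimation chain meets the noise-free recovery contract", {
  sim <- shared_sim()
  for (d in 1:3) {
    tr <- sim$params[[d]]
    est <- estimate_slice_params(sim$stack$data[d, , 4, , , drop = TRUE])
    expect_lt(max(abs(est$p_lateral - tr$p_lateral)) * 128, 0.02)
    expect_lt(ang_err_deg(est$phi0, tr$phi0), 2)
  }
})

test_that("noisy estimation stays within the stochastic tolerance", {
  cfg <- tiny_cfg()
  dist <- distortion_field(noise_power_dbw = 5, seed = 77)
  sim <- simulate_sim3d(n = 128, nz = 8, cfg = cfg, seed = 6, distortion = dist)
  for (d in 1:3) {
    tr <- sim$params[[d]]
    est <- estimate_slice_params(sim$stack$data[d, , 4, , , drop = TRUE],
                                 near_p1 = round(tr$p_lateral * 128))
    expect_lt(max(abs(est$p_lateral - tr$p_lateral)) * 128, 0.1)
    expect_lt(ang_err_deg(est$phi0, tr$phi0), 10)
  }
})

test_that("singular-value quality degrades monotonically with noise power", {
  cfg <- tiny_cfg()
  quals <- sapply(c(-Inf, 0, 5), function(dbw) {
    dist <- distortion_field(noise_power_dbw = dbw, seed = 55)
    sim <- simulate_sim3d(n = 64, nz = 6, cfg = cfg, seed = 9, distortion = dist)
    estimate_slice_params(sim$stack$data[1, , 3, , , drop = TRUE])$quality
  })
  expect_true(all(diff(quals) < 0))
})

test_that("HOSVD and per-layer estimates agree on z-homogeneous data", {
  sim <- shared_sim()
  d <- 1
  b1 <- array(0i, c(128, 128, 8)); b2 <- array(0i, c(128, 128, 8))
  for (z in 1:8) {
    bs <- separate_bands(sim$stack$data[d, , z, , , drop = TRUE])
    b1[, , z] <- bs$bands[["1"]]; b2[, , z] <- bs$bands[["2"]]
  }
  est3 <- estimate_volume_params(list(b1 = b1, b2 = b2), focus_layer = 4)
  est2 <- estimate_slice_params(sim$stack$data[d, , 4, , , drop = TRUE])
  expect_lt(max(abs(est3$p_lateral - est2$p_lateral)) * 128, 0.02)
  expect_equal(est3$source, "volume-hosvd")
})
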