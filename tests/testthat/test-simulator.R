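test_that("zero modulation gives a spatially constant field per frame", {
  cfg <- tiny_cfg()
  pr <- illum_params(c(0.1, 0.02), 0.3, a = c(1, 0, 0))
  pr$p_z <- 0.1
  il <- make_illumination(list(pr, pr, pr), distortion_field(), 32, 2, cfg)
  expect_equal(max(il) - min(il), 0, tolerance = 1e-12)
  expect_equal(il[1, 1, 1, 1, 1], 1)
})

test_that("undistorted illumination has exactly five spectral peaks at 0, +-p, +-2p", {
  cfg <- tiny_cfg()
  n <- 64
  p_bins <- c(11, 5)
  pr <- illum_params(p_bins / n, 0.4)
  pr$p_z <- 0.1
  il <- make_illumination(list(pr, pr, pr), distortion_field(), n, 1, cfg,
                          z_focus = 1)
  sp <- fft(il[1, 1, 1, , ])
  mag <- abs(sp)
  thresh <- 1e-8 * max(mag)
  peaks <- which(mag > thresh, arr.ind = TRUE)
  ky <- fft_bins(n)[peaks[, 1]]; kx <- fft_bins(n)[peaks[, 2]]
  found <- unique(paste(kx, ky))
  want <- c("0 0", paste(p_bins[1], p_bins[2]), paste(-p_bins[1], -p_bins[2]),
            paste(2 * p_bins[1], 2 * p_bins[2]), paste(-2 * p_bins[1], -2 * p_bins[2]))
  expect_setequal(found, want)
})

test_that("phase stepping advances harmonics by 2 pi/5 and 4 pi/5", {
  cfg <- tiny_cfg()
  n <- 64
  p_bins <- c(9, -4)
  pr <- illum_params(p_bins / n, 0.7)
  pr$p_z <- 0.12
  il <- make_illumination(list(pr, pr, pr), distortion_field(), n, 1, cfg,
                          z_focus = 1)
  iy1 <- (p_bins[2] %% n) + 1; ix1 <- (p_bins[1] %% n) + 1
  iy2 <- ((2 * p_bins[2]) %% n) + 1; ix2 <- ((2 * p_bins[1]) %% n) + 1
  ph1 <- sapply(1:5, function(np) Arg(fft(il[1, np, 1, , ])[iy1, ix1]))
  ph2 <- sapply(1:5, function(np) Arg(fft(il[1, np, 1, , ])[iy2, ix2]))
  d1 <- diff(ph1); d2 <- diff(ph2)
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  # R's forward FFT conjugates phases: the +p bin phase steps by -2 pi/5
  expect_equal(abs(wrap(d1)), rep(2 * pi / 5, 4), tolerance = 1e-9)
  expect_equal(abs(wrap(d2)), rep(4 * pi / 5, 4), tolerance = 1e-9)
})

test_that("interference intensity is non-negative for field-derived depths", {
  cfg <- tiny_cfg()
  il <- make_illumination(default_sim_params(cfg), distortion_field(), 48, 4, cfg)
  expect_gte(min(il), 0)
  bad <- illum_params(c(0.1, 0), 0, a = c(1, 0.9, 0.1))  # a0 + a2 < 2 a1
  bad$p_z <- 0.1
  expect_error(make_illumination(list(bad, bad, bad), distortion_field(), 16, 1, cfg),
               "negative")
})

test_that("no modulation and no noise reduce acquisition to the widefield image", {
  cfg <- tiny_cfg()
  gt <- ground_truth("beads", 32, 4, seed = 4)
  flat <- lapply(1:3, function(d) {
    pr <- illum_params(default_sim_params(cfg)[[d]]$p_lateral, 0, a = c(1, 0, 0))
    pr$p_z <- default_sim_params(cfg)[[d]]$p_z
    pr
  })
  st <- simulate_acquisition(gt, flat, cfg)
  # all 15 frames identical (orientation- and phase-independent)
  base <- st$data[1, 1, , , ]
  for (d in 1:3) for (np in 1:5) {
    expect_equal(st$data[d, np, , , ], base, tolerance = 1e-10)
  }
})

test_that("acquisition is deterministic given the seed", {
  cfg <- tiny_cfg()
  dist <- distortion_field(noise_power_dbw = 5, seed = 42)
  gt <- ground_truth("beads", 32, 4, seed = 4)
  pars <- default_sim_params(cfg)
  s1 <- simulate_acquisition(gt, pars, cfg, dist)
  s2 <- simulate_acquisition(gt, pars, cfg, dist)
  expect_identical(s1$data, s2$data)
})

test_that("simulated stacks have the documented geometry and scaling", {
  sim <- shared_sim()
  expect_equal(dim(sim$stack$data), c(3, 5, 8, 128, 128))
  expect_equal(dim(sim$gt), c(8, 256, 256))
  expect_gte(min(sim$stack$data), 0)
  expect_equal(mean(sim$stack$data), 100, tolerance = 0.05)  # count normalization
})

test_that("wave-vector distortion ramps the local wave vector across the field", {
  cfg <- tiny_cfg()
  dist <- distortion_field(wv_error_px = c(-1, 1), axis = "x")
  pr <- default_sim_params(cfg)[[1]]
  n <- 128
  left <- local_wavevector(pr, dist, n, c(0, n, 0, 32))
  right <- local_wavevector(pr, dist, n, c(0, n, n - 32, n))
  expect_lt(left[1], pr$p_lateral[1])
  expect_gt(right[1], pr$p_lateral[1])
  # full-field mean error is zero for a symmetric ramp
  full <- local_wavevector(pr, dist, n)
  expect_equal(full, pr$p_lateral, tolerance = 1e-9)
})

test_that("ground-truth volumes are non-negative, finite, and structured in a slab", {
  for (kind in c("beads", "point-pairs", "filaments")) {
    gt <- ground_truth(kind, 32, 8, seed = 5)
    expect_true(all(is.finite(gt)))
    expect_gte(min(gt), 0)
    per_layer <- apply(gt, 1, sum)
    expect_equal(per_layer[1], 0)            # outer layers empty
    expect_gt(per_layer[4], 0)               # central slab carries structure
  }
})
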