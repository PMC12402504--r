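random_band_set <- function(n, seed = 1) {
  set.seed(seed)
  orders <- -2:2
  bands <- lapply(orders, function(m) {
    matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  })
  names(bands) <- as.character(orders)
  structure(list(bands = bands, orders = orders), class = "band_set")
}

test_that("forward mixing then separation recovers every band to 1e-10", {
  n <- 16
  truth <- random_band_set(n, seed = 21)
  mixed <- remix_bands(truth)
  sep <- separate_bands(mixed, spectra = TRUE)
  for (nm in names(truth$bands)) {
    expect_lt(max(abs(sep$bands[[nm]] - truth$bands[[nm]])), 1e-10)
  }
})

test_that("real-valued inputs give Hermitian band pairing C_-m(k) = conj(C_+m(-k))", {
  sim <- shared_sim()
  bs <- separate_bands(sim$stack$data[1, , 4, , , drop = TRUE])
  n <- 128
  rev_idx <- function(m) c(1, m:2)
  for (m in c(1, 2)) {
    plus <- bs$bands[[as.character(m)]]
    minus <- bs$bands[[as.character(-m)]]
    expect_lt(max(abs(minus - Conj(plus[rev_idx(n), rev_idx(n)]))),
              1e-10 * max(abs(plus)))
  }
})

test_that("unmodulated input yields side bands with negligible energy", {
  set.seed(22)
  img <- matrix(runif(32 * 32), 32)
  frames <- array(0, c(5, 32, 32))
  for (np in 1:5) frames[np, , ] <- img
  bs <- separate_bands(frames)
  e0 <- sum(abs(bs$bands[["0"]])^2)
  for (nm in c("-2", "-1", "1", "2")) {
    expect_lt(sum(abs(bs$bands[[nm]])^2), 1e-10 * e0)
  }
})

test_that("degenerate phase step is rejected", {
  frames <- array(runif(5 * 8 * 8), c(5, 8, 8))
  expect_error(separate_bands(frames, delta_phi = 0), "singular|degenerate")
})

test_that("integer peak localization finds a delta and honours the DC exclusion", {
  n <- 32
  band <- matrix(0i, n, n)
  band[(( -7) %% n) + 1, ((12) %% n) + 1] <- 1    # bin (kx = 12, ky = -7)
  expect_equal(locate_integer_peak(band), c(12, -7))
  dc_only <- matrix(0i, n, n); dc_only[1, 1] <- 5
  expect_error(locate_integer_peak(dc_only), "peak")
})

test_that("restricted search localizes a weak peak next to strong off-window content", {
  n <- 64
  band <- matrix(0i, n, n)
  band[(5 %% n) + 1, (30 %% n) + 1] <- 0.1        # weak true peak (kx 30, ky 5)
  band[(1 %% n) + 1, ((-9) %% n) + 1] <- 1        # strong distractor
  expect_equal(locate_integer_peak(band, near = c(29, 4), search_radius = 3),
               c(30, 5))
})

test_that("peak localization on simulated data matches the sidecar truth", {
  sim <- shared_sim()
  for (d in 1:3) {
    bs <- separate_bands(sim$stack$data[d, , 4, , , drop = TRUE])
    pk1 <- locate_integer_peak(bs$bands[["1"]])
    expect_equal(pk1, round(sim$params[[d]]$p_lateral * 128))
    pk2 <- locate_integer_peak(bs$bands[["2"]], near = 2 * pk1, search_radius = 2)
    expect_equal(pk2, round(2 * sim$params[[d]]$p_lateral * 128))
  }
})

test_that("phasor of a noise-free single harmonic is a unit-modulus plane", {
  n <- 64
  p_bins <- c(12.31, -6.58)
  x <- 0:(n - 1)
  sig <- outer(exp(2i * pi * p_bins[2] * x / n), exp(2i * pi * p_bins[1] * x / n)) *
    exp(0.9i)
  band <- fft2(sig)
  pk <- locate_integer_peak(band)
  expect_equal(pk, round(p_bins))
  ph <- build_phasor(band, pk)
  expect_equal(max(abs(Mod(ph$values) - 1)), 0, tolerance = 1e-12)
  expect_lt(plane_fit_residual(ph$values), 1e-8)
})

test_that("zero sub-pixel residual gives a spatially constant phasor", {
  n <- 32
  sig <- planar_phasor(n, c(7, -3), const = 1.1)
  ph <- build_phasor(fft2(sig), c(7, -3))
  expect_lt(max(abs(ph$values - exp(1.1i))), 1e-10)
})

test_that("conjugate band yields the conjugate phasor", {
  n <- 32
  sig <- planar_phasor(n, c(5.3, 2.2), const = 0.4)
  ph_plus <- build_phasor(fft2(sig), c(5, 2))
  ph_minus <- build_phasor(fft2(Conj(sig)), c(-5, -2))
  expect_lt(max(abs(ph_minus$values - Conj(ph_plus$values))), 1e-10)
})

test_that("masking leaves an in-window planar phasor's slope essentially unchanged", {
  n <- 64
  ph <- as_phasor_field(planar_phasor(n, c(0.31, -0.22), const = 0.2))
  est0 <- estimate_2d(ph, c(0, 0))
  est1 <- estimate_2d(mask_phasor(ph, 7), c(0, 0))
  # the Dirichlet tails of a sub-bin slope extend slightly past any finite
  # window, so the identity is approximate at finite half-width ...
  expect_lt(max(abs(est1$p_sub - est0$p_sub)), 0.02)
  # ... and exact when the window reaches the grid Nyquist
  est_full <- estimate_2d(suppressWarnings(mask_phasor(ph, n)), c(0, 0))
  expect_lt(max(abs(est_full$p_sub - est0$p_sub)), 1e-12)
})

test_that("masking reduces the phase-plane error under heavy pixel noise", {
  set.seed(23)
  n <- 64
  truth_bins <- c(0.27, -0.41)
  clean <- planar_phasor(n, truth_bins, const = 0.5)
  errs <- sapply(1:5, function(i) {
    noisy <- clean + 1.5 * matrix(complex(real = rnorm(n^2),
                                          imaginary = rnorm(n^2)), n)
    noisy <- noisy / Mod(noisy)
    masked <- mask_phasor(as_phasor_field(noisy), 7, renormalize = TRUE)
    c(raw = plane_fit_residual(noisy), masked = plane_fit_residual(masked$values))
  })
  # the plane-fit residual of the masked field is strictly smaller, per draw
  expect_true(all(errs["masked", ] < errs["raw", ]))
  # and the masked slope estimate is close to the truth
  noisy <- clean + 1.5 * matrix(complex(real = rnorm(n^2),
                                        imaginary = rnorm(n^2)), n)
  msk_est <- estimate_2d(mask_phasor(as_phasor_field(noisy / Mod(noisy)), 7),
                         c(0, 0))
  expect_lt(max(abs(msk_est$p_sub - truth_bins)), 0.1)
})

test_that("a Nyquist-wide mask window is the identity", {
  n <- 32
  set.seed(24)
  vals <- exp(1i * matrix(runif(n^2, -pi, pi), n))
  ph <- as_phasor_field(vals)
  expect_warning(out <- mask_phasor(ph, n), "clipping")
  expect_equal(out$values, vals)
})
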