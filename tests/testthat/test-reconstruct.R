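test_that("band shifting: identity, pure integer roll, and round trip", {
  set.seed(71)
  n <- 32
  spec <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  # p = 0 is the identity up to zero-pad embedding
  z0 <- shift_band(spec, c(0, 0))
  back <- fourier_crop2(z0)
  expect_lt(max(abs(back - spec)), 1e-10)
  # pure integer shift equals an array roll on the padded grid
  p_int <- c(3, -5)                            # bins (kx, ky)
  si <- shift_band(spec, p_int / n)
  ref <- roll(fourier_pad2(spec), c(5, -3))    # B(k + s): roll by -s
  expect_lt(max(abs(si - ref)), 1e-10)
  # energy conservation and fractional round trip
  p <- c(0.3, -0.6) / n
  fwd <- shift_band(spec, p)
  expect_equal(sum(abs(fwd)^2), 16 * sum(abs(spec)^2), tolerance = 1e-9)
  bwd <- shift_band(fwd, -p, pad = FALSE, n_raw = n)
  expect_lt(max(abs(bwd - fourier_pad2(spec))), 1e-9)
  expect_error(shift_band(spec, c(2, 0)), "exceeds")
})

test_that("band OTF assembly extends the axial support for p_z > 0", {
  cfg <- tiny_cfg()
  otf <- make_otf3d(cfg, 64, 16)
  # p_z = 0: the 1-order OTF equals the widefield OTF
  b0 <- assemble_band_otfs(otf, 0)
  expect_equal(b0$m1, otf$values, tolerance = 1e-12)
  expect_equal(b0$m0, otf$values)
  expect_equal(b0$m2, otf$values)
  # p_z > 0: strictly larger axial support at a mid-lateral frequency
  bz <- assemble_band_otfs(otf, 0.2)
  floor_v <- 1e-4
  count_axial <- function(O) sum(O[1, 6, ] > floor_v)
  expect_gt(count_axial(bz$m1), count_axial(otf$values))
  # symmetry in k_z is preserved
  rev_z <- c(1, 16:2)
  expect_equal(bz$m1, bz$m1[, , rev_z], tolerance = 1e-9)
  expect_error(assemble_band_otfs(otf, 0.8), "Nyquist")
})

test_that("single 0-order band with small w reduces to Wiener widefield deconvolution", {
  set.seed(72)
  n <- 16
  O <- array(runif(n^3, 0.1, 1), c(n, n, n))
  spec <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), c(n, n, n))
  w <- 1e-4
  got <- wiener_combine(list(list(spec = spec, otf = O, gain = 1 + 0i)),
                        wiener_config(w = w))
  expect_equal(got, spec * O / (O^2 + w^2), tolerance = 1e-12)
  expect_error(wiener_combine(list()), "empty")
})

test_that("reconstruction output is real, finite and clamp-logged", {
  sim <- shared_sim()
  rec <- reconstruct_subset(sim$stack$data, sim$params, sim$stack$config,
                            z_ref = 4)
  expect_true(all(is.finite(rec$sr)))
  expect_gte(min(rec$sr), 0)
  expect_gte(rec$clamp_fraction, 0)
  expect_lt(rec$clamp_fraction, 0.6)
  expect_equal(dim(rec$sr), c(8, 256, 256))
  expect_equal(rec$p_z, sim$params[[1]]$p_z, tolerance = 0.01)
})

test_that("two-point object unresolved in widefield is resolved in SR", {
  res <- two_point_experiment(seed = 42)
  expect_gt(res$dip_sr, 0.2)                   # resolved with a >= 20% dip
  expect_lt(res$dip_wf, 0.05)                  # no dip in widefield
})

test_that("wrong initial phase produces more ghosting than the correct one", {
  sim <- shared_sim()
  cfg <- sim$stack$config
  otf <- make_otf3d(cfg, 256, 8, pixel_size_nm = cfg$pixel_size_nm / 2)
  rec_ok <- reconstruct_subset(sim$stack$data, sim$params, cfg, otf, z_ref = 4)
  wrong <- lapply(sim$params, function(e) { e$phi0 <- e$phi0 + pi / 2; e })
  rec_bad <- reconstruct_subset(sim$stack$data, wrong, cfg, otf, z_ref = 4,
                                gains = rec_ok$gains)
  # ghost energy: residual after matching to the ground truth's support
  gtn <- sim$gt / max(sim$gt)
  err <- function(r) {
    v <- r$sr / max(r$sr)
    mean((v - gtn)^2)
  }
  expect_gt(err(rec_bad), err(rec_ok))
})

test_that("uniform in-focus plane reconstructs flat without tiling or fringe artifacts", {
  cfg <- tiny_cfg()
  nz <- 6
  gt <- array(0, c(nz, 128, 128))
  gt[3, , ] <- 1                               # one uniform fluorescent plane
  pars <- default_sim_params(cfg)
  stack <- simulate_acquisition(gt, pars, cfg, z_focus = 3)
  est <- lapply(pars, function(e) e)           # true parameters
  otf <- make_otf3d(cfg, 128, nz, pixel_size_nm = cfg$pixel_size_nm / 2)
  rec <- reconstruct_subset(stack$data, est, cfg, otf, z_ref = 3)
  plane <- rec$sr[3, , ]
  inner <- plane[17:112, 17:112]
  expect_lt(stats::sd(inner) / mean(inner), 0.02)   # < 2% RMS ripple
})
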