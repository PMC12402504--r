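test_that("tile counts, sizes and strides match the closed form", {
  # the printed configuration: a 384-pixel field segmented on the 2x grid
  g <- tile_grid(768, 64)
  expect_equal(g$n_tiles, 121)               # (2*384/64 - 1)^2
  expect_equal(g$n_side, 11)
  expect_equal(g$tile_size, 128)
  expect_equal(g$stride, 64)
  expect_true(all(g$bounds[, 2] - g$bounds[, 1] == 128))
  expect_true(all(g$bounds[, 4] - g$bounds[, 3] == 128))
  # half overlap between lateral neighbours
  expect_equal(unname(g$bounds[2, 3] - g$bounds[1, 3]), 64)
  # closed form for a few other shapes
  for (nm in list(c(256, 64), c(512, 32), c(256, 128))) {
    gg <- tile_grid(nm[1], nm[2])
    expect_equal(gg$n_tiles, (nm[1] / nm[2] - 1)^2)
  }
})

test_that("a 2m field is exactly one full-field tile", {
  g <- tile_grid(128, 64)
  expect_equal(g$n_tiles, 1)
  expect_equal(unname(g$bounds[1, ]), c(0, 128, 0, 128))
})

test_that("coverage oracle: union covers the field, interior pixels 4-fold", {
  g <- tile_grid(256, 32)
  cov <- tile_coverage(g)
  expect_true(all(cov >= 1))                 # full coverage
  inner <- cov[33:224, 33:224]
  expect_true(all(inner == 4))               # interior: exactly 4 tiles
  expect_equal(cov[1, 1], 1)                 # corners: 1 tile
})

test_that("indivisible field sizes are rejected with guidance", {
  expect_error(tile_grid(250, 32), "divisible")
  expect_error(tile_grid(32, 32), "at least")
})

test_that("slice selection partitions layers at the threshold", {
  q <- normalize_scores(c(1.0, 0.9, 0.3))
  sel <- select_slices(q, threshold = 0.85)
  expect_equal(sel$direct, c(1, 2))
  expect_equal(sel$merged, 3)
  all_direct <- select_slices(normalize_scores(c(5, 5, 5)))
  expect_equal(all_direct$direct, 1:3)
  expect_length(all_direct$merged, 0)
  # all below threshold: direct set legally empty
  weak <- normalize_scores(c(0.2, 0.5, 1e-3))
  weak$mcnr_norm <- weak$mcnr_norm * 0.8     # push the best layer under M_t
  sel_w <- select_slices(weak)
  expect_length(sel_w$direct, 0)
  expect_equal(sel_w$merged, 1:3)
})

test_that("block merging weights are a probability vector over retained layers", {
  set.seed(41)
  sub <- array(runif(5 * 4 * 6 * 6), c(5, 4, 6, 6))   # [phase, z, y, x]
  q <- normalize_scores(c(1, 0.5, 0.1, 0.05))
  comp <- merge_block(sub, q, prefilter = 0.2)
  # layers 3, 4 are pre-filtered out; weights (1, 0.5)/1.5
  manual <- (sub[, 1, , ] * (1 / 1.5) + sub[, 2, , ] * (0.5 / 1.5))
  expect_equal(comp, manual, tolerance = 1e-12)
})

test_that("single-layer and identical-layer merges return the layer", {
  sub <- array(runif(3 * 1 * 4 * 4), c(3, 1, 4, 4))
  q1 <- normalize_scores(1)
  expect_equal(merge_block(sub, q1), array(sub[, 1, , ], c(3, 4, 4)))
  layer <- matrix(runif(16), 4)
  two <- array(0, c(2, 4, 4)); two[1, , ] <- layer; two[2, , ] <- layer
  q2 <- normalize_scores(c(1, 0.7))
  expect_equal(merge_block(two, q2), layer, tolerance = 1e-12)
})

test_that("zero surviving weight falls back to an unweighted mean with warning", {
  two <- array(runif(2 * 4 * 4), c(2, 4, 4))
  q <- normalize_scores(c(1, 0.5))
  expect_warning(comp <- merge_block(two, q, prefilter = 2), "pre-filter")
  expect_equal(comp, (two[1, , ] + two[2, , ]) / 2, tolerance = 1e-12)
})

test_that("anomaly resolution substitutes layer estimates and keeps a ledger", {
  mk_est <- function(src = "tile") {
    structure(list(p_lateral = c(0.1, 0), phi0 = 0, p_sub = c(0, 0),
                   quality = 10, low_confidence = FALSE, source = src),
              class = "param_estimate")
  }
  tiles <- list(
    list(`1` = list(mk_est(), mk_est(), mk_est())),
    list(`1` = list(mk_est(), mk_est(), mk_est()))
  )
  layers <- list(`1` = list(mk_est("layer"), mk_est("layer"), mk_est("layer")))
  ok <- structure(list(sd_wv = 0, sd_ang = 0, anomalous = FALSE),
                  class = "orientation_check")
  bad <- structure(list(sd_wv = 0, sd_ang = 12, anomalous = TRUE),
                   class = "orientation_check")
  # no anomalies: identical estimates, empty ledger
  pf <- resolve_params(tiles, layers, list(list(`1` = ok), list(`1` = ok)))
  expect_equal(nrow(pf$ledger), 0)
  expect_equal(pf$estimates, tiles)
  # one flagged tile: exactly that tile's entries become layer-sourced
  pf2 <- resolve_params(tiles, layers, list(list(`1` = ok), list(`1` = bad)))
  expect_equal(nrow(pf2$ledger), 1)
  expect_equal(pf2$ledger$tile, 2)
  expect_equal(pf2$estimates[[2]][["1"]][[1]]$source, "layer")
  expect_equal(pf2$estimates[[1]][["1"]][[1]]$source, "tile")
  # missing fallback is an error
  expect_error(resolve_params(tiles, list(), list(list(`1` = ok), list(`1` = bad))),
               "fallback")
})

test_that("low-confidence tile estimates also trigger the layer fallback", {
  lowq <- structure(list(p_lateral = c(0.1, 0), phi0 = 0, p_sub = c(0, 0),
                         quality = 1.2, low_confidence = TRUE, source = "tile"),
                    class = "param_estimate")
  hiq <- structure(list(p_lateral = c(0.1, 0), phi0 = 0, p_sub = c(0, 0),
                        quality = 10, low_confidence = FALSE, source = "layer"),
                   class = "param_estimate")
  tiles <- list(list(`1` = list(lowq, lowq, lowq)))
  layers <- list(`1` = list(hiq, hiq, hiq))
  ok <- structure(list(sd_wv = 0, sd_ang = 0, anomalous = FALSE),
                  class = "orientation_check")
  pf <- resolve_params(tiles, layers, list(list(`1` = ok)))
  expect_equal(nrow(pf$ledger), 1)
  expect_equal(pf$estimates[[1]][["1"]][[1]]$source, "layer")
})
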