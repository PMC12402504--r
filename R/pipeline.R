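#' Estimate illumination parameters of a raw 3DSIM stack
#'
#' The main fitting entry point. Three modes are supported:
#' \describe{
#'   \item{`"global"`}{one parameter set per orientation from the whole
#'     volume by HOSVD of the phasor tensor (assumes spatially uniform
#'     illumination parameters);}
#'   \item{`"tiled"`}{the adaptive tiled-block strategy: the stack is cut
#'     into half-overlapping tiles, each tile's layers are gated by the
#'     normalized MCNR (threshold `M_t`), low-modulation layers share a
#'     merged composite slice, and tiles whose orientation triple violates
#'     the wave-vector prior fall back to full-field layer estimates;}
#'   \item{`"tiled-no-adapt"`}{tiles with per-layer estimation but no MCNR
#'     gating or anomaly fallback (ablation mode).}
#' }
#'
#' @param stack a [raw_stack()]
#' @param mode estimation mode, see Details
#' @param m half-tile size in pixels (default 64: 128 x 128 tiles)
#' @param mcnr_a percentile constant for the layer score (in (5,10))
#' @param mcnr_threshold modulation threshold `M_t` (default 0.85)
#' @param mask_half_width frequency-mask half-width in bins
#' @param prefilter minimum normalized MCNR for a layer to enter a composite
#' @param quality_floor singular-value ratio below which an estimate is
#'   flagged low-confidence
#' @return an object of class `sim3d_fit` with `print`, `summary`, `coef`
#'   and `plot` methods
#' @export
sim_estimate <- function(stack, mode = c("tiled", "global", "tiled-no-adapt"),
                         m = 64, mcnr_a = 7, mcnr_threshold = 0.85,
                         mask_half_width = 7, prefilter = 0.2,
                         quality_floor = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "raw_stack"))
  n <- stack$n; nz <- stack$nz
  quality <- stack_mcnr(stack, a = mcnr_a, threshold = mcnr_threshold)
  z_ref <- which.max(quality$mcnr_norm)

  # full-field per-layer band stacks (reused for global HOSVD, per-layer
  # fallback estimates and tile search priors)
  b1 <- lapply(1:3, function(d) array(0i, c(n, n, nz)))
  b2 <- lapply(1:3, function(d) array(0i, c(n, n, nz)))
  for (d in 1:3) for (z in seq_len(nz)) {
    bs <- separate_bands(stack$data[d, , z, , , drop = TRUE])
    b1[[d]][, , z] <- bs$bands[["1"]]
    b2[[d]][, , z] <- bs$bands[["2"]]
  }

  if (mode == "global") {
    glob <- lapply(1:3, function(d) {
      estimate_volume_params(list(b1 = b1[[d]], b2 = b2[[d]]),
                             mask_half_width = mask_half_width,
                             focus_layer = z_ref,
                             quality_floor = quality_floor)
    })
    chk <- check_orientation_set(lapply(glob, `[[`, "p_lateral"), grid_n = n)
    fit <- list(mode = mode, config = stack$config, n = n, nz = nz,
                quality = quality, z_ref = z_ref,
                global = glob, check = chk,
                mask_half_width = mask_half_width)
    class(fit) <- "sim3d_fit"
    return(fit)
  }

  # segmentation equivalent to 2m x 2m tiles on the 2x-upsampled grid:
  # raw-grid windows of m x m at stride m/2
  if (m %% 2 != 0) stop("half-tile size m must be even")
  grid <- tile_grid(n, m %/% 2)
  # full-field per-layer estimates: anomaly fallbacks and tile peak priors.
  # The reference layer is estimated without a prior; the remaining layers
  # search near its peaks (the pattern wave vector is nearly z-invariant,
  # while deeply defocused layers alone carry too little modulation to
  # localize from scratch under noise).
  ref_est <- lapply(1:3, function(d) {
    e <- estimate_slice_params(
      band_set_from(list(b1[[d]][, , z_ref], b2[[d]][, , z_ref])),
      mask_half_width = mask_half_width, quality_floor = quality_floor)
    e$source <- "layer"
    e
  })
  layer_est <- list()
  for (z in seq_len(nz)) {
    layer_est[[as.character(z)]] <- if (z == z_ref) ref_est else
      lapply(1:3, function(d) {
        e <- estimate_slice_params(
          band_set_from(list(b1[[d]][, , z], b2[[d]][, , z])),
          mask_half_width = mask_half_width,
          near_p1 = round(ref_est[[d]]$band1$p_band_bins), search_radius = 3,
          quality_floor = quality_floor)
        e$source <- "layer"
        e
      })
  }
  layer_est[["merged"]] <- lapply(layer_est[[as.character(z_ref)]], function(e) {
    e$source <- "layer"
    e
  })
  # tile-level peak priors (bins of the tile grid) from the reference layer
  prior_p1 <- lapply(layer_est[[as.character(z_ref)]], function(e) {
    e$band1$p_band_bins / n * grid$tile_size
  })

  tile_est <- vector("list", grid$n_tiles)
  checks <- vector("list", grid$n_tiles)
  tile_quality <- vector("list", grid$n_tiles)
  for (t in seq_len(grid$n_tiles)) {
    b <- grid$bounds[t, ]
    ys <- (b[1] + 1):b[2]; xs <- (b[3] + 1):b[4]
    tq <- local_quality(quality, ys, xs, mcnr_a, mcnr_threshold)
    tile_quality[[t]] <- tq
    sel <- if (mode == "tiled") select_slices(tq)
           else list(direct = seq_len(nz), merged = integer())
    est_t <- list(); chk_t <- list()
    for (z in sel$direct) {
      ests <- lapply(1:3, function(d) {
        e <- estimate_slice_params(
          stack$data[d, , z, ys, xs, drop = TRUE],
          mask_half_width = mask_half_width,
          near_p1 = round(prior_p1[[d]]), search_radius = 3,
          quality_floor = quality_floor)
        e$source <- "tile"
        e
      })
      zk <- as.character(z)
      est_t[[zk]] <- ests
      chk_t[[zk]] <- check_orientation_set(lapply(ests, `[[`, "p_lateral"),
                                           grid_n = grid$tile_size)
    }
    if (length(sel$merged) > 0) {
      sub <- stack$data[, , , ys, xs, drop = FALSE]
      comp <- merge_block(aperm(sub, c(1, 2, 3, 4, 5)), tq, prefilter = prefilter)
      ests <- lapply(1:3, function(d) {
        e <- estimate_slice_params(comp[d, , , ], mask_half_width = mask_half_width,
                                   near_p1 = round(prior_p1[[d]]),
                                   search_radius = 3,
                                   quality_floor = quality_floor)
        e$source <- "merged-block"
        e
      })
      est_t[["merged"]] <- ests
      chk_t[["merged"]] <- check_orientation_set(lapply(ests, `[[`, "p_lateral"),
                                                 grid_n = grid$tile_size)
    }
    tile_est[[t]] <- est_t
    checks[[t]] <- chk_t
  }
  pf <- if (mode == "tiled") resolve_params(tile_est, layer_est, checks)
        else structure(list(estimates = tile_est,
                            ledger = data.frame(tile = integer(), z = character(),
                                                sd_wv = numeric(), sd_ang = numeric())),
                       class = "param_field")
  fit <- list(mode = mode, config = stack$config, n = n, nz = nz,
              quality = quality, z_ref = z_ref,
              grid = grid, params = pf, layer_estimates = layer_est,
              tile_quality = tile_quality, checks = checks,
              mask_half_width = mask_half_width)
  class(fit) <- "sim3d_fit"
  fit
}

# helper: wrap precomputed first/second-harmonic band spectra into a minimal
# band_set accepted by estimate_slice_params (which only reads bands 1 and 2)
band_set_from <- function(bands12) {
  structure(list(bands = list(`-2` = NULL, `-1` = NULL, `0` = NULL,
                              `1` = bands12[[1]], `2` = bands12[[2]]),
                 orders = -2:2), class = "band_set")
}

# per-tile slice quality from the full-field MCNR maps
local_quality <- function(quality, ys, xs, a, threshold) {
  scores <- vapply(quality$mean_maps, function(mm) slice_score(mm[ys, xs], a), 0)
  if (max(scores) <= 0) scores <- scores + 1e-12
  normalize_scores(scores, a, threshold)
}

#' @export
print.sim3d_fit <- function(x, ...) {
  cat(sprintf("3DSIM illumination fit (mode: %s), %d x %d x %d stack\n",
              x$mode, x$n, x$n, x$nz))
  cat(sprintf("  reference (best-MCNR) layer: %d\n", x$z_ref))
  print(coef(x))
  invisible(x)
}

#' @export
coef.sim3d_fit <- function(object, ...) {
  ests <- representative_estimates(object)
  cfg <- object$config
  do.call(rbind, lapply(1:3, function(d) {
    e <- ests[[d]]
    pm <- sqrt(sum(e$p_lateral^2))
    data.frame(orientation = d,
               p_x = e$p_lateral[1], p_y = e$p_lateral[2],
               p_mag = pm,
               angle_deg = atan2(e$p_lateral[2], e$p_lateral[1]) * 180 / pi,
               phi0 = e$phi0,
               p_z = axial_wavevector(pm, cfg),
               quality = e$quality)
  }))
}

# one representative estimate per orientation (global set, or the reference
# layer's full-field estimates for tiled fits)
representative_estimates <- function(fit) {
  if (fit$mode == "global") fit$global
  else fit$layer_estimates[[as.character(fit$z_ref)]]
}

#' @export
summary.sim3d_fit <- function(object, ...) {
  out <- list(coef = coef(object), mode = object$mode,
              quality = object$quality)
  if (!is.null(object$params)) {
    out$n_tiles <- object$grid$n_tiles
    out$n_anomalous <- nrow(object$params$ledger)
    pmags <- unlist(lapply(object$params$estimates, function(tt) {
      lapply(tt, function(zz) vapply(zz, function(e) sqrt(sum(e$p_lateral^2)), 0))
    }))
    out$p_mag_range <- range(pmags)
  }
  class(out) <- "summary.sim3d_fit"
  out
}

#' @export
print.summary.sim3d_fit <- function(x, ...) {
  cat("3DSIM illumination parameter fit, mode:", x$mode, "\n\n")
  print(x$coef)
  cat("\nlayer MCNR (normalized):",
      paste(sprintf("%.2f", x$quality$mcnr_norm), collapse = " "), "\n")
  if (!is.null(x$n_tiles)) {
    cat(sprintf("tiles: %d (%d anomalous, replaced by layer estimates)\n",
                x$n_tiles, x$n_anomalous))
    cat(sprintf("per-tile |p| range: %.5f .. %.5f cyc/px\n",
                x$p_mag_range[1], x$p_mag_range[2]))
  }
  invisible(x)
}

#' Map of per-tile wave-vector magnitudes (tiled fits)
#'
#' @param x a `sim3d_fit` from a tiled mode
#' @param orientation orientation index (1..3)
#' @param z layer key (character) or `"merged"`; defaults to the reference
#'   layer where available
#' @param ... passed to [graphics::image()]
#' @export
plot.sim3d_fit <- function(x, orientation = 1, z = NULL, ...) {
  if (is.null(x$grid)) {
    graphics::barplot(x$quality$mcnr_norm, names.arg = seq_len(x$nz),
                      xlab = "layer", ylab = "normalized MCNR", ...)
    graphics::abline(h = x$quality$threshold, lty = 2)
    return(invisible(x))
  }
  ns <- x$grid$n_side
  mp <- matrix(NA_real_, ns, ns)
  for (t in seq_len(x$grid$n_tiles)) {
    keys <- names(x$params$estimates[[t]])
    zk <- if (!is.null(z) && z %in% keys) z
          else if (as.character(x$z_ref) %in% keys) as.character(x$z_ref)
          else keys[1]
    e <- x$params$estimates[[t]][[zk]][[orientation]]
    mp[x$grid$ij[t, "i"], x$grid$ij[t, "j"]] <- sqrt(sum(e$p_lateral^2))
  }
  graphics::image(seq_len(ns), seq_len(ns), t(mp[ns:1, , drop = FALSE]),
                  xlab = "tile column", ylab = "tile row",
                  main = sprintf("|p| (cyc/px), orientation %d", orientation), ...)
  invisible(x)
}

#' Reconstruct the super-resolved volume from a fitted stack
#'
#' @param stack the [raw_stack()] the fit was computed from
#' @param fit a `sim3d_fit`
#' @param wcfg a [wiener_config()]
#' @return object of class `sr_volume`: `data` (`[z, 2N, 2N]`), `mode`,
#'   `p_z`, `clamp_fraction`
#' @export
sim_reconstruct <- function(stack, fit, wcfg = wiener_config()) {
  stopifnot(inherits(stack, "raw_stack"), inherits(fit, "sim3d_fit"))
  nz <- stack$nz
  if (fit$mode == "global") {
    otf <- make_otf3d(stack$config, 2L * stack$n, nz,
                      pixel_size_nm = stack$config$pixel_size_nm / 2)
    rec <- reconstruct_subset(stack$data, fit$global, stack$config, otf,
                              wcfg = wcfg, z_ref = fit$z_ref)
    return(structure(list(data = rec$sr, mode = fit$mode, p_z = rec$p_z,
                          clamp_fraction = rec$clamp_fraction,
                          pixel_size_nm = stack$config$pixel_size_nm / 2),
                     class = "sr_volume"))
  }
  grid <- fit$grid
  otf <- make_otf3d(stack$config, 2L * grid$tile_size, nz,
                    pixel_size_nm = stack$config$pixel_size_nm / 2)
  # modulation depths are properties of the illumination, not of a tile:
  # fit the complex band gains once on a central high-signal window and
  # share them across tiles (per-tile fits are unstable on sparse tiles)
  shared_gains <- central_window_gains(stack, fit, wcfg)
  tiles <- vector("list", grid$n_tiles)
  clampf <- 0
  pz <- NA_real_
  for (t in seq_len(grid$n_tiles)) {
    b <- grid$bounds[t, ]
    ys <- (b[1] + 1):b[2]; xs <- (b[3] + 1):b[4]
    est_t <- fit$params$estimates[[t]]
    pars <- lapply(1:3, function(d) {
      lapply(seq_len(nz), function(z) {
        zk <- as.character(z)
        if (!is.null(est_t[[zk]])) est_t[[zk]][[d]]
        else if (!is.null(est_t[["merged"]])) est_t[["merged"]][[d]]
        else fit$layer_estimates[[zk]][[d]]
      })
    })
    rec <- reconstruct_subset(stack$data[, , , ys, xs, drop = FALSE],
                              pars, stack$config, otf,
                              wcfg = wcfg, z_ref = fit$z_ref,
                              gains = shared_gains)
    tiles[[t]] <- rec$sr
    clampf <- clampf + rec$clamp_fraction / grid$n_tiles
    pz <- rec$p_z
  }
  fused <- fuse_grid(tiles, grid, upsample = 2)
  structure(list(data = fused, mode = fit$mode, p_z = pz,
                 clamp_fraction = clampf,
                 pixel_size_nm = stack$config$pixel_size_nm / 2),
            class = "sr_volume")
}

# translate a phase referenced at the field origin to a window origin
translate_phi0 <- function(est, x0, y0) {
  est$phi0 <- wrap_pi(est$phi0 + 2 * pi * sum(est$p_lateral * c(x0, y0)))
  est
}

# complex band gains fitted on a central high-signal window using the
# full-field per-layer parameter estimates
central_window_gains <- function(stack, fit, wcfg) {
  n <- stack$n; nz <- stack$nz
  win <- min(128L, n)
  y0 <- (n - win) %/% 2L; x0 <- (n - win) %/% 2L
  ys <- (y0 + 1):(y0 + win); xs <- (x0 + 1):(x0 + win)
  pars <- lapply(1:3, function(d) {
    lapply(seq_len(nz), function(z) {
      translate_phi0(fit$layer_estimates[[as.character(z)]][[d]], x0, y0)
    })
  })
  otf_w <- make_otf3d(stack$config, 2L * win, nz,
                      pixel_size_nm = stack$config$pixel_size_nm / 2)
  rec <- reconstruct_subset(stack$data[, , , ys, xs, drop = FALSE],
                            pars, stack$config, otf_w,
                            wcfg = wcfg, z_ref = fit$z_ref)
  rec$gains
}

#' @export
print.sr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("super-resolution volume: %d x %d x %d layers (%s mode), %.3g nm/px\n",
              d[2], d[3], d[1], x$mode, x$pixel_size_nm))
  if (x$clamp_fraction > 0)
    cat(sprintf("  %.2f%% of voxels clamped at zero\n", 100 * x$clamp_fraction))
  invisible(x)
}

#' @export
plot.sr_volume <- function(x, z = ceiling(dim(x$data)[1] / 2), ...) {
  m <- x$data[z, , ]
  graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, main = sprintf("SR layer %d", z), ...)
  invisible(x)
}

#' Run the full reconstruction pipeline
#'
#' Segmentation, MCNR gating, parameter estimation, anomaly resolution,
#' per-subset reconstruction and fusion, with optional report files: the SR
#' volume as TIFF, the per-tile parameter table as TSV, and a JSON manifest.
#'
#' @param stack a [raw_stack()]
#' @param mode estimation mode, see [sim_estimate()]
#' @param out_dir optional output directory for reports
#' @param wcfg a [wiener_config()]
#' @param ... further arguments to [sim_estimate()]
#' @return list with `fit`, `sr` and (if written) `paths`
#' @export
run_pipeline <- function(stack, mode = "tiled", out_dir = NULL,
                         wcfg = wiener_config(), ...) {
  fit <- sim_estimate(stack, mode = mode, ...)
  sr <- sim_reconstruct(stack, fit, wcfg = wcfg)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      sr_tiff = file.path(out_dir, "sr.tif"),
      manifest = file.path(out_dir, "manifest.json"))
    write_stack_tiff(sr$data, paths$sr_tiff)
    if (!is.null(fit$grid)) {
      paths$params_tsv <- file.path(out_dir, "params.tsv")
      write_params_tsv(fit$params, fit$grid, paths$params_tsv)
    }
    manifest <- list(mode = mode, n = fit$n, nz = fit$nz,
                     z_ref = fit$z_ref,
                     config = unclass(fit$config),
                     wiener = unclass(wcfg),
                     package_version = as.character(utils::packageVersion("sim3dr")))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(fit = fit, sr = sr, paths = paths)
}
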