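#' Reconstruction (generalized Wiener) configuration
#'
#' @param w Wiener regularization constant, relative to the peak-normalized
#'   OTF (default 0.05)
#' @param apodization `"cosine"` (raised-cosine roll-off to the extended
#'   cutoff, the default: it suppresses edge ringing while keeping the
#'   doubled passband usable), `"triangle"` (linear roll-off, more
#'   conservative), or `"none"`
#' @param otf_floor minimum OTF value (fraction of its maximum) for a
#'   frequency to enter modulation-depth fits
#' @param min_overlap minimum overlap-region size for modulation-depth fits
#' @param clamp_negative clamp negative intensities in the final volume
#' @param upsample_lateral lateral upsampling factor (1 or 2; default 2)
#' @return object of class `wiener_config`
#' @export
wiener_config <- function(w = 0.05, apodization = c("cosine", "triangle", "none"),
                          otf_floor = 0.05, min_overlap = 50,
                          clamp_negative = TRUE, upsample_lateral = 2) {
  stopifnot(w > 0, upsample_lateral %in% c(1, 2))
  structure(list(w = w, apodization = match.arg(apodization),
                 otf_floor = otf_floor, min_overlap = min_overlap,
                 clamp_negative = clamp_negative,
                 upsample_lateral = upsample_lateral),
            class = "wiener_config")
}

# raised-cosine edge profile of length n with taper width t on both ends
taper_profile <- function(n, t) {
  w <- rep(1, n)
  if (t > 0) {
    idx <- seq_len(t)
    ramp <- 0.5 * (1 - cos(pi * (idx - 0.5) / t))
    w[idx] <- ramp
    w[n + 1 - idx] <- ramp
  }
  w
}

#' Shift a band spectrum by a real-valued lateral wave vector
#'
#' Embeds the spectrum on the zero-padded (2x) lateral grid, applies the
#' integer-bin part of the shift as an array roll and the sub-pixel remainder
#' as a spatial-domain linear phase ramp. Energy is conserved (roll and unit
#' ramp are unitary). The shift moves content located at `+p` to the origin,
#' i.e. returns `B(k + p)`.
#'
#' @param spec complex lateral spectrum, `[ky, kx]` or `[ky, kx, z]`
#'   (unshifted layout, raw grid of side `n_raw`)
#' @param p length-2 shift `(px, py)` in cycles/(raw pixel); may also be an
#'   `nz x 2` matrix of per-layer shifts for 3-D input
#' @param pad zero-pad laterally by 2x before shifting (default TRUE)
#' @param n_raw raw-grid side defining the cycles/pixel unit of `p`;
#'   defaults to the input side. Pass the original raw side when feeding an
#'   already padded spectrum back in (with `pad = FALSE`).
#' @return shifted complex spectrum on the (padded) grid
#' @export
shift_band <- function(spec, p, pad = TRUE, n_raw = dim(spec)[1]) {
  d <- dim(spec)
  stopifnot(d[2] == d[1])
  arr3 <- length(d) == 3
  nz <- if (arr3) d[3] else 1L
  pm <- if (is.matrix(p)) p else matrix(p, nz, 2, byrow = TRUE)
  stopifnot(nrow(pm) == nz, ncol(pm) == 2)
  s_bins <- pm * n_raw                       # shift in frequency bins
  if (max(abs(s_bins)) > n_raw * (if (pad) 1 else 0.5))
    stop("requested band shift exceeds the grid")
  x <- if (arr3) spec else array(spec, c(d, 1L))
  if (pad) x <- fourier_pad2(x)
  np <- dim(x)[1]
  si <- round(s_bins)
  frac <- s_bins - si
  out <- array(0i, dim(x))
  # group layers sharing an integer roll so lateral FFTs stay batched
  key <- paste(si[, 1], si[, 2])
  for (k in unique(key)) {
    zs <- which(key == k)
    # B(k + s): content at bin s moves to 0 -> roll by -s
    xs <- roll(x[, , zs, drop = FALSE], c(-si[zs[1], 2], -si[zs[1], 1], 0))
    if (any(frac[zs, ] != 0)) {
      img <- ifft2(xs)
      idx <- 0:(np - 1)
      for (jj in seq_along(zs)) {
        z <- zs[jj]
        ramp <- outer(exp(-2i * pi * frac[z, 2] * idx / np),
                      exp(-2i * pi * frac[z, 1] * idx / np))
        img[, , jj] <- img[, , jj] * ramp
      }
      xs <- fft2(img)
    }
    out[, , zs] <- xs
  }
  if (arr3) out else out[, , 1]
}

#' Per-band OTFs with the axially extended first-order support
#'
#' The 0- and 2-order bands see the widefield OTF itself; the +/-1-order
#' bands, whose axial modulation splits their spectrum, see the axially
#' extended average `(O(kxy, kz - p_z) + O(kxy, kz + p_z)) / 2`. Axial shifts
#' by the (generally fractional) `p_z` use circular linear interpolation
#' along `kz`.
#'
#' @param otf an [make_otf3d()] object
#' @param p_z axial wave vector in cycles per z-step
#' @return list with elements `m0`, `m1`, `m2`: real arrays of the same shape
#'   as `otf$values`
#' @export
assemble_band_otfs <- function(otf, p_z) {
  O <- otf$values
  nz <- dim(O)[3]
  if (abs(p_z) * nz > nz / 2 + 1e-9) stop("p_z beyond the axial Nyquist limit")
  dz_bins <- p_z * nz
  m1 <- (shift_otf_kz(O, -dz_bins) + shift_otf_kz(O, dz_bins)) / 2
  list(m0 = O, m1 = m1, m2 = O)
}

# O evaluated at (kxy, kz + dz_bins): circular linear interpolation along kz
shift_otf_kz <- function(O, dz_bins) {
  i0 <- floor(dz_bins); f <- dz_bins - i0
  a <- roll(O, c(0, 0, -i0))
  if (f == 0) return(a)
  b <- roll(O, c(0, 0, -(i0 + 1)))
  (1 - f) * a + f * b
}

# O evaluated at (kx + dx_bins, ky + dy_bins, kz): circular bilinear
# interpolation. An interpolated (slightly smoothed) OTF matches the
# observed band transfer of finite-window data better than the analytically
# exact shifted OTF: the pattern carrier is incommensurate with the field,
# so each band's effective transfer is the exact OTF convolved with a
# narrow window kernel. The smoothing also keeps the near-singular kz = 0
# ridge of the 3-D OTF from dominating the modulation-gain fits.
shift_otf_lat <- function(O, dx_bins, dy_bins) {
  ix <- floor(dx_bins); fx <- dx_bins - ix
  iy <- floor(dy_bins); fy <- dy_bins - iy
  r <- function(ddy, ddx) roll(O, c(-ddy, -ddx, 0))
  (1 - fy) * (1 - fx) * r(iy, ix) + (1 - fy) * fx * r(iy, ix + 1) +
    fy * (1 - fx) * r(iy + 1, ix) + fy * fx * r(iy + 1, ix + 1)
}

# apodization weight on the padded reconstruction grid
apodization_filter <- function(np, nz, k_lat_max, k_ax_max, n_raw,
                               shape = "cosine") {
  kxy <- fft_bins(np) / n_raw                # cycles/raw-pixel (padded grid)
  kz <- fft_bins(nz) / nz                    # cycles/z-step
  r_lat <- sqrt(outer(kxy^2, kxy^2, `+`)) / k_lat_max
  a <- array(0, c(np, np, nz))
  for (iz in seq_len(nz)) {
    rho <- pmin(sqrt(r_lat^2 + (kz[iz] / k_ax_max)^2), 1)
    a[, , iz] <- if (shape == "cosine") cos(pi * rho / 2) else pmax(0, 1 - rho)
  }
  a
}

#' Generalized Wiener recombination of shifted bands
#'
#' Combines frequency-aligned band components into the super-resolved
#' spectrum using the band-equalized generalized Wiener filter:
#' `SR(k) = A(k) sum_c conj(O_c) B_c / g_c / (sum_c |O_c|^2 + w^2)`
#' where `B_c` are the recentred band spectra (each carrying its complex
#' gain `g_c`, which is divided out), `O_c` their (shifted) OTFs and `A`
#' the apodization. For unit gains this is the textbook generalized Wiener
#' deconvolution; `w` is interpreted relative to the peak-normalized OTFs.
#'
#' @param components list of components, each a list with `spec` (complex 3-D
#'   band spectrum), `otf` (matching real array), `gain` (complex scalar)
#' @param cfg a [wiener_config()]
#' @param apod optional precomputed apodization array (1 to disable)
#' @return complex SR spectrum
#' @export
wiener_combine <- function(components, cfg = wiener_config(), apod = 1) {
  if (length(components) == 0) stop("empty band set")
  dd <- dim(components[[1]]$spec)
  num <- array(0i, dd)
  den <- array(0, dd)
  for (comp in components) {
    num <- num + Conj(comp$otf) * comp$spec / comp$gain
    den <- den + comp$otf^2
  }
  num / (den + cfg$w^2) * apod
}

# normalize the per-orientation parameter spec into a lookup by layer;
# accepts fitted estimates, plain (p_lateral, phi0) lists, or true
# illumination parameters from the simulator
params_by_layer <- function(par_d, nz) {
  if (inherits(par_d, "param_estimate") || inherits(par_d, "illum_params") ||
      !is.null(par_d$p_lateral)) {
    return(rep(list(par_d), nz))
  }
  stopifnot(length(par_d) == nz)
  par_d
}

#' Super-resolution reconstruction of one (sub-)stack
#'
#' Runs the per-orientation reconstruction chain: band separation per layer,
#' lateral shifting onto the 2x grid with per-layer parameters, axial
#' demodulation of the two first-order copies, modulation-gain estimation
#' against the 0-order band, generalized Wiener recombination over all seven
#' components per orientation, apodization and inverse transform.
#'
#' @param data 5-D array `[3, 5, nz, ny, nx]` (a full stack or one tile)
#' @param params list of 3 entries (one per orientation): a single
#'   `param_estimate` applied to all layers, or a list of per-layer estimates
#' @param cfg a [sim_config()]
#' @param otf fine-grid OTF from [make_otf3d()] with
#'   `pixel_size_nm = cfg$pixel_size_nm / 2`, shape `[2 ny, 2 ny, nz]`
#' @param wcfg a [wiener_config()]
#' @param z_ref reference (focus) layer index: the axial demodulation ramps
#'   are phased so this layer carries zero axial phase. Use the MCNR-best
#'   layer.
#' @param p_z axial wave vector (cycles/z-step); derived from the mean
#'   estimated lateral wave vector and the beam geometry when NULL
#' @param gains optional list of 3 complex length-6 vectors (per orientation:
#'   +2, -2, +1 upper/lower, -1 upper/lower band gains) overriding the
#'   per-subset modulation-depth fits; used to share gains measured on the
#'   full field across tiles
#' @return list: `sr` (`[nz, 2ny, 2nx]` real array), `gains` (per-orientation
#'   complex modulation gains), `p_z`, `clamp_fraction`
#' @export
reconstruct_subset <- function(data, params, cfg, otf = NULL,
                               wcfg = wiener_config(), z_ref = 1, p_z = NULL,
                               gains = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 5, d[1] == 3, d[2] == 5, d[4] == d[5])
  nz <- d[3]; n <- d[4]; np <- 2L * n
  if (is.null(otf)) {
    otf <- make_otf3d(cfg, np, nz, pixel_size_nm = cfg$pixel_size_nm / 2)
  }
  stopifnot(all(dim(otf$values) == c(np, np, nz)))
  pars <- lapply(1:3, function(dd) params_by_layer(params[[dd]], nz))
  if (is.null(p_z)) {
    pmags <- vapply(1:3, function(dd) {
      mean(vapply(pars[[dd]], function(e) sqrt(sum(e$p_lateral^2)), 0))
    }, 0)
    p_z <- axial_wavevector(mean(pmags), cfg)
  }
  O <- otf$values
  zseq <- (seq_len(nz) - z_ref)               # axial coordinate wrt focus layer
  axial_plus <- exp(-2i * pi * p_z * zseq)    # demodulates the +p_z copy
  num <- array(0i, c(np, np, nz))
  den <- array(0, c(np, np, nz))
  mean_pmag <- 0
  gains_out <- vector("list", 3)
  for (dd in 1:3) {
    # per-layer band separation (lateral spectra)
    b <- vector("list", 5)
    for (m in 1:5) b[[m]] <- array(0i, c(n, n, nz))
    for (z in seq_len(nz)) {
      bs <- separate_bands(data[dd, , z, , , drop = TRUE])
      for (m in 1:5) b[[m]][, , z] <- bs$bands[[m]]   # order -2..2
    }
    pl <- t(vapply(pars[[dd]], function(e) e$p_lateral, c(0, 0)))  # nz x 2
    ph0 <- vapply(pars[[dd]], function(e) e$phi0, 0)
    mean_pmag <- mean_pmag + mean(sqrt(rowSums(pl^2))) / 3
    # 0-order reference band on the padded grid
    B0 <- fftz(shift_band(b[[3]], matrix(0, nz, 2)))
    comps <- list(list(spec = B0, otf = O, gain = 1 + 0i))
    phase_corr <- function(spec, ph) {       # per-layer phase alignment
      sweep(spec, 3, exp(-1i * ph), `*`)
    }
    side <- list(
      list(b = b[[5]], shift = +2, harm = 2),   # +2 band
      list(b = b[[1]], shift = -2, harm = 2),   # -2 band
      list(b = b[[4]], shift = +1, harm = 1),   # +1 band
      list(b = b[[2]], shift = -1, harm = 1)    # -1 band
    )
    gidx <- 0
    add_comp <- function(spec3, Om) {
      gidx <<- gidx + 1
      g <- if (!is.null(gains)) gains[[dd]][gidx]
           else estimate_modulation_depth(spec3, B0, Om, O,
                                          otf_floor = wcfg$otf_floor,
                                          min_overlap = wcfg$min_overlap)$gain
      comps[[length(comps) + 1]] <<- list(spec = spec3, otf = Om, gain = g)
    }
    for (sb in side) {
      sh <- shift_band(sb$b, sb$shift * pl)
      sh <- phase_corr(sh, sb$shift * ph0)
      s_bins <- colMeans(sb$shift * pl) * n
      Om <- shift_otf_lat(O, s_bins[1], s_bins[2])
      if (sb$harm == 2) {
        add_comp(fftz(sh), Om)
      } else {
        # the two axial copies of the 1-order band: demodulating by
        # exp(-+ 2i pi p_z z) recentres one copy and shifts its OTF by
        # +- p_z along kz — this is the axial support extension
        for (sgn in c(1, -1)) {
          ax <- if (sgn > 0) axial_plus else Conj(axial_plus)
          add_comp(fftz(sweep(sh, 3, ax, `*`)),
                   shift_otf_kz(Om, sgn * p_z * nz))
        }
      }
    }
    gains_out[[dd]] <- vapply(comps[-1], function(cc) cc$gain, 0i)
    for (cc in comps) {
      # band-equalized accumulation: divide each band by its complex gain
      num <- num + Conj(cc$otf) * cc$spec / cc$gain
      den <- den + cc$otf^2
    }
  }
  apod <- 1
  if (wcfg$apodization != "none") {
    # widefield cutoff in cycles/raw-pixel plus the second-harmonic shift
    k_lat_max <- 2 * cfg$na / cfg$wavelength_em_nm * cfg$pixel_size_nm + 2 * mean_pmag
    k_ax_max <- otf$cutoff_axial + abs(p_z)
    apod <- apodization_filter(np, nz, k_lat_max, k_ax_max, n,
                               shape = wcfg$apodization)
  }
  sr_spec <- num / (den + wcfg$w^2) * apod
  sr <- Re(ifft3(sr_spec))
  clamp_fraction <- 0
  if (wcfg$clamp_negative) {
    clamp_fraction <- mean(sr < 0)
    sr[sr < 0] <- 0
  }
  list(sr = aperm(sr, c(3, 1, 2)), gains = gains_out, p_z = p_z,
       clamp_fraction = clamp_fraction)
}

#' Widefield volume of a raw stack (mean over orientations and phases)
#'
#' @param stack a [raw_stack()]
#' @return `[z, y, x]` real array on the raw lateral grid
#' @export
reconstruct_widefield <- function(stack) {
  d <- dim(stack$data)
  wf <- colMeans(matrix(stack$data, 15, prod(d[3:5])))
  array(wf, d[3:5])
}
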