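#' Optical system configuration
#'
#' Collects the physical acquisition metadata shared by the simulator,
#' the OTF model and the reconstruction: wavelengths, numerical aperture,
#' immersion index, samplings, and the three-beam interference half-angle.
#'
#' @param wavelength_exc_nm excitation wavelength (nm)
#' @param wavelength_em_nm emission wavelength (nm)
#' @param na numerical aperture of the objective
#' @param n_imm immersion refractive index (must exceed `na`)
#' @param pixel_size_nm lateral sampling of the raw camera grid (nm/pixel)
#' @param z_step_nm axial sampling (nm/layer)
#' @param beam_angle_beta angle (radians) between the centre illumination beam
#'   and each side beam. The default places the pattern second harmonic `2p`
#'   at 90% of the widefield emission cutoff `2 NA / lambda_em`, so the
#'   second-harmonic spectral peak stays inside the detection passband and is
#'   directly localizable, while still extending lateral support by ~1.9x.
#'   Must lie in (0, pi/2).
#' @return an object of class `sim_config`
#' @export
sim_config <- function(wavelength_exc_nm = 488,
                       wavelength_em_nm = 525,
                       na = 1.4,
                       n_imm = 1.518,
                       pixel_size_nm = 62.5,
                       z_step_nm = 125,
                       beam_angle_beta = asin(0.9 * (na / n_imm) *
                                              wavelength_exc_nm / wavelength_em_nm)) {
  stopifnot(wavelength_exc_nm > 0, wavelength_em_nm > 0,
            na > 0, pixel_size_nm > 0, z_step_nm > 0)
  if (!(na < n_imm)) stop("numerical aperture must be smaller than the immersion index")
  if (!(beam_angle_beta > 0 && beam_angle_beta < pi / 2))
    stop("beam_angle_beta must lie in (0, pi/2)")
  structure(list(
    wavelength_exc_nm = wavelength_exc_nm,
    wavelength_em_nm = wavelength_em_nm,
    na = na,
    n_imm = n_imm,
    pixel_size_nm = pixel_size_nm,
    z_step_nm = z_step_nm,
    beam_angle_beta = beam_angle_beta
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("3DSIM system configuration\n")
  cat(sprintf("  excitation/emission: %g / %g nm\n",
              x$wavelength_exc_nm, x$wavelength_em_nm))
  cat(sprintf("  NA %g, immersion n %g, beam half-angle %.2f deg\n",
              x$na, x$n_imm, x$beam_angle_beta * 180 / pi))
  cat(sprintf("  sampling: %g nm/px lateral, %g nm/layer axial\n",
              x$pixel_size_nm, x$z_step_nm))
  invisible(x)
}

#' Raw 3DSIM acquisition stack
#'
#' Canonical container for a raw acquisition: a 5-D intensity array indexed
#' `[orientation, phase, z, y, x]` with exactly 3 orientations and 5 phase
#' steps per layer (15 frames per z-layer), plus the system configuration.
#'
#' @param data 5-D numeric array `[3, 5, nz, ny, nx]`, non-negative, with
#'   `ny == nx` (square field)
#' @param config a [sim_config()]
#' @param validate check invariants (shape, non-negativity)
#' @return an object of class `raw_stack`
#' @export
raw_stack <- function(data, config, validate = TRUE) {
  d <- dim(data)
  if (validate) {
    if (length(d) != 5) stop("raw stack data must be a 5-D array [d, n, z, y, x]")
    if (d[1] != 3) stop("exactly 3 illumination orientations are required")
    if (d[2] != 5) stop("exactly 5 phase steps are required")
    if (d[4] != d[5]) stop("field must be square (y and x extents equal)")
    if (anyNA(data) || any(!is.finite(data))) stop("stack contains non-finite values")
    if (min(data) < 0) stop("raw intensities must be non-negative")
    stopifnot(inherits(config, "sim_config"))
  }
  structure(list(data = data, config = config,
                 n = d[5], nz = d[3]), class = "raw_stack")
}

#' @export
print.raw_stack <- function(x, ...) {
  cat(sprintf("raw 3DSIM stack: %d x %d px, %d layers, 3 orientations x 5 phases\n",
              x$n, x$n, x$nz))
  invisible(x)
}

#' Supported raw-frame ordering dialects
#'
#' Vendors interleave the 15 frames per layer differently; all conversion to
#' the canonical `[orientation, phase, z, y, x]` layout happens here.
#'
#' * `"pzd"`: phase fastest, then z, then orientation (OMX-style).
#' * `"pdz"`: phase fastest, then orientation, then z (N-SIM-style).
#' * `"dpz"`: orientation fastest, then phase, then z.
#' @export
ordering_dialects <- function() c("pzd", "pdz", "dpz")

# frame index (1-based) of (d, n, z) under a dialect, given nz
frame_index <- function(d, n, z, nz, dialect) {
  switch(dialect,
    pzd = (d - 1) * 5 * nz + (z - 1) * 5 + n,
    pdz = (z - 1) * 15 + (d - 1) * 5 + n,
    dpz = (z - 1) * 15 + (n - 1) * 3 + d,
    stop("unknown ordering dialect: ", dialect)
  )
}

#' Canonicalize a flat frame sequence into a raw stack
#'
#' @param frames either a 3-D array `[frame, y, x]` or a list of equally sized
#'   matrices, with `15 * nz` frames in total
#' @param config a [sim_config()]
#' @param ordering one of [ordering_dialects()]
#' @return a [raw_stack()]
#' @seealso [flatten_stack()] for the inverse operation
#' @export
canonicalize_ordering <- function(frames, config, ordering = "pzd") {
  if (!ordering %in% ordering_dialects())
    stop("unknown ordering dialect: ", ordering)
  if (is.list(frames)) {
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  if (length(dim(frames)) != 3) stop("frames must be [frame, y, x]")
  nf <- dim(frames)[1]
  if (nf %% 15 != 0)
    stop("malformed stack: frame count ", nf, " is not a multiple of 15")
  nz <- nf %/% 15
  ny <- dim(frames)[2]; nx <- dim(frames)[3]
  out <- array(0, c(3, 5, nz, ny, nx))
  for (d in 1:3) for (n in 1:5) for (z in 1:nz) {
    out[d, n, z, , ] <- frames[frame_index(d, n, z, nz, ordering), , ]
  }
  raw_stack(out, config)
}

#' Flatten a raw stack back into a frame sequence under a dialect
#'
#' @param stack a [raw_stack()]
#' @param ordering one of [ordering_dialects()]
#' @return a 3-D array `[frame, y, x]`
#' @export
flatten_stack <- function(stack, ordering = "pzd") {
  if (!ordering %in% ordering_dialects())
    stop("unknown ordering dialect: ", ordering)
  nz <- stack$nz
  out <- array(0, c(15 * nz, stack$n, stack$n))
  for (d in 1:3) for (n in 1:5) for (z in 1:nz) {
    out[frame_index(d, n, z, nz, ordering), , ] <- stack$data[d, n, z, , ]
  }
  out
}

#' Per-orientation illumination parameters
#'
#' @param p_lateral length-2 numeric, first-harmonic lateral wave vector in
#'   cycles/pixel `(px, py)`; its modulus must stay below the lateral Nyquist
#'   limit of 0.5 cycles/pixel
#' @param phi0 initial phase (radians) of the illumination first harmonic at
#'   pixel (0,0) of the analysed region; reported wrapped to (-pi, pi]
#' @param a modulation depths `(a0, a1, a2)` of the 0/1/2-order harmonics
#' @param p_z axial wave vector in cycles per z-step (may be NA until derived)
#' @return an object of class `illum_params`
#' @export
illum_params <- function(p_lateral, phi0, a = c(1, 2 / 3, 1 / 3), p_z = NA_real_) {
  stopifnot(length(p_lateral) == 2, length(a) == 3)
  if (!(a[1] > 0)) stop("a0 must be positive")
  if (sqrt(sum(p_lateral^2)) >= 0.5)
    stop("|p_lateral| must be below the lateral Nyquist limit (0.5 cycles/pixel)")
  structure(list(p_lateral = as.numeric(p_lateral),
                 phi0 = wrap_pi(phi0),
                 a = as.numeric(a),
                 p_z = p_z), class = "illum_params")
}

#' @export
print.illum_params <- function(x, ...) {
  cat(sprintf("illumination: p = (%.5f, %.5f) cyc/px (|p| %.5f), phi0 %.3f rad, a = (%.3g, %.3g, %.3g), p_z %s cyc/step\n",
              x$p_lateral[1], x$p_lateral[2], sqrt(sum(x$p_lateral^2)),
              x$phi0, x$a[1], x$a[2], x$a[3],
              ifelse(is.na(x$p_z), "NA", sprintf("%.4f", x$p_z))))
  invisible(x)
}
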