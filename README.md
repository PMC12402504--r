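# sim3dr

Adaptive tiled PCA parameter estimation and reconstruction for
three-dimensional structured illumination microscopy (3DSIM), in R.

## The problem

3DSIM doubles lateral and axial resolution by exciting the specimen with a
three-beam interference pattern (five phase steps in three orientations, 15
frames per z-layer) and computationally reassembling the seven overlapping
spectral bands each frame encodes. Reconstruction quality hinges on knowing
the illumination parameters — the lateral wave vector $p$, the initial
phase $\varphi_0$, the modulation depths $a_n$ and the axial frequency
$p_z$ — to a small fraction of a frequency bin. On real microscopes these
parameters drift across the field of view and along the stack (aberrations,
stage errors, fluorescence heterogeneity), so a single global parameter set
produces ghosting artifacts.

This package estimates the parameters by principal component analysis of
the band *phasor fields*: after band separation and integer peak
recentring, the ideal phasor $e^{i(2\pi p_{\rm sub}\cdot r + 2\varphi_0)}$
is a rank-one matrix (or Tucker-rank-one tensor over a stack), so its
dominant singular vectors are complex exponentials whose phase slopes give
the sub-pixel wave vector. A frequency-domain mask suppresses the noise
floor before the SVD. Spatial parameter variation is handled by an adaptive
tiled-block strategy: the stack is cut into half-overlapping tiles
(128×128 on the 2× grid), each tile's layers are gated by the modulation
contrast-to-noise ratio (MCNR), low-modulation layers share a merged
composite slice, tiles violating the three-orientation wave-vector prior
fall back to full-field layer estimates, and per-tile reconstructions are
fused with sigmoid-weighted blending. Reconstruction itself is a
band-equalized generalized Wiener filter with an axially extended
first-order OTF. A full three-beam-interference simulator (with
controllable wave-vector gradients, per-layer stage jitter, and Gaussian
noise) makes every stage testable against known ground truth.

## Worked example

```r
library(sim3dr)

cfg <- sim_config()                     # 100x/1.4NA oil, 488/525 nm, 62.5 nm px
dist <- distortion_field(wv_error_px = c(-0.5, 0.5),   # wave vector ramps across x
                         z_displacement_nm = c(-3, 3), # stage jitter per layer
                         noise_power_dbw = 5, seed = 7)
sim <- simulate_sim3d(n = 128, nz = 8, cfg = cfg, distortion = dist, seed = 7)

fit <- sim_estimate(sim$stack, mode = "tiled")
fit
#> 3DSIM illumination fit (mode: tiled), 128 x 128 x 8 stack
#>   reference (best-MCNR) layer: 4
#>   orientation        p_x        p_y     p_mag angle_deg         phi0       p_z  quality
#> 1           1  0.1448287 0.03882818 0.1499433  15.00791  0.005877356 0.1414118 6.359419
#> 2           2  0.0388666 0.14484492 0.1499689  74.97951  0.685628121 0.1414359 7.216494
#> 3           3 -0.1059149 0.10600798 0.1498521 134.97485 -1.450022536 0.1413258 6.274547

sr <- sim_reconstruct(sim$stack, fit)
sr
#> super-resolution volume: 256 x 256 x 8 layers (tiled mode), 31.2 nm/px
#>   29.58% of voxels clamped at zero

summary(fit)
#> ...
#> layer MCNR (normalized): 0.32 0.47 0.87 1.00 0.69 0.37 0.65 0.62
#> tiles: 9 (0 anomalous, replaced by layer estimates)
#> per-tile |p| range: 0.14782 .. 0.15234 cyc/px
```

`coef(fit)` returns the per-orientation wave vectors (cycles/pixel), their
magnitudes and angles (the three orientations sit 60° apart modulo 180°),
the initial phases, and the axial wave vector in cycles per z-step derived
from the beam geometry ($p_z = p\tan(\beta/2)$). Here the recovered
magnitudes (0.14985–0.14997) are the field averages of the simulated
±0.5-bin ramp around the true 0.14995, the angles sit within 0.03° of the
simulated 15/75/135°, and the per-tile range 0.14782–0.15234 cyc/px tracks
the ramp itself — `plot(fit)` maps it. The `quality` column is the
first-to-second singular value ratio of the phasor fit — the margin by
which the phasor is rank-one; values near 1 mean an unreliable estimate,
and such tiles are automatically replaced by full-field layer estimates
(`summary(fit)` reports how many). The displayed `phi0` belongs to the
reference layer's full-field fit; under a wave-vector gradient the global
phase intercept is an extrapolated plane fit, and the per-tile phases are
what reconstruction actually consumes.

A command-line front end over the same functions lives in
`inst/cli/sim3dr.R`:

```sh
Rscript inst/cli/sim3dr.R simulate --out raw.tif --size 256 --layers 12 --seed 1
Rscript inst/cli/sim3dr.R mcnr-report raw.tif --out report.tsv
Rscript inst/cli/sim3dr.R reconstruct raw.tif --mode tiled --out sr.tif
```

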