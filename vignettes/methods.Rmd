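---
title: "Adaptive tiled PCA parameter estimation for 3DSIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive tiled PCA parameter estimation for 3DSIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sim3dr)
```

## The imaging model

Three-dimensional structured illumination microscopy (3DSIM) excites the
specimen with the interference pattern of three coherent beams: a centre
beam and two side beams at an angle $\beta$ to it. The intensity seen by a
fluorophore at lateral position $r$ and depth $z$ is

$$
I(r, z) = a_0 + 2 a_1 \cos(2\pi p\cdot r + \varphi)\,
          \cos(2\pi p_z (z - z_f)) + a_2 \cos(2(2\pi p\cdot r + \varphi)),
$$

where $p$ is the lateral wave vector of the first harmonic, $p_z$ the axial
modulation frequency, $\varphi = \varphi_0 + n\,2\pi/5$ the pattern phase at
step $n$, and the modulation depths derive from the beam field amplitudes:
$a_0 = E_0^2 + 2E_1^2$, $a_1 = 2E_0E_1$, $a_2 = 2E_1^2$. Because the
intensity is a squared field modulus it is automatically non-negative. The
beam geometry ties the axial to the lateral modulation frequency:

$$
\frac{p}{\sin\beta} = \frac{p_z}{1-\cos\beta}
\quad\Longleftrightarrow\quad
p_z = p \tan(\beta/2).
$$

Each camera frame is the widefield image of the modulated object, so its
lateral spectrum is the sum of five overlapping copies of the object
spectrum: the 0-order (widefield) band, a pair of $\pm 1$-order bands
displaced laterally by $\pm p$ and split axially into $k_z \pm p_z$
components (seven components in total), and a pair of $\pm 2$-order bands
displaced by $\pm 2p$ that carry the lateral resolution doubling.
Reconstruction requires $p$, $\varphi_0$, the modulation depths, and $p_z$
with sub-pixel accuracy; errors of a fraction of a frequency bin already
produce visible ghosting.

## Parameter estimation as a principal-component problem

With five phase steps the bands are separated exactly by inverting the
known $5\times 5$ mixing matrix $e^{i m n \Delta\varphi}$,
$\Delta\varphi = 2\pi/5$. After locating the integer-bin peak of a side
band and rolling it to the origin, the remaining information is the phasor

$$
e^{\,i(2\pi\,p_{\mathrm{sub}}\cdot r + h\varphi_0)},
$$

a unit-modulus plane whose slope is the sub-pixel wave-vector residual and
whose value at the origin carries $h\varphi_0$ ($h = 2$ for the second
harmonic). Every matrix unfolding of this field — and of its 3-D tensor
extension over a stack — is rank one, so its first singular vectors are
complex exponentials. The estimator therefore takes the dominant singular
pair (the tensor case uses the x- and y-mode unfoldings, a higher-order
SVD), reads the phase slopes of the singular vectors, and reads
$\varphi_0$ from the rank-one reconstruction at the analysis origin.
Noise, out-of-focus haze, and object structure live in the higher
principal components and are discarded.

Three numerical choices matter in practice and are this package's own:

* **Peak search order.** The second-harmonic peak sits near the edge of
  the detection passband where the OTF transmits only a few per cent;
  a global argmax on that band can lose against low-frequency object
  content. The first-harmonic peak is strongly transmitted, so the
  estimator locates it first and searches the second-harmonic band only
  within a few bins of twice that location. The same mechanism accepts a
  prior from a full-field estimate when analysing small tiles.
* **Phase slopes.** The singular-vector phase slope is first estimated by
  the argument of the lag-1 autocorrelation, which is exact for a clean
  exponential and cannot suffer $2\pi$ unwrap failures, and then refined
  by unwrapping the demodulated residual and fitting a weighted least
  squares line. Plain sequential unwrapping is available
  (`phase_slope(..., method = "unwrap")`) and agrees on clean data, but
  fails catastrophically on noisy tiles.
* **Frequency masking.** The ideal phasor's spectrum is a Dirichlet
  kernel concentrated around one bin; zeroing everything outside a
  $15\times 15$ window (half-width 7, configurable) removes most of the
  broadband noise. The masked field keeps its smoothed magnitudes, which
  act as SNR weights in the SVD; renormalizing each pixel to unit modulus
  (the textbook phasor form, `renormalize = TRUE`) is equivalent on clean
  data but re-amplifies pure-noise pixels on dim tiles.

The second-harmonic band determines $\varphi_0$ only modulo $\pi$; the
ambiguity is resolved against the first-harmonic phasor phase, read at the
best-focus layer because the axial envelope $\cos(2\pi p_z(z-z_f))$ of the
first-order band changes sign away from focus.

## Modulation quality and the adaptive tiled-block strategy

The per-pixel modulation contrast-to-noise ratio follows from the
five-point DFT along the phase axis,
$N(n) = A_0 + A_1\cos(2\pi n/5 + \alpha_1) + A_2\cos(4\pi n/5 + \alpha_2)$,
as $\mathrm{MCNR} = 2\sqrt{A_1^2 + A_2^2}/\sqrt{A_0^2}$, with the DFT
amplitude convention chosen so that a pure series $c + b\cos(2\pi n/5)$
returns exactly $A_0 = c$, $A_1 = b$. MCNR maps are averaged over the
three orientations; a layer's score is the mean of the 100th and
$(100-a)$th percentiles of that map (linear interpolation between order
statistics; $a = 7$, the midpoint of the admissible interval $5 < a < 10$),
and scores are normalized so the best layer is 1.

Spatially varying illumination (aberrations, stage errors, heterogeneous
fluorescence) breaks the usual assumption of one global parameter set.
The adaptive strategy segments the field into half-overlapping tiles —
on the 2x-upsampled lateral grid, $128\times128$ tiles at stride 64, i.e.
$(2N/m-1)^2$ tiles for a field of side $N$ with $m = 64$ — and treats each
tile's layers by quality:

* layers with normalized MCNR above $M_t = 0.85$ are estimated directly;
* the remaining layers share one composite slice, the MCNR-weighted merge
  of the tile's layers (weights renormalized to sum to one; layers below
  0.2 are excluded as pure defocus, a pre-filter whose exact form the
  strategy leaves open);
* a tile whose three orientation estimates violate the illumination prior
  (equal magnitudes, directions 120 degrees apart: population SDs
  $SD_{wv} > 0.5$ bins or $SD_{ang} > 5$ degrees), or whose estimates are
  low-confidence ($\sigma_1/\sigma_2 < 3$), falls back to the full-field
  estimate of its layer. Estimated directions carry a sign ambiguity, so
  the prior check canonicalizes signs before measuring angles.

Full-field per-layer estimates are computed once per stack: they provide
the anomaly fallbacks and the tile search priors. Layers other than the
MCNR-best one reuse the best layer's peak location as a search prior,
since the wave vector is nearly z-invariant while deeply defocused layers
cannot be localized from scratch at realistic noise.

## Reconstruction

Per orientation, the separated bands are embedded on the 2x lateral grid,
shifted by the (per-layer, where available) estimated wave vector —
integer bins by rolling, the sub-pixel remainder by a spatial phase ramp —
and phase-aligned with the estimated $\varphi_0$. The two axial copies of
each first-order band are demodulated by $e^{\mp 2\pi i p_z (z - z_\mathrm{ref})}$,
which recentres one copy and shifts its OTF by $\pm p_z$ along $k_z$: this
is precisely the axial support extension of 3DSIM, handled without any
interpolation. $z_\mathrm{ref}$ is the MCNR-best layer, shared by all
tiles so the axial phase reference is consistent across the field.

Complex band gains (modulation depth and residual phase) are fitted by
least squares against the 0-order band over the OTF overlap region, with
two 10%-trimmed refits: the pattern carrier is incommensurate with the
finite field, so its spectral window leakage produces gross per-bin
outliers in the ratio. The shifted band OTFs use interpolated rolls
rather than analytically exact shifts — the effective transfer of
finite-window data is the exact OTF convolved with a narrow window
kernel, and the mildly smoothed interpolated OTF matches it measurably
better, besides keeping the near-singular `kz = 0` ridge of the 3-D OTF
from dominating the gain regressions. Gains are illumination properties
rather than tile properties, so the tiled mode fits them once on a
central high-signal window and shares them; the per-tile fit is unstable
on sparse tiles.

Recombination uses a band-equalized generalized Wiener filter,

$$
\mathrm{SR}(k) = A(k)\,
\frac{\sum_c \overline{O_c(k)}\, B_c(k)/g_c}{\sum_c |O_c(k)|^2 + w^2},
$$

with $w = 0.05$ relative to the peak-normalized OTFs and a raised-cosine
apodization $A = \cos(\pi\rho/2)$ to the extended cutoff
($\rho$ is the elliptic distance with lateral semi-axis $k_{wf} + 2p$ and
axial semi-axis $k_{z,wf} + p_z$). Equalizing the bands by their gains
keeps $w$ meaningful against unit-gain OTFs; weighting by $g_c^2$ instead
(the other common convention) makes the same $w$ crush the outer band
extension, because the second-harmonic gain of a three-beam pattern is
only $a_2/2a_0 \approx 0.17$. The triangle apodization is available but
attenuates the mid-band enough to blur a 0.6-Rayleigh point pair past
its dip; the cosine default preserves the doubled passband. Negative
intensities are clamped to zero and the clamped fraction recorded.

Fused output: each tile reconstruction is blended with separable logistic
weight profiles, $\omega(r) = 1/(1+e^{-k(r-r_c)})$ centred on each overlap
midpoint with $k = 0.05$ per pixel of the fused (super-resolved) grid.
Adjacent profiles are complementary and corner regions receive the
product of the x- and y-profiles, so the effective weights sum to one at
every pixel; field-border tiles keep unit weight at the outer edge.

## The simulator and what it does (not) emulate

The synthetic-data generator exists so every stage above is testable
without external data. It renders a ground-truth volume on the 2x lateral
grid (beads, point pairs, or filaments, confined to a central axial slab,
plus a diffuse haze of 0.3 relative to unit structure amplitude —
real specimens always carry out-of-focus and unbound fluorophore signal,
and that low-frequency mass is also what any spectral-peak estimator
locks onto; a background-free point cloud is an adversarial object for
the whole method class), modulates it with the three-beam pattern,
attenuates with a scalar defocused-pupil 3-D OTF, downsamples to the
camera grid in Fourier space, normalizes to a mean of 100 counts, adds
Gaussian noise of the configured dBW power on that count scale, and
clamps negatives. "5 dBW" therefore means noise variance
$10^{0.5} \approx 3.16$ counts$^2$ against a mean signal of 100 counts —
a mild, realistic camera-noise level consistent with the quality regime
structured-illumination studies report; referencing the same power to a
unit-mean stack would put the per-pixel SNR near 0.5, at which no
published 3DSIM pipeline (nor the quality gating here) operates.

Spatial distortions reproduce the canonical stress test: a wave-vector
error ramping linearly across the field (±0.5 to ±1 bins), applied by
integrating the local wave-vector offset into the pattern phase, and
per-layer stage displacement errors (±3 nm) applied as lateral pattern
phase jitter — a rigid axial shift of a z-separable pattern is otherwise
unobservable layer by layer.

Defaults are chosen once for a 100x/1.4NA oil objective: 488/525 nm
excitation/emission, 62.5 nm camera pixels (slightly finer than the
emission Nyquist limit, as real SIM cameras are), 125 nm z-steps, and a
beam angle placing the pattern's second harmonic at 90% of the widefield
cutoff so that it remains directly localizable inside the detection
passband while still extending lateral support by a factor
$1 + 2p/k_{wf} \approx 1.9$.

What the simulator does **not** model: vectorial/polarization effects,
aberrations beyond the wave-vector ramp, photobleaching, shot-noise
statistics (noise is additive Gaussian), or axially non-periodic blur
(the stack is blurred with FFT-periodic boundaries in z). Passing the
test suite therefore demonstrates correctness of the estimation and
reconstruction machinery under controlled violations of parameter
uniformity — not performance on aberrated experimental data.

## Problem sizes and evaluation choices

The test suite and the reproduction script run at desk scale: parameter
recovery on $128\times128\times8$ stacks, the two-point resolution study
on a $256\times256\times8$ super-resolved field (pair separation 0.6 of
the Rayleigh distance, spot centres placed at fractional pixels so the
separation is exact), and the tiled-versus-global comparison on
$256\times256\times12$ stacks with a ±0.5-bin wave-vector ramp, ±3 nm
layer jitter and 5 dBW noise, three seeded replicates. Reconstructions
are compared to ground truth by mean per-layer SSIM after least-squares
affine intensity matching: the absolute scale of a Wiener reconstruction
is arbitrary, and min–max scaling lets single hot pixels dominate the
comparison. Spectral support is read at a $10^{-8}$ relative magnitude
threshold, appropriate for noise-free spectra with a hard band limit.

## Known limitations

* Tiles are cropped, not windowed: periodic-FFT edge effects remain in
  the tile rims and are only suppressed by the overlap down-weighting of
  the fusion stage. Edge tapering was evaluated and rejected — a taper
  does not commute with deconvolution and measurably worsened the fused
  result.
* On distortion-free data a tiled reconstruction is slightly inferior to
  a global one (small windows trade spectral resolution for locality);
  the adaptive mode earns its keep when parameters vary across the
  volume, which is its purpose.
* The modulation-depth estimator is a trimmed complex least squares over
  the OTF overlap; it has no shading or notch model, and the first-order
  gains remain biased low by roughly 10% (the counter-rotating axial copy
  overlaps the fit region).
* $\varphi_0$ disambiguation relies on the first-order band being in
  phase at the reference layer; a pattern focused far outside the stack
  would defeat it.
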