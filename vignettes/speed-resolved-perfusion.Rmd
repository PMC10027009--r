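---
title: "Speed-resolved perfusion from multi-exposure speckle contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-resolved perfusion from multi-exposure speckle contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Laser speckle contrast imaging (LSCI) quantifies microcirculatory blood flow
from the motion blur of laser speckle: the local contrast `K = SD/mean` of
pixel intensity falls as red blood cells (RBCs) move faster. A single
exposure time yields only a relative perfusion index, because the amount of
Doppler-shifted light, the number of shifts per photon, and the shape of the
RBC speed distribution all affect one contrast value in similar ways.
Multi-exposure LSCI (MELSCI) measures `K(T)` at several exposure times and
thereby constrains the full speckle decorrelation curve.

`speckperf` implements a simulation-trained inverse method: a physics
forward model maps randomized three-layer skin models to squared
multi-exposure contrast `K²(T)` at `T = 1, 2, 4, 8, 16, 32, 64` ms, and a
small neural network trained on that synthetic corpus estimates
*speed-resolved perfusion* in absolute units (%RBC × mm/s) in the bands
0–1 mm/s, 1–10 mm/s and >10 mm/s, applied per pixel of a contrast image.

## The tissue model

Each synthetic sample is a three-layer skin model at 780 nm:

* a bloodless epidermis of thickness `t_epi` with melanin-driven absorption
  `mua_epi`;
* an upper dermis of fixed 0.2 mm thickness;
* a semi-infinite lower dermis.

The reduced scattering coefficient `musp` is common to all layers. Each
dermis layer has its own blood tissue fraction `c_blood` (%RBC), oxygen
saturation `S_oxy` and vessel diameter `d_vessels`; the two layers' values
are generated as a randomized average plus a randomized difference bounded
at ±50% of the average, so the layers never diverge arbitrarily.

The RBC speed distribution `c_RBC(v)` is a weighted sum of ten uniform
distributions on `[0, v_k]` with exponentially increasing top speeds
(`v_k = 0.5, 1, …, 256` mm/s) — the projection of parabolic (Poiseuille)
flow profiles in vessels with ten different average speeds. Its integral is
the total RBC tissue fraction, and true perfusion over a band is

$$P[v_{min}, v_{max}] = \int_{v_{min}}^{v_{max}} v\, c_{RBC}(v)\, dv ,$$

with per-layer contributions weighted by the fraction of detected photon
path length in that layer, so that `P_true` reflects the optical sampling
volume (a thicker bloodless epidermis slightly lowers total perfusion).

### Parameter distributions

Only medians and a few supports of the original parameter distributions are
stated numerically (sweep anchors 0.205 mm, 1.6 mm⁻¹, 0.055 mm, 0.55 %,
1 mm/s; supports [0.01, 3.5] mm⁻¹ for `mua_epi` and [0, 100]% for `S_oxy`),
together with three shaping principles: cover all values expected in skin,
down-weight rare values, and put more probability where a small change has a
large effect on contrast (exponential decay, as Beer–Lambert attenuation
suggests). The package therefore uses truncated exponential-decay
distributions whose decay rate is solved so the median matches the printed
anchor:

| parameter | family | support | median |
|---|---|---|---|
| `t_epi` [mm] | truncated exp. decay | 0.04–1.0 | 0.205 |
| `mua_epi` [mm⁻¹] | truncated exp. decay | 0.01–3.5 | 0.25 |
| `musp` [mm⁻¹] | truncated lognormal (sdlog 0.35) | 0.5–4.5 | 1.6 |
| `c_blood` [%] | truncated exp. decay | 0.01–4.0 | 0.55 |
| `S_oxy` | uniform | 0–1 | 0.5 |
| `d_vessels` [mm] | truncated exp. decay | 0.004–0.6 | 0.055 |
| mean RBC speed [mm/s] | truncated exp. decay | 0.05–20 | 1.0 |

Speed-mixture weights are drawn per model: independent exponentials tilted
by a lognormal kernel centered on a sampled target mean speed with a
randomized width, which produces broad, variably-shaped distributions whose
mean speeds follow the configured distribution. Every family, support and
median is configurable through a YAML file (`read_config()`). These choices
are a reconstruction, not a reproduction: absolute evaluation metrics
depend measurably on them, which is why headline errors are checked as
banded approximations rather than exact values.

Both dermis layers share one set of speed-distribution weights (each has its
own `c_blood`). This is the simplest reading consistent with the layer
description and keeps the spectral composition exact in the lag domain.

## Photon transport and path lengths

Photon migration is simulated once per `(t_epi, musp)` grid node (default
7 × 7 nodes spanning the supports, 10⁵ photons per node) in the three-layer
slab, with Fresnel reflection at the tissue–air boundary
(n = 1.4 / 1.0; the ~2.8% specular reflection at launch is excluded) and
index-matched internal boundaries. Every photon exiting the top surface is
detected, which is the wide-field imaging geometry: by reciprocity,
uniform illumination with a pixel-sized detector is equivalent to a point
source with an unbounded detector.

Transport is absorption-free; per-layer path lengths `(l₁, l₂, l₃)` of
detected photons are stored as a **joint** 40³ log-binned histogram.
Beer–Lambert absorption `exp(−μ_a,1 l₁ − μ_a,2 l₂ − μ_a,3 l₃)` is applied
afterwards per tissue model; the joint histogram matters because per-layer
paths are strongly correlated and marginal factorization would bias the
absorption weighting. Histograms are interpolated bilinearly in
`(t_epi, musp)` between nodes.

Scattering during transport is isotropic at the reduced scattering
coefficient (first similarity relation). Simulating the actual
forward-peaked phase function (anisotropy 0.991) would need two orders of
magnitude more scattering events for the same `musp`. We verified the
approximation directly: re-running the grid with Henyey–Greenstein
anisotropy 0.5 and 0.8 at the similarity-scaled `mus = musp/(1−g)` changes
median-model contrast curves by less than 1.5% and the unshifted fraction by
about 0.02. `g_transport` is configurable for users who want the slower,
higher-fidelity transport.

Dermis absorption includes the vessel-packaging effect: blood confined in
discrete vessels self-screens, so
`mua_dermis = c_blood · C_pack · mua_blood(S_oxy) + (1 − c_blood) · mua_baseline`
with the cylindrical packaging factor
`C_pack = (1 − exp(−2 mua_blood R)) / (2 mua_blood R)`, `R = d/2`.
Whole-blood absorption mixes oxygenated (0.40 mm⁻¹) and deoxygenated
(0.58 mm⁻¹) coefficients at 780 nm linearly in saturation.

## Doppler spectrum composition

A single Doppler shift from an RBC with speed `v` has frequency
`f = (2 n v / λ) sin(θ/2) cos ψ`, with the scattering angle θ drawn from the
Gegenbauer kernel phase function (`g_Gk = 0.948`, `α_Gk = 1.0`, anisotropy
0.991) and a random angle ψ between light and RBC velocity. The substitution
`w = (1 + g² − 2g cos θ)^{−α}` makes the phase function exactly uniform in
`w`, so the sharp forward peak is integrated without loss of accuracy — the
same substitution gives exact inverse-CDF sampling in the Monte Carlo
oracles.

The number of Doppler shifts per photon is a vessel-packaged compound
Poisson: a photon with path `l` in a perfused layer crosses
`Poisson(l · 4c/(π d))` vessels (mean chord of randomly oriented cylinders
is `π d / 4`) and collects `Poisson(mus_blood · π d / 4)` shifts per
crossing, with `mus_blood = 222 mm⁻¹` the (non-reduced) scattering
coefficient of whole blood at 780 nm. The mean shift count is exactly
`l · c · mus_blood`, and the homogeneous Poisson limit is recovered as
`d → 0`; finite vessels over-disperse the count. The distribution over total
shifts in both dermis layers, mixed over the absorption-weighted joint
path-length histogram, is computed exactly by evaluating the probability
generating function on the unit circle and inverting with an FFT. The
composition is truncated at the smallest `n` with cumulative probability
above `1 − 10⁻⁴`, capped at 64, with residual mass assigned to the cap.

The full spectrum is `H(f) = Σ_n P(n) H_n(f)`, where `H₁` marginalizes the
single-shift spectrum over the speed distribution (shift probability
proportional to RBC concentration, independent of speed) and `H_n` is the
n-fold self-composition. Spectra are one-sided with the unshifted delta at
`f = 0`; composition happens on the symmetric two-sided extension where
cross-correlation and convolution coincide.

### Biological zero

Under arterial occlusion a residual decorrelation persists (Brownian RBC
motion, interstitial macromolecules). It is added to the spectrum as
`H_BZ(f) = 10^{ξ_offset + f ξ_slope}` for `f > 0` (zero at `f = 0`) with
`ξ_offset ~ N(−5.3, 0.125)` and `ξ_slope ~ N(−5.2·10⁻⁵, 6·10⁻⁶)`, then the
spectrum is renormalized. The amplitude convention is that the add applies
to the histogram normalized to unit total power; at the mean parameters the
BZ carries ≈4% of total power and changes normal-flow contrast by at most a
few percent at the longest exposure, while dominating decorrelation under
occlusion.

## From spectrum to multi-exposure contrast

The Wiener–Khinchine theorem gives the field autocorrelation
`g¹(τ) = |F⁻¹{H(f)}|`, and contrast follows the triangular-window integral

$$K^2(T) = \frac{2\beta}{T}\int_0^T |g^{(1)}(\tau)|^2\,(1 - \tau/T)\, d\tau,$$

with the coherence factor β = 1 (calibrated system, `K = 1` for a static
target).

**Lag-domain fast path.** A uniform frequency grid fine enough for both the
64 ms exposure (few-Hz resolution) and 256 mm/s top speeds (~1 MHz span)
would need ~10⁶ bins per model. The package instead evaluates the
composition in the lag domain: the transform of the n-fold spectrum is
`a(τ)ⁿ`, so `g¹(τ) = Σ_n P(n) a(τ)ⁿ`, where
`a(τ) = Σ_k w_k Ābar(v_k τ)` and `Ābar` is the exact uniform-speed running
mean of the universal single-shift kernel `A(s) = E_θ[sinc(4π n s sin(θ/2)/λ)]`,
tabulated once per optics configuration. This is mathematically identical
to the histogram route without discretization error in `f`, and evaluates a
tissue model in a few milliseconds — which is what makes 10⁴–10⁵-model
corpora practical. The histogram route is retained in full
(`compose_doppler_histogram()` and friends) and the test suite asserts the
two routes agree and that the composed spectra match a brute-force
photon-resampling Monte Carlo oracle per bin.

`K²(T)` is integrated by composite Gauss–Legendre quadrature on log-spaced
panels in `u = τ/T` (36 panels from 10⁻⁹ to 1, 6 points each), which
resolves decorrelation scales from microseconds (fast flow, biological
zero) to the full exposure; the quadrature matches the closed form for
exponential decorrelation to better than 10⁻⁶ over `T/τ_c ∈ [10⁻³, 10³]`.

### Measurement noise

Contrast noise is a correlated sequence proportional to the mean contrast
over all exposures: `K_noise(1) = ⟨K⟩ ξ₁ η₁` and
`K_noise(T) = K_noise(T/2) + ⟨K⟩ ξ_T η_diff(T)`, ξ i.i.d. standard normal.
The constants depend on the speckle/pixel sampling of the instrument and
are not published; defaults `η₁ = 0.02`, `η_diff = 0.01` are the order of
magnitude expected for 7×7-pixel contrast windows and are configurable.
Noisy contrast is floored at 10⁻⁴ so squared contrast and the
single-exposure index stay finite.

## The inverse model

The estimator is a fully connected 7–25–3 network (tanh hidden layer,
linear output) mapping standardized `K²(T)` to the three perfusion bands.
It is trained with the total-perfusion-weighted mean square error

$$wMSE(j) = \frac{1}{N}\sum_i \frac{(P_{pred,j,i} - P_{true,j,i})^2}{P_{true,tot,i}},$$

which keeps small bands from inflating relative errors unless total
perfusion is also small (the per-sample total is floored at 10⁻⁶ %RBC·mm/s
to protect near-bloodless models). Training uses minibatch Adam
(learning rate 3·10⁻³, batch 256, at most 3000 epochs) with early stopping
on a validation split when the loss stops improving by a relative 10⁻⁵ for
50 consecutive epochs; the dataset is split 70/15/15 into
train/validation/test, several restarts are trained from random
initializations, and the restart with the lowest test-split wMSE is
selected. That selection re-uses the test split by design; the unbiased
metrics come from a separate evaluation dataset. Evaluation reports wMAPE
per band, plain MAPE for total perfusion, and R².

The *restricted* ablation freezes `t_epi`, `musp`, `mua_epi`, `d_vessels`
and `S_oxy` at their medians and omits contrast noise, so only parameters
that directly determine perfusion vary; it bounds the accuracy achievable
from the contrast curve alone and must outperform the main model on every
band.

### Problem sizes

The package's default study (`melsci_study()`) uses desk-scale sizes chosen
as a deliberate accuracy/compute trade-off: 7×7 Monte Carlo nodes at 10⁵
photons, 10,000-model training pools and 10,000-model evaluation sets for
both the main and restricted models, 5 restarts, and 1,000 models per sweep
point. The original study's corpus was an order of magnitude larger
(100,000 + 100,000 models, 25 restarts); all sizes are configurable and the
larger scale is a configuration change, not a code change. At desk scale the
evaluation metrics carry extra variance and are expected to sit somewhat
above the large-corpus values.

## Sweep experiments

`sweep_parameter()` changes one parameter at a time over a grid while
holding each of ~1000 randomized models' other parameters (and its noise
and biological-zero draws) fixed, and records the median relative change in
true perfusion, network perfusion, and single-exposure perfusion
`P_SE(T) = 1/K(T) − 1` at 1, 8 and 64 ms. Blood fraction and mean speed are
swept over 0.2×–5× of their anchors (0.55 %, 1 mm/s). The range is kept
inside the generator supports deliberately: points outside the training
distribution (e.g. blood fractions above the 4% support) would measure
extrapolation, not response linearity. Summary statistics are the log–log
response slope and the mean percentage deviation from the ideal
proportional response.

## Numerical choices and degenerate inputs

* Histogram grid: 2¹⁴ bins to 200 kHz by default; n-fold composition is
  carried out on a 2× zero-padded grid and raises an error if more than
  10⁻⁶ of the mass would land beyond the grid (no silent aliasing).
* The `f = 0` bin of a composed histogram carries the zero-shift delta plus
  whatever dynamic mass falls inside the first half-bin; the exact
  zero-shift probability is exposed as an attribute.
* Shift-count PGF inversion uses an FFT of size 128, doubling automatically
  until the tail is captured.
* All-zero speed weights, negative concentrations, non-covering grids,
  out-of-hull interpolation queries and non-finite network inputs raise
  errors rather than propagating.
* `c_blood = 0` yields a pure static spectrum (`H = δ(f=0)`, `K = √β`);
  zero-perfusion targets are protected by the wMSE floor.
* Seeds: every entry point takes an integer seed; datasets, training,
  sweeps and fixtures are bit-reproducible given the seed.

## What the generator does and does not emulate

The synthetic corpus emulates the physics of speckle decorrelation in
layered skin — multiple Doppler shifts, static scattering, vessel
packaging, biological zero and instrument-like contrast noise — under broad
parameter randomization. It does not emulate: lateral tissue heterogeneity
within a pixel's sampling volume (models are laterally homogeneous),
curved or voxelized vessel geometry, motion artifacts, depth-dependent
scattering, or the instrument's on-sensor exposure accumulation. Synthetic
image fixtures (`synth_image_fixture()`) assemble per-region homogeneous
models into scenes; they exercise the imaging code path and provide ground
truth, but they are labelled synthetic and are structurally simpler than
in-vivo images. Passing tests therefore demonstrate internal consistency of
the physics and inversion under the stated model, not calibrated accuracy
on real tissue.

## Known limitations

* Absolute evaluation metrics depend on the reconstructed parameter
  distributions; with a different plausible reconstruction the headline
  errors shift by tens of percent in relative terms.
* The detection geometry (all exit positions and angles) corresponds to
  wide-field imaging; modeling an instrument with a restrictive collection
  aperture would require adding an exit-angle criterion to the transport
  code and recomputing the grid.
* The network saturates where contrast physically loses sensitivity — very
  high blood fractions (most light already fully decorrelated) and very low
  mean speeds under biological zero — which bounds response linearity at
  the sweep extremes.
* Containers use R serialization (RDS) plus optional float TIFF export for
  stacks; there is no HDF5 dependency.
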