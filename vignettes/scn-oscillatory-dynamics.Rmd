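---
title: "Estimating circadian phase and simulating virtual slicing in the SCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating circadian phase and simulating virtual slicing in the SCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnphase)
```

This vignette is the package's account of its methods: the models, their
assumptions, the tunable parameters, the numerical conventions, and what the
synthetic data generators do and do not emulate.

## 1. The signal model for slice movies

A bioluminescence movie of a cultured SCN slice records, at each in-tissue
pixel, an hourly brightness series over at least two days. The working model
per pixel is a decaying sinusoid plus baseline and noise,

$$I_p(t) = C + A_p\, e^{-t/\tau}\, w\!\left(\tfrac{2\pi (t - \phi_p - 12)}{24}\right) + \varepsilon_t,
\qquad w(\theta) = \cos\theta + a_2 \cos(2\theta - \pi/2),$$

with hourly $t = 0,\dots,47$. The four meaningful ingredients:

* **Phase $\phi_p$ (hours)**: the quantity of interest. The phase field in
  tissue is tightly clustered (within a few hours) and unimodal; the
  generator builds it from a medial-lateral spatial gradient
  (`gradient_span`, default 2 h across the mask) plus skew-normal jitter
  (`jitter_scale` 0.8 h, `jitter_skew` 4), centred to mean zero. The 12-hour
  offset in the argument puts the global-mean **trough** at $t \approx 0$,
  the CT0000 convention (circadian time is measured from the trough of PER2
  expression).
* **Amplitude $A_p$**: lognormal across pixels (`amplitude_mean` 100 a.u.,
  `amplitude_cv` 0.2), reflecting brightness heterogeneity.
* **Decay $\tau$** (default 96 h): cultured slices dim slowly; decay
  multiplies the oscillatory part only, not the baseline. `Inf` disables it.
* **Waveform asymmetry $a_2$** (default 0.15): PER2 rises slowly and falls
  quickly, so the waveform is not a pure cosine. The second harmonic with
  locked phase $-\pi/2$ can be written
  $w(\theta) = \cos\theta\,(1 + 2 a_2 \sin\theta)$: it steepens the falling
  limb and flattens the rising limb while leaving the trough, the peak hour,
  the mean crossings and — because the harmonic lives in a different Fourier
  bin — the 24-hour component's amplitude and phase exactly unchanged.
  $a_2 = 0$ recovers the pure cosine. This term matters: with a strictly
  symmetric cosine the two mean crossings (6 h and 18 h after the trough)
  are exact mirror images, so no analysis could prefer the falling limb, and
  amplitude decay would in fact slightly favour the *rising* crossing. The
  empirical phenomenon the package reproduces — the brightness-phase
  regression being best ~19 h after the trough — is a property of the
  asymmetric waveform.
* **Noise**: additive Gaussian with standard deviation `noise_sd`
  (default 0.1) times the pixel's amplitude, constant over time.

## 2. Fourier phase extraction

`circadian_component()` takes the first 48 hourly frames and computes, per
pixel, DFT bin $k = 2$ (the 24-hour period). Writing
$X_2 = \sum_t I(t) e^{-2\pi i \cdot 2 t/48}$, the component reconstructs as
$A\cos(2\pi(t - h)/24)$ with $A = 2|X_2|/48$ and $h = -\mathrm{Arg}(X_2)
\cdot 24/2\pi$, wrapped into $(-12, 12]$. Conventions pinned by tests on
shifted-cosine fixtures:

* the phase is computed with **atan2** (full quadrant); a plain arctangent
  of the coefficient ratio is ambiguous for shifts beyond 6 hours;
* phases are **normalized** to the tissue-mean series
  (`normalize_phases()`): the reference phase is subtracted and re-wrapped,
  so zero phase means "in phase with the mean oscillation" and every pixel
  is at most 12 h advanced or delayed. Normalization always restarts from
  the stored raw phases, making it idempotent. Note the reference is the
  phase of the *mean signal* — an amplitude-weighted compromise — not the
  arithmetic mean of phases; the two differ at the millihour level on
  heterogeneous tissue.
* pixels with zero 24-hour amplitude (constant series) are flagged
  undefined rather than erroring.

Because a decaying envelope convolves the spectrum, decay leaks a small,
phase-dependent bias (~0.05–0.1 h at $\tau = 96$ h) into the extracted
phases. The noiseless-recovery tests therefore run with decay off, where
recovery is exact to numerical precision; parameter-recovery tests at 10%
noise include decay and stay well under 0.5 h RMSE.

`power_spectrum()` reports per-bin power scaled so a cosine of amplitude
$A$ contributes $A^2/2$ and bin powers sum to the series variance
(Parseval); `circadian_power_fraction()` is the 24-hour bin's share of
non-DC power. `cluster_pixels()` is k-means (10 restarts, fixed seed) on
per-pixel z-scored series — the clustering algorithm is a presentation
device, so the simplest standard method is used — with labels reordered by
the cluster-mean circadian peak time. `find_trough()` takes the argmin over
integer hours of the circadian reconstruction of the tissue-mean series
within the first 24 h.

## 3. The brightness-difference model

At one movie frame, phase differences between pixels are approximately
proportional to brightness differences wherever the waveform is locally
linear in phase. The preprocessing (`preprocess_bins()`) follows five steps:
z-score intensities over in-tissue pixels; trim the top and bottom 10%;
sort the survivors into 400 equal-width bins over the trimmed range
(empty bins dropped — "equally sized" is read as equal *width*, the natural
reading, though equal *count* is conceivable); form $\Delta I$ as
differences of bin centers and $\Delta\phi$ as differences of per-bin
arithmetic mean phases (valid because the mean of pairwise differences
equals the difference of means; circular means are unnecessary at this
clustering tightness); and emit **all ordered pairs** of distinct bins.

`fit_delta_model()` then fits $\Delta I = \alpha\,\Delta\phi + c +
\epsilon$ by OLS. Numerical/inferential choices:

* The ordered-pair set is antisymmetric by construction, which forces the
  intercept to zero — a property the data should and does exhibit — and
  makes the pair-level OLS slope algebraically identical to the bin-level
  OLS slope.
* **Inference comes from the bin-level regression** (df = bins − 2): the
  pair expansion duplicates each bin's information ~400-fold, and pair-level
  degrees of freedom would understate the standard error by a factor of
  ~$\sqrt{\text{bins}}$.
* Standard errors are **heteroskedasticity-consistent (HC3)**: the per-bin
  mean phase carries sampling noise proportional to
  $1/\sqrt{\text{occupancy}}$, and sparsely occupied tail bins are both
  high-leverage and high-variance, so the homoskedastic SE is
  anti-conservative (replicate calibration showed ~6% undercoverage,
  removed by HC3).
* The residual SE is also reported in hours ($\sigma/|\alpha|$), the
  natural units for "how accurately does brightness predict phase".
* The regression is unweighted by occupancy (occupancy weighting is
  available as an option).

`scan_hours()` fits one model per hour $t = 0..23$ after the trough. On
the asymmetric waveform the best fit sits at the falling mean crossing
($t = 18$–19): there $\partial I/\partial\phi$ is maximal (steepest limb),
while at the peak ($t \approx 12$) the derivative vanishes and brightness
differences reflect amplitude heterogeneity, not phase. Per-hour failures
are flagged rather than aborting the scan.

## 4. Order parameter and calibration

The order parameter $O(\{\phi_j\}) = |N^{-1}\sum_j e^{i\phi_j}|$ measures
synchronization: 1 for identical phases, ~0 for uniform scatter. The
snapshot model $\phi_i = \alpha m_i$ (mean-centered intensities $m_i$) has
one free constant, which only sets the dispersion of the estimated phases.
`calibrate_alpha()` tunes $\alpha$ so the order parameter of
$\{\alpha m_i\}$ equals a representative target — default **0.8**, a
representative slice-tissue synchronization level at CT1900; the mean of
the six published per-slice order parameters (`slice_order_parameters`) is
0.8358, and 0.84 is an equally defensible target, so the value is exposed
in the configuration rather than hard-coded.

Numerically, $O(\alpha)$ starts at 1 and decreases on an initial monotone
branch; the solver walks down that branch in steps of $0.05/\mathrm{sd}(m)$
until the target is bracketed and refines by `uniroot` (achieved $O$ within
$10^{-6}$ of target, enforced). If the branch turns upward before reaching
the target (possible for few-point or strongly clustered intensity sets),
calibration fails explicitly rather than jumping to a larger root: the
smallest dispersion consistent with the data is the only defensible choice.
Calibration is exactly unit-covariant ($\alpha \mapsto \alpha/c$ under
$I \mapsto cI$), and scale-free statistics of the estimated phases
(skewness, kurtosis) do not depend on the target at all.

`estimate_snapshot_phases()` guards against applying a calibration to a
different table (an intensity fingerprint is checked), and warns — without
clipping — when estimates leave $(-12, 12]$ h, a diagnostic of
miscalibration or extrapolation.

## 5. The synthetic snapshot cloud

`synth_snapshot()` places `n_neurons` (default 3,000; tests and the
acceptance checks use this size to keep a full sweep within minutes on one
CPU) uniformly in an ellipsoid with semi-axes (147, 255, 82) µm on the
(medial-lateral, rostral-caudal, dorsal-ventral) axes. These axes are
**derived targets, not measured anatomy**: the one-coordinate marginal of a
uniform ellipsoid is $\propto 1 - (u/L)^2$, so central 100 µm slabs retain
29% / 49% / 80% of neurons in the coronal / sagittal / horizontal
orientations — i.e. remove 71% / 51% / 20%, the removal fractions reported
for whole-mount SCN. The true phase of neuron $i$ is

$$\phi_i = \mathrm{skewnormal}(0, 1.2\,\mathrm{h}, 4) \;-\;
  s_r\,\rho_i \;-\; \text{(mean)},$$

where $\rho_i \in [0, 1]$ is the normalised ellipsoidal radius and
$s_r$ = `radial_span_h` (default 3 h). The radial term emulates the
center-periphery (core-shell) phase organisation of the SCN — shell neurons
phase-advanced relative to the center by a few hours — and is what gives
virtual slabs *systematic* phase offsets: how central a slab is in the
cloud determines how far its mean phase sits from the whole-tissue mean,
and the coronal slab is by far the most central (it spans only 100 of
510 µm of its axis). Without any spatial phase structure the slab offsets
are pure finite-size noise of order $\sigma/\sqrt{n_{\text{slab}}}$ and the
slicing comparison has no stable signal at this problem size. The combined
distribution is right-skewed and leptokurtic, the shape reported for
estimated phase distributions in tissue.

Intensities encode phase linearly, $I_i = g\,\phi_i + \bar I +
\varepsilon_i$ (gain $g$ = 500 a.u./h, offset 5,000 a.u., noise sd 75
a.u.), making the snapshot model recoverable by construction; the default
gain-to-noise ratio is ~6, and recovery degrades gracefully as it falls.
With `gain = 0` the intensities carry no phase signal: the generator warns,
and with zero noise the downstream calibration fails on the constant
intensity set. An optional `laminar_spacing_um` quantises the
dorsal-ventral coordinate onto equally spaced planes (weighted by
cross-section area), which concentrates nearest-neighbour connection
directions at polar angle $\pi/2$ — the in-plane anisotropy seen in
direction histograms of real clouds. Lamination is off by default; the
plane spacing of real tissue is not known, so it is exercised explicitly in
anisotropy tests (15 µm spacing against a 20 µm connection radius).

## 6. Direction anisotropy

`connection_directions()` emits, for every ordered pair within the
connection radius (20 µm default, the scale of direct soma-to-soma
apposition), the unit vector $v_{ij} = (r_i - r_j)/\|r_i - r_j\|$ in the
spherical parameterization $v = (\cos\theta\sin\phi, \sin\theta\sin\phi,
\cos\phi)$; ordered pairs make the multiset antipodally symmetric.
Coincident points are skipped with a warning. `direction_histogram()` bins
the raw angles on an equal-width 35×35 grid, *uncorrected* for solid angle,
because that is how such maps are conventionally rendered; note a truly
isotropic field is then $\propto \sin\phi$, **not** flat — so the histogram
also carries a solid-angle-corrected density (fraction per steradian) in
which isotropy *is* flat. Both renderings are produced; consumers should
say which they use.

## 7. Kuramoto simulation and virtual slicing

Connectivity: all pairs within 20 µm, plus each remaining unordered pair
independently with probability $q$ (undirected; the random edges are
sampled once per $(q, \text{seed})$ on the intact cloud, and slab
simulations use the **induced subgraph** — cutting removes edges, it does
not resample them). Dynamics:
$\dot\theta_i = \omega + K \sum_j A_{ij}\sin(\theta_j - \theta_i)$ with a
common $\omega = 2\pi/24\ \mathrm{h}^{-1}$, integrated by classical RK4 at
a fixed 30 s step for 24 h from the calibrated snapshot phases, hourly
checkpoints. Phases are integrated unwrapped; wrapping happens only inside
order-parameter and deviation computations, avoiding branch artifacts.
Halving the step changes 24 h phases by under $10^{-8}$ rad at $K \le 2$,
and the integrator matches the two-oscillator closed form
$\tan(\delta/2) = \tan(\delta_0/2)\,e^{-2Kt}$ to better than $10^{-6}$ rad
— the package's integration-accuracy contracts.

A virtual slice keeps the neurons within a 100 µm slab centered on the mean
of one coordinate (coronal on y, sagittal on x, horizontal on z; boundary
inclusive). The damage done by slicing is the deviation statistic: the mean
over slab neurons of the absolute principal-value difference between sliced
and intact phases at the 24 h checkpoint, in $[0, \pi]$ radians (hourly
checkpoints are retained for visualisation, but the statistic uses 24 h
only). `orientation_sweep()` maps the winner (highest deviation) over a
$(q, K)$ grid — default $q$ log-spaced on $[10^{-4}, 10^{-2}]$ and $K$
linear on $[0, 2]$, 4×4. The default $q$ range is deliberately the
narrower of the two ranges in circulation for this analysis: at
$q \sim 0.1$ random edges outnumber local edges ~40-fold, the network is
effectively a random graph, and the orientation comparison changes
character (development runs showed the horizontal slab winning there) —
with dense long-range randomness the slab geometry no longer matters, and
such connectivity is not biologically plausible for the SCN, where local
coupling dominates. At $K = 0$ the dynamics are identical with or without
slicing, deviations are exactly zero, and cells are reported as ties.

## 8. Known limitations

* The generators emulate the *statistical* structure the analyses assume —
  tight unimodal phases, linear intensity-phase coding, ellipsoidal
  geometry with core-shell phase structure — not SCN biophysics: no TTFL
  dynamics, no bilateral two-lobe geometry, no regional (core/shell
  AVP/VIP) cell types, no empirically measured connectome. Passing
  recovery tests demonstrates the pipeline's correctness on data satisfying
  its assumptions, not the validity of those assumptions for any real
  tissue.
* The decay-induced phase bias (Section 2) is accepted, not corrected; at
  realistic decay it is an order of magnitude below the noise floor.
* The binned-pair regression's slope acquires an upward bias of relative
  order $(\sigma_I/\alpha\,\mathrm{sd}(\phi))^2$ when intensity noise is
  large, because binning on a noisy response tilts the conditional means;
  slope-recovery guarantees are therefore stated in the high
  gain-to-noise regime.
* Kuramoto with identical frequencies and binary symmetric coupling is the
  simplest dynamical model that can express the slicing question; its
  deviations should be read comparatively (between orientations), never as
  predicted hours of phase shift in real tissue.
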