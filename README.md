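# scnphase

Circadian phase estimation and virtual slicing dynamics for the
suprachiasmatic nucleus (SCN).

## The problem

The SCN, the master circadian clock, is a nucleus of ~20,000 neurons whose
PER2 expression oscillates with a 24-hour period. Slice preparations
(PER2::LUC bioluminescence movies) give time series but physically cut the
circuit; cleared whole-mount imaging (iDISCO + light sheet) preserves the
intact circuit but yields a single time point — a *snapshot* of each
neuron's position and PER2 intensity. This package implements, end to end,
a pipeline that bridges the two modalities:

1. **Fourier phase extraction** — for each movie pixel, the 24-hour
   component of the 48-point DFT gives amplitude and phase,
   `A·cos(2π(t − h)/24)`, with phases normalized to the tissue-mean
   oscillation (`circadian_component()`, `normalize_phases()`; clustering,
   power spectra and phase histograms accompany it).
2. **The brightness-difference model** — at a fixed hour after the trough
   (CT0000), differences in single-frame brightness are linearly related to
   differences in phase, `ΔI = αΔφ + c + ε`, fitted on 400 intensity bins
   after z-scoring and 10% tail trimming (`preprocess_bins()`,
   `fit_delta_model()`, `scan_hours()`). The fit is best on the falling limb
   of the oscillation (~CT1900) and degenerate at the peak.
3. **Order-parameter calibration** — the snapshot model `φᵢ = α·mᵢ` (mᵢ
   mean-centered intensity) has a single scale constant, tuned so that the
   Kuramoto order parameter `O = |N⁻¹ Σ exp(iφⱼ)|` of the estimated phases
   equals a representative synchronization level (default 0.8)
   (`order_parameter()`, `calibrate_alpha()`, `estimate_snapshot_phases()`).
4. **Anisotropy and virtual slicing** — nearest-neighbour connection
   directions in spherical coordinates (`connection_directions()`,
   `direction_histogram()`); Kuramoto dynamics
   `θ̇ᵢ = ω + K Σⱼ Aᵢⱼ sin(θⱼ − θᵢ)` integrated by fixed-step RK4 (30 s) on
   distance-plus-random connectivity (`build_connectivity()`,
   `simulate_kuramoto()`); 100 µm virtual slabs in coronal/sagittal/
   horizontal orientation (`virtual_slice()`); and the deviation statistic
   `|S|⁻¹ Σⱼ |arg e^{i(θ̂₂₄ⱼ − θ₂₄ⱼ)}|` quantifying how much each slicing
   orientation damages the dynamics (`deviation_statistic()`,
   `orientation_sweep()`).

Because the source imaging data are not deposited, the package ships
synthetic generators for both modalities (`synth_slice_timeseries()`,
`synth_snapshot()`) that carry ground truth, so every stage is exercised by
parameter-recovery tests.

## Worked example

```r
library(scnphase)

# --- slice movie: generate, extract phases, scan the 24 hours from trough
sim   <- synth_slice_timeseries(slice_synth_config(seed = 7))
field <- normalize_phases(circadian_component(sim$grid), sim$grid)
scan  <- scan_hours(sim$grid)
scan
#> <scn_hour_scan> trough at frame 0; best R^2 = 0.866 at t = 18 h
scan$models[[19]]
#> <scn_delta_model> hour 18: slope = 1.2241 (95% CI 1.1751..1.2731),
#>   c = -1.75e-17, R^2 = 0.866, sigma = 0.300 h, p = 1.08e-166

# --- snapshot: calibrate the scale constant and estimate per-neuron phases
snap <- synth_snapshot(snapshot_synth_config(seed = 1))
cal  <- calibrate_alpha(snap$table$intensity, target = 0.8)
cal
#> <scn_calibration> alpha = 0.00140165 rad/unit (0.00535391 h/unit),
#>   O = 0.800000 (target 0.80), n = 3000
est <- estimate_snapshot_phases(snap$table, cal)
phase_distribution_stats(est)
#>      n     mean   sd skewness excess_kurtosis
#> 1 3000 2.07e-15 2.56    0.539           0.135

# --- virtual slicing: which orientation damages the dynamics most?
sw <- orientation_sweep(snap$table, est$phase_radians,
                        q_grid = 1e-4, K_grid = 1, seed = 101)
sw$results[, c("orientation", "deviation_hours", "winner")]
#>   orientation deviation_hours  winner
#> 1     coronal           0.658 coronal
#> 2    sagittal           0.582 coronal
#> 3  horizontal           0.269 coronal
```

Reading the output: the hourly scan shows the linear brightness-phase
relation is strong 18 h after the trough (the falling limb) and useless at
the peak; the calibration makes the estimated snapshot phase distribution
exactly as synchronized as slice tissue (order parameter 0.8), mean zero by
construction, right-skewed and leptokurtic; and virtual coronal slicing
perturbs the simulated dynamics most (deviation ~0.66 h for the slab
neurons), sagittal less, horizontal least.

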