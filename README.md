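# plaquewave

Shear wave elastography (SWE) analysis of carotid plaques: combined
spatiotemporal **group velocity** and frequency-resolved **phase
velocity** estimation from ultrafast ultrasound acquisitions, plus the
cohort statistics linking those velocities to plaque vulnerability —
with synthetic wave-field and cohort generators so the whole chain is
verifiable without patient data.

It is written for researchers in ultrasound elastography and vascular
imaging who want a tested, scriptable reference implementation of the
dual-readout analysis: the clinical-style group velocity and the
dispersion analysis that bounded, layered plaque tissue actually calls
for.

## What it computes

From a complex baseband (IQ) ensemble or particle-velocity movie
`v(z, x, t)` and a plaque ROI mask:

1. **Motion estimation** — 2D autocorrelation Doppler estimator:
   `v = c / (4 π f₀ Δt) · arg R₁`, with `R₁` the lag-one slow-time
   autocorrelation averaged over a small spatial kernel.
2. **Directional filtering** — f–k quadrant split of each depth row into
   leftward- and rightward-travelling waves (dual-sided push produces
   both); zero-padded, mask-complementary, energy-conserving.
3. **Depth averaging** — per-direction space–time map `v(x, t)` over the
   masked depth pixels.
4. **Group velocity** — time-to-peak arrival per lateral position, RANSAC
   line fit `t = b + x/v`, 50 % inlier quality gate, left/right
   combination.
5. **Phase velocity** — 2D FFT dispersion magnitude `|V(f, k)|`, peak
   intensity ridge `c(f) = f / k*(f)` with parabolic peak interpolation
   and prominence gating, averaged in the 200–300, 300–400 and
   400–500 Hz bands.
6. **Cohort statistics** — per-plaque mean ± SD aggregation, two-sided
   Wilcoxon rank-sum comparisons of AHA type VI against types III/V/VII
   (exact enumeration at the study's group sizes), and Pearson +
   Spearman correlation screens against plaque components and lipids
   with the `|R| ≥ 0.5, p < 0.05` flag rule.

The synthetic generators provide the ground truth: dispersive dual-push
wave fields whose component at frequency `f` travels at a configurable
law `c(f)` (constant, power law, or the thin-plate flexural asymptote
`c(f) = √(2π f h c_T/√3)`), IQ speckle modulation with the exact Doppler
phase increment, and cohorts with the 7/8/8/4 AHA group structure and
configurable effect sizes and correlation targets.

## Worked example

A noise-free 5 m/s packet on the default acquisition grid (0.3 mm
pitch, 128 lateral pixels, 180 frames at 10 kHz, 5 MHz tracking) is
recovered by both pipelines:

```r
library(plaquewave)

grid <- acquisition_grid()            # 0.3 mm, 18 ms, 5 MHz defaults
roi  <- roi_rect(grid)                # central-half lateral ROI
cfg  <- wave_sim_config(grid = grid, roi = roi,
                        dispersion = dispersion_law("constant", c0 = 5))
res  <- analyze_wavefield(simulate_wavefield(cfg), roi)

res$gv$combined
#> <group_velocity_estimate> combined: 5.000 m/s (inliers 100% of 128, passed)
res$pv$combined_bands
#> <phase_velocity_bands>
#>   200-300 Hz: 4.835 m/s
#>   300-400 Hz: 4.942 m/s
#>   400-500 Hz: 5.046 m/s
```

The group velocity is exact (the time-to-peak points are perfectly
collinear) and the three band means sit within 3.3 % of the true
5 m/s — the residual is f–k grid quantisation, reduced by the default
4× zero-padding.

A dispersive plate-mode field is recovered against its closed form:

```r
law <- dispersion_law("plate_A0", h = 3e-3, c_T = 4)
cfg <- wave_sim_config(grid = acquisition_grid(n_depth = 4),
                       dispersion = law, roi = roi_rect(acquisition_grid(n_depth = 4)))
map <- depth_average(directional_filter(simulate_wavefield(cfg))$rightward,
                     cfg$roi, "rightward")
bands <- band_average(extract_curve(compute_dispersion(map)))
bands
#> <phase_velocity_bands>
#>   200-300 Hz: 3.173 m/s
#>   300-400 Hz: 3.850 m/s
#>   400-500 Hz: 4.478 m/s
```

against analytic within-band averages of 3.293, 3.900 and 4.424 m/s
(errors 3.7 %, 1.3 %, 1.2 %).

Synthetic cohorts and the statistical report:

```r
cohort <- simulate_cohort(cohort_sim_config(seed = 2))
report <- run_full_evaluation(cohort)
subset(report$group_comparisons, significant_all, c(metric, view))
#>   metric view
#> 2     gv    T
```

— the transverse-view group velocity separates AHA type VI plaques from
every other type, the cohort-level effect the defaults encode.

A full synthetic pipeline run (simulate → motion → maps → velocities →
report, with a reproducibility manifest and per-acquisition exclusion
accounting):

```r
run_pipeline(pipeline_config_from_list(list(seed = 1)), "out/")
```

A command-line front end with the same verbs
(`simulate-wave`, `simulate-cohort`, `estimate-motion`, `make-maps`,
`group-velocity`, `phase-velocity`, `evaluate`, `run`) is installed at
`system.file("cli/swe.R", package = "plaquewave")`.

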