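# pwvttf

Thoracic aortic **pulse wave velocity (PWV)** from phase-contrast CMR flow
curves, using the **time-to-foot (TTF)** transit-time method, plus a
computer-phantom framework for asking how much temporal resolution an
acquisition needs before the answer can be trusted.

PWV is the speed of the systolic wavefront along the aorta and a standard
biomarker of arterial stiffness:

```
PWV = D / Δt        [mm / ms ≡ m/s]
```

where `D` is the centre-line distance between the two flow-measurement
planes (ascending aorta and aorta at the diaphragm) and `Δt` is the transit
time of the wavefront between them. `Δt` is measured by locating each flow
curve's *foot* — the intersection of a regression line fitted to the maximal
systolic upslope with a baseline tangent — and differencing the two foot
times.

The package is written for CMR physicists and image-analysis engineers. It
provides:

* `generate_waveform()` / `make_phantom_pair()` — a parametric aortic
  waveform model and phantom curve pairs with a known injected PWV;
* `upsample_cubic()`, `downsample_antialiased()`, `gaussian_smooth()` —
  periodic, zero-phase signal machinery for cardiac-cycle curves;
* `detect_foot()`, `transit_time()`, `compute_pwv()`, `measure_pwv()`,
  `auto_baseline_offset()` — the TTF measurement with full tangent
  diagnostics and eddy-current baseline correction;
* `extract_flow_curve()` — ROI flow integration from through-plane velocity
  maps (NIfTI readable via `read_velocity_series()`);
* `centerline_length()` — polyline / spline aortic travel distance;
* `run_phantom_experiment()`, `determine_cutoff()` — the temporal-resolution
  experiment (true PWV × frame-count grid, per-frame-count error table,
  plateau cut-off);
* `bland_altman()` — agreement statistics for method and observer
  comparisons.

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods, so everything composes with the usual tidyverse
verbs. A thin command-line front end (`inst/cli/pwvttf.R`, subcommands
`simulate | measure | phantom | distance | agree | extract`) wraps the same
functions for shell use.

## Worked example

Build a phantom pair with a known PWV of 6 m/s over 250 mm, sampled at 35
frames per cycle, and measure it back:

```r
library(pwvttf)

pair <- make_phantom_pair(waveform_params(), pwv_true = 6,
                          distance_mm = 250, n_frames = 35)
pair
#> # Phantom pair: true PWV 6 m/s over 250 mm -> shift 41.667 ms, 35 frames

res <- measure_pwv(pair$proximal, pair$distal, distance_mm = 250)
res
#> # PWV 6.002 m/s = 250.0 mm / 41.653 ms (feet 100.438 -> 142.091 ms)
glance(res)
#> # A tibble: 1 × 6
#>   pwv_m_s delta_t_ms distance_mm cycle_ms proximal_foot_ms distal_foot_ms
#>     <dbl>      <dbl>       <dbl>    <dbl>            <dbl>          <dbl>
#> 1    6.00       41.7         250     1000             100.           142.
```

The injected 41.667 ms shift is recovered as 41.653 ms (−0.03 %). The foot
times sit ~20 ms after the waveform's flow onset (80 ms): the
intersecting-tangent foot is a property of the upslope geometry, and the
common offset cancels in `Δt`.

The full temporal-resolution experiment — 10 true PWVs × 21 frame counts =
210 conditions — runs in a few seconds:

```r
exp <- run_phantom_experiment(phantom_grid())
glance(exp)
#> # A tibble: 1 × 4
#>   n_conditions n_failed cutoff_n_frames max_abs_pct_error
#>          <int>    <int>           <int>             <dbl>
#> 1          210        0              21              7.08
determine_cutoff(exp, tolerance_pct = 6)
#> [1] 21
```

`exp$errors` holds the per-frame-count table (temporal resolution, median
signed error, median/max absolute percentage error); `autoplot(exp)` draws
the error-versus-frame-count figure. With the default band-limited analysis
the maximum error stays below 1 % for 35+ frames and ~7 % at the coarsest
sampling (20 frames, 50 ms resolution); see the vignette for why tangent
fitting without dense reconstruction degrades much faster and where these
numbers do and do not transfer to real acquisitions.

Agreement between two measurement methods:

```r
d <- data.frame(at = c(5.9, 6.4, 5.1, 7.2, 6.8),
                cmr = c(4.6, 5.5, 4.2, 6.0, 5.6))
glance(bland_altman(d, at, cmr))
#> # A tibble: 1 × 5
#>       n  bias    sd loa_lower loa_upper
#>   <int> <dbl> <dbl>     <dbl>     <dbl>
#> 1     5   1.1 0.187     0.733      1.47
```

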