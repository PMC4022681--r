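# rotaframe

Quantitative **T1ρ mapping** of articular cartilage: simulation, calibration,
fitting, segmentation and reliability statistics in one R package.

T1ρ — the spin-lattice relaxation time in the rotating frame — is measured by
locking the magnetization along an applied RF field of amplitude B<sub>1sl</sub>
for a variable spin-lock time (TSL) and fitting the resulting signal series
voxel-wise to a mono-exponential decay,

```
S(TSL) = S0 · exp(−TSL / T1ρ)
```

In knee cartilage, T1ρ tracks proteoglycan loss and rises early in
osteoarthritis, so reliable high-resolution T1ρ maps are a sensitive probe of
cartilage molecular integrity. At high field, however, B0 and B1
inhomogeneity during spin locking corrupts the decay unless the preparation
cluster compensates for it and the reference frequency and transmit voltage
are calibrated locally over the cartilage. This package implements that whole
chain for desk-scale, fully synthetic study:

- **Rotating-frame Bloch simulation** of spin-lock preparation clusters — a
  `simple` single-phase cluster and a `compensated` rotary-echo +
  180°-refocusing cluster that cancels first-order B0/B1 errors — plus a
  synthetic knee phantom (annular cartilage band with deep/middle/superficial
  zones, fluid, bone, smooth B0/B1rel fields, Rician noise).
- **Calibration**: WASSR z-spectrum B0 mapping (cubic-interpolated dip
  minimum), double-angle B1 mapping (`b1rel = acos(S2/2S1)/α0`), and STEAM
  two-spectrum reference-voltage calibration (`S ∝ sin³α`, so
  `S2/S1 = 8cos³α` and `V = x·90/α`).
- **Mapping**: integer-shift registration to the TSL = 0 volume, linearized
  (log-linear) and nonlinear (Levenberg–Marquardt) voxel-wise fits with
  native-scale R² maps, display thresholds (R² ≥ 0.8, T1ρ ≤ 300 ms), ROI
  summaries.
- **Segmentation**: morphological layer-peeling split of a cartilage mask
  into deep/middle/superficial zones along local thickness, and
  medial/lateral side splitting about a user-supplied divider.
- **Statistics**: Rician-corrected SNR (×0.655), test–retest ICC (two-way
  random, absolute agreement, single measures, with F-based 95% CI), Pearson
  r, coefficient of variation, Welch's t from summary statistics, SNR decay
  projection.

## Worked example

Simulate a multi-TSL patellar-like phantom under localized-calibration field
conditions (B0 residual 0 ± 30 Hz, B1rel 1.0 ± 0.1, SNR 90), fit it, and
summarize per zone:

```r
library(rotaframe)

spec <- phantom_spec(base_snr = 90, seed = 1)
sim  <- simulate_tsl_series(spec, prep_cluster("compensated", b1sl_hz = 500))
sim$series
#> <tsl_series> 96x96x4 voxels, 5 TSLs (0, 10, 20, 30, 40 ms), B1sl 500 Hz at 7T

fit <- fit_t1rho(sim$series, mask_select(sim$mask))
glance(fit)
#> # A tibble: 1 × 5
#>   n_valid median_t1rho_ms mean_t1rho_ms median_r2 method
#>      3664            45.3          45.6     0.999 linearized

roi_mean_t1rho(fit, sim$mask, zones = "deep")          # truth: 35 ms
#>   mean_ms  sd_ms     n
#> 1    35.0  0.975  1104
roi_mean_t1rho(fit, sim$mask, zones = "superficial")   # truth: 55 ms
#>   mean_ms  sd_ms     n
#> 1    55.0  1.71   1328

frequency_offset_summary(sim$b0, mask_select(sim$mask))
#>   mean_hz sd_hz     n
#> 1  0.0985  29.8  3664
```

Every zone mean lands on its ground truth, the median R² of 0.999 reflects
the high SNR, and the B0 summary recovers the configured 0 ± 30 Hz residual
regime. The same pipeline with `prep_cluster("simple")` and a 139 Hz bulk
offset (a patellar-like scanner-prescan miscalibration) produces the
characteristic elevated deep/middle-zone T1ρ artifact that the compensated
cluster suppresses.

Summary-statistic utilities work directly from printed group summaries, e.g.
a Welch test on two field strengths:

```r
welch_t_from_summary(summary_group(50.5, 2.4, 6), summary_group(43.9, 2.9, 6))
#>       t    df  p.value mean_diff
#> 1  4.29  9.66  0.00170       6.6

snr_decay_projection(240, 44.1, 40)   # base SNR through T1rho decay
#> [1] 96.9
```

A thin command-line dispatcher over the same functions is at
`inst/cli/rotaframe.R` (subcommands `simulate`, `b0map`, `b1map`,
`calibrate-voltage`, `fit`, `segment`, `snr`, `stats`).

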