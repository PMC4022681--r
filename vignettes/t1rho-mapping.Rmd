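---
title: "Spin-lock T1ρ mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-lock T1ρ mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotaframe)
```

## The measurement and its model

T1ρ is the relaxation time of magnetization locked along an RF field in the
rotating frame. The acquisition prepares the longitudinal magnetization with
a spin-lock cluster of variable duration TSL, reads it out, and fits the
per-voxel series to

$$S(\mathrm{TSL}) = S_0\, e^{-\mathrm{TSL}/T_{1\rho}}.$$

Healthy cartilage T1ρ sits below ~60 ms and increases from the deep to the
superficial zone; focal pathology can more than double it. The quantities
that corrupt this measurement at high field — B0 offset $\Delta f$ (Hz) and
relative transmit field $B_{1\mathrm{rel}}$ — are exactly the ones the
calibration module maps.

## Rotating-frame Bloch model

States are unit 3-vectors in the rotating frame. Hard pulses are
instantaneous Rodrigues rotations about a transverse axis at the RF phase,
scaled by $B_{1\mathrm{rel}}$; by the package's sign convention a 90° pulse
at phase 0 takes $(0,0,1)$ to $(0,-1,0)$. During a lock segment the
effective field is the vector sum of the lock amplitude
$B_{1sl}B_{1\mathrm{rel}}$ (transverse, at the lock phase) and $\Delta f$
(longitudinal). The component of $m$ parallel to the effective field decays
with $T_{1\rho}$; the perpendicular component precesses at the
effective-field frequency $\sqrt{(B_{1sl}B_{1\mathrm{rel}})^2+\Delta f^2}$
and decays with $T_{2\rho}$. This closed form is verified in the tests
against brute-force Bloch integration at 1 µs steps (agreement ≤ 1e-4).

Approximations, all standard for preparation clusters and documented rather
than hidden: relaxation and off-resonance are neglected during the (µs-scale)
hard pulses; equilibrium regrowth is neglected during the (≤ 40 ms) lock;
the segmented gradient-echo readout is modeled as proportional sampling of
the prepared magnetization (no T1-recovery mixing, no k-space/encoding
simulation, no fat signal).

Two cluster modes exist because the interesting claim is comparative:

* `simple` — tip-down 90°, lock at one phase, tip-up; the uncompensated
  failure mode.
* `compensated` — rotary echo with a central 180° refocusing rotation
  *about the lock axis* (tip-down 90° at phase 0, lock TSL/2 at +90°, 180°
  at +90°, lock TSL/2 at 270°, tip-up at phase 0). The tip-up returns the
  locked component to $-z$; since magnitude images are sign-insensitive the
  retained longitudinal magnitude $|m_z|$ is the model signal. The published
  schematic does not fix the phase scheme; the implemented one is declared
  here as this package's scheme, chosen because it cancels the first-order
  B0 and B1 errors (maximum deviation from $e^{-\mathrm{TSL}/T_{1\rho}}$
  over $|\Delta f| \le 200$ Hz, $B_{1\mathrm{rel}} \in [0.85, 1.15]$ is
  ~0.045 versus ~0.42 for `simple` at TSL 20 ms / T1ρ 40 ms).

$T_{2\rho}$ is not separately specified by the acquisition this emulates;
it defaults to $T_{1\rho}$, to which the on-resonance signal is insensitive.

## The synthetic phantom

`phantom_spec()` defines the study conditions; its defaults are fixed and
are not tuned per experiment:

| parameter | default | why |
|---|---|---|
| grid, voxel | 96×96×4, 0.3×0.6×3 mm | high in-plane / coarse through-plane, desk-scale |
| geometry | annular band, bone radius 28 vox, thickness 9 vox, 180° sector, 2-vox fluid rim | patellar-like curved slab over bone with adjacent fluid |
| zone T1ρ | deep 35, middle 45, superficial 55 ms | respects the deep→superficial increase and the healthy < 60 ms range; configuration values, not measured truth |
| fluid T1ρ | 150 ms | long relative to cartilage, below the 300 ms display ceiling |
| B0 field | bulk 0 Hz + per-voxel jitter s.d. 30 Hz (gradient available, default 0) | the post-localized-calibration residual regime, 0 ± 30 Hz; a 139 Hz bulk offset emulates patellar scanner-prescan miscalibration |
| B1rel field | 1.0 ± 0.1 | localized-voltage-setting regime |
| base SNR | 240 | TSL = 0 cartilage SNR; 90 is used where the lowest-SNR regime is the point |
| noise | Gaussian σ = amp/SNR on two quadrature channels, magnitude taken | Rician by construction; background s.d. = 0.655 σ |

What the phantom does **not** emulate — hence what passing tests do not show
about in vivo data: anatomy beyond an annular sector, partial-volume mixing
at tissue interfaces, magic-angle collagen physics (only a configurable
regional T1ρ modifier), coil sensitivity, physiological motion beyond
integer shifts, and T1-recovery contamination of the segmented readout.

## Calibration operations

* **WASSR B0**: the ppm ladder (−0.8…0.8, step 0.1) is converted to Hz
  (γ = 42.5764 MHz/T, so 0.1 ppm ≈ 29.8 Hz at 7 T), each z-spectrum is
  upsampled by cubic spline to a 1 Hz grid, and the interpolated minimum is
  the offset. This interpolated-minimum rule is a deliberate, documented
  simplification of the symmetry-center algorithm the WASSR literature uses;
  for noiseless dips anywhere in the inner 80 % of the range the recovery
  error is under a tenth of the grid spacing, which is sufficient for the
  ±30 Hz regime of interest. Minima on the grid boundary are censored to NaN
  rather than extrapolated.
* **Double-angle B1**: `acos(S2/2S1)` under the full-relaxation (shot TR 5 s)
  regime; no T1 correction term. Ratios outside the arccos domain map to NaN.
* **STEAM voltage**: with three identical pulses the stimulated-echo signal
  is proportional to $\sin^3\alpha$; doubling the transmit voltage doubles
  α under the scanner's voltage→flip linearity, so
  $S_2/S_1 = 8\cos^3\alpha$ and the true 90° reference voltage is
  $V = x\,(90/\alpha)$. The method is scale-invariant in signal units and,
  under 1 % signal noise, recovers V within 6 % across α ∈ [40°, 90°].

## Fitting and quality maps

The linearized fit is unweighted least squares on log-signal (the
computational workhorse); the nonlinear fit is Levenberg–Marquardt on the
exponential, initialized from the linearized estimate. The package keeps
both because their equivalence at high SNR is itself a result worth
reproducing (they agree within 1 % in median at SNR 90), not a choice to be
hidden. R² is computed on the native signal scale for both methods so a
display floor (default 0.8) means the same thing under either; whether a
log-scale R² was intended by the original processing chain is unknowable
from the published material, and the native-scale choice is documented, not
asserted. Values above 300 ms are zeroed for display only — stored maps keep
NaN for invalid voxels and never conflate "invalid" with zero.

Degenerate voxels (nonpositive signal for the log fit, fewer than 3 usable
points, non-decaying slope) are flagged invalid rather than raising errors.
Registration is integer-shift NCC by default: sufficient for simulated
motion and fully testable; on extruded phantoms the through-plane shift is
inherently ambiguous, so the search window there should be set to in-plane
only.

## Segmentation

Zone splitting peels morphological layers (6-neighbour dilation) from the
bone-facing surface and from the outer surface; normalized depth
$(d_{in}-0.5)/(d_{in}+d_{out}-1)$ is binned by cumulative zone fractions.
The default fractions (deep 0.5, middle 0.3, superficial 0.2) follow the
anatomical deep ~50–60 % / superficial ~10–20 % split and are configurable,
since any morphological division is an approximation. On curved geometry the
layer metric is city-block, so zone volume fractions deviate from the
nominal fractions by a few percentage points (curvature makes outer shells
bigger; the tests bound the deviation at 5 points on study geometry). Side
splitting is deliberately manual — a user-supplied divider plane — mirroring
semi-automatic practice.

## Statistics

The ICC is fixed as two-way random, absolute agreement, single measures
(McGraw & Wong ICC(A,1)), the standard test–retest form, with the F-based
95 % CI and an `MSR/MSE` significance test; the implementation is verified
against an `aov()` variance-components oracle to 1e-10. Pearson r is kept
alongside deliberately: it is insensitive to systematic offset or scale,
which the ICC penalizes — the documented contrast. The test–retest CV uses
the two-measurement (n−1) s.d. over the pair mean. Cross-field-strength
comparisons are Welch's t computed from summary statistics (mean, s.d., n),
because per-subject pairings from summary tables are unavailable; this is a
re-check of printed significance, not a replication of the exact test. SNR
uses the 0.655 Rician factor (= $\sqrt{2-\pi/2}$, the
background-magnitude-s.d. to per-channel-σ ratio), averaged over the
background ROIs supplied.

## Numerical choices and problem sizes

Deterministic phantoms derive from a single integer seed (fields at `seed`,
noise at `seed + 1`); rotations conserve $|m|$ to 1e-9; the degenerate
zero-effective-field case falls back to the nominal lock axis. The default
test problem sizes — 96×96×4 phantoms (~3700 cartilage voxels), 2000-voxel
Monte-Carlo fits, 10⁶ Rician draws — were chosen as the smallest sizes at
which the sampling checks (e.g. field s.d. within 30 ± 3 Hz, the Rician
factor within ±0.005) are stable, and the whole suite runs in a few minutes
on one core.

## Known limitations

No DICOM/vendor ingestion; no CEST-scale saturation modeling behind WASSR;
no multi-exponential, B1-corrected or magic-angle-aware fitting; no
automatic cartilage segmentation from raw images; TSLs capped at 40 ms mean
long-T1ρ pathology (≳ 100 ms) is estimated with wide uncertainty, as the
acquisition this emulates itself acknowledges.
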