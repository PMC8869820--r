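---
title: "Models and methods behind holocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holocyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocyte)
```

## The measurement model

Quantitative phase imaging with off-axis digital holographic microscopy
(DHM) measures the optical path-length delay a cell imposes on coherent
light relative to the surrounding buffer.  For a cell of thickness
$d(x, y)$ and volume-averaged (integral) refractive index $n_{cell}$
suspended in a medium of index $n_{medium}$, the phase contrast at
wavelength $\lambda$ is

$$\Delta\varphi(x,y) \;=\; \frac{2\pi}{\lambda}\, d(x,y)\,
  (n_{cell} - n_{medium}).$$

Suspended leukocytes are close to spherical, so the thickness profile of a
cell of radius $R$ centred at $(x_0, y_0)$ is
$d = 2\sqrt{\max(0,\, R^2 - \rho^2)}$ with $\rho$ the in-plane distance
from the centre.  The two unknowns $R$ and $n_{cell}$ enter the
phase profile differently — thickness bends the profile across the whole
disk while index scales it — which is what makes the two parameters
separable ("decoupled") from a single 2-D fit.

Everything downstream is a deterministic function of the fitted
parameters and the segmented outline:

* volume $V = \tfrac{4}{3}\pi R^3$,
* dry mass $DM = (V/\alpha)(n_{cell} - n_{medium})$ with the refractive
  index increment $\alpha = 0.2\,\mathrm{mL/g} \equiv
  0.2\,\mu m^3/\mathrm{pg}$, so $V$ in $\mu m^3$ gives $DM$ in pg,
* form factor $FF = 4\pi A / P^2 \in [0, 1]$ from the projected area $A$
  and perimeter $P$ (1 for a circle; smaller for elongated or irregular
  outlines such as platelet–monocyte complexes).

## Optical configuration and defaults

| parameter | default | unit | why |
|---|---|---|---|
| `wavelength` | 0.532 | µm | frequency-doubled DPSS laser line |
| `n_medium` | 1.337 | — | PBS-type measurement buffer |
| `pixel_scale` | 0.1 | µm/px | 40×-class sampling; a lymphocyte (R ≈ 3.7 µm) projects onto ≈ 73 px, giving the fit > 4000 in-mask pixels |
| `image_shape` | 128 × 128 | px | one cell per field, as in manual single-cell acquisition |
| `carrier_freq` | (0.25, 0.25) | cycles/px | diagonal off-axis tilt, comfortably separating the sideband from DC |
| `noise_sigma` | 0.01 | intensity units | mild sensor noise on fringes of amplitude 2 |

The pixel scale, sensor noise level and carrier are declared defaults, not
measured properties of any particular instrument.  A carrier of 0.25
cycles/px lands on an integer FFT bin of the default 128-px field; off-bin
carriers work but add spectral leakage, so on-bin carriers are
recommended for synthetic studies.

## Hologram synthesis and reconstruction

`synthesize_hologram()` interferes the object wave $O = e^{i\varphi}$ with
a unit tilted plane reference, records
$|O + R|^2 = 2 + 2\cos(\varphi - 2\pi f \cdot x)$, adds Gaussian intensity
noise and clips at zero as a real sensor would.  Speckle and coherent
artifacts are deliberately not modelled.

`reconstruct_hologram()` is the standard single-shot Fourier demodulation:

1. 2-D FFT; locate the strongest peak outside a DC exclusion zone
   (0.05 cycles/px).  An image without such a peak at least 10× above the
   spectral noise floor is rejected as not being an off-axis hologram.
2. Isolate the sideband with a Butterworth window (default radius 0.4×
   the carrier magnitude, order 5) and re-centre it with a circular
   spectral shift.
3. Inverse FFT; the argument of the complex field is the wrapped phase.
4. Unwrap (`unwrap_phase()`, quality-guided flood fill; maps whose
   neighbour differences never exceed π are returned unchanged, which also
   makes unwrapping idempotent).
5. Fit and subtract a 2nd-degree polynomial background over cell-free
   pixels.  The fit is anchored on the median level first — the
   background is the majority of the image — and then iteratively
   re-trimmed, so the polynomial cannot absorb part of the cell signal.
6. Enforce the sign convention that cells are phase-positive (they are
   denser than the buffer): if most excursion energy is negative the map
   is flipped and flagged.

The window inevitably band-limits the reconstruction, so the recovered
phase rings slightly at the cell edge where the sphere profile has an
infinite slope.  Root-mean-square round-trip error is ≈ 0.01 rad; the
maximum error concentrates in a ~2 px edge ring, which is the same ring
the sphere fit excludes from its residual.

`refocus()` implements angular-spectrum propagation with evanescent
components suppressed; for band-limited fields (which is what the
windowed reconstruction produces) propagation conserves energy and
`refocus(d)` ∘ `refocus(-d)` is the identity to numerical precision.
`autofocus()` minimizes the amplitude standard deviation, which is
extremal at best focus for a pure phase object.

## Segmentation and morphometry

Cells are segmented by an absolute phase threshold: 0.1 rad (an order of
magnitude below a lymphocyte peak of ≈ 1.1 rad and well above
reconstruction noise), raised to 5 robust sigma when the background is
noisier.  A histogram-split (Otsu) threshold was considered and rejected
for area measurement: on the smooth dome of a spherical cap it lands
mid-dome (≈ 0.4 rad) and shrinks the projected area by ~15%.  Otsu is
still used inside the reconstruction, where a conservative in-cell mask
is exactly what the background fit and sign check want.

Touching cells are never split; a component with two or more
well-separated phase apices (after a σ = 2 px blur so noise cannot
masquerade as peaks) is flagged `attached` and excluded by QC.
Components are reported in row-major centroid order for determinism.

Perimeter and area come from a sub-pixel marching-squares contour of the
mask, simplified with Ramer–Douglas–Peucker (tolerance 0.9 px).  The
simplification collapses rasterization staircases onto straight runs while
preserving true corners, so a rasterized circle measures $FF$ within 0.02
of 1, a square within 0.02 of $\pi/4$, and an ellipse matches the
Ramanujan-perimeter value — a plain pixel-edge perimeter would bias $FF$
low by up to 10%.  $FF$ is clipped to $[0, 1]$; a pre-clip overshoot above
1.02 flags an inconsistent perimeter estimate.

## The sphere-model fit

`fit_sphere_model()` minimizes

$$\sum_{(x,y) \in \text{mask}} \Big[\varphi(x,y) -
  \tfrac{2\pi}{\lambda}\, 2\sqrt{\max(0, R^2-\rho^2)}\,
  (n_{cell}-n_{medium})\Big]^2$$

over $(x_0, y_0, R, n_{cell})$ jointly by damped Gauss–Newton with the
analytic Jacobian; Levenberg damping activates only when a plain step
fails.  Initialization: centre at the mask centroid, $R_0 = \sqrt{A/\pi}$
from the mask area, $n_0 = n_{medium} + \lambda\varphi_{peak}/(4\pi R_0)$
from the peak phase.  A joint 4-parameter fit rather than alternating 1-D
fits keeps the procedure testable against an exhaustive $(R, n_{cell})$
grid search, with which it agrees to within one grid step (0.01 µm ×
1e-4).

The thickness derivative diverges at $\rho = R$, and edge diffraction
corrupts measured phase there, so a boundary ring (default 2 px, the
`boundary_exclude_px` setting) is excluded from the residual.  Degenerate
inputs (mask under 25 px, projected radius under 3 px, no positive phase)
return a flagged failure rather than an unstable fit.  On noiseless
synthetic input the fit recovers $R$ and $n_{cell}$ essentially exactly;
with 0.05 rad phase noise the 150-cell mean volume stays within 1% of
truth; halving the pixel scale moves the recovered parameters by < 0.2%.

Quality control mirrors the study's manual exclusions with automated
proxies: form factor below 0.65 (deformed / platelet-tethered), fit RMS
residual above 0.15 rad (not sphere-like), per-cell-type volume gates,
and the `attached` flag.  Every exclusion carries a reason code and the
kept/excluded tables partition the input.

## The synthetic cohort

`cohort_spec()` encodes the study conditions: 25 patients sampled
before surgery (PreOP) and on postoperative days 1, 3 and 6, with 150
lymphocytes and 150 monocytes measured per sample.  Cohort-level per-day
means and SDs are fixed at the reported course — lymphocyte volume
208 ± 9 → 218 ± 11 → 210 ± 9 → 210 ± 9 µm³, monocyte volume
390 ± 25 → 413 ± 20 → 414 ± 27 → 400 ± 23 µm³, the monocyte
refractive-index dip at day 1, constant dry mass, and the monocyte form
factor dipping 0.75 → 0.73.  The printed ± values are treated as the SD
of per-patient means across patients.  Quantities the study did not
tabulate (the lymphocyte index course, per-day dry mass, within-sample
spread) are filled with physiologically consistent declared defaults:
dry mass follows from the volume and index courses through the DM
formula, within-sample radius CV is 5%, and the day-1 within-sample
spread is inflated 1.5× to emulate the enlarged day-1 scatter.

Per-patient day levels are chained,
$X_{t} = X_{t-1} + \Delta_t$, where each day difference has a mean shift,
a regression-to-the-mean term $a\,z_{t-1}$ proportional to the
standardized previous-day level, and a fresh innovation $b\,u$.  Given
the configured day SDs $s_{t-1}, s_t$ and innovation SD, $a$ is derived
in closed form so that both days reproduce their configured SDs (for the
monocyte volume this implies the negative baseline–response correlation
needed to shrink 25 µm³ of scatter to 20 µm³).

Marker changes are drawn jointly with the DHM day-one differences
through a Gaussian copula over the innovations, with the correlation
matrix chosen so that the configured difference-scale correlations
(e.g. lymphocyte volume change vs absolute B-cell count change,
$r = -0.514$) are realized; the matrix is projected to the nearest PSD
matrix if an injection set is internally inconsistent.  Two realism
constraints slightly attenuate realized correlations: marker levels are
clamped to their physical ranges (counts ≥ 0, percentages ≤ 100), and
the epinephrine dose is zeroed for untreated patients.  At n = 10,000
homogeneous patients the B-cell pair is still recovered within ±0.02.

Subgroups are assigned by exact counts — 9 complicated courses, 8
epinephrine-treated, 7 with CRP > 14 mg/dL, overlapping 6 and 2 with the
complicated group and not at all with each other — and scaled
proportionally for other cohort sizes.  When subgroup effects are on,
complicated-course and epinephrine patients get no day-1 lymphocyte
volume change, CRP-high patients get an amplified one (default 2×), and
the remaining patients are shifted so the cohort-level mean change stays
at the configured +10 µm³.  Because these group shifts are uncorrelated
with the markers, correlation-recovery experiments use
`subgroup_effects = FALSE`.  Default missingness reproduces the study:
two deceased patients (drawn from the complicated group) contribute only
PreOP samples, and three discharged regular-course patients miss day 6.

## Statistics

* `day_difference()` computes later-minus-baseline per patient, dropping
  (and counting) patients missing a timepoint; correlations use
  pairwise-complete deletion.
* `pearson_matrix()` runs two-sided Pearson tests with t-distribution
  p-values on $n - 2$ df, stars at 0.05/0.01/0.001, sorted by |r| —
  the layout of a day-difference correlation table.  Constant columns
  are flagged degenerate rather than tested.
* `bootstrap_stability()` draws 10,000 full-size with-replacement
  resamples and reports the fraction of resample means leaving a
  ±0.3 SD corridor around the original mean; each resample omits
  $(1 - 1/n)^n$ (36.7% at n = 150) of the distinct entities on average.
  Resampling is at the measurement-entity (cell or patient-difference)
  level.
* `bh_adjust()` is the Benjamini–Hochberg step-up via `stats::p.adjust`;
  the significance level is 0.05 throughout and error control is
  comparison-wise.
* `subgroup_compare()` uses a Welch two-sample t-test by default (the
  dichotomized groups are small and unbalanced), switchable to Wilcoxon;
  within-patient day contrasts in `summarize_days()` use paired t-tests.

## Numerical choices and determinism

Every stochastic entry point takes a `seed`; fixed seeds give
bit-identical outputs, and the pipeline derives per-stage child seeds
from one run seed.  Ties in component labeling and mask ordering are
resolved row-major.  FFT sideband selection prefers the configured
carrier convention (first non-zero component positive).  The Gauss–Newton
tolerance is 1e-10 on the relative step with at most 60 iterations.

Test and validation problem sizes were chosen so the full suite runs in
about a minute: 150-cell samples for recovery statistics, 1,200 patients
for generator moment checks, 10,000 patients for correlation injection,
10,000 replicates for test calibration.

## What the synthetic experiments do and do not show

The generator emulates spherical cells with the reported population
parameters, ideal two-beam interference with additive Gaussian sensor
noise, and a cohort with the reported correlation and subgroup structure.
It does not emulate speckle or parasitic interference, optical
aberrations beyond a low-order background, real leukocyte subpopulation
structure, platelet tethering, or preparation-induced artifacts.  Passing
recovery tests therefore demonstrates that the algorithms are correct and
unbiased under the stated physics, not that a particular instrument
achieves these accuracies on patient samples.  Ellipsoidal phantoms are
rendered (for QC tests) but the thickness model is always fitted as a
sphere, matching the measurement procedure.
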