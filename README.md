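# holocyte

Label-free biophysical profiling of suspended leukocytes with off-axis
digital holographic microscopy (DHM), for quantitative-phase-imaging
researchers and for statisticians working with perioperative cohort data
built from such measurements.

A cell of thickness *d(x, y)* and integral refractive index *n*<sub>cell</sub>
in a buffer of index *n*<sub>medium</sub> delays coherent light of
wavelength λ by

> Δφ(x, y) = (2π/λ) · d(x, y) · (n<sub>cell</sub> − n<sub>medium</sub>)

Suspended leukocytes are near-spherical, so with
d = 2·√(max(0, R² − ρ²)) a single 2-D Gauss–Newton fit of the phase image
decouples the radius *R* from *n*<sub>cell</sub>. The package implements
the whole chain around that fit:

* **synth** — ground-truthed sphere/spheroid phantoms, their phase images
  and off-axis holograms, and a 25-patient × 4-timepoint perioperative
  cohort simulator with injectable marker correlations, subgroup
  structure and dropout;
* **holo** — hologram reconstruction (Fourier sideband demodulation,
  quality-guided phase unwrapping, polynomial background removal) and
  angular-spectrum refocusing;
* **morpho** — segmentation, the sphere-model fit, volume
  V = (4/3)πR³, dry mass DM = (V/α)(n<sub>cell</sub> − n<sub>medium</sub>)
  (α = 0.2 mL/g), form factor FF = 4πA/P² from sub-pixel contours, and QC
  exclusion rules;
* **stats** — per-sample aggregation, day differences, two-sided Pearson
  correlation tables, a 10,000-resample bootstrap stability test with a
  ±0.3 SD corridor and Benjamini–Hochberg adjustment, and dichotomized
  subgroup comparisons;
* **pipeline** — an end-to-end, seeded, CSV-checkpointed run.

All tabular results are tibbles; fitted objects have `tidy()`/`glance()`
methods and result types have `autoplot()` methods.

## Worked example

Render a lymphocyte-like phantom, record and reconstruct its off-axis
hologram, and measure it:

```r
library(holocyte)

cfg     <- optical_config()               # 532 nm, n_medium 1.337, 0.1 um/px
phantom <- phantom_population(1, radius_mean = 3.675, radius_sd = 0,
                              n_cell_mean = 1.3497, n_cell_sd = 0, seed = 1)
truth   <- render_phase_image(phantom, cfg)
truth
#> <phase_image> 128 x 128 px @ 0.1 um/px (synthetic)
#>   phase range: [0.0000, 1.1022] rad

holo  <- synthesize_hologram(truth, cfg, seed = 1)
rec   <- reconstruct_hologram(holo)
cells <- measure_cells(rec, cfg, label = "lymphocyte")
cells[, c("R_um", "n_cell", "V_um3", "DM_pg", "A_um2", "FF", "residual_rms")]
#>     R_um n_cell    V_um3   DM_pg A_um2     FF residual_rms
#> 1 3.6792 1.3497 208.6132 13.2257 42.69 0.9903       0.0049
```

The 3.675 µm, n 1.3497 ground truth comes back as R = 3.679 µm,
n = 1.3497 through the full record–reconstruct–fit chain: a 208.6 µm³
volume (truth 207.9), 13.2 pg of dry mass, a near-circular outline
(FF 0.99), and a 5 mrad RMS fit residual.

Cohort-level statistics on a simulated perioperative cohort:

```r
co <- simulate_cohort(cohort_spec(seed = 1))
d  <- day_difference(co, "d1", "PreOP")
pearson_matrix(d, "delta_V_lymphocyte", "delta_CD19_abs")
#>   var1               var2                r p_value     n degenerate stars
#> 1 delta_V_lymphocyte delta_CD19_abs -0.141   0.522    23 FALSE      ""

bootstrap_stability(d$delta_V_lymphocyte, n_boot = 10000, seed = 1)
#> <bootstrap_stability> n = 23, 10000 resamples, corridor 0.30 SD: sample p = 0.1421

subgroup_overlap(co)[, c("complicated", "epinephrine", "crp_high")]
#>   complicated epinephrine crp_high
#> 1           9           8        7
```

At the realistic cohort size (23 patients with complete day-1 data after
the configured dropout) the injected volume/B-cell association is washed
out by subgroup heterogeneity and sampling noise — exactly the situation
the bootstrap stability test and subgroup comparisons are for. With
`cohort_spec(n_patients = 10000, subgroup_effects = FALSE)` the injected
r = −0.514 is recovered within ±0.02.

## Documentation

The methods vignette (`vignettes/holocyte-methods.Rmd`) documents the
measurement model, the reconstruction and fitting design decisions, the
cohort generator's statistical construction, and what the synthetic
experiments do and do not demonstrate.
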