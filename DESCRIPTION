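Package: holocyte
Title: Digital Holographic Microscopy Morphometry and Cohort Statistics for
    Suspended Leukocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free biophysical profiling of suspended
    leukocytes with off-axis digital holographic microscopy (DHM).
    Simulates ground-truthed cell phantoms and their off-axis holograms,
    reconstructs quantitative phase images by Fourier sideband demodulation
    with phase unwrapping and polynomial background removal, retrieves the
    integral cellular refractive index and radius per cell by a damped
    Gauss-Newton fit of a sphere-projection phase model, derives cell
    volume, dry mass and shape form factor, and aggregates per-cell
    measurements into patient-by-timepoint cohort tables.  Includes the
    perioperative statistical machinery used with such data: day-difference
    Pearson correlations, a bootstrap stability test with
    Benjamini-Hochberg adjustment, and dichotomized subgroup comparisons,
    together with a synthetic perioperative cohort simulator with
    injectable marker correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
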