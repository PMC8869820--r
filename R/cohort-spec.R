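#' Specification of the synthetic perioperative cohort
#'
#' Encodes the study conditions the simulator reproduces: 25 patients
#' sampled at PreOP, d1, d3 and d6 with 150 lymphocytes and 150 monocytes
#' per sample; per-day cohort means and between-patient SDs of volume,
#' refractive index, dry mass and form factor for both cell types
#' (lymphocyte volume rising from 208 +/- 9 um^3 to 218 +/- 11 um^3 at d1,
#' monocytes from 390 +/- 25 to 413 +/- 20 um^3, with recovery over d3/d6);
#' flow-cytometry marker models; a correlation matrix linking
#' day-difference quantities (e.g. lymphocyte volume change vs change in
#' absolute B-cell count, r = -0.514); and dichotomized subgroups
#' (9 complicated course, 8 epinephrine-treated, 7 with CRP > 14 mg/dL;
#' 6 complicated+epinephrine, 2 complicated+CRP-high, no
#' epinephrine/CRP-high overlap).
#'
#' The printed per-day "+/-" figures are interpreted as the SD of
#' per-patient means across patients.  Day levels are generated by chaining
#' day-difference innovations onto a baseline draw; the baseline-difference
#' correlation is derived internally so that both the baseline and the
#' later-day SDs match their configured values.
#'
#' @param n_patients Number of patients (default 25).
#' @param timepoints Ordered timepoint labels.
#' @param cells_per_sample Cells measured per cell type per sample
#'   (default 150).
#' @param dhm_day_stats Tibble with columns `cell_type`, `parameter`
#'   (`V`, `n_cell`, `DM`, `FF`), `timepoint`, `mean`, `sd`; defaults via
#'   [default_dhm_day_stats()].
#' @param delta_sd Tibble with columns `cell_type`, `parameter`, `sd`: the
#'   stochastic SD of the per-patient day-to-day innovation.
#' @param markers Tibble of marker models; see [default_marker_models()].
#' @param delta_correlations Tibble with columns `var1`, `var2`, `r`:
#'   correlations injected between day-difference quantities
#'   (first-to-second timepoint).  Variables are named
#'   `<parameter>_<cell_type>` for DHM quantities (e.g. `V_lymphocyte`),
#'   by marker name, or `epinephrine_dose`.
#' @param subgroup_counts Named list with entries `complicated`,
#'   `epinephrine`, `crp_high`, `comp_epi`, `comp_crp`, `epi_crp`; counts
#'   refer to a 25-patient cohort and are scaled proportionally otherwise.
#' @param subgroup_effects If `TRUE`, the lymphocyte d1 volume response is
#'   group-dependent: complicated-course and epinephrine patients get no
#'   volume change, CRP-high patients an amplified one, and the remaining
#'   patients a compensating shift so the cohort-level day mean is
#'   preserved.
#' @param crp_amplification Multiplier on the mean lymphocyte volume change
#'   for CRP-high patients (default 2).
#' @param radius_cv Within-sample coefficient of variation of the cell
#'   radius (default 0.05).
#' @param d1_spread_multiplier Multiplier on within-sample spread at the
#'   second timepoint, emulating the enlarged d1 scatter (default 1.5).
#' @param dropout If `TRUE`, reproduces the study's missingness: two
#'   deceased patients contribute only PreOP samples and three discharged
#'   patients miss d6 (scaled for other cohort sizes).
#' @param seed Optional integer seed.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$n_patients
#' @export
cohort_spec <- function(n_patients = 25L,
                        timepoints = c("PreOP", "d1", "d3", "d6"),
                        cells_per_sample = 150L,
                        dhm_day_stats = default_dhm_day_stats(timepoints),
                        delta_sd = default_delta_sd(),
                        markers = default_marker_models(),
                        delta_correlations = default_delta_correlations(),
                        subgroup_counts = list(complicated = 9L, epinephrine = 8L,
                                               crp_high = 7L, comp_epi = 6L,
                                               comp_crp = 2L, epi_crp = 0L),
                        subgroup_effects = TRUE,
                        crp_amplification = 2,
                        radius_cv = 0.05,
                        d1_spread_multiplier = 1.5,
                        dropout = TRUE,
                        seed = NULL) {
  stopifnot(n_patients >= 1, cells_per_sample >= 1, length(timepoints) >= 2,
            all(dhm_day_stats$sd >= 0), all(delta_sd$sd >= 0),
            radius_cv >= 0, d1_spread_multiplier > 0)
  if (any(abs(delta_correlations$r) > 1)) {
    stop("injected correlations must lie in [-1, 1]", call. = FALSE)
  }
  need <- expand.grid(cell_type = unique(dhm_day_stats$cell_type),
                      timepoint = timepoints)
  structure(
    list(
      n_patients = as.integer(n_patients),
      timepoints = timepoints,
      cells_per_sample = as.integer(cells_per_sample),
      dhm_day_stats = dhm_day_stats,
      delta_sd = delta_sd,
      markers = markers,
      delta_correlations = delta_correlations,
      subgroup_counts = subgroup_counts,
      subgroup_effects = isTRUE(subgroup_effects),
      crp_amplification = crp_amplification,
      radius_cv = radius_cv,
      d1_spread_multiplier = d1_spread_multiplier,
      dropout = isTRUE(dropout),
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' Default per-day DHM parameter statistics
#'
#' Cohort-level means and between-patient SDs per cell type, parameter and
#' timepoint: volumes and their perioperative course for both cell types,
#' the monocyte refractive-index dip at d1, constant dry mass, and the
#' monocyte form-factor dip at d1.  Values for quantities the study did not
#' tabulate (lymphocyte refractive-index course, per-day dry mass, absolute
#' lymphocyte form factor) are filled with physiologically consistent
#' figures: dry mass follows DM = (V/0.2)(n_cell - n_medium) from the
#' volume and index courses, and non-significant courses are near-flat.
#'
#' @param timepoints Ordered timepoint labels (4 expected).
#' @return A tibble with columns `cell_type`, `parameter`, `timepoint`,
#'   `mean`, `sd`.
#' @export
default_dhm_day_stats <- function(timepoints = c("PreOP", "d1", "d3", "d6")) {
  stopifnot(length(timepoints) == 4)
  rows <- list(
    list("lymphocyte", "V",      c(208, 218, 210, 210),   c(9, 11, 9, 9)),
    list("monocyte",   "V",      c(390, 413, 414, 400),   c(25, 20, 27, 23)),
    list("lymphocyte", "n_cell", c(1.3497, 1.3492, 1.3494, 1.3496), rep(1e-4, 4)),
    list("monocyte",   "n_cell", c(1.3497, 1.3485, 1.3490, 1.3494), rep(1e-4, 4)),
    list("lymphocyte", "DM",     c(13.2, 13.2, 13.2, 13.2), rep(0.8, 4)),
    list("monocyte",   "DM",     c(24.8, 24.8, 24.8, 24.8), rep(1.5, 4)),
    list("lymphocyte", "FF",     c(0.80, 0.80, 0.80, 0.80), rep(0.03, 4)),
    list("monocyte",   "FF",     c(0.75, 0.73, 0.74, 0.75), c(0.03, 0.04, 0.03, 0.03))
  )
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(cell_type = r[[1]], parameter = r[[2]],
                   timepoint = timepoints, mean = r[[3]], sd = r[[4]])
  })
}

#' Default stochastic day-to-day innovation SDs
#'
#' Within-patient SD of the day-difference beyond any subgroup shift, per
#' cell type and parameter.  The lymphocyte volume figure (6.3 um^3) makes
#' the PreOP and d1 between-patient SDs (9 and 11 um^3) mutually consistent
#' under an uncorrelated baseline; the monocyte figure implies the
#' regression-to-the-mean correlation needed to shrink the SD from 25 to
#' 20 um^3.
#'
#' @return A tibble with columns `cell_type`, `parameter`, `sd`.
#' @export
default_delta_sd <- function() {
  tibble::tribble(
    ~cell_type,    ~parameter, ~sd,
    "lymphocyte",  "V",        6.3,
    "monocyte",    "V",        15,
    "lymphocyte",  "n_cell",   1e-4,
    "monocyte",    "n_cell",   1e-4,
    "lymphocyte",  "DM",       0.6,
    "monocyte",    "DM",       1.2,
    "lymphocyte",  "FF",       0.025,
    "monocyte",    "FF",       0.025
  )
}

#' Default flow-cytometry marker models
#'
#' Baseline mean/SD, first-postoperative-day change mean/SD, and the SD of
#' the later random-walk steps, for the markers carried alongside the DHM
#' aggregates.  Units: `CD19_abs` and `platelets` are absolute counts
#' (cells/uL and 10^9/L), the remaining markers are percentages of their
#' parent gate.
#'
#' @return A tibble with columns `marker`, `baseline_mean`, `baseline_sd`,
#'   `d1_delta_mean`, `d1_delta_sd`, `later_delta_sd`, `is_percent`.
#' @export
default_marker_models <- function() {
  tibble::tribble(
    ~marker,                    ~baseline_mean, ~baseline_sd, ~d1_delta_mean, ~d1_delta_sd, ~later_delta_sd, ~is_percent,
    "CD19_abs",                 190,            70,           -25,            60,           30,              FALSE,
    "CD19_rel",                 9,              3,            1.0,            2.5,          1.5,             TRUE,
    "CD86",                     25,             8,            3,              7,            4,               TRUE,
    "mHLA_DR",                  90,             12,           -12,            10,           6,               TRUE,
    "mCD206",                   18,             6,            4,              6,            3,               TRUE,
    "necrosis_late_apoptosis",  4,              2,            2.5,            2.5,          1.5,             TRUE,
    "CD3",                      70,             8,            -6,             7,            4,               TRUE,
    "CD4",                      45,             7,            -4,             6,            3,               TRUE,
    "platelets",                230,            55,           -45,            35,           25,              FALSE
  )
}

#' Default injected day-difference correlations
#'
#' The significant bivariate associations between DHM parameter changes and
#' marker/dose changes on the first-to-second-timepoint difference scale,
#' in descending magnitude, plus the two intra-DHM associations.
#'
#' @return A tibble with columns `var1`, `var2`, `r`.
#' @export
default_delta_correlations <- function() {
  tibble::tribble(
    ~var1,               ~var2,                     ~r,
    "V_lymphocyte",      "CD19_abs",                -0.514,
    "V_lymphocyte",      "epinephrine_dose",        -0.484,
    "V_monocyte",        "necrosis_late_apoptosis",  0.479,
    "n_cell_lymphocyte", "CD86",                     0.464,
    "FF_monocyte",       "mHLA_DR",                  0.464,
    "n_cell_monocyte",   "necrosis_late_apoptosis", -0.44,
    "V_monocyte",        "n_cell_monocyte",         -0.431,
    "n_cell_monocyte",   "mCD206",                   0.405,
    "FF_monocyte",       "n_cell_monocyte",          0.401
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d patients x %s, %d cells/sample/type\n",
              x$n_patients, paste(x$timepoints, collapse = "/"),
              x$cells_per_sample))
  cat(sprintf("  subgroup effects: %s, dropout: %s, seed: %s\n",
              x$subgroup_effects, x$dropout,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  %d injected delta correlations\n", nrow(x$delta_correlations)))
  invisible(x)
}
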