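#' Configuration of an end-to-end pipeline run
#'
#' @param output_dir Directory for the run's CSV checkpoints and log.
#' @param optics An [optical_config()].
#' @param cohort A [cohort_spec()].
#' @param fit A [fit_settings()].
#' @param qc A [qc_rules()].
#' @param contrast Character pair `c(later, baseline)` for the
#'   day-difference statistics (default `c("d1", "PreOP")`).
#' @param n_boot,corridor Bootstrap settings.
#' @param mode `"aggregates"` simulates cohort-level aggregates directly;
#'   `"images"` additionally renders, records, reconstructs and fits every
#'   cell of every sample (slow; intended for reduced cohort sizes).
#' @param seed Integer seed governing every random draw of the run.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       optics = optical_config(),
                       cohort = cohort_spec(),
                       fit = fit_settings(),
                       qc = qc_rules(),
                       contrast = c("d1", "PreOP"),
                       n_boot = 10000L,
                       corridor = 0.3,
                       mode = c("aggregates", "images"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(optics, "optical_config"), inherits(cohort, "cohort_spec"),
            inherits(fit, "fit_settings"), inherits(qc, "qc_rules"),
            length(contrast) == 2, is.numeric(seed))
  structure(
    list(output_dir = output_dir, optics = optics, cohort = cohort,
         fit = fit, qc = qc, contrast = contrast, n_boot = n_boot,
         corridor = corridor, mode = mode, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (synthesize -> reconstruct -> fit ->) aggregate ->
#' statistics, checkpointing each stage as CSV in the output directory:
#' `cohort.csv` (patient x timepoint x cell-type aggregates),
#' `cells/<sample>.csv` (per-cell measurements, images mode only),
#' `correlations.csv` (day-difference Pearson table),
#' `day_summary.csv` and `day_contrasts.csv` (perioperative course),
#' `subgroups.csv` (dichotomized group comparisons and overlap counts),
#' `bootstrap.csv`, and `run_log.txt` with per-stage counts.  A fixed seed
#' makes the whole run byte-reproducible.
#'
#' @param config A [run_config()].
#'
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `deltas`, `correlations`, `day_summary`, `subgroups`, `bootstrap`,
#'   `log`) and the output paths.
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"), seed = 1)
#' res <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  spec <- config$cohort
  spec$seed <- derive_seed(config$seed, 1L)
  log_add("stage simulate: %d patients x %s", spec$n_patients,
          paste(spec$timepoints, collapse = "/"))
  cohort <- simulate_cohort(spec, emit_phantoms = config$mode == "images")

  if (config$mode == "images") {
    cohort <- run_imaging_stage(cohort, config, log_add)
  }
  write_cohort_csv(cohort, file.path(config$output_dir, "cohort.csv"))
  log_add("stage cohort: %d sample rows", nrow(cohort))

  deltas <- day_difference(cohort, config$contrast[1], config$contrast[2])
  log_add("stage deltas: %d patients complete, %d dropped",
          nrow(deltas), attr(deltas, "n_dropped_any"))

  correlations <- pearson_matrix(deltas)
  readr::write_csv(correlations, file.path(config$output_dir, "correlations.csv"))

  day <- summarize_days(cohort)
  readr::write_csv(day$summary, file.path(config$output_dir, "day_summary.csv"))
  readr::write_csv(day$contrasts, file.path(config$output_dir, "day_contrasts.csv"))

  overlap <- subgroup_overlap(cohort)
  comparisons <- purrr::map_dfr(
    c("complicated_course", "epinephrine", "crp_high"),
    function(g) {
      tryCatch(subgroup_compare(deltas, g, "delta_V_lymphocyte"),
               error = function(e) {
                 log_add("stage subgroups: skipping %s (%s)", g,
                         conditionMessage(e))
                 NULL
               })
    }
  )
  readr::write_csv(comparisons, file.path(config$output_dir, "subgroups.csv"))
  readr::write_csv(overlap, file.path(config$output_dir, "subgroup_overlap.csv"))
  log_add("stage subgroups: %d/%d/%d patients (complicated/epinephrine/CRP-high)",
          overlap$complicated, overlap$epinephrine, overlap$crp_high)

  boot <- tryCatch(
    bootstrap_cohort(cohort, config$contrast[1], config$contrast[2],
                     n_boot = config$n_boot, corridor = config$corridor,
                     seed = derive_seed(config$seed, 2L)),
    error = function(e) {
      log_add("stage bootstrap: skipped (%s)", conditionMessage(e))
      NULL
    }
  )
  if (!is.null(boot)) {
    readr::write_csv(boot, file.path(config$output_dir, "bootstrap.csv"))
  }

  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(list(
    cohort = cohort, deltas = deltas, correlations = correlations,
    day_summary = day, subgroups = list(overlap = overlap,
                                        comparisons = comparisons),
    bootstrap = boot, log = log_lines, output_dir = config$output_dir
  ))
}

# Imaging mode: replace the drawn aggregates by aggregates measured from
# rendered/recorded/reconstructed/fitted cells of the emitted phantoms.
run_imaging_stage <- function(cohort, config, log_add) {
  phantoms <- attr(cohort, "phantoms")
  cells_dir <- file.path(config$output_dir, "cells")
  dir.create(cells_dir, recursive = TRUE, showWarnings = FALSE)
  n_rendered <- n_kept <- n_excluded <- 0L
  for (j in seq_len(nrow(cohort))) {
    key <- paste(cohort$patient_id[j], cohort$timepoint[j],
                 cohort$cell_type[j], sep = "_")
    ph <- phantoms[[key]]
    cells <- measure_phantom_sample(
      ph, config$optics, settings = config$fit,
      seed = derive_seed(config$seed, 100L + j)
    )
    qcres <- qc_filter(cells, config$qc)
    n_rendered <- n_rendered + nrow(cells)
    n_kept <- n_kept + nrow(qcres$kept)
    n_excluded <- n_excluded + nrow(qcres$excluded)
    readr::write_csv(cells, file.path(cells_dir, paste0(key, ".csv")))
    if (nrow(qcres$kept) > 0) {
      agg <- aggregate_cells(qcres$kept)
      cohort$n_cells[j] <- agg$n_cells
      for (col in c("V_mean", "V_sd", "n_cell_mean", "n_cell_sd",
                    "DM_mean", "DM_sd", "FF_mean", "FF_sd")) {
        cohort[[col]][j] <- agg[[col]]
      }
    }
  }
  log_add("stage imaging: %d cells rendered = %d kept + %d excluded",
          n_rendered, n_kept, n_excluded)
  cohort
}

#' Measure a phantom sample through the full imaging chain
#'
#' For each phantom: render the phase image, synthesize the off-axis
#' hologram (with the configured noise), reconstruct, and fit the sphere
#' model.  One cell per field of view, as in manual single-cell
#' acquisition.
#'
#' @param phantoms Phantom tibble ([phantom_population()] layout).
#' @param config An [optical_config()].
#' @param settings A [fit_settings()].
#' @param seed Optional seed for the hologram noise.
#' @param reconstruct If `FALSE`, fit the rendered phase directly
#'   (no hologram round trip).
#'
#' @return A measurement tibble ([measure_cells()] layout).
#' @export
measure_phantom_sample <- function(phantoms, config,
                                   settings = fit_settings(),
                                   seed = NULL, reconstruct = TRUE) {
  purrr::map_dfr(seq_len(nrow(phantoms)), function(i) {
    truth <- render_phase_image(phantoms[i, ], config)
    img <- if (reconstruct) {
      holo <- synthesize_hologram(truth, config, seed = derive_seed(seed, i))
      reconstruct_hologram(holo)
    } else {
      truth
    }
    m <- measure_cells(img, config, label = phantoms$label[i])
    if (nrow(m) > 0) m$cell_id <- phantoms$cell_id[i]
    m
  })
}
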