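#' Aggregate QC-kept per-cell measurements into a sample summary
#'
#' Arithmetic mean and sample SD (denominator n-1) of volume, refractive
#' index, dry mass and form factor over the kept cells of one
#' patient/timepoint/cell-type sample — the "average value from a fraction
#' of 150 cells" that all cohort statistics operate on.
#'
#' @param cells Measurement tibble (e.g. from [measure_cells()] after
#'   [qc_filter()]); must contain `V_um3`, `n_cell`, `DM_pg`, `FF`.
#' @param patient_id,timepoint,cell_type Optional identifiers copied into
#'   the output row.
#'
#' @return A one-row tibble with `n_cells` and `<param>_mean` /
#'   `<param>_sd` columns matching the cohort-table layout.
#' @examples
#' cells <- tibble::tibble(V_um3 = c(100, 200, 300), n_cell = 1.35,
#'                         DM_pg = 13, FF = 0.9)
#' aggregate_cells(cells)
#' @export
aggregate_cells <- function(cells, patient_id = NA_character_,
                            timepoint = NA_character_,
                            cell_type = NA_character_) {
  if (nrow(cells) < 1) stop("no cells to aggregate", call. = FALSE)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  tibble::tibble(
    patient_id = patient_id,
    timepoint = timepoint,
    cell_type = cell_type,
    n_cells = nrow(cells),
    V_mean = mean(cells$V_um3), V_sd = sd0(cells$V_um3),
    n_cell_mean = mean(cells$n_cell), n_cell_sd = sd0(cells$n_cell),
    DM_mean = mean(cells$DM_pg), DM_sd = sd0(cells$DM_pg),
    FF_mean = mean(cells$FF), FF_sd = sd0(cells$FF)
  )
}

#' Per-patient day differences of cohort columns
#'
#' Computes `value(later) - value(baseline)` per patient (and cell type,
#' where the column is cell-type specific).  Patients missing either
#' timepoint are dropped; the number dropped per column is reported in the
#' `n_dropped` attribute.
#'
#' @param cohort A cohort table ([simulate_cohort()] layout).
#' @param later,baseline Timepoint labels, e.g. `"d1"`, `"PreOP"`.
#' @param columns Character vector of value columns to difference.  DHM
#'   aggregate columns (`V_mean`, ...) are differenced within cell type and
#'   widened to `<parameter>_<cell_type>` delta columns; marker/clinical
#'   columns (identical across the two cell-type rows) are differenced per
#'   patient.  Default: lymphocyte/monocyte `V`, `n_cell`, `DM`, `FF`
#'   plus every marker, `CRP` and `epinephrine_dose`.
#'
#' @return A tibble with one row per patient with complete data:
#'   `patient_id`, subgroup labels, and one `delta_*` column per requested
#'   quantity.  Attribute `n_dropped` records patients lost per column.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' deltas <- day_difference(cohort, "d1", "PreOP")
#' names(deltas)
#' @export
day_difference <- function(cohort, later, baseline, columns = NULL) {
  tps <- levels(factor(cohort$timepoint))
  if (!(later %in% cohort$timepoint) && !(later %in% tps)) {
    stop(sprintf("unknown timepoint label '%s'", later), call. = FALSE)
  }
  if (!(baseline %in% cohort$timepoint) && !(baseline %in% tps)) {
    stop(sprintf("unknown timepoint label '%s'", baseline), call. = FALSE)
  }

  dhm_cols <- c(V = "V_mean", n_cell = "n_cell_mean",
                DM = "DM_mean", FF = "FF_mean")
  group_cols <- intersect(c("complicated_course", "epinephrine", "crp_high"),
                          names(cohort))
  id_cols <- c("patient_id", "timepoint", "cell_type", group_cols)
  shared_cols <- setdiff(
    names(cohort)[vapply(cohort, is.numeric, logical(1))],
    c(dhm_cols, "V_sd", "n_cell_sd", "DM_sd", "FF_sd", "n_cells")
  )
  if (is.null(columns)) columns <- c(dhm_cols, shared_cols)

  lat <- cohort[cohort$timepoint == later, , drop = FALSE]
  bas <- cohort[cohort$timepoint == baseline, , drop = FALSE]

  out <- tibble::tibble(patient_id = sort(unique(cohort$patient_id)))

  # subgroup labels per patient
  for (g in group_cols) {
    out[[g]] <- cohort[[g]][match(out$patient_id, cohort$patient_id)]
  }

  # cell-type specific DHM deltas
  for (par in names(dhm_cols)) {
    col <- dhm_cols[[par]]
    if (!(col %in% columns)) next
    for (ct in unique(cohort$cell_type)) {
      l <- lat[lat$cell_type == ct, , drop = FALSE]
      b <- bas[bas$cell_type == ct, , drop = FALSE]
      d <- l[[col]][match(out$patient_id, l$patient_id)] -
        b[[col]][match(out$patient_id, b$patient_id)]
      out[[paste0("delta_", par, "_", ct)]] <- d
    }
  }

  # patient-level shared columns (markers, CRP, dose): use the first
  # cell-type row per patient/timepoint
  lat1 <- lat[!duplicated(lat$patient_id), , drop = FALSE]
  bas1 <- bas[!duplicated(bas$patient_id), , drop = FALSE]
  for (col in intersect(columns, shared_cols)) {
    out[[paste0("delta_", col)]] <-
      lat1[[col]][match(out$patient_id, lat1$patient_id)] -
      bas1[[col]][match(out$patient_id, bas1$patient_id)]
  }

  # drop patients missing either timepoint entirely; partially missing
  # columns are left NA for pairwise-complete handling downstream
  delta_cols <- grep("^delta_", names(out), value = TRUE)
  n_dropped <- vapply(out[delta_cols], function(x) sum(is.na(x)), integer(1))
  all_na <- rowSums(!is.na(out[delta_cols])) == 0
  res <- out[!all_na, , drop = FALSE]
  attr(res, "n_dropped") <- n_dropped
  attr(res, "n_dropped_any") <- sum(all_na)
  res
}
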