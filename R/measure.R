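#' Measure all cells in a phase image
#'
#' The single-image analysis chain: [segment_cells()], then
#' [fit_sphere_model()] per component, then derived parameters.  Output
#' follows the per-cell measurement record used throughout the package:
#' fitted centre, radius and refractive index, volume
#' \eqn{V = (4/3)\pi R^3}, dry mass \eqn{DM = (V/\alpha)(n_{cell} -
#' n_{medium})}, segmented projected area A, perimeter P and form factor
#' \eqn{FF = 4\pi A/P^2}, the fit RMS residual, and accumulated QC flags.
#'
#' @param phase A [phase_image()].
#' @param config An [optical_config()].
#' @param label Cell-type tag stored with every measurement.
#' @param min_area,max_area Segmentation area gates in um^2.
#' @param settings A [fit_settings()].
#'
#' @return A tibble with columns `cell_id`, `label`, `x0_um`, `y0_um`,
#'   `R_um`, `n_cell`, `V_um3`, `DM_pg`, `A_um2`, `P_um`, `FF`,
#'   `residual_rms`, `qc_flags` (comma-joined, empty when clean).
#' @examples
#' cfg <- optical_config()
#' ph <- phantom_population(1, 3.675, 0, seed = 1)
#' measure_cells(render_phase_image(ph, cfg), cfg)
#' @export
measure_cells <- function(phase, config,
                          label = "lymphocyte",
                          min_area = 10, max_area = 400,
                          settings = fit_settings()) {
  seg <- segment_cells(phase, min_area = min_area, max_area = max_area)
  if (nrow(seg) == 0) return(empty_measurement_table())
  rows <- purrr::map(seq_len(nrow(seg)), function(i) {
    fit <- fit_sphere_model(phase, seg$mask[[i]], config, settings)
    flags <- character(0)
    if (seg$attached[i]) flags <- c(flags, "attached")
    if (fit$fit_failed) flags <- c(flags, "fit_failed")
    if (seg$form_factor_raw[i] > 1.02) flags <- c(flags, "perimeter_inconsistent")
    tibble::tibble(
      cell_id = i,
      label = label,
      x0_um = fit$x0_um, y0_um = fit$y0_um,
      R_um = fit$R_um, n_cell = fit$n_cell,
      V_um3 = fit$V_um3, DM_pg = fit$DM_pg,
      A_um2 = seg$area_um2[i], P_um = seg$perimeter_um[i],
      FF = seg$form_factor[i],
      residual_rms = fit$residual_rms,
      qc_flags = paste(flags, collapse = ",")
    )
  })
  dplyr::bind_rows(rows)
}

empty_measurement_table <- function() {
  tibble::tibble(
    cell_id = integer(), label = character(), x0_um = numeric(),
    y0_um = numeric(), R_um = numeric(), n_cell = numeric(),
    V_um3 = numeric(), DM_pg = numeric(), A_um2 = numeric(),
    P_um = numeric(), FF = numeric(), residual_rms = numeric(),
    qc_flags = character()
  )
}

#' QC exclusion rules for per-cell measurements
#'
#' Automated proxies for the manual exclusion of damaged, deformed or
#' platelet-tethered cells: a form-factor floor (non-spherical outlines,
#' e.g. platelet-monocyte complexes), a residual ceiling (phase profiles
#' the sphere model cannot explain), per-cell-type volume gates, and the
#' `attached` segmentation flag.
#'
#' @param ff_min Minimum form factor (default 0.65).
#' @param residual_max Maximum fit RMS residual in rad (default 0.15).
#' @param volume_gates Named list mapping cell-type label to `c(min, max)`
#'   volume in um^3; types without an entry are not gated.
#'
#' @return An object of class `qc_rules`.
#' @export
qc_rules <- function(ff_min = 0.65,
                     residual_max = 0.15,
                     volume_gates = list(lymphocyte = c(80, 450),
                                         monocyte = c(150, 800))) {
  structure(
    list(ff_min = ff_min, residual_max = residual_max,
         volume_gates = volume_gates),
    class = "qc_rules"
  )
}

#' Partition measurements into QC-kept and QC-excluded cells
#'
#' @param cells A measurement tibble from [measure_cells()].
#' @param rules A [qc_rules()].
#'
#' @return A list with tibbles `kept` and `excluded`; `excluded` carries a
#'   `qc_reason` column (first matching reason among `fit_failed`,
#'   `attached`, `deformed` (low FF), `high_residual`, `volume_gate`).
#' @examples
#' cells <- tibble::tibble(cell_id = 1, label = "lymphocyte", R_um = 3.7,
#'   n_cell = 1.35, V_um3 = 212, DM_pg = 13, A_um2 = 42, P_um = 23,
#'   FF = 0.95, residual_rms = 0.01, qc_flags = "")
#' qc_filter(cells, qc_rules())
#' @export
qc_filter <- function(cells, rules = qc_rules()) {
  stopifnot(inherits(rules, "qc_rules"))
  if (nrow(cells) == 0) {
    return(list(kept = cells, excluded = dplyr::mutate(cells, qc_reason = character(0))))
  }
  reason <- purrr::pmap_chr(
    list(cells$label, cells$V_um3, cells$FF, cells$residual_rms, cells$qc_flags),
    function(label, V, FF, res, flags) {
      if (grepl("fit_failed", flags)) return("fit_failed")
      if (grepl("attached", flags)) return("attached")
      if (!is.na(FF) && FF < rules$ff_min) return("deformed")
      if (!is.na(res) && res > rules$residual_max) return("high_residual")
      gate <- rules$volume_gates[[label]]
      if (!is.null(gate) && !is.na(V) && (V < gate[1] || V > gate[2])) {
        return("volume_gate")
      }
      NA_character_
    }
  )
  list(
    kept = cells[is.na(reason), , drop = FALSE],
    excluded = dplyr::mutate(cells[!is.na(reason), , drop = FALSE],
                             qc_reason = reason[!is.na(reason)])
  )
}
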