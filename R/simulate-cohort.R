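#' Simulate the perioperative cohort table
#'
#' Generates per-patient, per-timepoint, per-cell-type DHM aggregates
#' (mean and within-sample SD of volume, refractive index, dry mass and
#' form factor over `cells_per_sample` cells), flow-cytometry markers, CRP,
#' epinephrine dose and subgroup labels, with the statistical structure
#' declared in the [cohort_spec()]:
#'
#' * Day levels are chained: `level[t] = level[t-1] + delta[t]`, with the
#'   baseline drawn at the configured first-day mean/SD and each
#'   day-difference composed of a (possibly subgroup-dependent) mean shift,
#'   a regression-to-the-mean term proportional to the standardized
#'   previous-day level, and a fresh innovation.  The regression
#'   coefficient is derived internally so each day's configured
#'   between-patient SD is reproduced.
#' * The first-transition innovations of all DHM quantities, markers and
#'   the epinephrine-dose latent are drawn jointly from a Gaussian copula
#'   whose correlation matrix realizes the configured day-difference
#'   correlations (projected to the nearest PSD matrix if necessary).
#' * Subgroups are assigned by exact counts (scaled for cohorts other than
#'   25 patients); when `subgroup_effects` is on, the lymphocyte d1 volume
#'   response is suppressed for complicated-course/epinephrine patients and
#'   amplified for CRP-high patients, with the remaining patients shifted
#'   so the cohort mean is preserved.
#'
#' @param spec A [cohort_spec()].
#' @param emit_phantoms If `TRUE`, attaches per-sample phantom populations
#'   (attribute `"phantoms"`, a named list of tibbles) whose per-sample
#'   mean volume and refractive index match the drawn aggregates exactly —
#'   the input for end-to-end imaging runs.
#'
#' @return A tibble (class `cohort_table`) with one row per patient x
#'   timepoint x cell type and columns `patient_id`, `timepoint`,
#'   `cell_type`, `n_cells`, `V_mean`, `V_sd`, `n_cell_mean`, `n_cell_sd`,
#'   `DM_mean`, `DM_sd`, `FF_mean`, `FF_sd`, one column per marker, `CRP`,
#'   `epinephrine_dose`, `complicated_course`, `epinephrine`, `crp_high`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 7))
#' dplyr::count(cohort, timepoint)
#' @export
simulate_cohort <- function(spec, emit_phantoms = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, simulate_cohort_impl(spec, emit_phantoms))
}

simulate_cohort_impl <- function(spec, emit_phantoms) {
  n <- spec$n_patients
  tps <- spec$timepoints
  K <- length(tps)

  groups <- assign_subgroups(n, spec$subgroup_counts)

  # ---- subgroup-dependent mean shift of the lymphocyte volume response ----
  stats_vl <- dhm_stats_for(spec, "lymphocyte", "V")
  mu_delta_vl <- stats_vl$mean[2] - stats_vl$mean[1]
  if (spec$subgroup_effects) {
    amplified <- groups$crp_high
    zeroed <- (groups$complicated | groups$epinephrine) & !amplified
    rest <- !amplified & !zeroed
    shift_vl <- numeric(n)
    shift_vl[amplified] <- spec$crp_amplification * mu_delta_vl
    if (any(rest)) {
      shift_vl[rest] <- (n * mu_delta_vl - sum(shift_vl)) / sum(rest)
    }
  } else {
    shift_vl <- rep(mu_delta_vl, n)
  }
  shift_var_vl <- mean((shift_vl - mean(shift_vl))^2)

  # ---- copula over first-transition innovations ----
  dhm_vars <- paste(spec$delta_sd$parameter, spec$delta_sd$cell_type, sep = "_")
  vars <- c(dhm_vars, spec$markers$marker, "epinephrine_dose")
  p <- length(vars)

  sd_tot <- b_innov <- a_reg <- stats::setNames(numeric(p), vars)
  for (i in seq_along(dhm_vars)) {
    ct <- spec$delta_sd$cell_type[i]
    par <- spec$delta_sd$parameter[i]
    st <- dhm_stats_for(spec, ct, par)
    sdst <- spec$delta_sd$sd[i]
    svar <- if (par == "V" && ct == "lymphocyte") shift_var_vl else 0
    v <- dhm_vars[i]
    sd_tot[v] <- sqrt(sdst^2 + svar)
    a_reg[v] <- clamp((st$sd[2]^2 - st$sd[1]^2 - sd_tot[v]^2) / (2 * st$sd[1]),
                      -0.99 * sdst, 0.99 * sdst)
    b_innov[v] <- sqrt(max(sdst^2 - a_reg[v]^2, 1e-12))
  }
  for (m in spec$markers$marker) {
    sdm <- spec$markers$d1_delta_sd[spec$markers$marker == m]
    sd_tot[m] <- sdm
    a_reg[m] <- 0
    b_innov[m] <- max(sdm, 1e-12)
  }
  sd_tot["epinephrine_dose"] <- 1
  b_innov["epinephrine_dose"] <- 1

  Cu <- diag(p)
  dimnames(Cu) <- list(vars, vars)
  for (i in seq_len(nrow(spec$delta_correlations))) {
    v1 <- spec$delta_correlations$var1[i]
    v2 <- spec$delta_correlations$var2[i]
    if (!(v1 %in% vars) || !(v2 %in% vars)) {
      stop(sprintf("unknown variable in delta_correlations: %s / %s", v1, v2),
           call. = FALSE)
    }
    cu <- clamp(spec$delta_correlations$r[i] * sd_tot[v1] * sd_tot[v2] /
                  (b_innov[v1] * b_innov[v2]), -0.99, 0.99)
    Cu[v1, v2] <- Cu[v2, v1] <- cu
  }
  ev <- eigen(Cu, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    Cu <- as.matrix(Matrix::nearPD(Cu, corr = TRUE)$mat)
  }
  U <- matrix(rnorm(n * p), n, p) %*% chol(Cu + diag(1e-10, p))
  colnames(U) <- vars

  # ---- DHM day levels ----
  levels <- list()
  for (i in seq_along(dhm_vars)) {
    v <- dhm_vars[i]
    ct <- spec$delta_sd$cell_type[i]
    par <- spec$delta_sd$parameter[i]
    st <- dhm_stats_for(spec, ct, par)
    sdst <- spec$delta_sd$sd[i]
    lv <- matrix(NA_real_, n, K)
    z <- rnorm(n)
    lv[, 1] <- st$mean[1] + st$sd[1] * z
    shift <- if (v == "V_lymphocyte") shift_vl else rep(st$mean[2] - st$mean[1], n)
    lv[, 2] <- lv[, 1] + shift + a_reg[v] * z + b_innov[v] * U[, v]
    for (k in seq_len(K)[-(1:2)]) {
      a_k <- clamp((st$sd[k]^2 - st$sd[k - 1]^2 - sdst^2) / (2 * st$sd[k - 1]),
                   -0.99 * sdst, 0.99 * sdst)
      b_k <- sqrt(max(sdst^2 - a_k^2, 1e-12))
      z_k <- (lv[, k - 1] - st$mean[k - 1]) / max(st$sd[k - 1], 1e-12)
      lv[, k] <- lv[, k - 1] + (st$mean[k] - st$mean[k - 1]) +
        a_k * z_k + b_k * rnorm(n)
    }
    if (par == "FF") lv <- pmin(pmax(lv, 0), 1)
    levels[[v]] <- lv
  }

  # ---- markers ----
  marker_levels <- list()
  for (i in seq_len(nrow(spec$markers))) {
    mk <- spec$markers[i, ]
    lv <- matrix(NA_real_, n, K)
    lv[, 1] <- mk$baseline_mean + mk$baseline_sd * rnorm(n)
    lv[, 2] <- lv[, 1] + mk$d1_delta_mean + mk$d1_delta_sd * U[, mk$marker]
    for (k in seq_len(K)[-(1:2)]) {
      lv[, k] <- lv[, k - 1] + mk$later_delta_sd * rnorm(n)
    }
    lv <- pmax(lv, 0)
    if (mk$is_percent) lv <- pmin(lv, 100)
    marker_levels[[mk$marker]] <- lv
  }

  # ---- epinephrine dose (ug/kg/min); only treated patients receive any ----
  dose <- matrix(0, n, K)
  dose_d1 <- pmax(0.01, 0.08 + 0.04 * U[, "epinephrine_dose"])
  dose[groups$epinephrine, 2] <- dose_d1[groups$epinephrine]
  for (k in seq_len(K)[-(1:2)]) {
    dose[, k] <- dose[, k - 1] * 0.5
  }

  # ---- CRP (mg/dL), dichotomized at 14 on the second timepoint ----
  crp <- matrix(NA_real_, n, K)
  crp[, 1] <- pmax(0.05, rnorm(n, 0.6, 0.3))
  crp[, 2] <- ifelse(groups$crp_high,
                     14.5 + abs(rnorm(n, 6, 3)),
                     pmin(13.5, pmax(0.5, rnorm(n, 8, 3))))
  if (K >= 3) crp[, 3] <- crp[, 2] * 0.65 + abs(rnorm(n, 0, 0.8))
  if (K >= 4) crp[, 4] <- crp[, 2] * 0.30 + abs(rnorm(n, 0, 0.5))

  # ---- assemble the long table ----
  id_width <- max(2L, nchar(n))
  pid <- sprintf(paste0("P%0", id_width, "d"), seq_len(n))
  grid <- tidyr::expand_grid(
    patient_id = pid,
    timepoint = factor(tps, levels = tps),
    cell_type = c("lymphocyte", "monocyte")
  )
  pi_idx <- match(grid$patient_id, pid)
  tp_idx <- match(as.character(grid$timepoint), tps)
  spread <- ifelse(tp_idx == 2L, spec$d1_spread_multiplier, 1)

  pick <- function(par) {
    v <- paste(par, grid$cell_type, sep = "_")
    vapply(seq_len(nrow(grid)),
           function(j) levels[[v[j]]][pi_idx[j], tp_idx[j]], numeric(1))
  }
  out <- grid
  out$n_cells <- spec$cells_per_sample
  out$V_mean <- pick("V")
  out$V_sd <- 3 * spec$radius_cv * out$V_mean * spread
  out$n_cell_mean <- pick("n_cell")
  out$n_cell_sd <- 5e-4 * spread
  out$DM_mean <- pick("DM")
  out$DM_sd <- 0.12 * out$DM_mean * spread
  out$FF_mean <- pick("FF")
  out$FF_sd <- 0.05
  for (m in spec$markers$marker) {
    out[[m]] <- marker_levels[[m]][cbind(pi_idx, tp_idx)]
  }
  out$CRP <- crp[cbind(pi_idx, tp_idx)]
  out$epinephrine_dose <- dose[cbind(pi_idx, tp_idx)]
  out$complicated_course <- groups$complicated[pi_idx]
  out$epinephrine <- groups$epinephrine[pi_idx]
  out$crp_high <- groups$crp_high[pi_idx]

  # ---- missingness: deceased after surgery, early discharge before d6 ----
  if (spec$dropout && K >= 2) {
    scale <- n / 25
    n_dec <- round(2 * scale)
    n_dis <- round(3 * scale)
    comp_ids <- which(groups$complicated)
    reg_ids <- which(!groups$complicated & !groups$epinephrine)
    deceased <- if (n_dec > 0 && length(comp_ids) > 0) {
      comp_ids[sample.int(length(comp_ids), min(n_dec, length(comp_ids)))]
    } else integer(0)
    discharged <- if (n_dis > 0 && length(reg_ids) > 0) {
      reg_ids[sample.int(length(reg_ids), min(n_dis, length(reg_ids)))]
    } else integer(0)
    drop <- (pi_idx %in% deceased & tp_idx > 1L) |
      (pi_idx %in% discharged & tp_idx == K)
    out <- out[!drop, , drop = FALSE]
  }

  if (emit_phantoms) {
    attr(out, "phantoms") <- emit_sample_phantoms(out, spec)
  }
  attr(out, "spec") <- spec
  class(out) <- c("cohort_table", class(out))
  out
}

dhm_stats_for <- function(spec, ct, par) {
  st <- spec$dhm_day_stats
  st <- st[st$cell_type == ct & st$parameter == par, , drop = FALSE]
  st <- st[match(spec$timepoints, st$timepoint), , drop = FALSE]
  if (anyNA(st$mean)) {
    stop(sprintf("dhm_day_stats incomplete for %s/%s", ct, par), call. = FALSE)
  }
  st
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assign_subgroups <- function(n, counts) {
  # exclusive Venn cells at the 25-patient reference scale
  ref <- c(comp_epi = counts$comp_epi,
           comp_crp = counts$comp_crp,
           epi_crp = counts$epi_crp,
           comp_only = counts$complicated - counts$comp_epi - counts$comp_crp,
           epi_only = counts$epinephrine - counts$comp_epi - counts$epi_crp,
           crp_only = counts$crp_high - counts$comp_crp - counts$epi_crp)
  if (any(ref < 0) || sum(ref) > 25) {
    stop("inconsistent subgroup rules: counts do not fit the cohort",
         call. = FALSE)
  }
  cells <- as.integer(round(ref * n / 25))
  names(cells) <- names(ref)
  # rounding may overflow tiny cohorts; shrink the largest cells until fit
  while (sum(cells) > n) {
    k <- which.max(cells)
    cells[k] <- cells[k] - 1L
  }
  comp_epi <- cells[["comp_epi"]]
  comp_crp <- cells[["comp_crp"]]
  epi_crp <- cells[["epi_crp"]]
  comp_only <- cells[["comp_only"]]
  epi_only <- cells[["epi_only"]]
  crp_only <- cells[["crp_only"]]
  perm <- sample.int(n)
  complicated <- epinephrine <- crp_high <- logical(n)
  pos <- 0L
  take <- function(k) {
    ids <- if (k > 0) perm[(pos + 1L):(pos + k)] else integer(0)
    pos <<- pos + k
    ids
  }
  ids <- take(comp_epi); complicated[ids] <- TRUE; epinephrine[ids] <- TRUE
  ids <- take(comp_crp); complicated[ids] <- TRUE; crp_high[ids] <- TRUE
  ids <- take(epi_crp); epinephrine[ids] <- TRUE; crp_high[ids] <- TRUE
  ids <- take(comp_only); complicated[ids] <- TRUE
  ids <- take(epi_only); epinephrine[ids] <- TRUE
  ids <- take(crp_only); crp_high[ids] <- TRUE
  list(complicated = complicated, epinephrine = epinephrine, crp_high = crp_high)
}

# Phantom populations whose per-sample mean volume and refractive index
# match the drawn aggregates exactly (radii rescaled, indices recentred).
emit_sample_phantoms <- function(cohort, spec) {
  out <- vector("list", nrow(cohort))
  names(out) <- paste(cohort$patient_id, cohort$timepoint, cohort$cell_type,
                      sep = "_")
  for (j in seq_len(nrow(cohort))) {
    nc <- cohort$n_cells[j]
    r_cv <- spec$radius_cv *
      ifelse(cohort$timepoint[j] == spec$timepoints[2], spec$d1_spread_multiplier, 1)
    r_target <- (3 * cohort$V_mean[j] / (4 * pi))^(1 / 3)
    radii <- rnorm(nc, r_target, r_cv * r_target)
    radii <- pmax(radii, 0.2 * r_target)
    radii <- radii * (cohort$V_mean[j] / mean((4 / 3) * pi * radii^3))^(1 / 3)
    ncell <- rnorm(nc, cohort$n_cell_mean[j], cohort$n_cell_sd[j])
    ncell <- ncell + (cohort$n_cell_mean[j] - mean(ncell))
    out[[j]] <- tibble::tibble(
      cell_id = seq_len(nc),
      label = cohort$cell_type[j],
      shape = "sphere",
      x_um = NA_real_, y_um = NA_real_,
      radius_um = radii,
      n_cell = ncell,
      axis_ratio = 1, orientation = 0,
      volume_um3 = (4 / 3) * pi * radii^3
    )
  }
  out
}
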