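test_that("the default cohort reproduces the subgroup overlap structure", {
  co <- simulate_cohort(cohort_spec(seed = 7))
  ov <- subgroup_overlap(co)
  expect_equal(ov$n_patients, 25)
  expect_equal(ov$complicated, 9)
  expect_equal(ov$epinephrine, 8)
  expect_equal(ov$crp_high, 7)
  expect_equal(ov$complicated_and_epinephrine, 6)
  expect_equal(ov$complicated_and_crp_high, 2)
  expect_equal(ov$epinephrine_and_crp_high, 0)
  expect_equal(ov$all_three, 0)

  # CRP dichotomization is consistent with the label at the second day
  d1 <- co[co$timepoint == "d1" & !duplicated(paste(co$patient_id, co$timepoint)), ]
  expect_true(all(d1$CRP[d1$crp_high] > 14))
  expect_true(all(d1$CRP[!d1$crp_high] <= 14))
  # only treated patients carry an epinephrine dose
  expect_true(all(co$epinephrine_dose[!co$epinephrine] == 0))
  expect_true(all(d1$epinephrine_dose[d1$epinephrine] > 0))
})

test_that("cohort simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_spec(seed = 11))
  b <- simulate_cohort(cohort_spec(seed = 11))
  attr(a, "spec") <- attr(b, "spec") <- NULL
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cohort_spec(seed = 12))
  expect_false(identical(a$V_mean, c$V_mean))
})

test_that("dropout reproduces the study's missingness pattern", {
  co <- simulate_cohort(cohort_spec(seed = 5))
  counts <- table(co$timepoint) / 2   # two cell types per sample
  expect_equal(unname(counts[["PreOP"]]), 25)
  expect_equal(unname(counts[["d1"]]), 23)   # two deceased after surgery
  expect_equal(unname(counts[["d3"]]), 23)
  expect_equal(unname(counts[["d6"]]), 20)   # plus three early discharges
  # deceased patients are drawn from the complicated-course group
  miss_d1 <- setdiff(unique(co$patient_id),
                     unique(co$patient_id[co$timepoint == "d1"]))
  expect_true(all(co$complicated_course[match(miss_d1, co$patient_id)]))

  full <- simulate_cohort(cohort_spec(seed = 5, dropout = FALSE))
  expect_equal(nrow(full), 25 * 4 * 2)
})

test_that("large cohorts reproduce every configured day mean and SD", {
  n <- 1200
  sp <- cohort_spec(n_patients = n, dropout = FALSE, seed = 3)
  co <- simulate_cohort(sp)
  sm <- summarize_days(co)$summary
  sm$parameter <- sub("_mean$", "", sm$parameter)
  chk <- dplyr::inner_join(sm, sp$dhm_day_stats,
                           by = c("cell_type", "parameter", "timepoint"),
                           suffix = c("_obs", "_cfg"))
  expect_equal(nrow(chk), 32)   # 2 cell types x 4 parameters x 4 days
  z <- (chk$mean_obs - chk$mean_cfg) / (chk$sd_cfg / sqrt(n))
  expect_lt(max(abs(z)), 3)
  # SDs: chi-square MC error ~ 1/sqrt(2n) ~ 2%; allow 3 of those
  expect_lt(max(abs(chk$sd_obs / chk$sd_cfg - 1)), 0.06)
})

test_that("PreOP lymphocyte volume matches the configured 208 um^3", {
  co <- simulate_cohort(cohort_spec(seed = 1))
  pre <- co[co$timepoint == "PreOP" & co$cell_type == "lymphocyte", ]
  expect_lt(abs(mean(pre$V_mean) - 208), 2 * 9 / sqrt(25))
})

test_that("a correlation-free spec yields uncorrelated day differences", {
  sp <- cohort_spec(
    n_patients = 4000,
    delta_correlations = tibble::tibble(var1 = character(),
                                        var2 = character(), r = numeric()),
    subgroup_effects = FALSE, dropout = FALSE, seed = 21
  )
  d <- day_difference(simulate_cohort(sp), "d1", "PreOP")
  pairs <- list(c("delta_V_lymphocyte", "delta_CD19_abs"),
                c("delta_V_monocyte", "delta_n_cell_monocyte"),
                c("delta_FF_monocyte", "delta_mHLA_DR"))
  for (p in pairs) {
    expect_lt(abs(cor(d[[p[1]]], d[[p[2]]])), 4 / sqrt(4000))
  }
})

test_that("an injected delta correlation is recovered at large n", {
  sp <- cohort_spec(n_patients = 10000, subgroup_effects = FALSE,
                    dropout = FALSE, seed = 3)
  d <- day_difference(simulate_cohort(sp), "d1", "PreOP")
  r <- cor(d$delta_V_lymphocyte, d$delta_CD19_abs)
  expect_lt(abs(r - (-0.514)), 0.02)
})

test_that("subgroup effects shape the lymphocyte volume response", {
  sp <- cohort_spec(n_patients = 500, dropout = FALSE, seed = 13)
  d <- day_difference(simulate_cohort(sp), "d1", "PreOP")
  zeroed <- (d$complicated_course | d$epinephrine) & !d$crp_high
  regular <- !d$complicated_course & !d$epinephrine & !d$crp_high
  expect_lt(abs(mean(d$delta_V_lymphocyte[zeroed])), 2)
  expect_gt(mean(d$delta_V_lymphocyte[d$crp_high]), 15)
  expect_gt(mean(d$delta_V_lymphocyte[regular]), 8)
  # cohort-level mean change is preserved at the configured +10
  expect_lt(abs(mean(d$delta_V_lymphocyte) - 10), 1.5)
})

test_that("emitted phantom samples match their drawn aggregates exactly", {
  sp <- cohort_spec(n_patients = 2, cells_per_sample = 30, dropout = FALSE,
                    seed = 17)
  co <- simulate_cohort(sp, emit_phantoms = TRUE)
  phs <- attr(co, "phantoms")
  expect_equal(length(phs), nrow(co))
  for (j in c(1, 5, nrow(co))) {
    ph <- phs[[paste(co$patient_id[j], co$timepoint[j], co$cell_type[j],
                     sep = "_")]]
    expect_equal(nrow(ph), 30)
    expect_equal(mean(ph$volume_um3), co$V_mean[j], tolerance = 1e-10)
    expect_equal(mean(ph$n_cell), co$n_cell_mean[j], tolerance = 1e-10)
  }
})

test_that("inconsistent subgroup rules are rejected", {
  expect_error(
    simulate_cohort(cohort_spec(
      subgroup_counts = list(complicated = 3, epinephrine = 8, crp_high = 7,
                             comp_epi = 6, comp_crp = 2, epi_crp = 0),
      seed = 1
    )),
    "inconsistent subgroup"
  )
})

test_that("invalid injected correlations are rejected", {
  expect_error(
    cohort_spec(delta_correlations = tibble::tibble(
      var1 = "V_lymphocyte", var2 = "CD19_abs", r = -1.4)),
    "\\[-1, 1\\]"
  )
  expect_error(
    simulate_cohort(cohort_spec(delta_correlations = tibble::tibble(
      var1 = "V_lymphocyte", var2 = "no_such_marker", r = 0.5), seed = 1)),
    "unknown variable"
  )
})
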