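test_that("sample aggregation computes means and ddof-1 SDs", {
  cells <- tibble::tibble(V_um3 = c(100, 200, 300), n_cell = 1.3497,
                          DM_pg = 13.2, FF = 0.9)
  agg <- aggregate_cells(cells, "P01", "PreOP", "lymphocyte")
  expect_equal(agg$V_mean, 200)
  expect_equal(agg$V_sd, 100)
  expect_equal(agg$n_cells, 3)
  expect_equal(agg$n_cell_sd, 0)

  same <- tibble::tibble(V_um3 = rep(212, 150), n_cell = 1.3497,
                         DM_pg = 13.5, FF = 0.92)
  agg2 <- aggregate_cells(same)
  expect_equal(agg2$V_mean, 212)
  expect_equal(agg2$V_sd, 0)

  expect_error(aggregate_cells(cells[0, ]), "no cells")
})

test_that("aggregates of phantom populations sit within CLT bounds", {
  ph <- phantom_population(150, 3.675, 0.18375, seed = 33)   # 5% radius CV
  cells <- tibble::tibble(V_um3 = ph$volume_um3, n_cell = ph$n_cell,
                          DM_pg = 1, FF = 1)
  agg <- aggregate_cells(cells)
  ev <- (4 / 3) * pi * (3.675^3 + 3 * 3.675 * 0.18375^2)
  se <- 4 * pi * 3.675^2 * 0.18375 / sqrt(150)
  expect_lt(abs(agg$V_mean - ev), 3 * se)
})

test_that("day differences follow the later-minus-baseline contract", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  d0 <- day_difference(co, "PreOP", "PreOP")
  expect_true(all(abs(d0$delta_V_lymphocyte) < 1e-12))

  # hand-built two-row check: 208 at PreOP, 218 at d1 gives +10
  mini <- tibble::tibble(
    patient_id = "P01",
    timepoint = factor(c("PreOP", "d1"), levels = c("PreOP", "d1")),
    cell_type = "lymphocyte",
    V_mean = c(208, 218)
  )
  d <- day_difference(mini, "d1", "PreOP", columns = "V_mean")
  expect_equal(d$delta_V_lymphocyte, 10)

  expect_error(day_difference(co, "d9", "PreOP"), "unknown timepoint")
})

test_that("patients missing a timepoint are dropped and counted", {
  co <- simulate_cohort(cohort_spec(seed = 5))   # 3 discharged before d6
  d <- day_difference(co, "d6", "PreOP")
  expect_equal(attr(d, "n_dropped_any"), 5)   # 2 deceased + 3 discharged
  expect_equal(nrow(d), 20)
})

test_that("pearson_matrix recovers exact linear relations", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 3, z = -0.5 * (1:10))
  res <- pearson_matrix(d, c("x"), c("y", "z"))
  expect_equal(res$r[res$var2 == "y"], 1)
  expect_equal(res$r[res$var2 == "z"], -1)
  expect_lt(res$p_value[1], 1e-10)
})

test_that("pearson_matrix r equals sign(a) under affine maps", {
  set.seed(4)
  x <- rnorm(40)
  for (a in c(3, -0.2, 0.001)) {
    d <- tibble::tibble(x = x, y = a * x + 7)
    expect_equal(pearson_matrix(d, "x", "y")$r, sign(a))
  }
})

test_that("constant columns are flagged degenerate, not tested", {
  d <- tibble::tibble(x = 1:10, y = rep(5, 10))
  res <- pearson_matrix(d, "x", "y")
  expect_true(res$degenerate)
  expect_true(is.na(res$r))
})

test_that("the two-sided Pearson test is calibrated under the null", {
  n <- 25
  n_sim <- 10000
  withr::with_seed(314, {
    x <- matrix(rnorm(n * n_sim), n)
    y <- matrix(rnorm(n * n_sim), n)
  })
  r <- vapply(seq_len(n_sim),
              function(i) cor(x[, i], y[, i]), numeric(1))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), n - 2)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.045)
  expect_lt(rate, 0.055)
  # and the p-values are uniform: KS distance small
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(unname(ks), 0.02)
})

test_that("correlation table reproduces an injected association", {
  sp <- cohort_spec(n_patients = 10000, subgroup_effects = FALSE,
                    dropout = FALSE, seed = 3)
  d <- day_difference(simulate_cohort(sp), "d1", "PreOP")
  res <- pearson_matrix(d, "delta_V_lymphocyte", "delta_CD19_abs")
  expect_lt(abs(res$r - (-0.514)), 0.02)
  expect_equal(res$stars, "***")
  expect_equal(res$n, 10000)
})

test_that("bootstrap of a constant sample never leaves the corridor", {
  b <- bootstrap_stability(rep(3.14, 150), n_boot = 2000, seed = 1)
  expect_equal(b$sample_p, 0)
  expect_equal(b$original_sd, 0)
})

test_that("bootstrap sample p matches the CLT closed form", {
  # resample means are ~N(m, s/sqrt(n)); a 0.3 SD corridor is crossed with
  # probability 2 Phi(-0.3 sqrt(n)) ~ 2.4e-4 at n = 150
  withr::with_seed(8, values <- rnorm(150))
  b <- bootstrap_stability(values, n_boot = 10000, seed = 99)
  p_clt <- 2 * stats::pnorm(-0.3 * sqrt(150))
  expect_lt(abs(b$sample_p - p_clt), 1.5e-3)
  expect_true(all(tidy(b)$sample_p == b$sample_p))
})

test_that("bootstrap is seeded-deterministic and corridor-monotone", {
  withr::with_seed(12, values <- rnorm(80))
  b1 <- bootstrap_stability(values, n_boot = 3000, seed = 5)
  b2 <- bootstrap_stability(values, n_boot = 3000, seed = 5)
  expect_identical(b1$sample_p, b2$sample_p)

  p_narrow <- bootstrap_stability(values, n_boot = 3000, corridor = 0.1,
                                  seed = 5)$sample_p
  p_mid <- bootstrap_stability(values, n_boot = 3000, corridor = 0.3,
                               seed = 5)$sample_p
  p_wide <- bootstrap_stability(values, n_boot = 3000, corridor = 0.5,
                                seed = 5)$sample_p
  expect_gte(p_narrow, p_mid)
  expect_gte(p_mid, p_wide)

  expect_error(bootstrap_stability(c(1)), "at least 2")
})

test_that("the expected omitted-entity fraction is 36.7% at n = 150", {
  expect_equal(expected_omitted_fraction(150), (1 - 1 / 150)^150)
  expect_equal(100 * expected_omitted_fraction(150), 36.7, tolerance = 1e-3)
  # approaches 1/e from below as n grows
  expect_lt(expected_omitted_fraction(150), exp(-1))
  expect_gt(expected_omitted_fraction(10000), 0.9996 * exp(-1))
})

test_that("BH adjustment matches the hand-worked step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  # order-preserving under permutation, and never below the raw values
  p <- c(0.04, 0.001, 0.2, 0.015, 0.8)
  adj <- bh_adjust(p)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_true(all(adj >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("cohort-wide bootstrap table carries BH-adjusted p-values", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  bt <- bootstrap_cohort(co, n_boot = 500, seed = 9)
  expect_equal(nrow(bt), 8)
  expect_true(all(bt$bh_adjusted_p >= bt$sample_p))
  expect_true(all(bt$sample_p >= 0 & bt$sample_p <= 1))
})

test_that("subgroup comparison handles identical and shifted groups", {
  d <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), each = 8),
    val = rep(c(5, 5), each = 8) + rep(c(0.01, -0.01), 8)
  )
  res <- subgroup_compare(d, "grp", "val")
  expect_equal(res$difference, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.95)

  expect_error(
    subgroup_compare(tibble::tibble(grp = rep(TRUE, 4), val = rnorm(4)),
                     "grp", "val"),
    "non-empty"
  )
})

test_that("subgroup test detects a 2-pooled-SD shift with high power", {
  hits <- withr::with_seed(271, {
    vapply(1:200, function(i) {
      d <- tibble::tibble(
        grp = rep(c(TRUE, FALSE), c(8, 16)),
        val = c(rnorm(8, 2, 1), rnorm(16, 0, 1))
      )
      subgroup_compare(d, "grp", "val")$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.9)
})

test_that("the subgroup test is calibrated under the null", {
  rej <- withr::with_seed(97, {
    vapply(1:10000, function(i) {
      x <- rnorm(9)
      y <- rnorm(16)
      t.test(x, y)$p.value < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 0.008)
})
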