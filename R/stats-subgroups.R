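#' Compare a quantity between two dichotomized patient groups
#'
#' Welch two-sample t-test (default; Wilcoxon rank-sum optionally) of a
#' per-patient quantity between the patients inside and outside one of the
#' dichotomized subgroups: postoperative course (regular vs complicated),
#' epinephrine treatment, or CRP above/below 14 mg/dL.
#'
#' @param data A per-patient tibble carrying the grouping column and the
#'   quantity, e.g. the output of [day_difference()].
#' @param grouping One of `"complicated_course"`, `"epinephrine"`,
#'   `"crp_high"` (any logical column works).
#' @param quantity Name of the numeric column to compare.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#'
#' @return A one-row tibble: group sizes, means, SDs, difference of means
#'   (in-group minus out-group), test statistic, two-sided `p_value` and
#'   significance `stars`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' d <- day_difference(cohort, "d1", "PreOP")
#' subgroup_compare(d, "crp_high", "delta_V_lymphocyte")
#' @export
subgroup_compare <- function(data, grouping, quantity, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(grouping %in% names(data), quantity %in% names(data))
  g <- as.logical(data[[grouping]])
  x <- data[[quantity]][g & !is.na(data[[quantity]])]
  y <- data[[quantity]][!g & !is.na(data[[quantity]])]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sd(c(x, y)) == 0) {
    ht <- list(statistic = 0, p.value = 1)
  } else if (test == "welch") {
    ht <- t.test(x, y, var.equal = FALSE)
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE)
  }
  tibble::tibble(
    grouping = grouping,
    quantity = quantity,
    n_in = length(x), n_out = length(y),
    mean_in = mean(x), mean_out = mean(y),
    sd_in = sd(x), sd_out = sd(y),
    difference = mean(x) - mean(y),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    stars = significance_stars(ht$p.value)
  )
}

#' Venn-style overlap counts of the dichotomized subgroups
#'
#' @param cohort A cohort table with logical columns `complicated_course`,
#'   `epinephrine`, `crp_high` (one value per patient).
#'
#' @return A one-row tibble with the three group sizes, the three pairwise
#'   overlaps and the triple overlap.
#' @examples
#' subgroup_overlap(simulate_cohort(cohort_spec(seed = 1)))
#' @export
subgroup_overlap <- function(cohort) {
  pp <- cohort[!duplicated(cohort$patient_id),
               c("patient_id", "complicated_course", "epinephrine", "crp_high")]
  tibble::tibble(
    n_patients = nrow(pp),
    complicated = sum(pp$complicated_course),
    epinephrine = sum(pp$epinephrine),
    crp_high = sum(pp$crp_high),
    complicated_and_epinephrine = sum(pp$complicated_course & pp$epinephrine),
    complicated_and_crp_high = sum(pp$complicated_course & pp$crp_high),
    epinephrine_and_crp_high = sum(pp$epinephrine & pp$crp_high),
    all_three = sum(pp$complicated_course & pp$epinephrine & pp$crp_high)
  )
}
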