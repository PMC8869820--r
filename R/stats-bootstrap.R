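#' Bootstrap stability test of a sample mean
#'
#' Draws `n_boot` with-replacement resamples of the full sample size and
#' reports the fraction of resample means falling outside the corridor
#' `mean +/- corridor * SD` of the original data (default corridor 0.3 SD).
#' A small fraction indicates that the observed mean is a stable summary
#' of the measurement entities.  In a full-size with-replacement resample,
#' a fraction `(1 - 1/n)^n` of the distinct entities (36.7% at n = 150) is
#' absent on average — see [expected_omitted_fraction()].
#'
#' @param values Numeric vector of per-entity measurements (n >= 2).
#' @param n_boot Number of resamples (default 10000).
#' @param corridor Corridor half-width in units of the sample SD
#'   (default 0.3).
#' @param seed Optional seed for the resampling.
#'
#' @return An object of class `bootstrap_stability`: list with
#'   `original_mean`, `original_sd`, `n`, `n_boot`, `corridor`,
#'   `corridor_halfwidth`, `sample_p`.  Use [tidy()] for a tibble.
#' @examples
#' b <- bootstrap_stability(rnorm(150), seed = 1)
#' b$sample_p
#' @export
bootstrap_stability <- function(values, n_boot = 10000L, corridor = 0.3,
                                seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values (SD undefined)", call. = FALSE)
  stopifnot(n_boot >= 1, corridor >= 0)
  m <- mean(values)
  s <- sd(values)
  half <- corridor * s
  means <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n))
  })
  structure(
    list(
      original_mean = m, original_sd = s, n = n,
      n_boot = as.integer(n_boot), corridor = corridor,
      corridor_halfwidth = half,
      sample_p = mean(means < m - half | means > m + half),
      resample_means = means
    ),
    class = "bootstrap_stability"
  )
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_stability> n = %d, %d resamples, corridor %.2f SD: sample p = %.4g\n",
    x$n, x$n_boot, x$corridor, x$sample_p))
  invisible(x)
}

#' @export
tidy.bootstrap_stability <- function(x, ...) {
  tibble::tibble(
    original_mean = x$original_mean, original_sd = x$original_sd,
    n = x$n, n_boot = x$n_boot, corridor = x$corridor,
    sample_p = x$sample_p
  )
}

#' Expected fraction of distinct entities absent from one resample
#'
#' In a with-replacement resample of size n from n entities, each entity is
#' omitted with probability \eqn{(1 - 1/n)^n \to e^{-1}}; at n = 150 this
#' is 36.7%.
#'
#' @param n Sample size.
#' @return The expected omitted fraction in \[0, 1\].
#' @examples
#' expected_omitted_fraction(150)
#' @export
expected_omitted_fraction <- function(n) {
  stopifnot(n >= 1)
  (1 - 1 / n)^n
}

#' Benjamini-Hochberg adjustment of bootstrap sample p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' adjusted values are monotone in the input ranks, capped at 1, and
#' order-preserving with the input vector.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Bootstrap stability of every day-difference contrast in a cohort
#'
#' Runs [bootstrap_stability()] on the per-patient day differences of each
#' requested DHM parameter and cell type, then applies [bh_adjust()]
#' across the resulting sample p-values.
#'
#' @param cohort A cohort table.
#' @param later,baseline Timepoint labels of the contrast.
#' @param n_boot,corridor,seed Passed to [bootstrap_stability()].
#'
#' @return A tibble with one row per delta column: `quantity`,
#'   `original_mean`, `original_sd`, `n`, `sample_p`, `bh_adjusted_p`.
#' @export
bootstrap_cohort <- function(cohort, later = "d1", baseline = "PreOP",
                             n_boot = 10000L, corridor = 0.3, seed = NULL) {
  deltas <- day_difference(cohort, later, baseline)
  cols <- grep("^delta_(V|n_cell|DM|FF)_", names(deltas), value = TRUE)
  rows <- purrr::imap_dfr(cols, function(col, i) {
    b <- bootstrap_stability(deltas[[col]], n_boot = n_boot,
                             corridor = corridor,
                             seed = derive_seed(seed, i))
    tibble::tibble(quantity = col, original_mean = b$original_mean,
                   original_sd = b$original_sd, n = b$n,
                   sample_p = b$sample_p)
  })
  rows$bh_adjusted_p <- bh_adjust(rows$sample_p)
  rows
}
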