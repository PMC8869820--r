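#' Pairwise Pearson correlations of day-difference columns
#'
#' Two-sided Pearson correlation tests over all requested column pairs,
#' with pairwise-complete deletion, t-distribution p-values on n - 2
#' degrees of freedom and significance stars at 0.05 / 0.01 / 0.001.
#' Results are sorted in descending order of |r| — the layout of a
#' day-difference correlation table.  Constant columns (undefined r) are
#' flagged and excluded.
#'
#' @param deltas A tibble of per-patient difference values, e.g. from
#'   [day_difference()].
#' @param vars1,vars2 Character vectors of column names; every `vars1` x
#'   `vars2` pair (minus self-pairs and duplicates) is tested.  Defaults:
#'   all `delta_*` columns against each other.
#' @param min_pairs Minimum number of complete pairs (default 3).
#'
#' @return A tibble of class `correlation_table` with columns `var1`,
#'   `var2`, `r`, `p_value`, `n`, `stars`, `degenerate`.
#' @examples
#' d <- tibble::tibble(a = 1:10, b = 2 * (1:10) + rnorm(10))
#' pearson_matrix(d, "a", "b")
#' @export
pearson_matrix <- function(deltas, vars1 = NULL, vars2 = NULL, min_pairs = 3L) {
  num_cols <- names(deltas)[vapply(deltas, is.numeric, logical(1))]
  if (is.null(vars1)) vars1 <- grep("^delta_", num_cols, value = TRUE)
  if (length(vars1) == 0) vars1 <- num_cols
  if (is.null(vars2)) vars2 <- vars1
  stopifnot(all(c(vars1, vars2) %in% names(deltas)))

  pairs <- tidyr::expand_grid(var1 = vars1, var2 = vars2)
  pairs <- pairs[pairs$var1 != pairs$var2, , drop = FALSE]
  key <- purrr::map2_chr(pairs$var1, pairs$var2,
                         function(a, b) paste(sort(c(a, b)), collapse = "\r"))
  pairs <- pairs[!duplicated(key), , drop = FALSE]

  res <- purrr::pmap_dfr(pairs, function(var1, var2) {
    x <- deltas[[var1]]
    y <- deltas[[var2]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]
    y <- y[ok]
    n <- length(x)
    if (n < min_pairs || sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(var1 = var1, var2 = var2, r = NA_real_,
                            p_value = NA_real_, n = n, degenerate = TRUE))
    }
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    tibble::tibble(var1 = var1, var2 = var2, r = r, p_value = p, n = n,
                   degenerate = FALSE)
  })
  res$stars <- significance_stars(res$p_value)
  res <- res[order(-abs(res$r)), , drop = FALSE]
  class(res) <- c("correlation_table", class(res))
  res
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @describeIn pearson_matrix Lollipop chart of coefficients by pair.
#' @param object A `correlation_table`.
#' @param ... Unused.
#' @export
autoplot.correlation_table <- function(object, ...) {
  df <- dplyr::filter(object, !.data$degenerate)
  df$pair <- factor(paste(df$var1, "~", df$var2),
                    levels = rev(paste(df$var1, "~", df$var2)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$pair)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$r, yend = .data$pair),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < 0.05), size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Pearson r", y = NULL, colour = "p < 0.05") +
    ggplot2::theme_minimal()
}
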