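#' Per-day cohort summaries with day-contrast tests
#'
#' Cohort-level mean and SD across patients of each DHM aggregate per
#' timepoint and cell type (the "black horizontal line" view of the
#' perioperative course), plus paired t-tests between consecutive
#' timepoints and of every later timepoint against baseline.
#'
#' @param cohort A cohort table.
#' @param parameters Aggregate columns to summarize (default the four DHM
#'   means).
#'
#' @return A list with tibbles `summary` (`cell_type`, `parameter`,
#'   `timepoint`, `n`, `mean`, `sd`) and `contrasts` (`cell_type`,
#'   `parameter`, `later`, `baseline`, `n_pairs`, `mean_difference`,
#'   `p_value`, `stars`); `contrasts` is empty when only one timepoint is
#'   present.
#' @examples
#' fig <- summarize_days(simulate_cohort(cohort_spec(seed = 1)))
#' head(fig$summary)
#' @export
summarize_days <- function(cohort,
                           parameters = c("V_mean", "n_cell_mean",
                                          "DM_mean", "FF_mean")) {
  stopifnot(all(parameters %in% names(cohort)))
  long <- tidyr::pivot_longer(
    cohort[, c("patient_id", "timepoint", "cell_type", parameters)],
    dplyr::all_of(parameters), names_to = "parameter", values_to = "value"
  )
  summary <- long |>
    dplyr::group_by(.data$cell_type, .data$parameter, .data$timepoint) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )

  tps <- levels(factor(cohort$timepoint))
  contrast_pairs <- unique(rbind(
    if (length(tps) > 1) cbind(tps[-1], tps[-length(tps)]),
    if (length(tps) > 1) cbind(tps[-1], tps[1])
  ))
  contrasts <- if (is.null(contrast_pairs)) {
    tibble::tibble(cell_type = character(), parameter = character(),
                   later = character(), baseline = character(),
                   n_pairs = integer(), mean_difference = numeric(),
                   p_value = numeric(), stars = character())
  } else {
    purrr::map_dfr(seq_len(nrow(contrast_pairs)), function(i) {
      later <- contrast_pairs[i, 1]
      base <- contrast_pairs[i, 2]
      long |>
        dplyr::filter(.data$timepoint %in% c(later, base)) |>
        dplyr::group_by(.data$cell_type, .data$parameter) |>
        dplyr::group_modify(function(df, key) {
          w <- tidyr::pivot_wider(df[, c("patient_id", "timepoint", "value")],
                                  names_from = "timepoint",
                                  values_from = "value")
          ok <- !is.na(w[[later]]) & !is.na(w[[base]])
          d <- w[[later]][ok] - w[[base]][ok]
          if (length(d) < 2 || sd(d) == 0) {
            p <- if (length(d) >= 1 && all(d == 0)) 1 else NA_real_
          } else {
            p <- t.test(d)$p.value
          }
          tibble::tibble(later = later, baseline = base,
                         n_pairs = length(d),
                         mean_difference = mean(d),
                         p_value = p)
        }) |>
        dplyr::ungroup()
    }) |>
      dplyr::mutate(stars = significance_stars(.data$p_value))
  }
  list(summary = summary, contrasts = contrasts)
}

#' Pooled cohort mean of one parameter across all timepoints
#'
#' Mean over every patient-sample average of one cell type, pooling all
#' timepoints — e.g. the grand mean volume of all measured monocytes
#' (about 404 um^3 with the default per-day means 390/413/414/400).
#'
#' @param cohort A cohort table.
#' @param cell_type `"lymphocyte"` or `"monocyte"`.
#' @param parameter Aggregate column (default `"V_mean"`).
#'
#' @return A one-row tibble with `cell_type`, `parameter`, `n_samples`,
#'   `pooled_mean`, `pooled_sd`.
#' @export
pooled_parameter_mean <- function(cohort, cell_type, parameter = "V_mean") {
  v <- cohort[[parameter]][cohort$cell_type == cell_type]
  v <- v[!is.na(v)]
  tibble::tibble(cell_type = cell_type, parameter = parameter,
                 n_samples = length(v), pooled_mean = mean(v),
                 pooled_sd = sd(v))
}

#' @describeIn summarize_days Perioperative course plot of one parameter.
#' @param object A cohort table (for `autoplot`).
#' @param parameter Aggregate column to plot.
#' @param ... Unused.
#' @export
autoplot.cohort_table <- function(object, parameter = "V_mean", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$timepoint, y = .data[[parameter]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.4, colour = "black") +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = parameter) +
    ggplot2::theme_minimal()
}
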