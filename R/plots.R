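#' Plot a niche histogram against the null distribution
#'
#' Bars show the null distribution of site conditions (count of sites per
#' bin) and the occurrence-weighted distribution of the group, on free
#' scales.
#'
#' @param object A [niche_histogram()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot niche_histogram
#' @export
autoplot.niche_histogram <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(
      c("group_weight", "null_count"),
      names_to = "series", values_to = "y"
    ) |>
    mutate(series = dplyr::recode(.data$series,
      group_weight = "group (weighted occurrences)",
      null_count = "null (sites)"
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2, y = .data$y
  )) +
    ggplot2::geom_col(width = df$bin_right[1] - df$bin_left[1]) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = attr(object, "variable") %||% "environmental variable",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot niche-narrowness results
#'
#' SD ratio against Levene evidence for every group x variable, with the
#' decision thresholds drawn; significant results are labelled with their
#' star grade.
#'
#' @param object A `niche_result` tibble from [niche_narrowness()].
#' @param alpha Significance level drawn as the horizontal threshold.
#' @param sd_ratio_min Vertical threshold. Default 2.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot niche_result
#' @export
autoplot.niche_result <- function(object, alpha = 0.05, sd_ratio_min = 2,
                                  ...) {
  df <- as_tibble(object) |> filter(!.data$nd)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sd_ratio, y = -log10(.data$levene_p),
    colour = .data$significant, shape = .data$variable
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sd_ratio_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(
      x = "SD(null) / SD(group)", y = "-log10 Levene p",
      colour = "narrow niche"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of cross-validated R2 over repeats
#'
#' @param object A [cv_r2()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_r2
#' @export
autoplot.cv_r2 <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = mean(object$r2), linetype = 2) +
    ggplot2::labs(x = "out-of-fold R2 per repeat", y = "repeats") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
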