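#' Heatmap of a directed interaction matrix
#'
#' Primary strains as columns and secondary strains as rows, matching the
#' conventional layout of pairwise-interaction heatmaps; darker tiles mean
#' stronger (more negative for ECI/SI, larger for MRO) coefficients.
#'
#' @param object An `interaction_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  metric <- attr(object, "metric")
  df <- as_tibble(object)
  df$secondary <- factor(df$secondary, levels = rev(sort(unique(df$secondary))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$primary, y = .data$secondary,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_gradient2(low = "#67001f", mid = "white", high = "#053061",
                                  midpoint = 0, name = metric) +
    ggplot2::labs(x = "primary strain", y = "secondary strain",
                  title = sprintf("%s (primary → secondary)", metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Median and interquartile range of C_net per treatment
#'
#' @param object A `cnet_summary`.
#' @param ... Unused.
#' @return A ggplot object (pointrange: median with quartile bars).
#' @method autoplot cnet_summary
#' @export
autoplot.cnet_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$treatment, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3)) +
    ggplot2::labs(x = NULL, y = sprintf("%s (median, IQR)", object$value)) +
    ggplot2::theme_minimal()
}

#' Heatmap of consumption/production profiles
#'
#' Signed log2 fold changes of called features (non-significant features are
#' blank), isolates in rows and features in columns.
#'
#' @param profiles Consumption profiles from [classify_changes()].
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(profiles) {
  df <- profiles |>
    dplyr::mutate(signal = dplyr::if_else(.data$call == "unchanged",
                                          NA_real_, .data$log2fc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_id, y = .data$isolate,
                                   fill = .data$signal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                                  midpoint = 0, na.value = "grey95",
                                  name = "log2 fold change") +
    ggplot2::labs(x = "metabolite feature", y = "isolate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
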