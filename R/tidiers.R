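#' Tidy an interaction matrix into one row per directed pair
#'
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return Tibble with `metric`, `primary`, `secondary`, `value`, `valid`.
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(metric = attr(x, "metric"), .before = 1)
}

#' One-row summary of an interaction matrix
#'
#' @inheritParams tidy.interaction_matrix
#' @return Tibble with the metric, strain/pair counts, mean and median
#'   coefficient and the fraction of negative pairs.
#' @method glance interaction_matrix
#' @export
glance.interaction_matrix <- function(x, ...) {
  v <- x$value[x$valid]
  tibble(metric = attr(x, "metric"),
         n_strains = length(attr(x, "strains")),
         n_pairs = nrow(x), n_valid = sum(x$valid),
         mean = mean(v), median = median(v),
         fraction_negative = mean(v < 0))
}

#' @rdname tidy.interaction_matrix
#' @method tidy matrix_comparison
#' @export
tidy.matrix_comparison <- function(x, ...) {
  tibble(metric_a = x$metric_a, metric_b = x$metric_b, method = x$method,
         estimate = x$statistic, p_value = x$p_value, n_pairs = x$n_pairs,
         fraction_a_greater = x$fraction_a_greater)
}

#' @rdname glance.interaction_matrix
#' @method glance matrix_comparison
#' @export
glance.matrix_comparison <- function(x, ...) tidy(x)

#' @rdname tidy.interaction_matrix
#' @method tidy mantel_perm
#' @export
tidy.mantel_perm <- function(x, ...) {
  tibble(estimate = x$r, p_value = x$p_value, n_perm = x$n_perm,
         method = x$method, alternative = x$alternative,
         exhaustive = x$exhaustive)
}

#' @rdname glance.interaction_matrix
#' @method glance mantel_perm
#' @export
glance.mantel_perm <- function(x, ...) tidy(x)

#' Tidy a per-treatment C_net summary
#'
#' @param x A `cnet_summary`.
#' @param ... Unused.
#' @return The per-treatment tibble (`treatment`, `n`, `median`, `q1`, `q3`).
#' @method tidy cnet_summary
#' @export
tidy.cnet_summary <- function(x, ...) x$summary

#' @rdname tidy.cnet_summary
#' @return For `glance`: one row with the Kruskal-Wallis statistic, p-value
#'   and method, and the number of treatments.
#' @method glance cnet_summary
#' @export
glance.cnet_summary <- function(x, ...) {
  tibble(statistic = x$kruskal$statistic, p_value = x$kruskal$p_value,
         method = x$kruskal$method, n_treatments = nrow(x$summary))
}
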