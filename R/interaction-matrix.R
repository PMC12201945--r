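new_interaction_matrix <- function(tbl, metric, strains) {
  structure(tbl, metric = metric, strains = strains,
            class = c("interaction_matrix", class(tbl)))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix: %s, %d strains>\n",
              attr(x, "metric"), length(attr(x, "strains"))))
  NextMethod()
}

#' Directed ECI matrix from consumption profiles
#'
#' Evaluates [compute_eci()] for every ordered (primary, secondary) strain
#' pair over the shared feature set. Proportions must have been filled with
#' [estimate_proportions()].
#'
#' @param profiles Consumption profiles for all isolates over an identical
#'   feature set.
#' @return An `interaction_matrix`: a tibble with columns `primary`,
#'   `secondary`, `value` and `valid` (`FALSE` where the secondary strain
#'   consumes nothing, value reported as 0), with metric `"ECI"`.
#' @export
eci_matrix <- function(profiles) {
  check_cols(profiles, c("isolate", "feature_id", "proportion"), "consumption profile")
  if (any(is.na(profiles$proportion)))
    abort("proportions not filled; run estimate_proportions() first")
  wide <- profiles |>
    dplyr::select("isolate", "feature_id", "proportion") |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "proportion")
  if (anyNA(wide)) abort("isolates do not share an identical feature set")
  strains <- wide$isolate
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- strains
  pairs <- tidyr::expand_grid(primary = strains, secondary = strains)
  vals <- purrr::map2(pairs$primary, pairs$secondary,
                      function(p, s) compute_eci(mat[s, ], mat[p, ]))
  pairs$value <- purrr::map_dbl(vals, as.numeric)
  pairs$valid <- purrr::map_lgl(vals, function(v) isTRUE(attr(v, "valid")))
  new_interaction_matrix(pairs, "ECI", strains)
}

#' Directed MRO matrix from nutrient-requirement sets
#'
#' @param uptake_sets Long tibble with columns `strain` and `nutrient`
#'   (one row per set membership), as produced by [generate_uptake_sets()] or
#'   read from TSV/JSON.
#' @return An `interaction_matrix` with metric `"MRO"`; entries in `[0, 1]`,
#'   diagonal 1 for non-empty sets.
#' @export
mro_matrix <- function(uptake_sets) {
  check_cols(uptake_sets, c("strain", "nutrient"), "uptake sets")
  sets <- split(uptake_sets$nutrient, uptake_sets$strain)
  strains <- names(sets)
  pairs <- tidyr::expand_grid(primary = strains, secondary = strains)
  pairs$value <- purrr::map2_dbl(pairs$primary, pairs$secondary,
                                 function(p, s) compute_mro(sets[[s]], sets[[p]]))
  pairs$valid <- TRUE
  new_interaction_matrix(pairs, "MRO", strains)
}

#' Directed SI matrix from a sequential-growth table
#'
#' @inheritParams compute_si
#' @return An `interaction_matrix` with metric `"SI"`; entries >= -1.
#' @export
si_matrix <- function(growth, baseline_label = "PtSM",
                      aggregate = c("ratio-of-means", "mean-of-ratios")) {
  aggregate <- match.arg(aggregate)
  check_cols(growth, c("secondary", "primary", "count"), "growth table")
  strains <- sort(unique(growth$secondary))
  primaries <- setdiff(unique(growth$primary), baseline_label)
  pairs <- tidyr::expand_grid(primary = primaries, secondary = strains)
  pairs$value <- purrr::map2_dbl(pairs$primary, pairs$secondary, function(p, s) {
    compute_si(growth, s, p, baseline_label = baseline_label, aggregate = aggregate)
  })
  pairs$valid <- TRUE
  new_interaction_matrix(pairs, "SI", strains)
}

#' Widen an interaction matrix to secondary-by-primary numeric form
#'
#' Rows are secondary strains and columns primary strains, matching the
#' orientation of the heatmap figures.
#'
#' @param x An `interaction_matrix`.
#' @return A numeric matrix.
#' @export
as_matrix <- function(x) {
  stopifnot(inherits(x, "interaction_matrix"))
  wide <- x |>
    dplyr::select("primary", "secondary", "value") |>
    tidyr::pivot_wider(names_from = "primary", values_from = "value") |>
    dplyr::arrange(.data$secondary)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$secondary
  m
}

#' Correlate two interaction matrices over their common strain pairs
#'
#' Joins two directed interaction matrices on (primary, secondary), keeps
#' pairwise-complete valid cells, and reports the requested correlation along
#' with the fraction of pairs where the first matrix exceeds the second
#' (e.g. the share of SI values less negative than the matching ECI when
#' called as `compare_matrices(si, eci)`).
#'
#' @param a,b `interaction_matrix` objects over the same strains.
#' @param method `"pearson"` or `"spearman"`.
#' @param include_diagonal Include intraspecific (self) pairs (default `TRUE`,
#'   giving n = 100 for 10 strains).
#' @return A `matrix_comparison` object: list with `statistic` (correlation),
#'   `p_value`, `n_pairs`, `fraction_a_greater`, `n_excluded`, `method` and
#'   the two metric labels.
#' @export
compare_matrices <- function(a, b, method = c("pearson", "spearman"),
                             include_diagonal = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(a, "interaction_matrix"), inherits(b, "interaction_matrix"))
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), "primary", "secondary", a_value = "value", a_valid = "valid"),
    dplyr::select(tibble::as_tibble(b), "primary", "secondary", b_value = "value", b_valid = "valid"),
    by = c("primary", "secondary")
  )
  if (!include_diagonal) joined <- dplyr::filter(joined, .data$primary != .data$secondary)
  n_all <- nrow(joined)
  joined <- dplyr::filter(joined, .data$a_valid, .data$b_valid,
                          is.finite(.data$a_value), is.finite(.data$b_value))
  if (nrow(joined) < 3) abort("fewer than 3 valid common pairs")
  ct <- suppressWarnings(cor.test(joined$a_value, joined$b_value, method = method))
  structure(
    list(statistic = unname(ct$estimate), p_value = ct$p.value,
         n_pairs = nrow(joined),
         fraction_a_greater = mean(joined$a_value > joined$b_value),
         n_excluded = n_all - nrow(joined), method = method,
         metric_a = attr(a, "metric"), metric_b = attr(b, "metric")),
    class = "matrix_comparison"
  )
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat(sprintf("%s ~ %s: %s r = %.3f (p = %.3g, n = %d pairs)\n",
              x$metric_a, x$metric_b, x$method, x$statistic, x$p_value, x$n_pairs))
  cat(sprintf("fraction %s > %s: %.2f; excluded cells: %d\n",
              x$metric_a, x$metric_b, x$fraction_a_greater, x$n_excluded))
  invisible(x)
}
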