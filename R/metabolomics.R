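#' Validate a long-format feature-intensity table
#'
#' @param table Tibble/data frame with columns `feature_id`, `sample_id`,
#'   `group` and `intensity`. Groups are `"blank"`, `"control"` or
#'   `"isolate:<name>"`.
#' @param require_blank,require_control Whether those groups must be present.
#' @return The table, invisibly, after validation.
#' @keywords internal
validate_feature_table <- function(table, require_blank = FALSE, require_control = FALSE) {
  check_cols(table, c("feature_id", "sample_id", "group", "intensity"), "feature table")
  if (any(!is.finite(table$intensity)) || any(table$intensity < 0))
    abort("intensities must be finite and non-negative")
  if (require_blank && !any(table$group == "blank"))
    abort("feature table has no 'blank' group")
  if (require_control && !any(table$group == "control"))
    abort("feature table has no 'control' group")
  invisible(table)
}

group_sizes <- function(table) {
  table |>
    dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$group, name = "n_samples")
}

check_min_replicates <- function(table, groups = NULL) {
  sizes <- group_sizes(table)
  if (!is.null(groups)) sizes <- dplyr::filter(sizes, .data$group %in% groups)
  bad <- dplyr::filter(sizes, .data$n_samples < 2)
  if (nrow(bad) > 0)
    abort(sprintf("group(s) with fewer than 2 replicates: %s",
                  paste(bad$group, collapse = ", ")))
  invisible(sizes)
}

#' Retain features significantly above the extraction-blank background
#'
#' A feature is kept when, for at least one non-blank sample group, its mean
#' intensity exceeds the blank mean and a two-sample t-test against the blank
#' replicates is significant after multiple-testing correction. The correction
#' family is all feature-by-group contrasts tested in the call; its size is
#' recorded in the `"n_tests"` attribute, and per-ionization-mode retention
#' counts (from the feature-id prefix) in `"retained_by_mode"`.
#'
#' @param table Long feature table (see [validate_feature_table()]) containing
#'   a `blank` group.
#' @param alpha Significance level after correction.
#' @param correction `"bonferroni"` (default), `"holm"`, `"BH"` or `"none"`.
#' @param var_equal Pooled-variance Student t-test when `TRUE` (default);
#'   Welch when `FALSE`.
#' @return The subset of `table` for retained features, with attributes
#'   `n_retained`, `n_tests` and `retained_by_mode`.
#' @export
filter_above_background <- function(table, alpha = 0.05,
                                    correction = "bonferroni",
                                    var_equal = TRUE) {
  validate_feature_table(table, require_blank = TRUE)
  if (!any(table$group != "blank")) abort("feature table has no non-blank group")
  check_min_replicates(table)

  wide <- table |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      blank = list(.data$intensity[.data$group == "blank"]),
      groups = list(split(.data$intensity[.data$group != "blank"],
                          .data$group[.data$group != "blank"])),
      .groups = "drop"
    )

  tests <- wide |>
    dplyr::mutate(result = purrr::map2(.data$blank, .data$groups, function(bl, gs) {
      tibble(contrast_group = names(gs),
             above = purrr::map_dbl(gs, mean) > mean(bl),
             p_value = purrr::map_dbl(gs, safe_t_pvalue, y = bl, var_equal = var_equal))
    })) |>
    dplyr::select("feature_id", "result") |>
    tidyr::unnest("result")

  n_tests <- nrow(tests)
  tests$p_adj <- adjust_p(tests$p_value, correction, n_tests)
  kept_ids <- tests |>
    dplyr::filter(.data$above, !is.na(.data$p_adj), .data$p_adj < alpha) |>
    dplyr::distinct(.data$feature_id) |>
    dplyr::pull("feature_id")

  out <- dplyr::filter(table, .data$feature_id %in% kept_ids)
  mode <- sub("-.*$", "", kept_ids)
  attr(out, "n_retained") <- length(kept_ids)
  attr(out, "n_tests") <- n_tests
  attr(out, "retained_by_mode") <- table(mode)
  out
}

#' Call consumption and production of each feature by each isolate
#'
#' Compares each isolate group's replicate intensities to the uninoculated
#' control group with a two-sample t-test, correcting over the whole
#' feature-by-isolate family. Features with adjusted p at or below `alpha` are
#' called `consumed` (isolate mean below control) or `produced` (above);
#' otherwise `unchanged`. Log2 fold changes are isolate over control means;
#' a zero control mean with nonzero isolate mean yields an infinite log2fc and
#' sets the `flagged` column.
#'
#' @inheritParams filter_above_background
#' @param control_group Name of the uninoculated control group.
#' @param aggregate `"mean"` (arithmetic, default) or `"geometric"` replicate
#'   aggregation for the reported group means.
#' @return A consumption-profile tibble with columns `isolate`, `feature_id`,
#'   `mean_control`, `mean_isolate`, `log2fc`, `p_value`, `p_adj`, `call`
#'   (factor: consumed/produced/unchanged), `proportion` (`NA` until
#'   [estimate_proportions()] is applied) and `flagged`. The correction family
#'   size is in attribute `n_tests`.
#' @export
classify_changes <- function(table, control_group = "control", alpha = 0.05,
                             correction = "bonferroni", var_equal = TRUE,
                             aggregate = c("mean", "geometric")) {
  aggregate <- match.arg(aggregate)
  validate_feature_table(table)
  if (!any(table$group == control_group))
    abort(sprintf("control group '%s' not present", control_group))
  isolate_groups <- setdiff(unique(table$group), c("blank", control_group))
  if (length(isolate_groups) == 0) abort("no isolate groups present")
  check_min_replicates(table, groups = c(control_group, isolate_groups))
  agg <- if (aggregate == "mean") mean else function(x) exp(mean(log(pmax(x, .Machine$double.xmin))))

  by_feature <- table |>
    dplyr::filter(.data$group %in% c(control_group, isolate_groups)) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(values = list(split(.data$intensity, .data$group)), .groups = "drop")

  profiles <- purrr::map_dfr(isolate_groups, function(g) {
    purrr::pmap_dfr(by_feature, function(feature_id, values) {
      ctrl <- values[[control_group]]
      iso <- values[[g]]
      m0 <- agg(ctrl)
      m1 <- agg(iso)
      log2fc <- if (m0 == 0 && m1 == 0) 0 else log2(m1 / m0)
      tibble(isolate = sub("^isolate:", "", g), feature_id = feature_id,
             mean_control = m0, mean_isolate = m1, log2fc = log2fc,
             p_value = safe_t_pvalue(iso, ctrl, var_equal = var_equal),
             flagged = (m0 == 0 && m1 > 0))
    })
  })

  n_tests <- nrow(profiles)
  profiles <- profiles |>
    dplyr::mutate(
      p_adj = adjust_p(.data$p_value, correction, n_tests),
      call = factor(dplyr::case_when(
        is.na(.data$p_adj) | .data$p_adj > alpha ~ "unchanged",
        .data$mean_isolate < .data$mean_control ~ "consumed",
        .data$mean_isolate > .data$mean_control ~ "produced",
        TRUE ~ "unchanged"
      ), levels = c("consumed", "produced", "unchanged")),
      proportion = NA_real_
    ) |>
    dplyr::select("isolate", "feature_id", "mean_control", "mean_isolate",
                  "log2fc", "p_value", "p_adj", "call", "proportion", "flagged")
  attr(profiles, "n_tests") <- n_tests
  profiles
}

#' Fill consumption proportions into a consumption profile
#'
#' Under the default convention the proportion of a metabolite used by an
#' isolate is `p = clamp(1 - mean_isolate / mean_control, 0, 1)`, so full
#' depletion gives 1 and no change gives 0 (and two strains with identical
#' affinities yield a competition coefficient of -1). The raw intensity-ratio
#' convention (`p = clamp(mean_isolate / mean_control, 0, 1)`) is retained for
#' sensitivity analysis. By default proportions are assigned only to features
#' called `consumed`; all others get 0.
#'
#' @param profiles Output of [classify_changes()].
#' @param convention `"one-minus-ratio"` (default) or `"ratio"`.
#' @param only_consumed Restrict nonzero proportions to significant consumed
#'   calls (default `TRUE`).
#' @return `profiles` with the `proportion` column filled; rows with a zero
#'   control mean get proportion 0 and `flagged = TRUE`.
#' @export
estimate_proportions <- function(profiles,
                                 convention = c("one-minus-ratio", "ratio"),
                                 only_consumed = TRUE) {
  convention <- match.arg(convention)
  check_cols(profiles, c("mean_control", "mean_isolate", "call"), "consumption profile")
  ratio <- ifelse(profiles$mean_control > 0,
                  profiles$mean_isolate / profiles$mean_control, NA_real_)
  p <- switch(convention,
              "one-minus-ratio" = clamp(1 - ratio, 0, 1),
              "ratio" = clamp(ratio, 0, 1))
  if (only_consumed) p[profiles$call != "consumed"] <- 0
  undefined <- is.na(p)
  p[undefined] <- 0
  profiles$proportion <- p
  profiles$flagged <- profiles$flagged | undefined
  profiles
}

#' Features depleted by at least a given fold change by every isolate
#'
#' @param profiles Consumption profiles (all isolates, same feature set).
#' @param threshold_log2fc Maximum log2 fold change (default -1, at least a
#'   halving of intensity).
#' @return Tibble with `feature_id`, the number of isolates, and the maximum
#'   (least negative) log2fc across isolates, for features significantly
#'   consumed with `log2fc <= threshold_log2fc` by every isolate.
#' @export
shared_depletion_summary <- function(profiles, threshold_log2fc = -1) {
  check_cols(profiles, c("isolate", "feature_id", "log2fc", "call"), "consumption profile")
  if (nrow(profiles) == 0) abort("empty profile set")
  n_isolates <- dplyr::n_distinct(profiles$isolate)
  profiles |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_isolates = dplyr::n_distinct(.data$isolate),
      n_pass = sum(.data$call == "consumed" & .data$log2fc <= threshold_log2fc),
      max_log2fc = max(.data$log2fc),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_isolates == !!n_isolates, .data$n_pass == !!n_isolates) |>
    dplyr::select("feature_id", "n_isolates", "max_log2fc")
}
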