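#' Assemble a pipeline run configuration
#'
#' A run executes only the stages whose inputs (designs or file paths) are
#' present: metabolomics (feature filtering, change calling, proportions,
#' ECI), nutrient-set overlap (MRO), sequential growth (SI, classification),
#' metric comparisons, and isotope accounting (C_net, C_total). All
#' randomness derives from the single `seed`, which also seeds any synthetic
#' designs that were built without an explicit seed.
#'
#' @param metabolome A [metabolome_design()], a feature-table path, or `NULL`.
#' @param sequential A [sequential_design()], a growth-table path, or `NULL`.
#' @param nanosims A [nanosims_design()], a ROI-table path, or `NULL`.
#' @param uptake_sets An uptake-set tibble, a path, or `NULL`.
#' @param census Optional well-census tibble for C_total.
#' @param alpha,correction,var_equal Significance settings for the
#'   metabolomics tests.
#' @param proportion_convention Passed to [estimate_proportions()].
#' @param include_diagonal Include self pairs in metric comparisons.
#' @param constants [isotope_constants()] for the isotope stage.
#' @param seed Root seed recorded in the bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(metabolome = NULL, sequential = NULL, nanosims = NULL,
                       uptake_sets = NULL, census = NULL,
                       alpha = 0.05, correction = "bonferroni", var_equal = TRUE,
                       proportion_convention = "one-minus-ratio",
                       include_diagonal = TRUE,
                       constants = isotope_constants(), seed = 1) {
  structure(list(metabolome = metabolome, sequential = sequential,
                 nanosims = nanosims, uptake_sets = uptake_sets, census = census,
                 alpha = alpha, correction = correction, var_equal = var_equal,
                 proportion_convention = proportion_convention,
                 include_diagonal = include_diagonal,
                 constants = constants, seed = check_count(seed, "seed", 0L)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings (`alpha`, `correction`, `proportion_convention`, `seed`,
#' isotope constants) and input paths map directly onto [run_config()];
#' design blocks (`metabolome`, `sequential`, `nanosims` given as mappings)
#' are passed to the corresponding design constructors.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  as_stage <- function(x, ctor) {
    if (is.null(x)) NULL
    else if (is.character(x)) x
    else do.call(ctor, modifyList(list(seed = seed), x))
  }
  run_config(
    metabolome = as_stage(y$metabolome, metabolome_design),
    sequential = as_stage(y$sequential, sequential_design),
    nanosims = as_stage(y$nanosims, nanosims_design),
    uptake_sets = y$uptake_sets,
    alpha = y$alpha %||% 0.05,
    correction = y$correction %||% "bonferroni",
    proportion_convention = y$proportion_convention %||% "one-minus-ratio",
    constants = do.call(isotope_constants, y$constants %||% list()),
    seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages whose inputs are present in the configuration and
#' collects every headline quantity into a results bundle: retained-feature
#' count, per-isolate consumed/produced tallies, the ECI/MRO/SI matrices,
#' the negative/positive SI classification tally, metric comparisons
#' (SI ~ ECI Spearman, MRO ~ ECI Pearson, the fraction of SI values less
#' negative than ECI), per-treatment C_net summaries and C_total. Synthetic
#' designs are re-seeded from the run seed so a rerun reproduces the bundle
#' exactly.
#'
#' @param config A [run_config()] (or a YAML path).
#' @param out_dir Optional directory; when given, stage tables (TSV), the
#'   matrices and a `results.json` bundle are written there.
#' @return A `results_bundle` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  bundle <- list(provenance = list(
    package_version = as.character(packageVersion("phycoflow")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  ))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "phycoflow_stage_error")
    })
  }

  profiles <- NULL
  if (!is.null(config$metabolome)) {
    stage("metabolomics", {
      if (is.character(config$metabolome)) {
        table <- read_feature_table(config$metabolome)
        truth <- NULL
      } else {
        sim <- generate_metabolome(config$metabolome)
        table <- sim$table
        truth <- sim$ground_truth
      }
      filtered <- filter_above_background(table, alpha = config$alpha,
                                          correction = config$correction,
                                          var_equal = config$var_equal)
      profiles <- classify_changes(filtered, alpha = config$alpha,
                                   correction = config$correction,
                                   var_equal = config$var_equal) |>
        estimate_proportions(convention = config$proportion_convention)
      bundle$n_features_retained <- attr(filtered, "n_retained")
      bundle$n_tests_background <- attr(filtered, "n_tests")
      bundle$retained_by_mode <- as.list(attr(filtered, "retained_by_mode"))
      bundle$isolate_tallies <- profiles |>
        dplyr::group_by(.data$isolate) |>
        dplyr::summarise(n_consumed = sum(.data$call == "consumed"),
                         n_produced = sum(.data$call == "produced"), .groups = "drop")
      bundle$shared_depleted <- shared_depletion_summary(profiles)$feature_id
      bundle$eci <- eci_matrix(profiles)
      bundle$ground_truth_metabolome <- truth
      profiles <- profiles
    })
  }

  if (!is.null(config$uptake_sets)) {
    stage("mro", {
      sets <- if (is.character(config$uptake_sets)) read_uptake_sets(config$uptake_sets)
              else config$uptake_sets
      bundle$mro <- mro_matrix(sets)
    })
  }

  if (!is.null(config$sequential)) {
    stage("sequential", {
      growth <- if (is.character(config$sequential)) read_growth_table(config$sequential)
                else generate_sequential(config$sequential)
      si <- si_matrix(growth)
      cls <- classify_interaction(si$value)
      bundle$si <- si
      bundle$si_tally <- list(n_pairs = nrow(si),
                               n_negative = sum(cls == "competitive"),
                               n_neutral = sum(cls == "neutral"),
                               n_positive = sum(cls == "facilitative"))
    })
  }

  if (!is.null(bundle$si) && !is.null(bundle$eci)) {
    stage("compare_si_eci", {
      bundle$si_vs_eci <- compare_matrices(bundle$si, bundle$eci, method = "spearman",
                                            include_diagonal = config$include_diagonal)
    })
  }
  if (!is.null(bundle$mro) && !is.null(bundle$eci)) {
    stage("compare_mro_eci", {
      bundle$mro_vs_eci <- compare_matrices(bundle$mro, bundle$eci, method = "pearson",
                                             include_diagonal = config$include_diagonal)
    })
  }

  if (!is.null(config$nanosims)) {
    stage("isotope", {
      roi <- if (is.character(config$nanosims)) read_roi_table(config$nanosims)
             else generate_nanosims(config$nanosims)
      cn <- cnet_table(roi, constants = config$constants)
      bundle$cnet <- cn
      if (dplyr::n_distinct(cn$treatment) >= 2)
        bundle$cnet_summary <- summarize_treatment(cn)
      if (!is.null(config$census)) {
        ct <- c_total(config$census, cn)
        bundle$c_total <- ct
      }
    })
  }

  class(bundle) <- "results_bundle"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, profiles)
  bundle
}

write_bundle <- function(bundle, out_dir, profiles = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(profiles))
    readr::write_tsv(profiles, file.path(out_dir, "consumption_profiles.tsv"))
  for (m in c("eci", "mro", "si")) {
    if (!is.null(bundle[[m]]))
      write_interaction_matrix(bundle[[m]], file.path(out_dir, paste0(m, "_matrix.tsv")))
  }
  if (!is.null(bundle$cnet))
    readr::write_tsv(bundle$cnet, file.path(out_dir, "cnet_per_cell.tsv"))
  json <- bundle_json(bundle)
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

bundle_json <- function(bundle) {
  num <- function(x) if (is.null(x)) NULL else x
  cmp <- function(x) if (is.null(x)) NULL else
    list(r = x$statistic, p_value = x$p_value, n_pairs = x$n_pairs,
         fraction_a_greater = x$fraction_a_greater, method = x$method)
  list(
    provenance = bundle$provenance,
    n_features_retained = num(bundle$n_features_retained),
    isolate_tallies = if (!is.null(bundle$isolate_tallies)) bundle$isolate_tallies,
    shared_depleted = bundle$shared_depleted,
    si_tally = bundle$si_tally,
    si_vs_eci = cmp(bundle$si_vs_eci),
    mro_vs_eci = cmp(bundle$mro_vs_eci),
    cnet_summary = if (!is.null(bundle$cnet_summary)) bundle$cnet_summary$summary,
    c_total = if (!is.null(bundle$c_total)) as_tibble(bundle$c_total)
  )
}

#' Render a results bundle as a human-readable markdown report
#'
#' Matrices are laid out with primary strains as columns and secondary
#' strains as rows.
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @return A single markdown string.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "results_bundle"))
  lines <- c("# Pipeline results", "",
             sprintf("seed: %d | phycoflow %s", bundle$provenance$seed,
                     bundle$provenance$package_version), "")
  fmt_matrix <- function(x, label) {
    if (is.null(x) || nrow(x) == 0) return(c(sprintf("## %s", label), "", "no pairs", ""))
    m <- as_matrix(x)
    header <- paste(c("secondary \\ primary", colnames(m)), collapse = " | ")
    rule <- paste(rep("---", ncol(m) + 1), collapse = " | ")
    rows <- vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], sprintf("%.3f", m[i, ])), collapse = " | "), character(1))
    c(sprintf("## %s matrix", label), "", header, rule, rows, "")
  }
  if (!is.null(bundle$n_features_retained))
    lines <- c(lines, sprintf("Features retained above background: %d",
                              bundle$n_features_retained), "")
  lines <- c(lines, fmt_matrix(bundle$eci, "ECI"), fmt_matrix(bundle$mro, "MRO"),
             fmt_matrix(bundle$si, "SI"))
  if (!is.null(bundle$si_tally))
    lines <- c(lines, sprintf(
      "SI classification: %d negative / %d neutral / %d positive of %d pairs",
      bundle$si_tally$n_negative, bundle$si_tally$n_neutral,
      bundle$si_tally$n_positive, bundle$si_tally$n_pairs), "")
  for (nm in c("si_vs_eci", "mro_vs_eci")) {
    x <- bundle[[nm]]
    if (!is.null(x))
      lines <- c(lines, sprintf(
        "%s ~ %s: %s r = %.3f (p = %.3g, n = %d); fraction %s > %s = %.2f",
        x$metric_a, x$metric_b, x$method, x$statistic, x$p_value, x$n_pairs,
        x$metric_a, x$metric_b, x$fraction_a_greater), "")
  }
  if (!is.null(bundle$cnet_summary)) {
    s <- bundle$cnet_summary$summary
    lines <- c(lines, "## C_net by treatment", "",
               "treatment | n | median | q1 | q3", "--- | --- | --- | --- | ---",
               sprintf("%s | %d | %.2f | %.2f | %.2f", s$treatment, s$n,
                       s$median, s$q1, s$q3), "")
  }
  if (!is.null(bundle$c_total)) {
    ct <- bundle$c_total
    lines <- c(lines, "## C_total by treatment", "",
               sprintf("- %s: %.3g fg C (sd %.3g, %d microplates)", ct$treatment,
                       ct$c_total, ct$sd, ct$n_microplates), "")
  }
  paste(lines, collapse = "\n")
}
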