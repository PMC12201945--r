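#' Design for a synthetic exometabolomics experiment
#'
#' Describes a spent-medium incubation experiment: algal spent medium carrying
#' `n_features` LC-MS features is inoculated with each of `n_isolates`
#' bacterial isolates (with replication), alongside uninoculated controls and
#' extraction blanks. Each isolate consumes a known proportion of each feature
#' and may produce features it does not consume, so downstream estimates can be
#' scored against the truth.
#'
#' Intensities are modelled as `background + baseline * (1 - p + production)`
#' per feature, with multiplicative lognormal replicate noise at coefficient of
#' variation `noise_cv`. Blanks carry only the instrument background
#' (`blank_frac * baseline`). Optional pure-background features (present in
#' blanks and samples at the same low level) exercise the background filter.
#'
#' @param n_features Number of genuine exometabolite features.
#' @param n_isolates Number of bacterial isolates.
#' @param n_reps_isolate,n_reps_control,n_reps_blank Replicate tubes per
#'   isolate, uninoculated controls, and extraction blanks.
#' @param baseline_log_mean,baseline_log_sd Lognormal parameters of the
#'   per-feature baseline intensity in uninoculated spent medium.
#' @param noise_cv Coefficient of variation of replicate intensities.
#' @param blank_frac Instrument background level as a fraction of baseline.
#' @param n_background Number of extra pure-background features (no analyte).
#' @param true_proportions Optional isolate x feature matrix of consumption
#'   proportions in `[0, 1]`; drawn at random (sparse, Uniform(0.3, 0.95) on
#'   roughly a third of features per isolate) when `NULL`.
#' @param production_rates Optional isolate x feature matrix (>= 0) of
#'   production as a fraction of baseline; a consumed feature cannot also be
#'   produced. Drawn sparsely at random when `NULL`.
#' @param isolates,features Optional label vectors.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return An object of class `metabolome_design`.
#' @seealso [generate_metabolome()]
#' @export
metabolome_design <- function(n_features = 162, n_isolates = 10,
                              n_reps_isolate = 5, n_reps_control = 12,
                              n_reps_blank = 5,
                              baseline_log_mean = log(1e6), baseline_log_sd = 1,
                              noise_cv = 0.1, blank_frac = 0.01,
                              n_background = 0,
                              true_proportions = NULL, production_rates = NULL,
                              isolates = NULL, features = NULL, seed = 1) {
  n_features <- check_count(n_features, "n_features")
  n_isolates <- check_count(n_isolates, "n_isolates")
  n_reps_isolate <- check_count(n_reps_isolate, "n_reps_isolate", min = 2L)
  n_reps_control <- check_count(n_reps_control, "n_reps_control", min = 2L)
  n_reps_blank <- check_count(n_reps_blank, "n_reps_blank", min = 2L)
  n_background <- check_count(n_background, "n_background", min = 0L)
  check_fraction(noise_cv, "noise_cv", 0, Inf)
  check_fraction(blank_frac, "blank_frac")
  seed <- check_count(seed, "seed", min = 0L)

  isolates <- isolates %||% sprintf("isolate%02d", seq_len(n_isolates))
  features <- features %||% sprintf("Positive-%d", seq_len(n_features))
  if (length(isolates) != n_isolates) stop_field("isolates", "length must equal n_isolates")
  if (length(features) != n_features) stop_field("features", "length must equal n_features")

  if (is.null(true_proportions) || is.null(production_rates)) {
    drawn <- withr_seed(seed, draw_metabolome_truth(n_isolates, n_features))
    true_proportions <- true_proportions %||% drawn$proportions
    production_rates <- production_rates %||% (drawn$production * (true_proportions == 0))
  }
  true_proportions <- as.matrix(true_proportions)
  production_rates <- as.matrix(production_rates)
  if (!all(dim(true_proportions) == c(n_isolates, n_features)))
    stop_field("true_proportions", "must be an n_isolates x n_features matrix")
  if (!all(dim(production_rates) == c(n_isolates, n_features)))
    stop_field("production_rates", "must be an n_isolates x n_features matrix")
  check_fraction(true_proportions, "true_proportions")
  if (any(production_rates < 0)) stop_field("production_rates", "must be >= 0")
  if (any(true_proportions > 0 & production_rates > 0))
    stop_field("production_rates", "a feature cannot be both consumed and produced by one isolate")
  dimnames(true_proportions) <- dimnames(production_rates) <- list(isolates, features)

  structure(
    list(n_features = n_features, n_isolates = n_isolates,
         n_reps_isolate = n_reps_isolate, n_reps_control = n_reps_control,
         n_reps_blank = n_reps_blank, baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd, noise_cv = noise_cv,
         blank_frac = blank_frac, n_background = n_background,
         true_proportions = true_proportions, production_rates = production_rates,
         isolates = isolates, features = features, seed = seed),
    class = "metabolome_design"
  )
}

# sparse truth: ~1/3 of features consumed per isolate at Uniform(0.3, 0.95);
# a further 2% produced at Uniform(0.5, 2) x baseline
draw_metabolome_truth <- function(n_isolates, n_features) {
  consumed <- matrix(runif(n_isolates * n_features) < 1 / 3, n_isolates, n_features)
  proportions <- matrix(runif(n_isolates * n_features, 0.3, 0.95), n_isolates, n_features) * consumed
  produced <- matrix(runif(n_isolates * n_features) < 0.02, n_isolates, n_features) & !consumed
  production <- matrix(runif(n_isolates * n_features, 0.5, 2), n_isolates, n_features) * produced
  list(proportions = proportions, production = production)
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an exometabolomics feature table with known consumption truth
#'
#' Draws per-feature baseline intensities, then generates replicate intensities
#' for extraction blanks (instrument background only), uninoculated spent-medium
#' controls (background + baseline), and isolate-inoculated samples
#' (background + baseline scaled by `1 - p` plus any production), with
#' multiplicative lognormal noise.
#'
#' @param design A [metabolome_design()].
#' @return A list with components:
#'   * `table`: long-format feature table, a tibble with columns `feature_id`,
#'     `sample_id`, `group` (`"blank"`, `"control"` or `"isolate:<name>"`) and
#'     `intensity`.
#'   * `ground_truth`: tibble with `isolate`, `feature_id`, `true_proportion`
#'     and `production_rate`.
#' @examples
#' sim <- generate_metabolome(metabolome_design(n_features = 20, n_isolates = 3))
#' dplyr::count(sim$table, group)
#' @export
generate_metabolome <- function(design) {
  stopifnot(inherits(design, "metabolome_design"))
  d <- design
  withr_seed(d$seed, {
    baseline <- rlnorm(d$n_features, d$baseline_log_mean, d$baseline_log_sd)
    background <- d$blank_frac * baseline
    feat_ids <- d$features
    if (d$n_background > 0) {
      bg_baseline <- rlnorm(d$n_background, d$baseline_log_mean, d$baseline_log_sd)
      feat_ids <- c(feat_ids, sprintf("background-%d", seq_len(d$n_background)))
      baseline <- c(baseline, rep(0, d$n_background))
      background <- c(background, d$blank_frac * bg_baseline)
    }
    n_feat <- length(feat_ids)

    draw_group <- function(mean_by_feature, group, prefix, n_reps) {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        tibble(feature_id = feat_ids,
               sample_id = sprintf("%s_r%02d", prefix, r),
               group = group,
               intensity = mean_by_feature * ln_noise(n_feat, d$noise_cv))
      })
    }

    blanks <- draw_group(background, "blank", "blank", d$n_reps_blank)
    controls <- draw_group(background + baseline, "control", "control", d$n_reps_control)
    isolates <- purrr::map_dfr(seq_len(d$n_isolates), function(i) {
      p <- c(d$true_proportions[i, ], rep(0, d$n_background))
      prod <- c(d$production_rates[i, ], rep(0, d$n_background))
      mu <- background + baseline * (1 - p + prod)
      draw_group(mu, paste0("isolate:", d$isolates[i]), d$isolates[i], d$n_reps_isolate)
    })

    truth <- tibble(
      isolate = rep(d$isolates, each = d$n_features),
      feature_id = rep(d$features, times = d$n_isolates),
      true_proportion = as.vector(t(d$true_proportions)),
      production_rate = as.vector(t(d$production_rates))
    )
    list(table = dplyr::bind_rows(blanks, controls, isolates), ground_truth = truth)
  })
}
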