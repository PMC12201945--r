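#' Design for a synthetic sequential spent-media exchange experiment
#'
#' Each primary strain is grown on algal spent medium; its own spent medium is
#' then fed to every secondary strain, whose final cell counts are compared to
#' growth on unprocessed algal spent medium (the `"PtSM"` baseline). The true
#' sequential interaction coefficient for each ordered pair is known, so the
#' estimator can be scored.
#'
#' When `true_si` is `NULL` it is drawn to mirror the observed prevalence of
#' competition: 70% of ordered pairs negative (Uniform(-1, 0)) and 30%
#' positive (Uniform(0, 1)).
#'
#' @param n_strains Number of strains (each serves as primary and secondary).
#' @param true_si Optional primary x secondary matrix of true SI values
#'   (each >= -1).
#' @param baseline_counts Optional per-secondary expected cell count on plain
#'   algal spent medium (> 0); drawn lognormally around 1e5 when `NULL`.
#' @param n_reps Replicate wells per primary/secondary combination.
#' @param noise_cv Coefficient of variation of the multiplicative count noise.
#' @param strains Optional strain labels.
#' @param seed Integer seed.
#' @return An object of class `sequential_design`.
#' @seealso [generate_sequential()], [si_matrix()]
#' @export
sequential_design <- function(n_strains = 10, true_si = NULL,
                              baseline_counts = NULL, n_reps = 3,
                              noise_cv = 0.1, strains = NULL, seed = 1) {
  n_strains <- check_count(n_strains, "n_strains")
  n_reps <- check_count(n_reps, "n_reps")
  check_fraction(noise_cv, "noise_cv", 0, Inf)
  seed <- check_count(seed, "seed", min = 0L)
  strains <- strains %||% sprintf("strain%02d", seq_len(n_strains))
  if (length(strains) != n_strains) stop_field("strains", "length must equal n_strains")

  if (is.null(true_si) || is.null(baseline_counts)) {
    drawn <- withr_seed(seed, {
      neg <- matrix(runif(n_strains^2) < 0.7, n_strains, n_strains)
      si <- ifelse(neg, runif(n_strains^2, -1, 0), runif(n_strains^2, 0, 1))
      list(si = matrix(si, n_strains, n_strains),
           baseline = rlnorm(n_strains, log(1e5), 0.3))
    })
    true_si <- true_si %||% drawn$si
    baseline_counts <- baseline_counts %||% drawn$baseline
  }
  true_si <- as.matrix(true_si)
  if (!all(dim(true_si) == c(n_strains, n_strains)))
    stop_field("true_si", "must be an n_strains x n_strains matrix")
  if (any(true_si < -1)) stop_field("true_si", "entries must be >= -1")
  if (length(baseline_counts) != n_strains || any(baseline_counts <= 0))
    stop_field("baseline_counts", "must be n_strains positive values")
  dimnames(true_si) <- list(strains, strains)
  names(baseline_counts) <- strains

  structure(
    list(n_strains = n_strains, true_si = true_si,
         baseline_counts = baseline_counts, n_reps = n_reps,
         noise_cv = noise_cv, strains = strains, seed = seed),
    class = "sequential_design"
  )
}

#' Simulate a sequential-growth cell-count table
#'
#' Expected count of secondary strain `s` on primary strain `p`'s spent medium
#' is `baseline_s * (1 + true_si[p, s])`; replicate counts receive
#' multiplicative lognormal noise and are truncated at zero. Baseline wells on
#' unprocessed algal spent medium are labelled with primary `"PtSM"`.
#'
#' @param design A [sequential_design()].
#' @param baseline_label Label marking baseline wells (default `"PtSM"`).
#' @return A growth table: tibble with columns `secondary`, `primary`,
#'   `replicate`, `count`.
#' @examples
#' growth <- generate_sequential(sequential_design(n_strains = 3, seed = 7))
#' si_matrix(growth)
#' @export
generate_sequential <- function(design, baseline_label = "PtSM") {
  stopifnot(inherits(design, "sequential_design"))
  d <- design
  withr_seed(d$seed, {
    primaries <- c(baseline_label, d$strains)
    grid <- tidyr::expand_grid(secondary = d$strains, primary = primaries,
                               replicate = seq_len(d$n_reps))
    mu <- purrr::map2_dbl(grid$secondary, grid$primary, function(s, p) {
      base <- d$baseline_counts[[s]]
      if (p == baseline_label) base else base * (1 + d$true_si[p, s])
    })
    grid$count <- pmax(0, mu * ln_noise(nrow(grid), d$noise_cv))
    grid
  })
}
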