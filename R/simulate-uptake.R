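#' Generate strain nutrient-requirement sets with controlled overlap
#'
#' Stand-in for minimal nutrient requirements derived from genome-scale
#' metabolic models. Each strain receives a set of `set_size` nutrient
#' identifiers: a core of `round(overlap * set_size)` nutrients shared by all
#' strains plus strain-private nutrients, so every directed pairwise metabolic
#' resource overlap equals `overlap` up to the core rounding.
#'
#' @param n_strains Number of strains.
#' @param universe_size Number of distinct nutrients available.
#' @param set_size Nutrients per strain.
#' @param overlap Target directed pairwise overlap in `[0, 1]`.
#' @param strains Optional strain labels.
#' @param seed Integer seed.
#' @return A tibble with columns `strain` and `nutrient` (one row per
#'   membership), the same long format read by [mro_matrix()].
#' @examples
#' sets <- generate_uptake_sets(4, universe_size = 60, set_size = 10, overlap = 0.5)
#' mro_matrix(sets)
#' @export
generate_uptake_sets <- function(n_strains, universe_size, set_size, overlap,
                                 strains = NULL, seed = 1) {
  n_strains <- check_count(n_strains, "n_strains")
  universe_size <- check_count(universe_size, "universe_size")
  set_size <- check_count(set_size, "set_size")
  check_fraction(overlap, "overlap")
  seed <- check_count(seed, "seed", min = 0L)
  strains <- strains %||% sprintf("strain%02d", seq_len(n_strains))

  n_core <- round(overlap * set_size)
  n_private <- set_size - n_core
  needed <- n_core + n_strains * n_private
  if (universe_size < needed)
    abort(sprintf(
      "universe_size = %d is too small: need %d nutrients for %d strains with %d shared + %d private each",
      universe_size, needed, n_strains, n_core, n_private))

  withr_seed(seed, {
    universe <- sprintf("nutrient%04d", seq_len(universe_size))
    picked <- sample(universe, needed)
    core <- head(picked, n_core)
    privates <- if (n_private > 0)
      matrix(picked[n_core + seq_len(needed - n_core)], nrow = n_private) else
      matrix(character(), nrow = 0, ncol = n_strains)
    purrr::map_dfr(seq_len(n_strains), function(i) {
      tibble(strain = strains[i], nutrient = c(core, privates[, i]))
    })
  })
}
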