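#' Linear consumer-resource simulation of a sequential spent-media assay
#'
#' Models the growth of a secondary consumer on a metabolite pool before and
#' after depletion by a primary consumer, under a linear-yield model: growth
#' on the untouched pool is `sum(yields * pool)` and the primary strain
#' removes a proportion `p_primary[m]` of each metabolite before the secondary
#' strain feeds. The sequential interaction implied by this model
#' (`g_with / g_without - 1`) can be compared with the competition coefficient
#' computed from the same consumption profiles: with a binary secondary
#' profile, yields proportional to it, and equal pools, the two are
#' algebraically identical.
#'
#' @param p_primary,p_secondary Per-metabolite consumption proportions in
#'   `[0, 1]` (the secondary profile sets which metabolites support growth).
#' @param pool Per-metabolite amounts available (>= 0).
#' @param yields Secondary-strain biomass yield per unit of each metabolite
#'   (>= 0).
#' @return A one-row tibble with `g_without`, `g_with` and the implied `si`
#'   (`NA` when `g_without` is 0).
#' @examples
#' simulate_consumer_resource(p_primary = c(1, 0), p_secondary = c(1, 1),
#'                            pool = c(1, 1), yields = c(1, 1))
#' @export
simulate_consumer_resource <- function(p_primary, p_secondary, pool, yields) {
  n <- length(p_primary)
  if (length(p_secondary) != n || length(pool) != n || length(yields) != n)
    abort("p_primary, p_secondary, pool and yields must have the same length")
  check_fraction(p_primary, "p_primary")
  check_fraction(p_secondary, "p_secondary")
  if (any(pool < 0)) stop_field("pool", "amounts must be >= 0")
  if (any(yields < 0)) stop_field("yields", "yields must be >= 0")

  g_without <- sum(yields * pool)
  g_with <- sum(yields * pool * (1 - p_primary))
  tibble(g_without = g_without, g_with = g_with,
         si = if (g_without > 0) g_with / g_without - 1 else NA_real_)
}
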