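#' Natural-abundance isotope constants
#'
#' Defaults: 13C/12C = 0.011237 and 15N/14N = 0.003676. When unlabelled
#' control cells are measured in the same run, [estimate_natural_fraction()]
#' can replace the tabulated 13C baseline.
#'
#' @param natural_ratio_13c,natural_ratio_15n Natural isotope ratios (> 0).
#' @param clamp Clamp C_net to `[0, 100]` (negative apparent enrichment is
#'   counting noise); disable for QC.
#' @return A list of class `isotope_constants`.
#' @export
isotope_constants <- function(natural_ratio_13c = 0.011237,
                              natural_ratio_15n = 0.003676,
                              clamp = TRUE) {
  if (natural_ratio_13c <= 0 || natural_ratio_15n <= 0)
    abort("natural isotope ratios must be > 0")
  structure(list(natural_ratio_13c = natural_ratio_13c,
                 natural_ratio_15n = natural_ratio_15n,
                 clamp = isTRUE(clamp)),
            class = "isotope_constants")
}

#' Carbon isotope ratio from C2- dimer ion counts
#'
#' The 12C13C- dimer carries one 13C out of two carbon atoms, so the atomic
#' ratio is half the count ratio: `13C/12C = (n(12C13C) / n(12C12C)) / 2`.
#'
#' @param c12c13,c12c12 Ion counts (vectors recycle elementwise).
#' @return The 13C/12C ratio; `NA` with a warning for ROIs with a zero
#'   major-isotope count.
#' @examples
#' carbon_ratio(2200, 100000) # 0.011
#' @export
carbon_ratio <- function(c12c13, c12c12) {
  if (any(c12c13 < 0) || any(c12c12 < 0)) abort("ion counts must be >= 0")
  bad <- c12c12 == 0
  if (any(bad)) warn(sprintf("%d ROI(s) with zero 12C12C counts flagged as NA", sum(bad)))
  ifelse(bad, NA_real_, (c12c13 / c12c12) / 2)
}

#' Nitrogen isotope ratio from CN- ion counts
#'
#' The CN- ions carry a single nitrogen atom, so the ratio is the plain count
#' ratio `15N/14N = n(12C15N) / n(12C14N)`.
#'
#' @param c12c15n,c12c14n Ion counts.
#' @return The 15N/14N ratio; `NA` with a warning where the 14N count is zero.
#' @export
nitrogen_ratio <- function(c12c15n, c12c14n) {
  if (any(c12c15n < 0) || any(c12c14n < 0)) abort("ion counts must be >= 0")
  bad <- c12c14n == 0
  if (any(bad)) warn(sprintf("%d ROI(s) with zero 12C14N counts flagged as NA", sum(bad)))
  ifelse(bad, NA_real_, c12c15n / c12c14n)
}

#' Convert an isotope ratio to an atom fraction
#'
#' `F = R / (1 + R)`, the fraction of the minor isotope among all atoms of the
#' element; strictly increasing in R and bounded in `[0, 1)`.
#'
#' @param ratio Isotope ratio(s), >= 0 (`NA` passed through).
#' @return Atom fraction(s).
#' @export
atom_fraction <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) abort("isotope ratio must be >= 0")
  ratio / (1 + ratio)
}

#' Net carbon incorporation (C_net) from atom fractions
#'
#' Percent of cell carbon derived from the labelled algal source:
#' `C_net = 100 * (F_cell - F_nat) / (F_alga - F_nat)`, where `F_alga` is the
#' 13C atom fraction of the algal end-member and `F_nat` the natural-abundance
#' baseline. Because the isotopic enrichment of the exuded metabolites is not
#' measured directly, C_net is a comparative estimate across treatments rather
#' than an absolute tracer budget.
#'
#' @param f_cell Cell 13C atom fraction(s).
#' @param f_alga Algal end-member atom fraction; must exceed the natural atom
#'   fraction.
#' @param constants An [isotope_constants()] object.
#' @return C_net in percent, clamped to `[0, 100]` when the constants say so.
#' @examples
#' c_net(0.02, 0.10, isotope_constants(natural_ratio_13c = 0.011 / (1 - 0.011)))
#' @export
c_net <- function(f_cell, f_alga, constants = isotope_constants()) {
  f_nat <- atom_fraction(constants$natural_ratio_13c)
  if (f_alga <= f_nat) abort("unlabeled source: f_alga must exceed the natural atom fraction")
  out <- 100 * (f_cell - f_nat) / (f_alga - f_nat)
  if (constants$clamp) out <- clamp(out, 0, 100)
  out
}

#' Estimate the natural 13C atom fraction from unlabelled control ROIs
#'
#' @param roi ROI table subset holding unlabelled cells.
#' @return Median 13C atom fraction of the control ROIs.
#' @export
estimate_natural_fraction <- function(roi) {
  check_cols(roi, c("c12c13", "c12c12"), "ROI table")
  median(atom_fraction(carbon_ratio(roi$c12c13, roi$c12c12)), na.rm = TRUE)
}

#' Per-cell isotope enrichment and C_net from a ROI count table
#'
#' Computes isotope ratios, atom fractions, C_net and the 15N atom-fraction
#' excess for every bacterial ROI. The algal end-member defaults to the median
#' atom fraction of the algal ROIs (`target == "alga"`) in the same table.
#'
#' @param roi ROI table with columns `roi_id`, `treatment`, ion counts
#'   `c12c12`, `c12c13`, `c12c14n`, `c12c15n`, and optionally `target`,
#'   `well`, `biovolume`.
#' @param f_alga Algal end-member 13C atom fraction; when `NULL`, estimated
#'   from the algal ROIs per run.
#' @param constants An [isotope_constants()] object.
#' @return Tibble of bacterial ROIs with added columns `ratio13c`, `f13c`,
#'   `cnet`, `ratio15n`, `f15n`, `excess15n` (atom-fraction excess over
#'   natural) and `flagged` (zero-denominator ROIs). The end-member used is in
#'   attribute `f_alga`.
#' @export
cnet_table <- function(roi, f_alga = NULL, constants = isotope_constants()) {
  check_cols(roi, c("roi_id", "treatment", "c12c12", "c12c13", "c12c14n", "c12c15n"),
             "ROI table")
  if (is.null(f_alga)) {
    if (!"target" %in% names(roi) || !any(roi$target == "alga"))
      abort("no algal ROIs to estimate f_alga from; pass f_alga explicitly")
    f_alga <- estimate_natural_fraction(dplyr::filter(roi, .data$target == "alga"))
  }
  bact <- if ("target" %in% names(roi)) dplyr::filter(roi, .data$target != "alga") else roi
  out <- bact |>
    dplyr::mutate(
      ratio13c = suppressWarnings(carbon_ratio(.data$c12c13, .data$c12c12)),
      f13c = atom_fraction(.data$ratio13c),
      cnet = c_net(.data$f13c, f_alga, constants),
      ratio15n = suppressWarnings(nitrogen_ratio(.data$c12c15n, .data$c12c14n)),
      f15n = atom_fraction(.data$ratio15n),
      excess15n = .data$f15n - atom_fraction(constants$natural_ratio_15n),
      flagged = is.na(.data$ratio13c) | is.na(.data$ratio15n)
    )
  n_flagged <- sum(out$flagged)
  if (n_flagged > 0) warn(sprintf("%d ROI(s) flagged (zero-count denominator)", n_flagged))
  attr(out, "f_alga") <- f_alga
  out
}

#' Summarise single-cell C_net by treatment with rank-based tests
#'
#' Reports median, quartiles and n per treatment, pairwise two-sided Wilcoxon
#' rank-sum tests (exact for small samples without ties, normal approximation
#' otherwise) and a global Kruskal-Wallis test (exact enumeration when the
#' pooled sample is small, chi-square approximation otherwise; the method used
#' is recorded).
#'
#' @param cnet Tibble with a `treatment` column and the value column.
#' @param value Name of the value column (default `"cnet"`).
#' @param exact_max_n Pooled-size cutoff below which the Kruskal-Wallis
#'   p-value is computed by exhaustive enumeration (default 12).
#' @return A `cnet_summary` object: list with `summary` (per-treatment
#'   tibble), `pairwise` (Wilcoxon tibble), `kruskal` (statistic, p, method)
#'   and `value`.
#' @export
summarize_treatment <- function(cnet, value = "cnet", exact_max_n = 12) {
  check_cols(cnet, c("treatment", value), "C_net table")
  x <- cnet[[value]]
  keep <- !is.na(x)
  x <- x[keep]
  g <- as.character(cnet$treatment[keep])
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 treatments")
  if (any(sizes < 3)) abort(sprintf("treatment(s) with < 3 cells: %s",
                                    paste(names(sizes)[sizes < 3], collapse = ", ")))

  summary <- tibble(treatment = names(sizes)) |>
    dplyr::mutate(n = as.integer(sizes[.data$treatment]),
                  median = purrr::map_dbl(.data$treatment, ~ median(x[g == .x])),
                  q1 = purrr::map_dbl(.data$treatment, ~ unname(quantile(x[g == .x], 0.25))),
                  q3 = purrr::map_dbl(.data$treatment, ~ unname(quantile(x[g == .x], 0.75))))

  combos <- combn(names(sizes), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    wt <- suppressWarnings(wilcox.test(x[g == a], x[g == b]))
    tibble(treatment_a = a, treatment_b = b, statistic = unname(wt$statistic),
           p_value = wt$p.value,
           method = if (grepl("continuity|normal", wt$method) ||
                        length(x[g == a]) >= 50 || anyDuplicated(c(x[g == a], x[g == b])))
             "approximate" else "exact")
  })

  if (length(x) <= exact_max_n) {
    kw <- kruskal_exact(x, g)
  } else {
    kt <- kruskal.test(x, factor(g))
    kw <- list(statistic = unname(kt$statistic), p_value = kt$p.value,
               method = "chi-square approximation")
  }

  structure(list(summary = summary, pairwise = pairwise, kruskal = kw, value = value),
            class = "cnet_summary")
}

# exact Kruskal-Wallis p-value by enumeration of all distinct assignments of
# the pooled observations to the observed group sizes
kruskal_exact <- function(x, g) {
  n <- length(x)
  sizes <- table(g)
  n_arrangements <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_arrangements > 2e5) abort("too many arrangements for exact enumeration")
  h_stat <- function(ranks_by_group) {
    r <- unlist(ranks_by_group)
    ties <- table(r)
    h <- 12 / (n * (n + 1)) *
      sum(purrr::map_dbl(ranks_by_group, ~ sum(.x)^2 / length(.x))) - 3 * (n + 1)
    correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (correction > 0) h / correction else 0
  }
  rk <- rank(x)
  obs <- h_stat(split(rk, g))
  group_sizes <- as.integer(sizes)
  k <- length(group_sizes)
  stats_all <- numeric(0)
  recurse <- function(remaining, assigned) {
    gi <- length(assigned) + 1L
    if (gi == k) {
      stats_all[length(stats_all) + 1L] <<- h_stat(c(assigned, list(remaining)))
      return(invisible())
    }
    picks <- combn(seq_along(remaining), group_sizes[gi], simplify = FALSE)
    for (idx in picks) recurse(remaining[-idx], c(assigned, list(remaining[idx])))
  }
  recurse(rk, list())
  list(statistic = obs, p_value = mean(stats_all >= obs - 1e-12),
       method = "exact enumeration")
}

#' @export
print.cnet_summary <- function(x, ...) {
  cat(sprintf("Per-treatment %s summary:\n", x$value))
  print(x$summary)
  cat(sprintf("Kruskal-Wallis: H = %.3f, p = %.4g (%s)\n",
              x$kruskal$statistic, x$kruskal$p_value, x$kruskal$method))
  invisible(x)
}

#' Percent reduction of a treatment median relative to a control median
#'
#' `100 * (1 - treatment / control)`: e.g. the drop in per-cell algal carbon
#' drawdown caused by an upstream competitor.
#'
#' @param treatment,control Median values; `control` must be > 0.
#' @return Percent reduction (negative if the treatment exceeds the control).
#' @examples
#' percent_reduction(1.69, 3.44) # ~51
#' @export
percent_reduction <- function(treatment, control) {
  if (any(control <= 0)) abort("control median must be > 0")
  100 * (1 - treatment / control)
}

#' Cell carbon mass from biovolume
#'
#' Linear conversion by default (`mass = conversion * biovolume`, 148 fg C per
#' cubic micrometre); an allometric form `mass = a * V^b` is available for
#' larger cells.
#'
#' @param biovolume Cell volume(s) in cubic micrometres (> 0).
#' @param conversion Linear factor in fg C per cubic micrometre.
#' @param allometric Use the allometric form.
#' @param a,b Allometric coefficients (fg C, dimensionless exponent).
#' @return Carbon mass in fg C.
#' @export
cell_carbon_mass <- function(biovolume, conversion = 148, allometric = FALSE,
                             a = 133, b = 0.438) {
  if (any(biovolume <= 0)) abort("biovolume must be > 0")
  if (allometric) a * biovolume^b else conversion * biovolume
}

#' Total algal carbon incorporated by the bacterial population (C_total)
#'
#' Combines per-well cell abundances, mean cell size and the median
#' single-cell C_net into a population carbon mass:
#' `C_total = sum over wells of N_cells * cell_carbon_mass(mean_biovolume) *
#' median_cnet / 100` (fg C). When the census carries a `microplate` replicate
#' column, per-microplate totals give a mean and standard deviation per
#' treatment.
#'
#' @param census Well census: tibble with columns `well`, `strain`,
#'   `treatment`, `cell_count`, `mean_biovolume` and optionally `microplate`.
#' @param cnet Per-cell C_net table (e.g. from [cnet_table()]) with columns
#'   `treatment` and `cnet`, or a precomputed tibble with `treatment` and
#'   `median_cnet`. Matched to wells by `treatment` (and `strain` if present
#'   in both).
#' @param conversion Biovolume-to-carbon factor (fg C per cubic micrometre).
#' @return A `ctotal` tibble: per treatment, `c_total` (mean over microplates,
#'   fg C), `sd` and `n_microplates`.
#' @export
c_total <- function(census, cnet, conversion = 148) {
  check_cols(census, c("well", "strain", "treatment", "cell_count", "mean_biovolume"),
             "well census")
  if (any(census$cell_count < 0)) abort("cell counts must be >= 0")
  if (any(census$mean_biovolume <= 0)) abort("biovolumes must be > 0")
  keys <- intersect(c("treatment", "strain"), names(cnet))
  med <- if ("median_cnet" %in% names(cnet)) {
    dplyr::select(cnet, dplyr::all_of(c(keys, "median_cnet")))
  } else {
    check_cols(cnet, "cnet", "C_net table")
    cnet |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(median_cnet = median(.data$cnet, na.rm = TRUE), .groups = "drop")
  }
  joined <- dplyr::left_join(census, med, by = keys)
  if (anyNA(joined$median_cnet)) {
    bad <- unique(joined$well[is.na(joined$median_cnet)])
    abort(sprintf("no C_net summary for well(s): %s", paste(bad, collapse = ", ")))
  }
  joined$well_c <- joined$cell_count *
    cell_carbon_mass(joined$mean_biovolume, conversion) * joined$median_cnet / 100
  if (!"microplate" %in% names(joined)) joined$microplate <- "plate1"
  per_plate <- joined |>
    dplyr::group_by(.data$treatment, .data$microplate) |>
    dplyr::summarise(c_total = sum(.data$well_c), .groups = "drop")
  out <- per_plate |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(sd = if (dplyr::n() > 1) sd(.data$c_total) else NA_real_,
                     c_total = mean(.data$c_total),
                     n_microplates = dplyr::n(), .groups = "drop") |>
    dplyr::select("treatment", "c_total", "sd", "n_microplates")
  structure(out, class = c("ctotal", class(out)), per_plate = per_plate)
}

#' Ratio of total carbon incorporation between two treatments
#'
#' @param ct A `ctotal` result.
#' @param numerator,denominator Treatment labels.
#' @return One-row tibble with the ratio and a delta-method standard
#'   deviation propagated from the per-microplate replicate spread.
#' @export
ctotal_ratio <- function(ct, numerator, denominator) {
  stopifnot(inherits(ct, "ctotal"))
  num <- dplyr::filter(ct, .data$treatment == numerator)
  den <- dplyr::filter(ct, .data$treatment == denominator)
  if (nrow(num) != 1 || nrow(den) != 1) abort("treatment labels not found in C_total result")
  ratio <- num$c_total / den$c_total
  rel_sd <- sqrt((num$sd / num$c_total)^2 + (den$sd / den$c_total)^2)
  tibble(numerator = numerator, denominator = denominator,
         ratio = ratio, sd = ratio * rel_sd)
}
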