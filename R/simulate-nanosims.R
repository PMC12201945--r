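#' Design for synthetic NanoSIMS single-cell isotope measurements
#'
#' Emulates ion-count measurements of bacterial cells grown with a
#' 13C-labelled alga. Each cell is assigned a true net carbon incorporation
#' (C_net, percent of cell carbon derived from the alga), converted to an
#' expected 13C atom fraction `F = F_nat + (C_net/100) * (F_alga - F_nat)`,
#' and ion counts are drawn from Poisson distributions consistent with the
#' CN- / C2- detection chemistry (the 12C13C- dimer carries twice the isotope
#' ratio). A parallel 15N channel models labelled-leucine uptake.
#'
#' @param n_cells_per_treatment Cells measured per treatment.
#' @param treatments Character vector of treatment labels.
#' @param true_cnet_median Median true C_net (percent) per treatment; recycled.
#' @param true_cnet_spread Interquartile range (percentage points) of the
#'   per-cell true C_net distribution (normal, truncated at 0 and 100).
#' @param algal_atom_fraction 13C atom fraction of the algal carbon source;
#'   must exceed the natural atom fraction.
#' @param natural_ratio_13c,natural_ratio_15n Natural isotope ratios.
#' @param label_atom_fraction_15n 15N atom fraction of the nitrogen label
#'   available to fully labelled cells.
#' @param mean_total_counts Expected major-isotope (12C12C-) ion counts per
#'   region of interest.
#' @param mean_biovolume Mean cell biovolume in cubic micrometres.
#' @param n_algal_rois Algal cells measured per treatment (used to estimate
#'   the algal end-member atom fraction from the same run).
#' @param seed Integer seed.
#' @return An object of class `nanosims_design`.
#' @seealso [generate_nanosims()], [cnet_table()]
#' @export
nanosims_design <- function(n_cells_per_treatment = 300,
                            treatments = "treatment",
                            true_cnet_median = 2.71, true_cnet_spread = 1.0,
                            algal_atom_fraction = 0.10,
                            natural_ratio_13c = 0.011237,
                            natural_ratio_15n = 0.003676,
                            label_atom_fraction_15n = 0.05,
                            mean_total_counts = 1e6,
                            mean_biovolume = 0.3,
                            n_algal_rois = 25, seed = 1) {
  n_cells_per_treatment <- check_count(n_cells_per_treatment, "n_cells_per_treatment")
  n_algal_rois <- check_count(n_algal_rois, "n_algal_rois", min = 0L)
  seed <- check_count(seed, "seed", min = 0L)
  true_cnet_median <- rep_len(true_cnet_median, length(treatments))
  check_fraction(true_cnet_median, "true_cnet_median", 0, 100)
  if (true_cnet_spread < 0) stop_field("true_cnet_spread", "must be >= 0")
  f_nat <- natural_ratio_13c / (1 + natural_ratio_13c)
  if (algal_atom_fraction <= f_nat)
    stop_field("algal_atom_fraction", "must exceed the natural 13C atom fraction")
  if (mean_total_counts <= 0) stop_field("mean_total_counts", "must be > 0")
  if (mean_biovolume <= 0) stop_field("mean_biovolume", "must be > 0")

  structure(
    list(n_cells_per_treatment = n_cells_per_treatment,
         treatments = as.character(treatments),
         true_cnet_median = setNames(true_cnet_median, treatments),
         true_cnet_spread = true_cnet_spread,
         algal_atom_fraction = algal_atom_fraction,
         natural_ratio_13c = natural_ratio_13c,
         natural_ratio_15n = natural_ratio_15n,
         label_atom_fraction_15n = label_atom_fraction_15n,
         mean_total_counts = mean_total_counts,
         mean_biovolume = mean_biovolume,
         n_algal_rois = n_algal_rois, seed = seed),
    class = "nanosims_design"
  )
}

#' Simulate a NanoSIMS region-of-interest (ROI) count table
#'
#' @param design A [nanosims_design()].
#' @return A ROI table: tibble with columns `roi_id`, `treatment`, `well`
#'   (`"distal"` for bacteria, `"center"` for algal cells), `target`
#'   (`"bacteria"` or `"alga"`), ion counts `c12c12`, `c12c13`, `c12c14n`,
#'   `c12c15n`, and `biovolume`. The per-cell true C_net values are attached
#'   as the `"ground_truth"` attribute (a tibble with `roi_id`, `true_cnet`).
#' @examples
#' roi <- generate_nanosims(nanosims_design(n_cells_per_treatment = 50))
#' head(cnet_table(roi))
#' @export
generate_nanosims <- function(design) {
  stopifnot(inherits(design, "nanosims_design"))
  d <- design
  f_nat13 <- d$natural_ratio_13c / (1 + d$natural_ratio_13c)
  f_nat15 <- d$natural_ratio_15n / (1 + d$natural_ratio_15n)
  sd_cnet <- d$true_cnet_spread / (2 * stats::qnorm(0.75))

  withr_seed(d$seed, {
    rows <- purrr::map_dfr(d$treatments, function(tr) {
      n <- d$n_cells_per_treatment
      true_cnet <- clamp(rnorm(n, d$true_cnet_median[[tr]], sd_cnet), 0, 100)
      f13 <- f_nat13 + (true_cnet / 100) * (d$algal_atom_fraction - f_nat13)
      f15 <- f_nat15 + (true_cnet / 100) * (d$label_atom_fraction_15n - f_nat15)
      bact <- draw_rois(n, f13, f15, d) |>
        dplyr::mutate(roi_id = sprintf("%s_cell%04d", tr, seq_len(n)),
                      treatment = tr, well = "distal", target = "bacteria",
                      true_cnet = true_cnet, .before = 1)
      if (d$n_algal_rois > 0) {
        na <- d$n_algal_rois
        alga <- draw_rois(na, rep(d$algal_atom_fraction, na), rep(f_nat15, na), d) |>
          dplyr::mutate(roi_id = sprintf("%s_alga%04d", tr, seq_len(na)),
                        treatment = tr, well = "center", target = "alga",
                        true_cnet = NA_real_, .before = 1)
        bact <- dplyr::bind_rows(bact, alga)
      }
      bact
    })
    truth <- dplyr::select(rows, "roi_id", "true_cnet")
    rows <- dplyr::select(rows, -"true_cnet")
    attr(rows, "ground_truth") <- truth
    rows
  })
}

# Poisson ion counts for one batch of cells given atom fractions.
# The C2- dimer counting statistics: with atom fraction F, the 12C13C-/12C12C-
# count ratio is 2F/(1-F) = 2R, hence the measured ratio convention (n13/n12)/2.
draw_rois <- function(n, f13, f15, d) {
  r13 <- f13 / (1 - f13)
  r15 <- f15 / (1 - f15)
  n12 <- rpois(n, d$mean_total_counts)
  n13 <- rpois(n, 2 * r13 * d$mean_total_counts)
  n14 <- rpois(n, d$mean_total_counts / 2)
  n15 <- rpois(n, r15 * d$mean_total_counts / 2)
  tibble(c12c12 = n12, c12c13 = n13, c12c14n = n14, c12c15n = n15,
         biovolume = d$mean_biovolume * ln_noise(n, 0.2))
}
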