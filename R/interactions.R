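#' Expected competitive interaction (ECI) between two consumption profiles
#'
#' The expected effect of a primary strain on a secondary strain from their
#' metabolite-consumption proportion vectors:
#' `ECI = -sum(p_s * p_p) / sum(p_s^2)`, where `p_s` is the secondary and
#' `p_p` the primary strain's per-metabolite proportion. Identical profiles
#' give -1 (complete competition); disjoint consumed sets give 0.
#'
#' @param p_secondary,p_primary Equal-length proportion vectors over the same
#'   feature ordering, entries in `[0, 1]`.
#' @return A single coefficient in `[-1 * max, 0]`. When the secondary strain
#'   consumes nothing (`sum(p_s^2) = 0`) the coefficient is reported as 0 with
#'   attribute `valid = FALSE` ("no competition possible").
#' @examples
#' compute_eci(c(0.5, 0.25), c(0.2, 0.4)) # -0.64
#' @export
compute_eci <- function(p_secondary, p_primary) {
  if (length(p_secondary) != length(p_primary))
    abort("proportion vectors must have the same length")
  check_fraction(p_secondary, "p_secondary")
  check_fraction(p_primary, "p_primary")
  denom <- sum(p_secondary^2)
  if (denom == 0) return(structure(0, valid = FALSE))
  out <- -sum(p_secondary * p_primary) / denom
  if (out == 0) out <- 0  # avoid IEEE negative zero
  structure(out, valid = TRUE)
}

#' Metabolic resource overlap (MRO) between two nutrient-requirement sets
#'
#' Directed overlap `|M_s intersect M_p| / |M_s|`: the fraction of the
#' secondary strain's minimal nutrient requirements that the primary strain
#' can also take up. 1 means the primary strain can take up every resource the
#' secondary needs; 0 means none.
#'
#' @param m_secondary,m_primary Character vectors of nutrient identifiers
#'   (duplicates ignored); `m_secondary` must be non-empty.
#' @return A coefficient in `[0, 1]`.
#' @examples
#' compute_mro(c("A", "B", "C", "D"), c("A", "B")) # 0.5
#' @export
compute_mro <- function(m_secondary, m_primary) {
  m_secondary <- unique(m_secondary)
  m_primary <- unique(m_primary)
  if (length(m_secondary) == 0) abort("secondary nutrient set is empty")
  length(intersect(m_secondary, m_primary)) / length(m_secondary)
}

#' Sequential interaction (SI) from a growth table
#'
#' Relative change of secondary-strain growth on a primary strain's spent
#' medium versus unprocessed algal spent medium:
#' `SI = -(G_baseline - G_primary) / G_baseline = G_primary / G_baseline - 1`.
#' -1 means no growth, 0 the same growth, +1 twice the growth. Replicates are
#' aggregated as a ratio of means by default (mean of per-replicate ratios
#' available via `aggregate`).
#'
#' @param growth Growth table: tibble with columns `secondary`, `primary`,
#'   `replicate`, `count`; rows with `primary == baseline_label` are the
#'   plain-spent-medium baseline.
#' @param secondary,primary Strain names selecting the ordered pair.
#' @param baseline_label Primary label marking baseline wells.
#' @param aggregate `"ratio-of-means"` (default) or `"mean-of-ratios"`
#'   (pairs replicates by order).
#' @return The SI coefficient (>= -1 for non-negative counts).
#' @examples
#' growth <- tibble::tibble(
#'   secondary = "s", primary = rep(c("PtSM", "p"), each = 3),
#'   replicate = rep(1:3, 2), count = c(1200, 1180, 1220, 310, 290, 300))
#' compute_si(growth, "s", "p")
#' @export
compute_si <- function(growth, secondary, primary, baseline_label = "PtSM",
                       aggregate = c("ratio-of-means", "mean-of-ratios")) {
  aggregate <- match.arg(aggregate)
  check_cols(growth, c("secondary", "primary", "count"), "growth table")
  if (any(growth$count < 0)) abort("cell counts must be >= 0")
  base <- growth$count[growth$secondary == secondary & growth$primary == baseline_label]
  trt <- growth$count[growth$secondary == secondary & growth$primary == primary]
  if (length(base) == 0 || length(trt) == 0)
    abort(sprintf("no counts for secondary '%s' on primary '%s' and/or baseline", secondary, primary))
  if (mean(base) == 0) abort("baseline mean count is 0; SI undefined")
  if (aggregate == "ratio-of-means") {
    mean(trt) / mean(base) - 1
  } else {
    if (length(trt) != length(base))
      abort("mean-of-ratios needs equal replicate counts for baseline and treatment")
    mean(trt / base) - 1
  }
}

#' Classify a sequential interaction as competitive, neutral or facilitative
#'
#' Sign-based classification with an optional neutral band around zero
#' (default 0, i.e. strict sign).
#'
#' @param si Numeric vector of SI coefficients (finite).
#' @param neutral_band Half-width of the band classified as neutral.
#' @return Factor with levels competitive, neutral, facilitative.
#' @export
classify_interaction <- function(si, neutral_band = 0) {
  if (any(!is.finite(si))) abort("SI values must be finite")
  factor(dplyr::case_when(si < -neutral_band ~ "competitive",
                          si > neutral_band ~ "facilitative",
                          TRUE ~ "neutral"),
         levels = c("competitive", "neutral", "facilitative"))
}

#' Assess whether an absorbance time series indicates growth on a substrate
#'
#' Sole-carbon-source growth call from plate-reader optical density: the
#' series is lightly smoothed (centred running mean) and growth is called when
#' the rise from the initial reading exceeds both an absolute threshold and a
#' multiple of the blank well's rise.
#'
#' @param time Strictly increasing time vector (>= 3 points).
#' @param od,blank_od Absorbance series for the culture and blank wells on the
#'   same time grid.
#' @param min_delta Minimum absolute OD rise (default 0.05).
#' @param blank_factor Required multiple of the blank's rise (default 2).
#' @param window Running-mean window (odd, default 3).
#' @return `TRUE` if growth is called.
#' @export
growth_call <- function(time, od, blank_od, min_delta = 0.05,
                        blank_factor = 2, window = 3) {
  if (length(time) < 3) abort("need at least 3 timepoints")
  if (is.unsorted(time, strictly = TRUE)) abort("time vector must be strictly increasing")
  if (length(od) != length(time) || length(blank_od) != length(time))
    abort("od and blank_od must match the time grid")
  smooth <- function(x) {
    if (length(x) < window) return(x)
    sm <- stats::filter(x, rep(1 / window, window), sides = 2)
    ifelse(is.na(sm), x, as.numeric(sm))
  }
  delta <- max(smooth(od)) - od[1]
  blank_delta <- max(0, max(smooth(blank_od)) - blank_od[1])
  delta > min_delta && delta > blank_factor * blank_delta
}
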