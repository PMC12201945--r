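# deterministic long feature table from per-group replicate vectors:
# groups = named list of list(feature_id = replicate intensities)
make_feature_table <- function(groups) {
  purrr::imap_dfr(groups, function(features, group) {
    purrr::imap_dfr(features, function(values, feature_id) {
      tibble::tibble(
        feature_id = feature_id,
        sample_id = sprintf("%s_r%02d", gsub(":", "_", group), seq_along(values)),
        group = group,
        intensity = values
      )
    })
  })
}

# growth table for one secondary strain from replicate count vectors
make_growth_table <- function(secondary, baseline, ..., baseline_label = "PtSM") {
  primaries <- list(...)
  purrr::imap_dfr(c(setNames(list(baseline), baseline_label), primaries),
                  function(counts, primary) {
                    tibble::tibble(secondary = secondary, primary = primary,
                                   replicate = seq_along(counts), count = counts)
                  })
}

# small labelled symmetric distance matrix from its upper-triangle entries
make_dist <- function(labels, upper) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- upper
  m + t(m)
}

interaction_from_values <- function(values, metric = "TEST") {
  # values: secondary x primary matrix
  strains <- rownames(values)
  tbl <- tidyr::expand_grid(primary = colnames(values), secondary = strains)
  tbl$value <- purrr::map2_dbl(tbl$primary, tbl$secondary, ~ values[.y, .x])
  tbl$valid <- TRUE
  phycoflow:::new_interaction_matrix(tbl, metric, strains)
}
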