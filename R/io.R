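#' Read a feature-intensity table from TSV/CSV
#'
#' Accepts either the long schema (`feature_id, sample_id, group, intensity`)
#' or a wide intensity matrix (features in rows, first column `feature_id`)
#' plus a sample sheet (`sample_id, group`).
#'
#' @param path Path to the long table or the wide matrix.
#' @param sample_sheet Optional path to the sample sheet for a wide matrix.
#' @return A validated long feature table tibble.
#' @export
read_feature_table <- function(path, sample_sheet = NULL) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (is.null(sample_sheet)) {
    validate_feature_table(raw)
    return(as_tibble(raw))
  }
  sheet <- readr::read_delim(sample_sheet, delim = delim, show_col_types = FALSE)
  check_cols(sheet, c("sample_id", "group"), "sample sheet")
  long <- raw |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "intensity") |>
    dplyr::inner_join(sheet, by = "sample_id") |>
    dplyr::select("feature_id", "sample_id", "group", "intensity")
  validate_feature_table(long)
  long
}

#' Read strain nutrient-requirement sets
#'
#' TSV with columns `strain, nutrient`, or JSON mapping strain names to
#' nutrient arrays.
#'
#' @param path Path to the TSV or JSON file.
#' @return Long tibble (`strain`, `nutrient`).
#' @export
read_uptake_sets <- function(path) {
  if (grepl("\\.json$", path)) {
    sets <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(purrr::imap_dfr(sets, ~ tibble(strain = .y, nutrient = as.character(.x))))
  }
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(out, c("strain", "nutrient"), "uptake sets")
  out
}

#' Read a sequential-growth count table
#'
#' @param path TSV with columns `secondary, primary, replicate, count`;
#'   `primary == "PtSM"` marks baseline wells on plain algal spent medium.
#' @return A growth table tibble.
#' @export
read_growth_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(out, c("secondary", "primary", "replicate", "count"), "growth table")
  out
}

#' Read a NanoSIMS ROI count table
#'
#' @param path TSV with columns `roi_id, treatment, well, c12c12, c12c13,
#'   c12c14n, c12c15n` and optionally `target`, `biovolume`.
#' @return A ROI table tibble.
#' @export
read_roi_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(out, c("roi_id", "treatment", "well", "c12c12", "c12c13",
                    "c12c14n", "c12c15n"), "ROI table")
  out
}

#' Write an interaction matrix as a labelled square TSV
#'
#' Secondary strains in rows, primary strains in columns; the metric name is
#' recorded in a leading comment line.
#'
#' @param x An `interaction_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(x, path) {
  m <- as_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(x, "metric")), con)
  writeLines(paste(c("secondary", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 15)), collapse = "\t"), con)
  invisible(path)
}

#' Read an interaction matrix written by [write_interaction_matrix()]
#'
#' @param path Path to the TSV.
#' @return An `interaction_matrix` in long form.
#' @export
read_interaction_matrix <- function(path) {
  first <- readLines(path, n = 1)
  metric <- if (startsWith(first, "# metric:")) trimws(sub("# metric:", "", first)) else "unknown"
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-"secondary", names_to = "primary", values_to = "value") |>
    dplyr::mutate(valid = TRUE) |>
    dplyr::select("primary", "secondary", "value", "valid")
  new_interaction_matrix(long, metric, sort(unique(long$secondary)))
}
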