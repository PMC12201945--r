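#' Distance between isolates' consumption/production profiles
#'
#' Builds per-isolate signed log2-fold-change vectors with non-significant
#' entries set to zero (so only called consumption/production contributes) and
#' returns pairwise Euclidean distances. Non-finite fold changes (zero control
#' mean) are replaced by the largest finite magnitude observed, keeping the
#' distance defined.
#'
#' @param profiles Consumption profiles for >= 2 isolates over an identical
#'   feature set.
#' @param method Distance method passed to [stats::dist()].
#' @return A labelled symmetric distance matrix (base matrix, zero diagonal).
#' @export
profile_distance <- function(profiles, method = "euclidean") {
  check_cols(profiles, c("isolate", "feature_id", "log2fc", "call"), "consumption profile")
  if (dplyr::n_distinct(profiles$isolate) < 2) abort("need at least 2 isolates")
  cap <- max(abs(profiles$log2fc[is.finite(profiles$log2fc)]), 0)
  wide <- profiles |>
    dplyr::mutate(signal = dplyr::if_else(.data$call == "unchanged", 0,
                                          clamp(.data$log2fc, -cap, cap))) |>
    dplyr::select("isolate", "feature_id", "signal") |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "signal")
  if (anyNA(wide)) abort("isolates do not share an identical feature set")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$isolate
  as.matrix(dist(m, method = method))
}

#' Hierarchical clustering of isolates from a distance matrix
#'
#' Thin wrapper over [stats::hclust()] with labels sorted beforehand so the
#' merge order is deterministic regardless of input ordering (ties are broken
#' by the lexicographic label order).
#'
#' @param d Labelled symmetric distance matrix (or `dist`).
#' @param linkage Agglomeration method (default `"average"`).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (is.null(rownames(d))) abort("distance matrix must be labelled")
    if (any(is.na(d))) abort("distance matrix contains NA")
    if (max(abs(d - t(d))) > 1e-12) abort("distance matrix is not symmetric")
    ord <- order(rownames(d))
    d <- as.dist(d[ord, ord])
  }
  hclust(d, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights, so cophenetic distances in
#' the tree match the dendrogram.
#'
#' @param hc An `hclust` object.
#' @return A single Newick-format string.
#' @export
cluster_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the upper-triangle (off-diagonal) entries of two distance
#' matrices over the same labels and assesses significance by permuting the
#' label order of the second matrix. With `permutations = "exhaustive"` all
#' `n!` label permutations (including the identity) are enumerated and the
#' p-value is the exact tail probability; otherwise `n_perm` random
#' permutations give `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`
#' (one-sided positive association by default).
#'
#' @param d1,d2 Labelled symmetric matrices with identical label sets (`d2`
#'   is aligned to `d1`'s labels).
#' @param permutations Number of random permutations (>= 99) or
#'   `"exhaustive"`.
#' @param method Correlation for the statistic: `"pearson"` (default) or
#'   `"spearman"`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed Optional integer seed for the random permutations.
#' @return A `mantel_perm` object: list with `r`, `p_value`, `n_perm`,
#'   `method`, `alternative` and `exhaustive`.
#' @export
mantel_test <- function(d1, d2, permutations = 999,
                        method = c("pearson", "spearman"),
                        alternative = c("greater", "two.sided"),
                        seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  labs <- rownames(d1)
  if (is.null(labs) || is.null(rownames(d2))) abort("distance matrices must be labelled")
  if (!setequal(labs, rownames(d2))) abort("distance matrices have different labels")
  d2 <- d2[labs, labs]
  n <- length(labs)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (sd(v1) == 0 || sd(d2[ut]) == 0) abort("constant distance matrix; correlation undefined")
  stat <- function(perm) {
    v2 <- d2[perm, perm][ut]
    cor(v1, v2, method = method)
  }
  r_obs <- stat(seq_len(n))

  score <- function(r_perm) {
    if (alternative == "greater") r_perm >= r_obs - 1e-12
    else abs(r_perm) >= abs(r_obs) - 1e-12
  }

  if (identical(permutations, "exhaustive")) {
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, stat)
    p <- mean(score(r_all))
    n_perm <- nrow(perms)
    exhaustive <- TRUE
  } else {
    n_perm <- check_count(permutations, "permutations", min = 99L)
    draw <- function() stat(sample.int(n))
    r_perm <- if (is.null(seed)) replicate(n_perm, draw())
              else withr_seed(seed, replicate(n_perm, draw()))
    p <- (1 + sum(score(r_perm))) / (1 + n_perm)
    exhaustive <- FALSE
  }
  structure(list(r = r_obs, p_value = p, n_perm = n_perm, method = method,
                 alternative = alternative, exhaustive = exhaustive),
            class = "mantel_perm")
}

#' @export
print.mantel_perm <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.3f, p = %.4g (%s permutations%s)\n",
              x$method, x$alternative, x$r, x$p_value, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}
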