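make_profiles <- function(mat, calls = NULL) {
  # mat: isolate x feature log2fc matrix; calls defaults to consumed/produced by sign
  purrr::imap_dfr(asplit(mat, 1), function(row, iso) {
    tibble::tibble(isolate = iso, feature_id = colnames(mat), log2fc = as.numeric(row),
                   call = factor(ifelse(row == 0, "unchanged",
                                        ifelse(row < 0, "consumed", "produced")),
                                 levels = c("consumed", "produced", "unchanged")))
  })
}

test_that("profile distances reflect fold-change differences", {
  m <- rbind(A = c(f1 = -2, f2 = 0), B = c(f1 = -2, f2 = 0), C = c(f1 = 0, f2 = 0))
  d <- profile_distance(make_profiles(m))
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 2)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
})

test_that("distances are invariant to feature order", {
  set.seed(12)
  m <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(LETTERS[1:4], sprintf("f%d", 1:6)))
  prof <- make_profiles(m)
  shuffled <- dplyr::arrange(prof, dplyr::desc(feature_id), isolate)
  expect_equal(profile_distance(prof), profile_distance(shuffled))
})

test_that("non-significant entries do not contribute to distance", {
  prof <- tibble::tibble(
    isolate = rep(c("A", "B"), each = 2),
    feature_id = rep(c("f1", "f2"), 2),
    log2fc = c(-2, 5, -2, -5),
    call = factor(c("consumed", "unchanged", "consumed", "unchanged"),
                  levels = c("consumed", "produced", "unchanged")))
  d <- profile_distance(prof)
  expect_equal(d["A", "B"], 0)
})

test_that("clustering merges the closest pair first, deterministically", {
  d2 <- make_dist(c("A", "B"), 3)
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$height, 3)

  d3 <- make_dist(c("A", "B", "C"), c(1, 10, 10))  # AB close, C far
  hc3 <- hierarchical_cluster(d3)
  first_pair <- sort(hc3$labels[-hc3$merge[1, ]])
  expect_equal(first_pair, c("A", "B"))
  expect_equal(hc3$height, c(1, 10))

  # label-order invariance
  perm <- c("C", "A", "B")
  hc3b <- hierarchical_cluster(make_dist(c("A", "B", "C"), c(1, 10, 10))[perm, perm])
  expect_equal(hc3$height, hc3b$height)
})

test_that("average-linkage heights match a brute-force agglomeration oracle", {
  set.seed(9)
  n <- 5
  pts <- matrix(rnorm(n * 3), n, dimnames = list(letters[1:n], NULL))
  dm <- as.matrix(dist(pts))
  hc <- hierarchical_cluster(dm, linkage = "average")

  # naive UPGMA: repeatedly merge the closest clusters, averaging over all
  # inter-cluster point pairs
  clusters <- as.list(rownames(dm))
  heights <- c()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- mean(dm[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(sort(hc$height), sort(heights))
})

test_that("dendrograms export to Newick with the right tips", {
  d <- make_dist(c("A", "B", "C"), c(1, 10, 10))
  nwk <- cluster_newick(hierarchical_cluster(d))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})

test_that("a matrix tested against itself gives r = 1 at the smallest attainable p", {
  set.seed(5)
  # generic point configuration: only the identity permutation preserves the
  # distances, so the exhaustive tail contains exactly that one permutation
  d <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  res <- mantel_test(d, d, permutations = "exhaustive")
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 24)
  rand <- mantel_test(d, d, permutations = 199, seed = 1)
  expect_gte(rand$p_value, 1 / 200)
  expect_lte(rand$p_value, 0.05)
  expect_error(mantel_test(d, matrix(1, 4, 4, dimnames = dimnames(d))), "constant")
})

test_that("exhaustive Mantel p equals the enumerated permutation tail", {
  set.seed(8)
  d1 <- as.matrix(dist(matrix(rnorm(8), 4)))
  d2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  labs <- c("w", "x", "y", "z")
  dimnames(d1) <- dimnames(d2) <- list(labs, labs)
  res <- mantel_test(d1, d2, permutations = "exhaustive")
  expect_equal(res$n_perm, 24)

  # independent enumeration over all 24 label orders, written from scratch
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut])
  r_all <- apply(perms, 1, function(pr) {
    p2 <- d2[unlist(pr), unlist(pr)]
    cor(d1[ut], p2[ut])
  })
  expect_equal(res$p_value, mean(r_all >= r_obs - 1e-12))
  expect_equal(res$r, r_obs)
})

test_that("the observed Mantel statistic agrees with vegan and the null p is calibrated", {
  skip_if_not_installed("vegan")
  set.seed(30)
  d1 <- as.matrix(dist(matrix(rnorm(14), 7)))
  d2 <- as.matrix(dist(matrix(rnorm(14), 7)))
  dimnames(d1) <- dimnames(d2) <- list(letters[1:7], letters[1:7])
  ours <- mantel_test(d1, d2, permutations = 99, seed = 2)
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)

  # under the null (independent matrices) the permutation p is ~ uniform
  ps <- purrr::map_dbl(1:120, function(s) {
    set.seed(5000 + s)
    a <- as.matrix(dist(matrix(rnorm(12), 6)))
    b <- as.matrix(dist(matrix(rnorm(12), 6)))
    dimnames(a) <- dimnames(b) <- list(letters[1:6], letters[1:6])
    mantel_test(a, b, permutations = 99, seed = s)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
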