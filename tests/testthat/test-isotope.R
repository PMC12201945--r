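test_that("isotope ratios follow the dimer and CN count conventions", {
  expect_equal(carbon_ratio(0, 100000), 0)
  expect_equal(carbon_ratio(2200, 100000), 0.011)
  expect_equal(carbon_ratio(4400, 200000), 0.011)  # scale invariance
  expect_warning(r <- carbon_ratio(10, 0), "zero")
  expect_true(is.na(r))

  expect_equal(nitrogen_ratio(0, 50000), 0)
  expect_equal(nitrogen_ratio(368, 100000), 0.00368)
  expect_equal(nitrogen_ratio(736, 200000), 0.00368)
  expect_error(carbon_ratio(-1, 10), ">= 0")
})

test_that("atom fractions are the standard monotone transform of ratios", {
  expect_equal(atom_fraction(0), 0)
  expect_equal(atom_fraction(1), 0.5)
  expect_equal(atom_fraction(0.011237), 0.011237 / 1.011237)
  expect_error(atom_fraction(-0.1), ">= 0")
  r <- seq(0, 2, by = 0.1)
  expect_true(all(diff(atom_fraction(r)) > 0))
})

test_that("C_net anchors and arithmetic check out", {
  const <- isotope_constants(natural_ratio_13c = 0.011 / (1 - 0.011))
  f_nat <- atom_fraction(const$natural_ratio_13c)
  expect_equal(c_net(f_nat, 0.10, const), 0)
  expect_equal(c_net(0.10, 0.10, const), 100)
  expect_equal(c_net(0.02, 0.10, const), 100 * (0.02 - 0.011) / (0.10 - 0.011))
  expect_error(c_net(0.02, 0.005, const), "unlabeled")
})

test_that("C_net clamping and monotonicity behave as documented", {
  const_clamp <- isotope_constants()
  const_raw <- isotope_constants(clamp = FALSE)
  f_nat <- atom_fraction(const_clamp$natural_ratio_13c)
  expect_equal(c_net(f_nat * 0.5, 0.10, const_clamp), 0)
  expect_lt(c_net(f_nat * 0.5, 0.10, const_raw), 0)
  f <- seq(f_nat, 0.09, length.out = 20)
  expect_true(all(diff(c_net(f, 0.10, const_raw)) > 0))
})

test_that("cnet_table is invariant to proportional count rescaling and uses algal ROIs", {
  d <- nanosims_design(n_cells_per_treatment = 40, seed = 17)
  roi <- generate_nanosims(d)
  cn1 <- cnet_table(roi)
  scaled <- dplyr::mutate(roi, dplyr::across(c(c12c12, c12c13, c12c14n, c12c15n), ~ .x * 3))
  cn2 <- cnet_table(scaled)
  expect_equal(cn1$cnet, cn2$cnet)
  expect_equal(attr(cn1, "f_alga"), attr(cn2, "f_alga"))
  # without algal ROIs an explicit end-member is required
  bact_only <- dplyr::filter(roi, target == "bacteria")
  expect_error(cnet_table(bact_only), "f_alga")
  expect_silent(cnet_table(bact_only, f_alga = 0.1))
})

test_that("treatment summaries report exact small-sample rank tests", {
  cn <- tibble::tibble(treatment = rep(c("a", "b"), each = 3),
                       cnet = c(1, 2, 3, 101, 102, 103))
  out <- summarize_treatment(cn)
  expect_equal(out$pairwise$p_value, 0.1)  # 2 / choose(6, 3), two-sided exact
  expect_equal(out$pairwise$method, "exact")
  expect_equal(out$summary$median, c(2, 102))  # brute-force sort-and-pick
  expect_equal(out$kruskal$method, "exact enumeration")

  same <- tibble::tibble(treatment = rep(c("a", "b"), each = 4), cnet = rep(1, 8))
  res <- summarize_treatment(same)
  expect_equal(res$kruskal$p_value, 1)
})

test_that("exact Kruskal-Wallis matches an independent enumeration for n <= 6 per group", {
  x <- c(2.3, 1.1, 5.6, 4.4, 3.3, 7.1, 6.5, 0.2, 8.8)
  g <- rep(c("a", "b", "c"), each = 3)
  impl <- phycoflow:::kruskal_exact(x, g)

  # independent oracle: enumerate all 9!/(3!3!3!) assignments via nested combn
  rk <- rank(x)
  h_of <- function(groups) {
    n <- 9
    12 / (n * (n + 1)) * sum(vapply(groups, function(r) sum(r)^2 / 3, 0)) - 3 * (n + 1)
  }
  obs <- h_of(split(rk, g))
  hs <- c()
  idx <- seq_len(9)
  for (a in combn(9, 3, simplify = FALSE)) {
    rest <- setdiff(idx, a)
    for (b in combn(rest, 3, simplify = FALSE)) {
      hs <- c(hs, h_of(list(rk[a], rk[b], rk[setdiff(rest, b)])))
    }
  }
  expect_equal(length(hs), 1680)
  expect_equal(impl$p_value, mean(hs >= obs - 1e-12))
  # and the observed statistic agrees with the stock implementation
  expect_equal(impl$statistic, unname(kruskal.test(x, factor(g))$statistic))
})

test_that("Wilcoxon agreement with exhaustive rank enumeration for tiny samples", {
  x <- c(1.2, 3.4, 2.2); y <- c(5.5, 4.1, 6.6)
  wt <- wilcox.test(x, y)
  # enumerate all choose(6,3) assignments of ranks to group 1
  rk <- rank(c(x, y))
  w_obs <- sum(rk[1:3]) - 3 * 4 / 2
  ws <- vapply(combn(6, 3, simplify = FALSE),
               function(i) sum(rk[i]) - 6, numeric(1))
  p_enum <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5) - 1e-12)
  expect_equal(wt$p.value, p_enum)
})

test_that("percent reduction matches its closed form", {
  expect_equal(percent_reduction(5, 5), 0)
  expect_equal(percent_reduction(0, 3.2), 100)
  expect_error(percent_reduction(1, 0), "> 0")
})

test_that("cell carbon mass is linear in biovolume by default", {
  expect_equal(cell_carbon_mass(1), 148)
  expect_equal(cell_carbon_mass(0.5), 74)
  expect_equal(cell_carbon_mass(2), 2 * cell_carbon_mass(1))
  expect_equal(cell_carbon_mass(2, allometric = TRUE, a = 100, b = 0.5), 100 * sqrt(2))
  expect_error(cell_carbon_mass(0), "> 0")
})

test_that("C_total combines abundance, cell mass and C_net linearly", {
  census <- tibble::tibble(well = c("w1", "w2"), strain = "sec",
                           treatment = c("t", "t"),
                           cell_count = c(1e6, 0), mean_biovolume = 0.5)
  cn <- tibble::tibble(treatment = "t", median_cnet = 10)
  ct <- c_total(census, cn)
  expect_equal(ct$c_total, 1e6 * 74 * 0.10)  # 7.4e6 fg C

  doubled <- dplyr::mutate(census, cell_count = cell_count * 2)
  expect_equal(c_total(doubled, cn)$c_total, 2 * ct$c_total)

  zero <- dplyr::mutate(census, cell_count = 0)
  expect_equal(c_total(zero, cn)$c_total, 0)

  expect_error(c_total(census, tibble::tibble(treatment = "other", median_cnet = 5)),
               "w1")
})

test_that("treatment C_total ratios propagate replicate spread", {
  census <- tidyr::expand_grid(microplate = c("m1", "m2", "m3"),
                               treatment = c("fac", "comp")) |>
    dplyr::mutate(well = paste0(treatment, microplate), strain = "sec",
                  cell_count = c(1e6, 2e5, 1.1e6, 1.9e5, 0.9e6, 2.1e5),
                  mean_biovolume = 0.5)
  cn <- tibble::tibble(treatment = c("fac", "comp"), median_cnet = c(10, 5))
  ct <- c_total(census, cn)
  expect_equal(nrow(ct), 2)
  rat <- ctotal_ratio(ct, "fac", "comp")
  fac <- ct$c_total[ct$treatment == "fac"]
  comp <- ct$c_total[ct$treatment == "comp"]
  expect_equal(rat$ratio, fac / comp)
  expect_true(rat$sd > 0)
})
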