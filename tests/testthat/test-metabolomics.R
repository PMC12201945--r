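test_that("background filtering keeps clear signals and drops blank-level features", {
  blank12 <- function(mu, sd) mu + sd * scale(seq_len(12))[, 1]
  grp5 <- function(mu, sd) mu + sd * scale(seq_len(5))[, 1]
  tbl <- make_feature_table(list(
    blank = list(f_signal = blank12(100, 10), f_flat = blank12(100, 10)),
    control = list(f_signal = grp5(10000, 500), f_flat = grp5(100, 10)),
    "isolate:A" = list(f_signal = grp5(8000, 500), f_flat = grp5(100, 10))
  ))
  out <- filter_above_background(tbl)
  expect_setequal(unique(out$feature_id), "f_signal")
  expect_equal(attr(out, "n_retained"), 1L)
  expect_equal(attr(out, "n_tests"), 4L)  # 2 features x 2 non-blank groups

  # pooled t-statistic computed by hand for the retained contrast
  x <- grp5(10000, 500); y <- blank12(100, 10)
  sp2 <- ((5 - 1) * var(x) + (12 - 1) * var(y)) / (5 + 12 - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 12))
  p_hand <- 2 * pt(-abs(t_hand), df = 15)
  expect_equal(t.test(x, y, var.equal = TRUE)$p.value, p_hand)
  expect_lt(min(1, p_hand * 4), 0.05)
})

test_that("filtering validates its inputs", {
  tbl <- make_feature_table(list(control = list(f = c(1, 2, 3))))
  expect_error(filter_above_background(tbl), "blank")
  bad <- make_feature_table(list(blank = list(f = c(1, 2)),
                                 "isolate:A" = list(f = 5)))
  expect_error(filter_above_background(bad), "isolate:A")
})

test_that("filtering is monotone in alpha", {
  sim <- generate_metabolome(metabolome_design(n_features = 30, n_isolates = 3,
                                               n_background = 10, seed = 8))
  kept <- function(alpha) unique(filter_above_background(sim$table, alpha = alpha)$feature_id)
  a1 <- kept(0.001); a2 <- kept(0.05); a3 <- kept(0.5)
  expect_true(all(a1 %in% a2))
  expect_true(all(a2 %in% a3))
})

test_that("change calling labels consumption and production with hand-checked log2fc", {
  ctrl <- c(990, 1000, 1010, 995, 1005, 1000)
  tbl <- make_feature_table(list(
    control = list(f_same = ctrl, f_down = ctrl, f_up = ctrl),
    "isolate:A" = list(f_same = ctrl[1:5],
                       f_down = c(248, 252, 250, 249, 251),
                       f_up = c(3990, 4010, 4000, 3995, 4005))
  ))
  prof <- classify_changes(tbl)
  prof <- split(prof, prof$feature_id)
  expect_equal(as.character(prof$f_same$call), "unchanged")
  expect_equal(prof$f_same$log2fc, 0, tolerance = 1e-2)
  expect_equal(as.character(prof$f_down$call), "consumed")
  expect_equal(prof$f_down$log2fc, -2, tolerance = 1e-2)
  expect_equal(as.character(prof$f_up$call), "produced")
  expect_equal(attr(classify_changes(tbl), "n_tests"), 3L)
})

test_that("zero-mean edge cases are flagged or neutral", {
  tbl <- make_feature_table(list(
    control = list(f_inf = c(0, 0, 0), f_zero = c(0, 0, 0)),
    "isolate:A" = list(f_inf = c(10, 11, 12), f_zero = c(0, 0, 0))
  ))
  prof <- classify_changes(tbl)
  finf <- prof[prof$feature_id == "f_inf", ]
  expect_true(is.infinite(finf$log2fc) && finf$log2fc > 0)
  expect_true(finf$flagged)
  fzero <- prof[prof$feature_id == "f_zero", ]
  expect_equal(fzero$log2fc, 0)
  expect_equal(as.character(fzero$call), "unchanged")
})

test_that("Bonferroni adjustment multiplies by the logged family size, capped at 1", {
  sim <- generate_metabolome(metabolome_design(n_features = 12, n_isolates = 2, seed = 4))
  prof <- classify_changes(sim$table)
  n <- attr(prof, "n_tests")
  expect_equal(n, 24L)
  expect_equal(prof$p_adj, pmin(1, prof$p_value * n))
})

test_that("consumption proportions follow the one-minus-ratio convention", {
  prof <- tibble::tibble(
    isolate = "A", feature_id = c("a", "b", "c", "d", "e"),
    mean_control = c(1000, 1000, 1000, 0, 1000),
    mean_isolate = c(1000, 0, 250, 5, 4000),
    log2fc = c(0, -Inf, -2, Inf, 2),
    p_value = 1e-8, p_adj = 1e-6,
    call = factor(c("unchanged", "consumed", "consumed", "produced", "produced"),
                  levels = c("consumed", "produced", "unchanged")),
    proportion = NA_real_, flagged = FALSE
  )
  out <- estimate_proportions(prof)
  expect_equal(out$proportion, c(0, 1, 0.75, 0, 0))
  expect_true(out$flagged[4] || out$proportion[4] == 0)
  raw <- estimate_proportions(prof, only_consumed = FALSE)
  expect_equal(raw$proportion[5], 0)  # production clamps to 0 under 1 - ratio
  ratio <- estimate_proportions(prof, convention = "ratio", only_consumed = FALSE)
  expect_equal(ratio$proportion[3], 0.25)
})

test_that("proportions are invariant to a global intensity rescaling", {
  sim <- generate_metabolome(metabolome_design(n_features = 15, n_isolates = 2, seed = 5))
  p1 <- estimate_proportions(classify_changes(sim$table))
  scaled <- dplyr::mutate(sim$table, intensity = intensity * 37.5)
  p2 <- estimate_proportions(classify_changes(scaled))
  expect_equal(p1$proportion, p2$proportion, tolerance = 1e-12)
})

test_that("shared depletion returns exactly the engineered universal features", {
  set.seed(6)
  isolates <- sprintf("iso%02d", 1:10)
  features <- sprintf("f%02d", 1:20)
  shared <- features[1:4]  # all isolates deplete these by > half
  prof <- tidyr::expand_grid(isolate = isolates, feature_id = features) |>
    dplyr::mutate(
      log2fc = dplyr::case_when(
        feature_id %in% shared ~ runif(dplyr::n(), -3, -1.2),
        feature_id == "f05" & isolate == "iso01" ~ -0.5,  # one isolate too weak
        TRUE ~ runif(dplyr::n(), -0.9, 0.5)
      ),
      call = factor(ifelse(feature_id %in% c(shared, "f05"), "consumed", "unchanged"),
                    levels = c("consumed", "produced", "unchanged"))
    )
  prof$log2fc[prof$feature_id == "f05" & prof$isolate != "iso01"] <- -2
  out <- shared_depletion_summary(prof)
  expect_setequal(out$feature_id, shared)
})
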