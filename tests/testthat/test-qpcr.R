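qpcr_tbl <- function(ct_chip, ct_input, ct_igg = NULL, target = "site1",
                     condition = "wt") {
  rows <- dplyr::bind_rows(
    tibble::tibble(channel = "chip", ct = ct_chip),
    tibble::tibble(channel = "input", ct = ct_input),
    if (!is.null(ct_igg)) tibble::tibble(channel = "igg", ct = ct_igg))
  dplyr::mutate(rows, target = target, condition = condition)
}

test_that("percent of input halves per cycle and hits 100 at the adjusted input Ct", {
  adj <- 20 - log2(100) # 1% input, efficiency 2
  at_adj <- percent_of_input(qpcr_tbl(adj, 20), input_fraction = 0.01)
  expect_equal(at_adj$percent_input, 100)
  one_above <- percent_of_input(qpcr_tbl(adj + 1, 20), input_fraction = 0.01)
  expect_equal(one_above$percent_input, 50)
})

test_that("percent of input matches a step-by-step cycle-walk oracle", {
  # walk the fold difference cycle by cycle instead of using the closed form
  cycle_walk <- function(ct_chip, ct_input, frac, eff) {
    adj <- ct_input - log(1 / frac, base = eff)
    fold <- 1
    steps <- abs(adj - ct_chip)
    whole <- floor(steps)
    for (i in seq_len(whole)) fold <- fold * eff
    fold <- fold * eff^(steps - whole)
    if (ct_chip > adj) fold <- 1 / fold
    100 * fold
  }
  cases <- list(c(16.356, 20, 0.01, 2), c(24.2, 21.5, 0.05, 2),
                c(28.9, 22.3, 0.01, 1.9))
  for (cs in cases) {
    got <- percent_of_input(qpcr_tbl(cs[1], cs[2]), input_fraction = cs[3],
                            efficiency = cs[4])
    expect_equal(got$percent_input, cycle_walk(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
})

test_that("percent of input is invariant to a constant Ct shift", {
  base <- percent_of_input(qpcr_tbl(c(24.0, 24.4), c(20.1, 20.3), c(30, 31)),
                           input_fraction = 0.02)
  shifted <- percent_of_input(qpcr_tbl(c(27.0, 27.4), c(23.1, 23.3), c(33, 34)),
                              input_fraction = 0.02)
  expect_equal(shifted$percent_input, base$percent_input)
  # igg reported alongside, never subtracted
  expect_setequal(base$channel, c("chip", "igg"))
})

test_that("a missing input fraction or channel is an explicit error", {
  expect_error(percent_of_input(qpcr_tbl(24, 20)),
               class = "enrichdiff_config_error")
  no_input <- dplyr::filter(qpcr_tbl(24, 20), channel != "input")
  expect_error(percent_of_input(no_input, input_fraction = 0.01),
               class = "enrichdiff_data_error")
})

test_that("delta-delta-Ct gives fold 1 at the calibrator and doubles per cycle", {
  cts <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 2),
    condition = rep(c("ctrl", "treated"), each = 2),
    gene = rep(c("target", "ref"), 2),
    ct = c(25, 20, 24, 20))
  fold <- relative_expression(cts, "target", "ref", calibrator = "ctrl")
  expect_equal(fold$fold[fold$condition == "ctrl"], 1)
  expect_equal(fold$fold[fold$condition == "treated"], 2)
  missing_ref <- dplyr::filter(cts, !(gene == "ref" & sample == "s2"))
  expect_error(relative_expression(missing_ref, "target", "ref", "ctrl"),
               class = "enrichdiff_data_error")
})

test_that("random Ct tables match a per-sample recomputation", {
  cts <- withr::with_seed(3, tibble::tibble(
    sample = rep(sprintf("s%d", 1:6), each = 2),
    condition = rep(c("ctrl", "treated"), each = 6),
    gene = rep(c("goi", "ref"), 6),
    ct = runif(12, 18, 30)))
  res <- relative_expression(cts, "goi", "ref", calibrator = "ctrl")
  wide <- tidyr::pivot_wider(cts, names_from = gene, values_from = ct)
  dct <- wide$goi - wide$ref
  cal_mean <- mean(dct[wide$condition == "ctrl"])
  expect_equal(res$fold, 2^(cal_mean - dct))
  # calibrator geometric mean fold is 1 by construction
  expect_equal(exp(mean(log(res$fold[res$condition == "ctrl"]))), 1)
})

test_that("identical groups give an exact rank-test p of 1", {
  res <- compare_groups(c(3, 4, 5), c(3, 4, 5), test = "mann_whitney")
  expect_equal(res$p_value, 1)
})

test_that("the exact Mann-Whitney p equals full permutation enumeration", {
  res <- compare_groups(c(1, 2, 3), c(10, 11, 12), test = "mann_whitney")
  expect_equal(res$p_value, mw_permutation_oracle(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(res$p_value, 2 * 1 / choose(6, 3)) # most extreme split, both tails
  cases <- withr::with_seed(5, purrr::map(1:12, function(i) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    vals <- sample(1:6, nx + ny, replace = TRUE) # ties likely
    list(x = vals[seq_len(nx)], y = vals[-seq_len(nx)])
  }))
  for (cs in cases) {
    expect_equal(compare_groups(cs$x, cs$y, test = "mann_whitney")$p_value,
                 mw_permutation_oracle(cs$x, cs$y))
  }
})

test_that("the exact branch agrees with wilcox.test on tie-free data", {
  for (seed in 1:5) {
    g <- withr::with_seed(seed, list(x = rnorm(4), y = rnorm(5)))
    ours <- compare_groups(g$x, g$y, test = "mann_whitney")$p_value
    ref <- stats::wilcox.test(g$x, g$y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("bonferroni adjustment multiplies, caps at 1, and is monotone", {
  res <- compare_groups(c(1, 2, 3), c(2, 3, 4), test = "t_test", n_comparisons = 4)
  expect_equal(res$p_adjusted, min(1, res$p_value * 4))
  hi <- compare_groups(c(1, 2, 3), c(1.1, 2.1, 3.1), test = "t_test",
                       n_comparisons = 50)
  expect_equal(hi$p_adjusted, 1)
  expect_error(compare_groups(c(1, 1), c(2, 2), test = "t_test"),
               class = "enrichdiff_degenerate_input")
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  x <- withr::with_seed(8, rnorm(12)); y <- withr::with_seed(9, rnorm(12, 1))
  ours <- compare_groups(x, y, test = "mann_whitney")$p_value
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-9)
})
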