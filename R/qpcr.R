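#' ChIP-qPCR recovery as percent of input
#'
#' Standard percent-of-input quantification: the input Ct is first corrected
#' for the fraction of chromatin used as input
#' (`adjusted_input_ct = mean(ct_input) - log_E(1 / input_fraction)`, where E
#' is the amplification efficiency per cycle), then each antibody channel's
#' recovery is `100 * E^(adjusted_input_ct - mean(ct_channel))`. ChIP and IgG
#' channels are reported side by side — IgG is a displayed control, never
#' subtracted. The input fraction must be given explicitly; there is no
#' silent default.
#'
#' @param measurements A tibble with columns `target`, `condition`, `channel`
#'   (one of "chip", "igg", "input") , `ct` (one row per replicate; a
#'   `replicate` column may be present but is not required).
#' @param input_fraction Fraction of chromatin used as input (e.g. 0.01 for a
#'   1% input).
#' @param efficiency Amplification fold per cycle, in (1, 2.2] (default 2:
#'   perfect doubling).
#' @return A tibble with one row per target x condition x antibody channel:
#'   `target`, `condition`, `channel`, `mean_ct`, `percent_input`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   target = "site1", condition = "wt",
#'   channel = c("chip", "chip", "igg", "input"),
#'   ct = c(24.1, 24.3, 30.5, 26.0))
#' percent_of_input(m, input_fraction = 0.01)
percent_of_input <- function(measurements, input_fraction, efficiency = 2.0) {
  assert_columns(measurements, c("target", "condition", "channel", "ct"),
                 "qPCR measurements")
  if (missing(input_fraction) || is.null(input_fraction) || is.na(input_fraction)) {
    abort("input_fraction is required: percent of input is undefined without the input dilution",
          class = "enrichdiff_config_error")
  }
  if (input_fraction <= 0 || input_fraction > 1) {
    abort("input_fraction must lie in (0, 1]", class = "enrichdiff_config_error")
  }
  if (efficiency <= 1 || efficiency > 2.2) {
    abort("efficiency must lie in (1, 2.2]", class = "enrichdiff_config_error")
  }
  if (any(measurements$ct <= 0)) {
    abort("Ct values must be positive", class = "enrichdiff_data_error")
  }
  means <- measurements |>
    group_by(.data$target, .data$condition, .data$channel) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
  inputs <- means |>
    filter(.data$channel == "input") |>
    select("target", "condition", input_ct = "mean_ct")
  ab <- means |> filter(.data$channel %in% c("chip", "igg"))
  missing_input <- anti_join(ab, inputs, by = c("target", "condition"))
  if (nrow(missing_input)) {
    abort(sprintf("no input channel for: %s",
                  paste(unique(paste(missing_input$target,
                                     missing_input$condition)), collapse = ", ")),
          class = "enrichdiff_data_error")
  }
  ab |>
    inner_join(inputs, by = c("target", "condition")) |>
    mutate(
      adjusted_input_ct = .data$input_ct - log(1 / input_fraction, base = efficiency),
      percent_input = 100 * efficiency^(.data$adjusted_input_ct - .data$mean_ct)
    ) |>
    select("target", "condition", "channel", "mean_ct", "percent_input")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per-sample normalisation to a reference gene followed by calibration:
#' `delta_ct = ct_target - ct_reference` within each sample, and
#' `fold = efficiency^(mean(delta_ct of calibrator samples) - delta_ct)`.
#' The calibrator condition's geometric-mean fold is 1 by construction.
#'
#' @param cts A tibble with columns `sample`, `condition`, `gene`, `ct` (one
#'   row per well; replicate wells of the same sample x gene are averaged).
#' @param target Gene of interest.
#' @param reference Reference (housekeeping) gene; required, the method is
#'   undefined without one.
#' @param calibrator Condition whose mean sets fold = 1.
#' @param efficiency Amplification fold per cycle (default 2).
#' @return A tibble: `sample`, `condition`, `delta_ct`, `fold`.
#' @export
relative_expression <- function(cts, target, reference, calibrator,
                                efficiency = 2.0) {
  assert_columns(cts, c("sample", "condition", "gene", "ct"), "Ct table")
  means <- cts |>
    filter(.data$gene %in% c(target, reference)) |>
    group_by(.data$sample, .data$condition, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (!reference %in% names(means) || anyNA(means[[reference]])) {
    abort(sprintf("reference gene '%s' is missing for some sample(s)", reference),
          class = "enrichdiff_data_error")
  }
  if (!target %in% names(means) || anyNA(means[[target]])) {
    abort(sprintf("target gene '%s' is missing for some sample(s)", target),
          class = "enrichdiff_data_error")
  }
  means$delta_ct <- means[[target]] - means[[reference]]
  cal <- means$delta_ct[means$condition == calibrator]
  if (!length(cal)) {
    abort(sprintf("no samples in calibrator condition '%s'", calibrator),
          class = "enrichdiff_data_error")
  }
  means |>
    mutate(fold = efficiency^(mean(cal) - .data$delta_ct)) |>
    select("sample", "condition", "delta_ct", "fold")
}

#' Two-group comparisons with Bonferroni adjustment
#'
#' The group tests used for bench validation: an exact-permutation
#' Mann-Whitney rank-sum test for small samples (full enumeration of label
#' assignments when the combined n is at most `exact_max`, a normal
#' approximation with tie correction above), or Welch's unpaired two-tailed
#' t-test. Raw p-values are Bonferroni-adjusted for `n_comparisons` tests
#' (`min(1, p * n_comparisons)`).
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param test "mann_whitney" or "t_test" (Welch, two-tailed, unpaired).
#' @param n_comparisons Number of comparisons in the family (default 1).
#' @param exact_max Combined-n limit for exact enumeration (default 12).
#' @return A one-row tibble: `test`, `n_x`, `n_y`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_groups <- function(x, y, test = c("mann_whitney", "t_test"),
                           n_comparisons = 1L, exact_max = 12L) {
  test <- match.arg(test)
  if (n_comparisons < 1) {
    abort("n_comparisons must be >= 1", class = "enrichdiff_bad_config")
  }
  if (test == "t_test") {
    if (length(x) < 2 || length(y) < 2) {
      abort("t test needs at least 2 values per group", class = "enrichdiff_bad_input")
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      abort("degenerate input: zero variance in both groups",
            class = "enrichdiff_degenerate_input")
    }
    fit <- stats::t.test(x, y, var.equal = FALSE)
    stat <- unname(fit$statistic)
    p <- fit$p.value
  } else {
    if (length(x) < 1 || length(y) < 1) {
      abort("rank test needs at least 1 value per group", class = "enrichdiff_bad_input")
    }
    res <- mann_whitney_p(x, y, exact_max = exact_max)
    stat <- res$statistic
    p <- res$p
  }
  tibble(test = test, n_x = length(x), n_y = length(y), statistic = stat,
         p_value = p,
         p_adjusted = stats::p.adjust(p, method = "bonferroni",
                                      n = n_comparisons))
}

# Two-sided Mann-Whitney p-value. Exact branch: enumerate all
# choose(n, n_x) assignments of the pooled values to group x and count
# rank sums at least as far from the null mean as the observed one
# (handles ties naturally through midranks). Large samples: normal
# approximation with tie-corrected variance and continuity correction, as in
# the classical large-sample treatment.
mann_whitney_p <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  u_obs <- w_obs - nx * (nx + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = u_obs, p = p)
}
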