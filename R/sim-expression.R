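#' Generate a partially concordant differential-expression table
#'
#' Emulates the typical relationship between promoter-mark differences and
#' steady-state expression: only a fraction (`de_concordance`) of
#' differentially enriched genes are also differentially expressed, and most
#' differentially expressed genes show no enrichment difference at all
#' (`n_de_background` of them are drawn from the non-differential pool).
#' Concordant genes receive a fold change of at least 1.5 with p < 0.01 in
#' the direction of their enrichment; every other gene gets a null fold
#' (close to 1) and a uniform p-value.
#'
#' @param truth A `truth_table` from [generate_peak_landscapes()].
#' @param config The matching [sim_config()].
#' @return A list: `expression`, a tibble (gene_id, fold_change, direction,
#'   p_value) with one row per gene, and `truth`, the truth table with
#'   `de_status` filled in (up_wt/up_ko/null).
#' @export
generate_expression_table <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  genes <- truth$genes
  n <- nrow(genes)
  with_stream(config$seed, "expression", {
    direction_of <- dplyr::case_when(
      genes$enrichment_status %in% c("unique_wt", "preferential_wt") ~ "wt",
      genes$enrichment_status %in% c("unique_ko", "preferential_ko") ~ "ko",
      .default = NA_character_
    )
    is_diff <- !is.na(direction_of)
    concordant <- is_diff & runif(n) < config$de_concordance

    pool <- which(!is_diff)
    n_bg <- min(config$n_de_background, length(pool))
    bg <- sample(pool, n_bg)
    bg_dir <- rep(c("wt", "ko"), length.out = n_bg)

    de <- concordant
    de[bg] <- TRUE
    direction <- ifelse(concordant, direction_of,
                        sample(c("wt", "ko"), n, replace = TRUE))
    direction[bg] <- bg_dir

    fold <- exp(abs(stats::rnorm(n, 0, 0.1)))
    fold[de] <- runif(sum(de), 1.5, 4)
    p <- runif(n)
    p[de] <- runif(sum(de), 1e-6, 0.0099)

    expression <- tibble(gene_id = genes$gene_id, fold_change = fold,
                         direction = direction, p_value = p)
    truth$genes$de_status <- ifelse(de, paste0("up_", direction), "null")
    list(expression = expression, truth = truth)
  })
}
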