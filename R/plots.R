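#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_vline
#'   labs facet_grid theme_minimal scale_y_continuous position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a metagene profile
#'
#' Mean signal across genes over the upstream flank, the rescaled gene body
#' and the downstream flank, with the TSS and TES marked.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  step <- attr(object, "step")
  nb <- attr(object, "n_body_bins")
  df <- as_tibble(object) |>
    mutate(xpos = dplyr::case_when(
      .data$segment == "upstream" ~ .data$position,
      .data$segment == "body" ~ (.data$position - 0.5) / nb * attr(object, "flank"),
      .default = .data$position + attr(object, "flank")
    ))
  ggplot(df, aes(x = .data$xpos, y = .data$signal)) +
    geom_line(colour = "#b2182b") +
    geom_vline(xintercept = c(0, attr(object, "flank")), linetype = "dashed") +
    labs(x = "position (bp; TSS at 0, TES at dashed right line, body rescaled)",
         y = "mean pileup",
         title = sprintf("Metagene profile over %d genes", attr(object, "n_genes_used"))) +
    theme_minimal()
}

#' Bar chart of genomic-context category fractions
#'
#' @param fractions Output of [category_fractions()], or a named list of such
#'   tibbles (one per genotype) for a side-by-side comparison.
#' @return A ggplot object.
#' @export
plot_category_fractions <- function(fractions) {
  if (is.data.frame(fractions)) fractions <- list(all = fractions)
  df <- purrr::imap(fractions, function(f, nm) mutate(f, genotype = nm)) |>
    purrr::list_rbind() |>
    mutate(category = factor(.data$category,
                             c("upstream", "intragenic", "downstream", "intergenic")))
  ggplot(df, aes(x = .data$category, y = .data$percent, fill = .data$genotype)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "% of peaks", title = "Peak genomic context") +
    theme_minimal()
}

#' Bar chart of per-chromosome peak density
#'
#' @param distribution Output of [chromosome_distribution()].
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(distribution) {
  ggplot(distribution, aes(x = .data$chrom, y = .data$density_per_mb)) +
    geom_col(fill = "#2166ac") +
    labs(x = NULL, y = "peaks per Mb",
         title = "Peak density normalised to chromosome size") +
    theme_minimal()
}

#' Bar chart of enrichment/expression overlap percentages
#'
#' @param report An `overlap_report` from
#'   [intersect_enrichment_expression()], or a list of them (e.g. both tiers).
#' @return A ggplot object.
#' @export
plot_overlap_report <- function(report) {
  if (is.data.frame(report)) report <- list(report)
  df <- purrr::list_rbind(purrr::map(report, as_tibble))
  ggplot(df, aes(x = .data$genotype, y = .data$percent, fill = .data$tier)) +
    geom_col(position = position_dodge()) +
    labs(x = "genotype with higher expression", y = "% of DE genes enriched",
         title = "Differential expression vs differential enrichment") +
    theme_minimal()
}
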