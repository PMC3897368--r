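#' Recompute published summary percentages from printed counts
#'
#' Audit mode for a published two-genotype analysis: given the counts a paper
#' prints (called genes, unique and differential gene totals, peak counts,
#' differentially expressed gene totals and their overlaps with the
#' enrichment sets), recomputes every derived percentage with the package's
#' own arithmetic (half-up rounding to one decimal). Useful for checking that
#' a summary table is internally consistent. A count table matching the
#' analysis this package models ships with the package; see the example.
#'
#' @param counts A named list or single-row data frame. Recognised names:
#'   `called_wt`, `called_ko`, `unique_wt`, `unique_ko`, `differential_wt`,
#'   `differential_ko` (unique + preferential totals), `peaks_wt`,
#'   `peaks_ko`, `de_wt`, `de_ko`, `unique_overlap_wt`, `unique_overlap_ko`,
#'   `differential_overlap_wt`, `differential_overlap_ko`. Missing groups are
#'   skipped.
#' @return A tibble with `metric` and `value`, containing counts and derived
#'   percentages.
#' @export
#' @examples
#' counts <- jsonlite::read_json(
#'   system.file("extdata", "published_counts.json", package = "enrichdiff"))
#' audit_published_counts(counts)
audit_published_counts <- function(counts) {
  counts <- as.list(counts)
  counts <- purrr::map(counts, as.numeric)
  rows <- list()
  add <- function(metric, value) rows[[length(rows) + 1L]] <<- tibble(metric = metric, value = value)
  has <- function(...) all(c(...) %in% names(counts))

  if (has("called_wt", "called_ko")) {
    add("called_gene_difference_pct",
        percent_of(counts$called_wt - counts$called_ko, counts$called_wt))
  }
  if (has("unique_wt", "called_wt")) {
    add("unique_wt_pct", percent_of(counts$unique_wt, counts$called_wt))
  }
  if (has("unique_ko", "called_ko")) {
    add("unique_ko_pct", percent_of(counts$unique_ko, counts$called_ko))
  }
  if (has("differential_wt", "called_wt")) {
    add("differential_wt_pct", percent_of(counts$differential_wt, counts$called_wt))
  }
  if (has("differential_ko", "called_ko")) {
    add("differential_ko_pct", percent_of(counts$differential_ko, counts$called_ko))
  }
  if (has("peaks_wt", "peaks_ko")) {
    add("peak_decrease_pct",
        percent_of(counts$peaks_wt - counts$peaks_ko, counts$peaks_wt))
  }
  if (has("unique_overlap_wt", "de_wt")) {
    add("unique_overlap_wt_pct", percent_of(counts$unique_overlap_wt, counts$de_wt))
  }
  if (has("differential_overlap_wt", "de_wt")) {
    add("differential_overlap_wt_pct",
        percent_of(counts$differential_overlap_wt, counts$de_wt))
  }
  if (has("unique_overlap_ko", "de_ko")) {
    add("unique_overlap_ko_pct", percent_of(counts$unique_overlap_ko, counts$de_ko))
  }
  if (has("differential_overlap_ko", "de_ko")) {
    add("differential_overlap_ko_pct",
        percent_of(counts$differential_overlap_ko, counts$de_ko))
  }
  purrr::list_rbind(rows)
}
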