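#' Call differential expression from a fold/p table
#'
#' Applies the analysis' criterion to a precomputed expression table: a gene
#' is differentially expressed in the genotype where it is higher when its
#' fold change is at least `fold_min` (inclusive) and its p-value is below
#' `p_max` (strict).
#'
#' @param table A tibble with columns `gene_id`, `fold_change` (ratio > 0,
#'   higher/lower expression encoded by `direction`), `direction` ("wt" or
#'   "ko": the genotype with higher expression) and `p_value`.
#' @param fold_min Minimum fold change (default 1.5, inclusive).
#' @param p_max P-value cutoff (default 0.01, strict).
#' @return The input tibble with a logical `de` column and, filtered to DE
#'   genes, split by direction; returned as a tibble with columns `gene_id`,
#'   `direction`, `fold_change`, `p_value` containing only the DE genes.
#' @export
call_differential_expression <- function(table, fold_min = 1.5, p_max = 0.01) {
  assert_columns(table, c("gene_id", "fold_change", "direction", "p_value"),
                 "expression table")
  dup <- table$gene_id[duplicated(table$gene_id)]
  if (length(dup)) {
    abort(sprintf("duplicate gene id(s) in expression table: %s",
                  paste(unique(head(dup, 5)), collapse = ", ")),
          class = "enrichdiff_data_error")
  }
  if (any(table$fold_change <= 0)) {
    abort("fold_change must be positive", class = "enrichdiff_data_error")
  }
  table |>
    filter(.data$fold_change >= fold_min, .data$p_value < p_max) |>
    select("gene_id", "direction", "fold_change", "p_value") |>
    arrange(.data$gene_id)
}

#' Overlap differential expression with differential enrichment
#'
#' Intersects each genotype's differentially expressed gene set with its
#' differentially enriched set, either unique-only or unique plus
#' preferential, enforcing direction concordance (a gene counts only when its
#' higher-expression genotype equals its enrichment genotype).
#'
#' @param de A DE table from [call_differential_expression()].
#' @param diff_calls A `diff_call` tibble from [preferential_enrichment()].
#' @param tier "unique_only" or "unique_plus_preferential".
#' @return An `overlap_report` tibble with one row per genotype: `genotype`,
#'   `tier`, `n_de`, `n_enriched`, `n_overlap`, `percent` (of the DE set, one
#'   decimal).
#' @export
intersect_enrichment_expression <- function(de, diff_calls,
                                            tier = c("unique_plus_preferential",
                                                     "unique_only")) {
  tier <- match.arg(tier)
  out <- purrr::map(c("wt", "ko"), function(gt) {
    de_set <- de$gene_id[de$direction == gt]
    if (length(de_set) == 0) {
      abort(sprintf("overlap percentage undefined: empty DE set for %s", gt),
            class = "enrichdiff_undefined_percentage")
    }
    statuses <- paste0("unique_", gt)
    if (tier == "unique_plus_preferential") {
      statuses <- c(statuses, paste0("preferential_", gt))
    }
    enriched <- diff_calls$gene_id[diff_calls$status %in% statuses]
    ov <- length(intersect(de_set, enriched))
    tibble(genotype = gt, tier = tier, n_de = length(de_set),
           n_enriched = length(enriched), n_overlap = ov,
           percent = percent_of(ov, length(de_set)))
  }) |> purrr::list_rbind()
  class(out) <- c("overlap_report", class(out))
  out
}

#' @export
tidy.overlap_report <- function(x, ...) as_tibble(x)

#' @export
glance.overlap_report <- function(x, ...) {
  as_tibble(x) |>
    select("genotype", "percent") |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "percent",
                       names_prefix = "overlap_pct_")
}

#' Export plain gene lists per differential status
#'
#' Writes one sorted, deduplicated gene-id file per enrichment status and per
#' DE direction (ready for external pathway tools), plus a `manifest.json`
#' with the counts. Empty categories still produce an (empty) file and a
#' manifest entry.
#'
#' @param diff_calls A `diff_call` tibble.
#' @param de Optional DE table from [call_differential_expression()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a tibble of `list_name` and `n`.
#' @export
export_gene_lists <- function(diff_calls, de = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lists <- list(
    unique_wt = diff_calls$gene_id[diff_calls$status == "unique_wt"],
    unique_ko = diff_calls$gene_id[diff_calls$status == "unique_ko"],
    preferential_wt = diff_calls$gene_id[diff_calls$status == "preferential_wt"],
    preferential_ko = diff_calls$gene_id[diff_calls$status == "preferential_ko"]
  )
  if (!is.null(de)) {
    lists$de_wt <- de$gene_id[de$direction == "wt"]
    lists$de_ko <- de$gene_id[de$direction == "ko"]
  }
  lists <- purrr::map(lists, function(g) sort(unique(g)))
  purrr::iwalk(lists, function(g, nm) {
    writeLines(g, file.path(outdir, paste0(nm, ".txt")))
  })
  manifest <- purrr::imap(lists, function(g, nm) {
    list(file = paste0(nm, ".txt"), n = length(g))
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(tibble(list_name = names(lists),
                   n = purrr::map_int(lists, length)))
}
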