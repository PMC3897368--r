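#' Call genes enriched for the mark by TSS proximity
#'
#' A gene is "called" when at least one peak interval comes within `window`
#' bp of its TSS (inclusive boundary: a peak ending exactly `window` bp away
#' still calls the gene). The nearest such peak is recorded.
#'
#' @param peaks A `peak_set`.
#' @param annotation A `genome_annotation` with the same chromosome naming.
#' @param window Maximum peak-to-TSS distance in bp (default 1000).
#' @return A `gene_call` tibble: `gene_id`, `peak_id` (nearest qualifying
#'   peak), `distance` (bp from peak interval to TSS, 0 when the TSS lies
#'   inside the peak), `amplitude` of that peak. One row per called gene.
#' @export
call_genes <- function(peaks, annotation, window = 1000L) {
  check_chromosomes(peaks, annotation)
  genes <- annotation$genes
  out <- purrr::map(unique(genes$chrom), function(ch) {
    g <- genes[genes$chrom == ch, ]
    p <- peaks[peaks$chrom == ch, ]
    if (nrow(p) == 0 || nrow(g) == 0) return(NULL)
    tss_rng <- IRanges::IRanges(start = g$tss + 1L, width = 1L)
    peak_rng <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    hits <- IRanges::findOverlaps(tss_rng, peak_rng, maxgap = window)
    if (!length(hits)) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    d <- interval_point_distance(p$start[si], p$end[si], g$tss[qi])
    keep <- d <= window
    if (!any(keep)) return(NULL)
    tibble(gene_id = g$gene_id[qi[keep]], peak_id = p$peak_id[si[keep]],
           distance = d[keep], amplitude = p$amplitude[si[keep]]) |>
      group_by(.data$gene_id) |>
      arrange(.data$distance, dplyr::desc(.data$amplitude), .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }) |> purrr::list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(gene_id = character(), peak_id = character(),
                  distance = numeric(), amplitude = numeric())
  }
  arrange(out, .data$gene_id)
}

#' Partition called genes into genotype-unique and shared sets
#'
#' Strict set difference and intersection of the two genotypes' called-gene
#' sets: "unique" enrichment means a gene was called in one genotype and
#' completely absent from the other's call set.
#'
#' @param calls_wt,calls_ko `gene_call` tibbles (or character vectors of gene
#'   ids) for the two genotypes.
#' @return A tibble: `gene_id`, `set` in unique_wt/unique_ko/shared.
#' @export
unique_genes <- function(calls_wt, calls_ko) {
  ids <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  wt <- unique(ids(calls_wt))
  ko <- unique(ids(calls_ko))
  bind_rows(
    tibble(gene_id = setdiff(wt, ko), set = "unique_wt"),
    tibble(gene_id = setdiff(ko, wt), set = "unique_ko"),
    tibble(gene_id = intersect(wt, ko), set = "shared")
  ) |> arrange(.data$gene_id)
}

#' Two-tier differential enrichment: unique and preferential genes
#'
#' Implements the analysis' two-tier differential logic over a gene
#' annotation. Tier one ("unique") is presence/absence: a gene called in only
#' one genotype. Tier two ("preferential") compares amplitudes: peaks from
#' the two genotypes are matched when their intervals overlap or their
#' summits lie within one bin, and a matched pair near a gene (peak interval
#' within `gene_window` bp of the gene's annotated interval) makes the gene
#' preferential when the amplitude ratio is at least `fold_min` (inclusive)
#' and the larger amplitude is at least `amp_min`. Unique status takes
#' precedence, keeping the five statuses disjoint. Genes with no qualifying
#' pair are `unchanged`.
#'
#' @param peaks_wt,peaks_ko `peak_set`s with amplitudes.
#' @param annotation A `genome_annotation`.
#' @param fold_min Minimum amplitude ratio (default 2; ties count).
#' @param amp_min Minimum larger amplitude (default 10).
#' @param gene_window Peak-to-gene-interval distance in bp (default 1000).
#' @param call_window Peak-to-TSS window for gene calling (default 1000).
#' @param bin_step Summit-matching tolerance in bp (default 50, one bin).
#' @return A `diff_call` tibble with one row per annotated gene: `gene_id`,
#'   `status` (unique_wt/unique_ko/preferential_wt/preferential_ko/
#'   unchanged), `amp_wt`, `amp_ko` (0 when absent), `ratio`
#'   (max/min amplitude; `Inf` when one side is absent), `called_wt`,
#'   `called_ko`.
#' @export
preferential_enrichment <- function(peaks_wt, peaks_ko, annotation,
                                    fold_min = 2, amp_min = 10,
                                    gene_window = 1000L, call_window = 1000L,
                                    bin_step = 50L) {
  for (p in list(peaks_wt, peaks_ko)) {
    if (anyNA(p$amplitude)) {
      abort(sprintf("amplitude missing for peak(s): %s",
                    paste(head(p$peak_id[is.na(p$amplitude)], 5), collapse = ", ")),
            class = "enrichdiff_data_error")
    }
  }
  genes <- annotation$genes
  calls_wt <- call_genes(peaks_wt, annotation, window = call_window)
  calls_ko <- call_genes(peaks_ko, annotation, window = call_window)
  uq <- unique_genes(calls_wt, calls_ko)

  pairs <- match_peak_pairs(peaks_wt, peaks_ko, bin_step = bin_step)
  pair_genes <- pairs_near_genes(pairs, genes, gene_window = gene_window)
  pref <- pair_genes |>
    mutate(ratio = pmax(.data$amp_wt, .data$amp_ko) /
             pmin(.data$amp_wt, .data$amp_ko)) |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$ratio),
            dplyr::desc(pmax(.data$amp_wt, .data$amp_ko)), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(qualifies = .data$ratio >= fold_min &
             pmax(.data$amp_wt, .data$amp_ko) >= amp_min)

  out <- tibble(gene_id = genes$gene_id) |>
    left_join(uq, by = "gene_id") |>
    left_join(select(calls_wt, "gene_id", call_amp_wt = "amplitude"),
              by = "gene_id") |>
    left_join(select(calls_ko, "gene_id", call_amp_ko = "amplitude"),
              by = "gene_id") |>
    left_join(select(pref, "gene_id", pair_amp_wt = "amp_wt",
                     pair_amp_ko = "amp_ko", "ratio", "qualifies"),
              by = "gene_id")

  status <- dplyr::case_when(
    out$set == "unique_wt" ~ "unique_wt",
    out$set == "unique_ko" ~ "unique_ko",
    !is.na(out$qualifies) & out$qualifies & out$pair_amp_wt > out$pair_amp_ko ~ "preferential_wt",
    !is.na(out$qualifies) & out$qualifies & out$pair_amp_ko > out$pair_amp_wt ~ "preferential_ko",
    .default = "unchanged"
  )
  amp_wt <- dplyr::coalesce(out$pair_amp_wt, out$call_amp_wt, 0)
  amp_ko <- dplyr::coalesce(out$pair_amp_ko, out$call_amp_ko, 0)
  amp_wt[status == "unique_ko"] <- 0
  amp_ko[status == "unique_wt"] <- 0
  res <- tibble(
    gene_id = out$gene_id,
    status = status,
    amp_wt = amp_wt,
    amp_ko = amp_ko,
    ratio = dplyr::case_when(
      amp_wt > 0 & amp_ko > 0 ~ pmax(amp_wt, amp_ko) / pmin(amp_wt, amp_ko),
      amp_wt == 0 & amp_ko == 0 ~ NA_real_,
      .default = Inf
    ),
    called_wt = .data$gene_id %in% calls_wt$gene_id,
    called_ko = .data$gene_id %in% calls_ko$gene_id
  )
  class(res) <- c("diff_call", class(res))
  res
}

# Cross-genotype peak matching: interval overlap, or summits within one bin.
match_peak_pairs <- function(peaks_wt, peaks_ko, bin_step = 50L) {
  purrr::map(unique(c(peaks_wt$chrom, peaks_ko$chrom)), function(ch) {
    w <- peaks_wt[peaks_wt$chrom == ch, ]
    k <- peaks_ko[peaks_ko$chrom == ch, ]
    if (nrow(w) == 0 || nrow(k) == 0) return(NULL)
    rw <- IRanges::IRanges(w$start + 1L, w$end)
    rk <- IRanges::IRanges(k$start + 1L, k$end)
    ov <- IRanges::findOverlaps(rw, rk)
    sw <- IRanges::IRanges(w$summit + 1L, width = 1L)
    sk <- IRanges::IRanges(k$summit + 1L, width = 1L)
    near <- IRanges::findOverlaps(sw, sk, maxgap = bin_step)
    qi <- c(S4Vectors::queryHits(ov), S4Vectors::queryHits(near))
    si <- c(S4Vectors::subjectHits(ov), S4Vectors::subjectHits(near))
    dup <- duplicated(cbind(qi, si))
    tibble(chrom = ch,
           peak_wt = w$peak_id[qi[!dup]], peak_ko = k$peak_id[si[!dup]],
           start = pmin(w$start[qi[!dup]], k$start[si[!dup]]),
           end = pmax(w$end[qi[!dup]], k$end[si[!dup]]),
           amp_wt = w$amplitude[qi[!dup]], amp_ko = k$amplitude[si[!dup]])
  }) |> purrr::list_rbind()
}

# Attach matched pairs to genes whose interval lies within gene_window bp of
# the pair's combined interval.
pairs_near_genes <- function(pairs, genes, gene_window = 1000L) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble(gene_id = character(), amp_wt = numeric(), amp_ko = numeric()))
  }
  purrr::map(unique(pairs$chrom), function(ch) {
    p <- pairs[pairs$chrom == ch, ]
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) return(NULL)
    rp <- IRanges::IRanges(p$start + 1L, p$end)
    rg <- IRanges::IRanges(g$start + 1L, g$end)
    hits <- IRanges::findOverlaps(rp, rg, maxgap = gene_window)
    if (!length(hits)) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    d <- interval_distance(p$start[qi], p$end[qi], g$start[si], g$end[si])
    keep <- d <= gene_window
    tibble(gene_id = g$gene_id[si[keep]],
           amp_wt = p$amp_wt[qi[keep]],
           amp_ko = p$amp_ko[qi[keep]])
  }) |> purrr::list_rbind()
}

#' Summarise differential-enrichment calls
#'
#' Emits the headline counts and percentages: called totals per genotype, the
#' called-gene difference, unique counts and their percentage of the calling
#' genotype's total, and differential totals (unique plus preferential, the
#' "expanded list") with their percentages. Peak sets may be supplied to add
#' the peak-count decrease.
#'
#' @param diff_calls A `diff_call` tibble from [preferential_enrichment()].
#' @param peaks_wt,peaks_ko Optional `peak_set`s for peak-count rates.
#' @return A `diff_summary` tibble with `metric` and `value` columns.
#' @export
summarize_differential <- function(diff_calls, peaks_wt = NULL, peaks_ko = NULL) {
  n_called_wt <- sum(diff_calls$called_wt)
  n_called_ko <- sum(diff_calls$called_ko)
  if (n_called_wt == 0 || n_called_ko == 0) {
    abort("percentages undefined: no called genes in one genotype",
          class = "enrichdiff_undefined_percentage")
  }
  n <- function(s) sum(diff_calls$status == s)
  counts <- list(
    called_wt = n_called_wt, called_ko = n_called_ko,
    unique_wt = n("unique_wt"), unique_ko = n("unique_ko"),
    differential_wt = n("unique_wt") + n("preferential_wt"),
    differential_ko = n("unique_ko") + n("preferential_ko")
  )
  if (!is.null(peaks_wt)) counts$peaks_wt <- nrow(peaks_wt)
  if (!is.null(peaks_ko)) counts$peaks_ko <- nrow(peaks_ko)
  summarize_differential_counts(counts)
}

summarize_differential_counts <- function(counts) {
  rows <- list(
    c("called_genes_wt", counts$called_wt),
    c("called_genes_ko", counts$called_ko),
    c("called_gene_difference_pct",
      percent_of(counts$called_wt - counts$called_ko, counts$called_wt)),
    c("unique_wt", counts$unique_wt),
    c("unique_ko", counts$unique_ko),
    c("unique_wt_pct", percent_of(counts$unique_wt, counts$called_wt)),
    c("unique_ko_pct", percent_of(counts$unique_ko, counts$called_ko)),
    c("differential_wt", counts$differential_wt),
    c("differential_ko", counts$differential_ko),
    c("differential_wt_pct", percent_of(counts$differential_wt, counts$called_wt)),
    c("differential_ko_pct", percent_of(counts$differential_ko, counts$called_ko))
  )
  if (!is.null(counts$peaks_wt) && !is.null(counts$peaks_ko)) {
    rows <- c(rows, list(
      c("peaks_wt", counts$peaks_wt),
      c("peaks_ko", counts$peaks_ko),
      c("peak_decrease_pct",
        percent_of(counts$peaks_wt - counts$peaks_ko, counts$peaks_wt))
    ))
  }
  out <- tibble(metric = purrr::map_chr(rows, 1),
                value = as.numeric(purrr::map_chr(rows, 2)))
  class(out) <- c("diff_summary", class(out))
  out
}

#' @export
tidy.diff_summary <- function(x, ...) as_tibble(x)

#' @export
glance.diff_summary <- function(x, ...) {
  tidyr::pivot_wider(as_tibble(x), names_from = "metric", values_from = "value")
}
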