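#' Parameters for genomic-context peak classification
#'
#' The 2-kb windows mirror the convention for promoter-proximal histone
#' marks: a peak counts as upstream/downstream when its summit lies within
#' 2 kb of a TSS/TES, and as intergenic when it lies at least
#' `intergenic_min_distance` from every annotated gene interval.
#'
#' @param upstream_window,downstream_window Window sizes in bp (default 2000).
#' @param intergenic_min_distance Minimum summit distance from any gene for
#'   the intergenic label (default 2000).
#' @return An `annotation_params` list.
#' @export
annotation_params <- function(upstream_window = 2000L, downstream_window = 2000L,
                              intergenic_min_distance = 2000L) {
  if (any(c(upstream_window, downstream_window, intergenic_min_distance) <= 0)) {
    abort("annotation windows must be positive", class = "enrichdiff_bad_config")
  }
  structure(list(upstream_window = as.integer(upstream_window),
                 downstream_window = as.integer(downstream_window),
                 intergenic_min_distance = as.integer(intergenic_min_distance)),
            class = "annotation_params")
}

# Per-chromosome any-overlap test between two 0-based half-open interval
# tables; backs both CpG association and the planted CpG flags.
intervals_overlap_any <- function(x, y) {
  out <- logical(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    if (!length(yi)) next
    q <- IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    s <- IRanges::IRanges(start = y$start[yi] + 1L, end = y$end[yi])
    out[xi] <- IRanges::overlapsAny(q, s)
  }
  out
}

check_chromosomes <- function(peaks, annotation) {
  known <- annotation$chromosomes$chrom
  offenders <- setdiff(unique(peaks$chrom), known)
  if (length(offenders)) {
    abort(sprintf("peaks reference chromosome(s) absent from the annotation: %s",
                  paste(offenders, collapse = ", ")),
          class = "enrichdiff_mapping_error")
  }
}

#' Classify peaks by genomic context
#'
#' Assigns each peak exactly one of four categories from its summit position,
#' strand-aware: `upstream` when the summit lies within the upstream window
#' 5' of any TSS, else `intragenic` when it falls inside any gene body, else
#' `downstream` when it lies within the downstream window 3' of any TES, else
#' `intergenic`. The priority order resolves peaks near short genes whose
#' windows overlap; with equal window sizes the four categories are exhaustive
#' and mutually exclusive.
#'
#' @param peaks A `peak_set`.
#' @param annotation A `genome_annotation` sharing the peaks' chromosome
#'   naming.
#' @param params An [annotation_params()].
#' @return The peak tibble with added `category` (character) and
#'   `dist_to_gene` (bp from summit to the nearest gene interval, 0 inside a
#'   gene) columns.
#' @export
classify_peaks <- function(peaks, annotation, params = annotation_params()) {
  check_chromosomes(peaks, annotation)
  genes <- annotation$genes
  category <- rep("intergenic", nrow(peaks))
  dist_to_gene <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) next
    s <- peaks$summit[pi]
    pts <- IRanges::IRanges(start = s + 1L, width = 1L)

    up_start <- ifelse(g$strand == "+", g$tss - params$upstream_window, g$tss + 1L)
    up_end <- ifelse(g$strand == "+", g$tss - 1L, g$tss + params$upstream_window)
    dn_start <- ifelse(g$strand == "+", g$tes + 1L, g$tes - params$downstream_window)
    dn_end <- ifelse(g$strand == "+", g$tes + params$downstream_window, g$tes - 1L)

    in_up <- IRanges::overlapsAny(pts, IRanges::IRanges(up_start + 1L, up_end + 1L))
    in_body <- IRanges::overlapsAny(pts, IRanges::IRanges(g$start + 1L, g$end))
    in_dn <- IRanges::overlapsAny(pts, IRanges::IRanges(dn_start + 1L, dn_end + 1L))

    cat_ch <- ifelse(in_up, "upstream",
                     ifelse(in_body, "intragenic",
                            ifelse(in_dn, "downstream", "intergenic")))
    gene_rng <- IRanges::IRanges(g$start + 1L, g$end)
    hit <- IRanges::distanceToNearest(pts, gene_rng)
    d <- rep(Inf, length(pi))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    category[pi] <- cat_ch
    dist_to_gene[pi] <- d
  }
  # With the default equal window sizes, "not in any window" coincides with
  # "summit >= intergenic_min_distance from every gene"; dist_to_gene lets
  # callers audit the distance rule when they change one but not the other.
  peaks$category <- category
  peaks$dist_to_gene <- dist_to_gene
  peaks
}

#' Category fractions of a classified peak set
#'
#' @param peaks A classified `peak_set` (output of [classify_peaks()]).
#' @return A tibble with one row per category (all four always present):
#'   `category`, `n`, `fraction` (sums to 1) and `percent` (one decimal).
#' @export
category_fractions <- function(peaks) {
  assert_columns(peaks, "category", "classified peak_set")
  lv <- c("upstream", "intragenic", "downstream", "intergenic")
  n <- purrr::map_int(lv, function(l) sum(peaks$category == l))
  tibble(category = lv, n = n, fraction = n / sum(n),
         percent = percent_of(n, sum(n)))
}

#' CpG-island association of a peak set
#'
#' Fraction of peaks whose interval overlaps at least one CpG island by at
#' least 1 bp, optionally restricted to one genomic-context category (the
#' genome-wide and intergenic-only figures are the two the analysis reports).
#'
#' @param peaks A `peak_set`, classified if `category_filter` is used.
#' @param islands A tibble (chrom, start, end) of CpG islands, or a
#'   `genome_annotation`.
#' @param category_filter Optional category to restrict to.
#' @return A one-row tibble: `category`, `n_peaks`, `n_overlapping`,
#'   `percent` (one decimal).
#' @export
cpg_association <- function(peaks, islands, category_filter = NULL) {
  if (inherits(islands, "genome_annotation")) islands <- islands$cpg_islands
  sel <- peaks
  if (!is.null(category_filter)) {
    assert_columns(peaks, "category", "peak_set with category_filter")
    sel <- peaks[peaks$category == category_filter, ]
  }
  if (nrow(sel) == 0) {
    abort("CpG association undefined: no peaks in the selected category",
          class = "enrichdiff_undefined_fraction")
  }
  hit <- intervals_overlap_any(sel, islands)
  tibble(category = category_filter %||% "all",
         n_peaks = nrow(sel), n_overlapping = sum(hit),
         percent = percent_of(sum(hit), nrow(sel)))
}

#' Chromosome-normalised peak density
#'
#' Peak count per chromosome divided by chromosome length, reported per Mb.
#' Chromosomes without peaks are included with density 0.
#'
#' @param peaks A `peak_set`.
#' @param chrom_lengths A tibble (chrom, length), a named length vector, or a
#'   `genome_annotation`.
#' @return A tibble: `chrom`, `n_peaks`, `length`, `density_per_mb`.
#' @export
chromosome_distribution <- function(peaks, chrom_lengths) {
  if (inherits(chrom_lengths, "genome_annotation")) {
    chrom_lengths <- chrom_lengths$chromosomes
  }
  if (!is.data.frame(chrom_lengths)) {
    chrom_lengths <- tibble(chrom = names(chrom_lengths),
                            length = as.numeric(chrom_lengths))
  }
  missing <- setdiff(unique(peaks$chrom), chrom_lengths$chrom)
  if (length(missing)) {
    abort(sprintf("no length known for chromosome(s): %s",
                  paste(missing, collapse = ", ")),
          class = "enrichdiff_mapping_error")
  }
  counts <- dplyr::count(as_tibble(peaks), .data$chrom, name = "n_peaks")
  chrom_lengths |>
    left_join(counts, by = "chrom") |>
    mutate(n_peaks = tidyr::replace_na(.data$n_peaks, 0L),
           density_per_mb = .data$n_peaks / (.data$length / 1e6)) |>
    select("chrom", "n_peaks", "length", "density_per_mb")
}
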