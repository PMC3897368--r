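#' Read and write peak sets as BED6+3
#'
#' Peaks serialise as BED6 (chrom, start, end, name, score, strand; 0-based
#' half-open, strand always ".") plus three extra columns: summit (absolute
#' bp), amplitude, and p-value. Missing scores/p-values (planted peaks) are
#' written as ".". The round trip `read_peaks_bed(write_peaks_bed(x))`
#' reproduces the core peak columns bit-exactly.
#'
#' @param peaks A `peak_set`.
#' @param path File path.
#' @return `write_peaks_bed()` returns `path` invisibly; `read_peaks_bed()`
#'   returns a `peak_set`.
#' @export
write_peaks_bed <- function(peaks, path) {
  num <- function(v, int = FALSE) {
    out <- ifelse(is.na(v), ".",
                  if (int) sprintf("%.0f", v) else sprintf("%.17g", v))
    out
  }
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%s\t.\t%.0f\t%s\t%s",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   num(peaks$score), peaks$summit,
                   num(peaks$amplitude), num(peaks$p_value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @param genotype Optional genotype label to attach.
#' @export
read_peaks_bed <- function(path, genotype = NULL) {
  cols <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "peak_id", "score", "strand",
                  "summit", "amplitude", "p_value"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), peak_id = readr::col_character(),
      score = readr::col_character(), strand = readr::col_character(),
      summit = readr::col_double(), amplitude = readr::col_character(),
      p_value = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  dot_na <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  as_peak_set(tibble(
    peak_id = cols$peak_id, chrom = cols$chrom,
    start = as.integer(cols$start), end = as.integer(cols$end),
    summit = as.integer(cols$summit),
    amplitude = dot_na(cols$amplitude),
    p_value = dot_na(cols$p_value),
    score = dot_na(cols$score)
  ), genotype = genotype)
}

#' Read and write gene and CpG-island annotation as BED6
#'
#' Genes serialise as BED6 with the gene id in the name column and the strand
#' in column 6; CpG islands use the island id and strand ".". Coordinates are
#' 0-based half-open. `read_genome_annotation()` rebuilds a
#' `genome_annotation` from the two files plus a chromosome-length table.
#'
#' @param annotation A `genome_annotation`.
#' @param genes_path,cpg_path,chrom_path Output paths for the gene BED, island
#'   BED, and chromosome-length TSV.
#' @return `write_genome_annotation()` returns the paths invisibly;
#'   `read_genome_annotation()` returns a `genome_annotation`.
#' @export
write_genome_annotation <- function(annotation, genes_path, cpg_path,
                                    chrom_path = NULL) {
  g <- annotation$genes
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t0\t%s",
                     g$chrom, g$start, g$end, g$gene_id, g$strand), genes_path)
  i <- annotation$cpg_islands
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t0\t.",
                     i$chrom, i$start, i$end, i$island_id), cpg_path)
  if (!is.null(chrom_path)) {
    readr::write_tsv(annotation$chromosomes, chrom_path, progress = FALSE)
  }
  invisible(c(genes = genes_path, cpg = cpg_path))
}

#' @rdname write_genome_annotation
#' @param chromosomes A tibble (chrom, length), or path to the TSV written by
#'   `write_genome_annotation()`.
#' @export
read_genome_annotation <- function(genes_path, cpg_path, chromosomes) {
  bed6 <- function(p) {
    readr::read_tsv(p, col_names = c("chrom", "start", "end", "name",
                                     "score", "strand"),
                    col_types = "cddcdc", progress = FALSE)
  }
  g <- bed6(genes_path)
  genes <- tibble(
    gene_id = g$name, chrom = g$chrom, strand = g$strand,
    start = as.integer(g$start), end = as.integer(g$end)
  ) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
           tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start))
  i <- bed6(cpg_path)
  islands <- tibble(island_id = i$name, chrom = i$chrom,
                    start = as.integer(i$start), end = as.integer(i$end),
                    context = NA_character_)
  if (is.character(chromosomes)) {
    chromosomes <- readr::read_tsv(chromosomes, col_types = "cd", progress = FALSE)
  }
  structure(list(chromosomes = as_tibble(chromosomes), genes = genes,
                 cpg_islands = islands),
            class = "genome_annotation")
}
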