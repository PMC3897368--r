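# Gene placement keeps >=5 kb between gene intervals so every peak planted by
# the landscape generator has exactly one defensible genomic-context category
# and every 2-kb / 1-kb window rule is unambiguous.
MIN_INTERGENIC_GAP <- 5000L
INTERGENIC_CLEARANCE <- 2300L # distance kept between intergenic features and genes

#' Generate a seeded synthetic genome annotation
#'
#' Places non-overlapping genes with at least 5 kb of intergenic space on
#' equal-length chromosomes, assigns strands at random, and plants CpG islands
#' over a configured fraction of TSSs (+/- 500 bp) plus additional intergenic
#' islands. The same `config` (including its seed) always produces an
#' identical annotation.
#'
#' @param config A [sim_config()].
#' @return A `genome_annotation`: a list with tibbles `chromosomes`
#'   (chrom, length), `genes` (gene_id, chrom, strand, start, end, tss, tes;
#'   0-based half-open coordinates, TSS/TES strand-aware) and `cpg_islands`
#'   (island_id, chrom, start, end, context).
#' @export
#' @examples
#' ann <- generate_genome(sim_config(n_genes = 20, chrom_length = 1e6, seed = 7))
#' nrow(ann$genes)
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "genome", {
    chroms <- tibble(
      chrom = sprintf("chr%d", seq_len(config$n_chromosomes)),
      length = rep(config$chrom_length, config$n_chromosomes)
    )
    per_chrom <- diff(floor(seq(0, config$n_genes,
                                length.out = config$n_chromosomes + 1)))
    genes <- purrr::map2(chroms$chrom, per_chrom, function(ch, n) {
      if (n == 0) return(NULL)
      len_span <- config$gene_length_range[2] - config$gene_length_range[1] + 1L
      lens <- config$gene_length_range[1] + sample.int(len_span, n, replace = TRUE) - 1L
      need <- sum(lens) + (n + 1) * MIN_INTERGENIC_GAP
      if (need > config$chrom_length) {
        abort(sprintf(paste0(
          "cannot place %d genes of %d-%d bp with %d-bp gaps on a %.0f-bp ",
          "chromosome (needs %.0f bp): reduce n_genes or gene_length_range, ",
          "or increase chrom_length"),
          n, config$gene_length_range[1], config$gene_length_range[2],
          MIN_INTERGENIC_GAP, config$chrom_length, need),
          class = "enrichdiff_capacity_error")
      }
      slack <- config$chrom_length - need
      u <- runif(n + 1)
      extra <- floor(slack * u / sum(u))
      gaps <- MIN_INTERGENIC_GAP + extra # n + 1 gaps; the last is implicit slack
      starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, head(lens, -1)))
      tibble(chrom = ch, start = as.integer(starts),
             end = as.integer(starts + lens))
    }) |> purrr::list_rbind()
    genes <- genes |>
      mutate(
        gene_id = sprintf("g%04d", dplyr::row_number()),
        strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
        tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
        tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
      ) |>
      select("gene_id", "chrom", "strand", "start", "end", "tss", "tes")

    n_tss_cpg <- round(config$cpg_at_tss_fraction * nrow(genes))
    tss_idx <- sort(sample(nrow(genes), n_tss_cpg))
    tss_islands <- genes[tss_idx, ] |>
      transmute(chrom = .data$chrom,
                start = pmax(0L, as.integer(.data$tss - 500L)),
                end = as.integer(.data$tss + 501L),
                context = "tss")

    anchors <- intergenic_anchor_grid(genes, chroms)
    n_isl <- config$n_intergenic_islands
    if (nrow(anchors) < n_isl) {
      abort("not enough intergenic space for the requested CpG islands",
            class = "enrichdiff_capacity_error")
    }
    isl_rows <- anchors[sort(sample(nrow(anchors), n_isl)), ]
    intergenic_islands <- isl_rows |>
      transmute(chrom = .data$chrom,
                start = as.integer(.data$pos - 300L),
                end = as.integer(.data$pos + 300L),
                context = "intergenic")

    islands <- bind_rows(tss_islands, intergenic_islands) |>
      arrange(.data$chrom, .data$start) |>
      mutate(island_id = sprintf("cpg%04d", dplyr::row_number())) |>
      select("island_id", "chrom", "start", "end", "context")

    structure(list(chromosomes = chroms, genes = genes, cpg_islands = islands),
              class = "genome_annotation")
  })
}

# Candidate positions for intergenic features: a 2-kb grid over the regions at
# least INTERGENIC_CLEARANCE from every gene interval.
intergenic_anchor_grid <- function(genes, chroms, grid = 2000L) {
  purrr::map(seq_len(nrow(chroms)), function(i) {
    ch <- chroms$chrom[i]
    L <- chroms$length[i]
    g <- genes[genes$chrom == ch, ]
    starts <- c(0, g$end + INTERGENIC_CLEARANCE)
    ends <- c(g$start - INTERGENIC_CLEARANCE, L)
    keep <- ends - starts > 2 * grid
    if (!any(keep)) return(NULL)
    pos <- purrr::map(which(keep), function(j) {
      seq(starts[j] + grid, ends[j] - grid, by = grid)
    })
    tibble(chrom = ch, pos = as.numeric(unlist(pos)))
  }) |> purrr::list_rbind()
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat(sprintf("  %d chromosome(s), %d genes, %d CpG islands (%d at TSS)\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$cpg_islands),
              sum(x$cpg_islands$context == "tss")))
  invisible(x)
}
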