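# Planted peaks are 300 bp wide with the summit at a bin centre
# (bin_index * step + step/2). Together with the stratified fragment placement
# in generate_coverage_tracks this makes the emitted amplitude equal the
# full-height pileup over an ext/step-bin plateau, so peak detectability
# depends on amplitude alone and planted landscapes are recoverable.

#' Generate paired two-genotype peak landscapes with ground truth
#'
#' Plants one TSS-proximal ("upstream") peak per gene in each genotype, plus
#' intragenic, downstream-of-TES and intergenic peaks so the category mix of
#' the emitted peaks matches `config$category_mix`. Differential structure is
#' planted at TSS peaks: `n_unique_*` genes get a peak in only one genotype;
#' `n_preferential_*` genes get an amplitude ratio of `preferential_fold`
#' favouring one genotype with the larger amplitude at least 10. All other
#' peaks are shared with amplitudes equal across genotypes up to the
#' configured multiplicative jitter.
#'
#' @param annotation A `genome_annotation` from [generate_genome()].
#' @param config The same [sim_config()] used for the annotation.
#' @return A list with `peaks_wt` and `peaks_ko` (`peak_set` tibbles carrying
#'   planted_category, gene_id and cpg_flag columns) and `truth`, a
#'   `truth_table` with per-gene enrichment status and amplitudes and per-peak
#'   planted category and CpG flag.
#' @export
generate_peak_landscapes <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  genes <- annotation$genes
  n_genes <- nrow(genes)
  step <- config$bin_step
  half <- config$fragment_extension %/% 2L

  mix <- config$category_mix
  if (mix[["upstream"]] <= 0) {
    abort("category_mix must give upstream peaks positive weight: every gene carries a TSS peak",
          class = "enrichdiff_placement_error")
  }
  n_total <- round(n_genes / mix[["upstream"]])
  n_intra <- round(n_total * mix[["intragenic"]])
  n_down <- round(n_total * mix[["downstream"]])
  n_inter <- n_total - n_genes - n_intra - n_down
  if (n_inter < 0) {
    abort("category_mix is incompatible with one TSS peak per gene",
          class = "enrichdiff_placement_error")
  }

  with_stream(config$seed, "landscape", {
    ## --- assign per-gene differential status -----------------------------
    n_special <- config$n_unique_wt + config$n_unique_ko +
      config$n_preferential_wt + config$n_preferential_ko
    special_idx <- sample(n_genes, n_special)
    status <- rep("both", n_genes)
    take <- function(n) {
      out <- special_idx[seq_len(n)]
      special_idx <<- special_idx[-seq_len(n)]
      out
    }
    if (config$n_unique_wt > 0) status[take(config$n_unique_wt)] <- "unique_wt"
    if (config$n_unique_ko > 0) status[take(config$n_unique_ko)] <- "unique_ko"
    if (config$n_preferential_wt > 0) status[take(config$n_preferential_wt)] <- "preferential_wt"
    if (config$n_preferential_ko > 0) status[take(config$n_preferential_ko)] <- "preferential_ko"

    ## --- TSS peak geometry ----------------------------------------------
    off <- sample(150:600, n_genes, replace = TRUE)
    raw_summit <- ifelse(genes$strand == "+", genes$tss - off, genes$tss + off)
    tss_summit <- snap_to_bin_centre(raw_summit, step)

    ## --- amplitudes ------------------------------------------------------
    draw_amp <- function(n) {
      pmax(2, round(rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)))
    }
    base <- draw_amp(n_genes)
    uniq <- status %in% c("unique_wt", "unique_ko")
    base[uniq] <- pmax(12, base[uniq])
    pref <- status %in% c("preferential_wt", "preferential_ko")
    low_side <- sample(12:20, sum(pref), replace = TRUE)
    jit <- function(n) {
      if (config$amplitude_jitter <= 0) return(rep(1, n))
      b <- log(1 + config$amplitude_jitter)
      exp(runif(n, -b, b))
    }
    amp_wt <- base
    amp_ko <- base
    amp_wt[status == "preferential_wt"] <-
      round(config$preferential_fold * low_side[status[pref] == "preferential_wt"])
    amp_ko[status == "preferential_wt"] <- low_side[status[pref] == "preferential_wt"]
    amp_ko[status == "preferential_ko"] <-
      round(config$preferential_fold * low_side[status[pref] == "preferential_ko"])
    amp_wt[status == "preferential_ko"] <- low_side[status[pref] == "preferential_ko"]
    amp_wt <- pmax(1, round(amp_wt * jit(n_genes)))
    amp_ko <- pmax(1, round(amp_ko * jit(n_genes)))
    amp_wt[status == "unique_ko"] <- 0L
    amp_ko[status == "unique_wt"] <- 0L

    tss_peaks <- tibble(
      chrom = genes$chrom, summit = tss_summit,
      planted_category = "upstream", gene_id = genes$gene_id,
      amp_wt = amp_wt, amp_ko = amp_ko
    )

    ## --- shared non-TSS peaks -------------------------------------------
    nonspecial <- which(status == "both")
    if (n_intra > length(nonspecial) || n_down > length(nonspecial)) {
      abort("category_mix requires more intragenic/downstream host genes than are available",
            class = "enrichdiff_placement_error")
    }
    intra_hosts <- genes[sample(nonspecial, n_intra), ]
    d_in <- purrr::map_int(intra_hosts$end - intra_hosts$start, function(len) {
      lo <- 1800L
      hi <- len - 200L
      if (hi < lo) abort("gene too short for an intragenic peak",
                         class = "enrichdiff_placement_error")
      lo + sample.int(hi - lo + 1L, 1L) - 1L
    })
    intra_summit <- snap_to_bin_centre(
      ifelse(intra_hosts$strand == "+", intra_hosts$start + d_in,
             intra_hosts$end - 1L - d_in), step)

    down_hosts <- genes[sample(nonspecial, n_down), ]
    d_dn <- 400L + sample.int(1301L, n_down, replace = TRUE) - 1L
    down_summit <- snap_to_bin_centre(
      ifelse(down_hosts$strand == "+", down_hosts$tes + d_dn,
             down_hosts$tes - d_dn), step)

    islands <- annotation$cpg_islands |> filter(.data$context == "intergenic")
    n_cpg_inter <- round(config$intergenic_cpg_fraction * n_inter)
    if (n_cpg_inter > nrow(islands)) {
      abort("not enough intergenic CpG islands to host the configured intergenic peak fraction",
            class = "enrichdiff_placement_error")
    }
    isl_pick <- islands[sample(nrow(islands), n_cpg_inter), ]
    anchors <- intergenic_anchor_grid(genes, annotation$chromosomes) |>
      anti_join(tibble(chrom = islands$chrom, pos = islands$start + 300),
                by = c("chrom", "pos"))
    n_plain <- n_inter - n_cpg_inter
    if (n_plain > nrow(anchors)) {
      abort("not enough intergenic space for the configured intergenic peaks",
            class = "enrichdiff_placement_error")
    }
    plain_pick <- anchors[sample(nrow(anchors), n_plain), ]
    inter_summit <- snap_to_bin_centre(
      c(isl_pick$start + 300, plain_pick$pos), step)
    inter_chrom <- c(isl_pick$chrom, plain_pick$chrom)

    shared <- tibble(
      chrom = c(intra_hosts$chrom, down_hosts$chrom, inter_chrom),
      summit = c(intra_summit, down_summit, inter_summit),
      planted_category = rep(c("intragenic", "downstream", "intergenic"),
                             c(n_intra, n_down, n_inter)),
      gene_id = c(intra_hosts$gene_id, down_hosts$gene_id,
                  rep(NA_character_, n_inter))
    )
    shared_base <- draw_amp(nrow(shared))
    shared$amp_wt <- pmax(1, round(shared_base * jit(nrow(shared))))
    shared$amp_ko <- pmax(1, round(shared_base * jit(nrow(shared))))

    all_peaks <- bind_rows(tss_peaks, shared)

    build_set <- function(amp, genotype) {
      keep <- amp > 0
      p <- all_peaks[keep, ]
      out <- tibble(
        peak_id = sprintf("%s_p%04d", genotype, seq_len(nrow(p))),
        chrom = p$chrom,
        start = as.integer(p$summit - half),
        end = as.integer(p$summit + half),
        summit = as.integer(p$summit),
        amplitude = as.numeric(amp[keep]),
        p_value = NA_real_,
        score = NA_real_,
        planted_category = p$planted_category,
        gene_id = p$gene_id
      )
      out$cpg_flag <- overlaps_any(out, annotation$cpg_islands)
      new_peak_set(out, genotype = genotype)
    }
    peaks_wt <- build_set(all_peaks$amp_wt, "wt")
    peaks_ko <- build_set(all_peaks$amp_ko, "ko")

    truth_genes <- tibble(
      gene_id = genes$gene_id,
      enrichment_status = status,
      amp_wt = as.numeric(amp_wt),
      amp_ko = as.numeric(amp_ko),
      de_status = NA_character_
    )
    truth_peaks <- bind_rows(
      peaks_wt |> mutate(genotype = "wt"),
      peaks_ko |> mutate(genotype = "ko")
    ) |> select("peak_id", "genotype", "planted_category", "cpg_flag")
    truth <- structure(list(genes = truth_genes, peaks = truth_peaks,
                            config = config),
                       class = "truth_table")

    list(peaks_wt = peaks_wt, peaks_ko = peaks_ko, truth = truth)
  })
}

snap_to_bin_centre <- function(pos, step) {
  half <- step %/% 2L
  as.integer(round((pos - half) / step) * step + half)
}

# TRUE for rows of `x` whose [start, end) interval overlaps any island by >= 1 bp.
overlaps_any <- function(x, islands) {
  if (nrow(x) == 0) return(logical(0))
  purrr::map_lgl(seq_len(nrow(x)), function(i) {
    isl <- islands[islands$chrom == x$chrom[i], ]
    any(isl$start < x$end[i] & isl$end > x$start[i])
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table>\n")
  print(dplyr::count(x$genes, .data$enrichment_status))
  invisible(x)
}
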