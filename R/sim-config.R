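#' Configuration for the synthetic two-genotype ChIP-seq generator
#'
#' Bundles every tunable of the synthetic-data module into a validated list.
#' The defaults describe the study conditions the rest of the package is
#' exercised against: a single 10-Mb chromosome carrying 300 well-separated
#' genes, a peak landscape whose genomic-context mix matches the proportions
#' typical of H3K4me3 (74.1% upstream of a TSS, 6.3% intragenic, 8.3%
#' downstream of a TES, 11.3% intergenic), lognormal peak amplitudes with
#' median 30, and planted differential sites: genes enriched in only one
#' genotype ("unique") and genes with a fold difference in amplitude
#' ("preferential").
#'
#' @param n_chromosomes Number of chromosomes (default 1).
#' @param chrom_length Length of each chromosome in bp (default 1e7).
#' @param n_genes Number of genes to place (default 300).
#' @param gene_length_range Two-element bp range for gene lengths
#'   (default c(2000, 8000)).
#' @param cpg_at_tss_fraction Fraction of TSSs covered by a CpG island
#'   (+/-500 bp; default 0.9).
#' @param intergenic_cpg_fraction Fraction of intergenic peaks planted on a
#'   CpG island (default 0.401).
#' @param category_mix Named proportions over upstream/intragenic/downstream/
#'   intergenic peak categories; must sum to 1.
#' @param amplitude_meanlog,amplitude_sdlog Lognormal parameters of the peak
#'   amplitude distribution (defaults log(30) and 0.3: median 30).
#' @param n_unique_wt,n_unique_ko Genes with a TSS peak in only one genotype.
#' @param n_preferential_wt,n_preferential_ko Genes with a planted amplitude
#'   fold difference favouring that genotype.
#' @param preferential_fold Planted amplitude ratio for preferential genes
#'   (>= 2; default 3).
#' @param amplitude_jitter Half-width of the multiplicative log-uniform jitter
#'   applied independently per genotype to shared amplitudes (default 0.10;
#'   0 disables jitter).
#' @param de_concordance Fraction of differentially enriched genes that are
#'   also differentially expressed in the matching direction (default 0.17).
#' @param n_de_background Additional differentially expressed genes drawn from
#'   the non-differential pool, split between directions (default 60).
#' @param n_intergenic_islands Number of intergenic CpG islands to place;
#'   default `ceiling(0.15 * n_genes)`.
#' @param reads_per_condition Background (input-like) reads per condition
#'   (default 5000).
#' @param fragment_extension Fragment extension in bp applied to every read
#'   (default 300).
#' @param bin_step Fixed-step bin width in bp of the coverage tracks
#'   (default 50).
#' @param seed Integer seed; together with the config it fully determines
#'   every generator output.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, chrom_length = 2e6, seed = 1)
#' cfg$category_mix
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 1e7,
                       n_genes = 300L,
                       gene_length_range = c(2000L, 8000L),
                       cpg_at_tss_fraction = 0.9,
                       intergenic_cpg_fraction = 0.401,
                       category_mix = c(upstream = 0.741, intragenic = 0.063,
                                        downstream = 0.083, intergenic = 0.113),
                       amplitude_meanlog = log(30),
                       amplitude_sdlog = 0.3,
                       n_unique_wt = 10L,
                       n_unique_ko = 10L,
                       n_preferential_wt = 15L,
                       n_preferential_ko = 15L,
                       preferential_fold = 3,
                       amplitude_jitter = 0.10,
                       de_concordance = 0.17,
                       n_de_background = 60L,
                       n_intergenic_islands = NULL,
                       reads_per_condition = 5000L,
                       fragment_extension = 300L,
                       bin_step = 50L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    cpg_at_tss_fraction = cpg_at_tss_fraction,
    intergenic_cpg_fraction = intergenic_cpg_fraction,
    category_mix = category_mix,
    amplitude_meanlog = amplitude_meanlog,
    amplitude_sdlog = amplitude_sdlog,
    n_unique_wt = as.integer(n_unique_wt),
    n_unique_ko = as.integer(n_unique_ko),
    n_preferential_wt = as.integer(n_preferential_wt),
    n_preferential_ko = as.integer(n_preferential_ko),
    preferential_fold = preferential_fold,
    amplitude_jitter = amplitude_jitter,
    de_concordance = de_concordance,
    n_de_background = as.integer(n_de_background),
    n_intergenic_islands = if (is.null(n_intergenic_islands)) {
      as.integer(ceiling(0.15 * n_genes))
    } else {
      as.integer(n_intergenic_islands)
    },
    reads_per_condition = as.integer(reads_per_condition),
    fragment_extension = as.integer(fragment_extension),
    bin_step = as.integer(bin_step),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$cpg_at_tss_fraction, cfg$intergenic_cpg_fraction,
             cfg$de_concordance, cfg$amplitude_jitter)
  if (any(props < 0 | props > 1)) {
    abort("all proportions must lie in [0, 1]", class = "enrichdiff_bad_config")
  }
  mix <- cfg$category_mix
  needed <- c("upstream", "intragenic", "downstream", "intergenic")
  if (!all(needed %in% names(mix))) {
    abort("category_mix must name upstream, intragenic, downstream, intergenic",
          class = "enrichdiff_bad_config")
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    abort("category_mix must sum to 1 within 1e-9", class = "enrichdiff_bad_config")
  }
  if (any(mix < 0)) abort("category_mix must be non-negative", class = "enrichdiff_bad_config")
  n_special <- cfg$n_unique_wt + cfg$n_unique_ko +
    cfg$n_preferential_wt + cfg$n_preferential_ko
  if (n_special > cfg$n_genes) {
    abort("n_unique_* + n_preferential_* must not exceed n_genes",
          class = "enrichdiff_bad_config")
  }
  if (cfg$preferential_fold < 2) {
    abort("preferential_fold must be >= 2", class = "enrichdiff_bad_config")
  }
  if (cfg$gene_length_range[1] > cfg$gene_length_range[2] ||
      cfg$gene_length_range[1] < 200L) {
    abort("gene_length_range must be an increasing pair with minimum >= 200 bp",
          class = "enrichdiff_bad_config")
  }
  if (cfg$bin_step <= 0L || cfg$fragment_extension <= 0L ||
      cfg$fragment_extension %% cfg$bin_step != 0L) {
    abort("fragment_extension must be a positive multiple of bin_step",
          class = "enrichdiff_bad_config")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %.3g bp, %d genes\n",
              x$n_chromosomes, x$chrom_length, x$n_genes))
  cat(sprintf("  planted: %d/%d unique, %d/%d preferential (fold %.3g) wt/ko\n",
              x$n_unique_wt, x$n_unique_ko,
              x$n_preferential_wt, x$n_preferential_ko, x$preferential_fold))
  cat(sprintf("  mix: %s\n",
              paste(sprintf("%s %.1f%%", names(x$category_mix),
                            100 * x$category_mix), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Write or read a simulation config as a flat key=value file
#'
#' Vector-valued fields are comma-separated. Round-trips through
#' [read_sim_config()].
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- purrr::map_chr(unclass(config), function(v) {
    if (!is.null(names(v))) {
      paste(sprintf("%s:%s", names(v), format(v, digits = 15)), collapse = ",")
    } else {
      paste(format(v, digits = 15), collapse = ",")
    }
  })
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- purrr::map_chr(kv, 1)
  vals <- purrr::map(kv, function(p) {
    parts <- strsplit(p[[2]], ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      sub <- strsplit(parts, ":", fixed = TRUE)
      setNames(as.numeric(purrr::map_chr(sub, 2)), purrr::map_chr(sub, 1))
    } else {
      as.numeric(parts)
    }
  })
  do.call(sim_config, setNames(vals, keys))
}
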