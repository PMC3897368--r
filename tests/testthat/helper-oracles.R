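# Independent oracles and small fixtures shared across tests.

# Brute-force upper-tail Poisson mass P(X >= k; lambda): direct summation of
# exp(i*log(lambda) - lgamma(i+1) - lambda) until the terms vanish.
pois_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  i <- seq(k, k + 2000)
  sum(exp(i * log(lambda) - lgamma(i + 1) - lambda))
}

# Quadratic-scan classifier: for every peak, scan every gene on its
# chromosome and apply the strand-aware window rules with priority
# upstream > intragenic > downstream > intergenic.
classify_oracle <- function(peaks, annotation, window = 2000L) {
  genes <- annotation$genes
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    g <- genes[genes$chrom == peaks$chrom[i], ]
    plus <- g$strand == "+"
    intra <- any(s >= g$start & s < g$end)
    up <- any((plus & s < g$tss & g$tss - s <= window) |
                (!plus & s > g$tss & s - g$tss <= window))
    down <- any((plus & s > g$tes & s - g$tes <= window) |
                  (!plus & s < g$tes & g$tes - s <= window))
    if (up) "upstream" else if (intra) "intragenic" else if (down) "downstream" else "intergenic"
  }, character(1))
}

# All-pairs gene-calling scan: a gene is called when any peak interval comes
# within `window` bp of its TSS (inclusive).
call_genes_oracle <- function(peaks, annotation, window = 1000L) {
  genes <- annotation$genes
  called <- vapply(seq_len(nrow(genes)), function(j) {
    p <- peaks[peaks$chrom == genes$chrom[j], ]
    if (nrow(p) == 0) return(FALSE)
    d <- pmax(0, p$start - genes$tss[j], genes$tss[j] - (p$end - 1))
    any(d <= window)
  }, logical(1))
  sort(genes$gene_id[called])
}

# Full-permutation two-sided Mann-Whitney p-value via bitmask enumeration of
# every subset of the pooled values of size n_x (independent of the
# implementation's combn-over-ranks path).
mw_permutation_oracle <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  mu <- nx * (n + 1) / 2
  w_obs <- sum(r[seq_len(nx)])
  w_all <- c()
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[1:n]
    if (sum(bits) == nx) w_all <- c(w_all, sum(r[bits == 1]))
  }
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Small deterministic genome/landscape fixture used by several files.
tiny_config <- function(seed = 7, ...) {
  defaults <- list(n_genes = 40, chrom_length = 2.5e6, n_unique_wt = 3,
                   n_unique_ko = 2, n_preferential_wt = 4,
                   n_preferential_ko = 3, n_de_background = 10,
                   reads_per_condition = 1500, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# A hand-built annotation with one + and one - strand gene, handy for
# boundary tests. Gene A: chr1 [10000, 16000) on "+" (TSS 10000);
# gene B: chr1 [40000, 46000) on "-" (TSS 45999).
toy_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("geneA", "geneB"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(10000L, 40000L),
    end = c(16000L, 46000L)
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  structure(list(
    chromosomes = tibble::tibble(chrom = "chr1", length = 1e5),
    genes = genes,
    cpg_islands = tibble::tibble(island_id = "cpg0001", chrom = "chr1",
                                 start = 9500L, end = 10501L, context = "tss")
  ), class = "genome_annotation")
}

toy_peak <- function(summit, chrom = "chr1", amplitude = 20, id = "p1") {
  as_peak_set(tibble::tibble(
    peak_id = id, chrom = chrom, start = summit - 150L, end = summit + 150L,
    summit = as.integer(summit), amplitude = amplitude,
    p_value = 1e-8, score = 80
  ))
}
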