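# enrichdiff

Differential histone-mark enrichment analysis for two-genotype ChIP-seq, at
desk scale.

H3K4me3 marks the promoters of active genes in narrow, TSS-centred peaks.
Comparing its genome-wide distribution between two genotypes — say wild-type
pancreatic acinar cells and a knockout with chronic cellular stress — asks a
chain of small, well-defined questions: which regions are enriched over
input, where do those peaks sit relative to genes and CpG islands, which
genes are "called" as enriched, which genes differ between genotypes, and do
those differences track gene expression? `enrichdiff` implements that whole
chain as composable, tibble-in/tibble-out functions, plus a seeded synthetic
data generator with planted ground truth so every stage can be verified
end-to-end without touching a sequencing archive.

## The core methods

* **Peak calling** — a simplified MACS-style window-Poisson test on 50-bp
  fixed-step pileup bins. The input track is scaled to the treatment depth;
  each bin's rate is λ = max(scaled control mean over 1 kb, over 10 kb,
  genome-wide), the p-value is the Poisson upper tail P(X ≥ k; λ), peaks
  are merged significant bins (p ≤ 1e−5) at least 300 bp long, and each
  carries a summit, an amplitude (max pileup) and a score −10·log₁₀(p).
* **Annotation** — strand-aware summit classification into
  upstream (≤ 2 kb 5′ of a TSS) / intragenic / downstream (≤ 2 kb 3′ of a
  TES) / intergenic, CpG-island overlap fractions, chromosome-normalised
  densities, and metagene profiles (5-kb flanks, rescaled body).
* **Differential enrichment** — gene calling (a peak within 1 kb of the
  TSS), *unique* genes (called in exactly one genotype), and *preferential*
  genes (matched peak pair near the gene with amplitude ratio ≥ 2 and larger
  amplitude ≥ 10).
* **Expression integration** — DE criterion fold ≥ 1.5 with p < 0.01,
  direction-concordant overlaps with the enrichment sets, plain gene-list
  export.
* **Bench arithmetic** — ChIP-qPCR percent-of-input (dilution-corrected),
  ΔΔCt relative expression, exact-permutation Mann-Whitney and Welch t tests
  with Bonferroni adjustment.

See `vignettes/differential-enrichment-methods.Rmd` for the full model,
parameter meanings and design decisions.

## Worked example

Simulate a two-genotype landscape, call peaks against the matched inputs,
and recover the planted differential genes:

```r
library(enrichdiff)

cfg  <- sim_config(seed = 42)          # 10-Mb chromosome, 300 genes,
ann  <- generate_genome(cfg)           # 10+10 unique, 15+15 preferential
land <- generate_peak_landscapes(ann, cfg)

cov_wt <- generate_coverage_tracks(land$peaks_wt, cfg)
cov_ko <- generate_coverage_tracks(land$peaks_ko, cfg)
peaks_wt <- call_peaks(cov_wt$treatment, cov_wt$control)
peaks_ko <- call_peaks(cov_ko$treatment, cov_ko$control)
head(peaks_wt, 3)
#> # A tibble: 3 × 8
#>   peak_id    chrom start   end summit amplitude  p_value score
#>   <chr>      <chr> <int> <int>  <int>     <dbl>    <dbl> <dbl>
#> 1 peak_00001 chr1   1900  2200   1900        21 2.15e-22  217.
#> 2 peak_00002 chr1  16950 17250  17050        25 4.47e-33  323.
#> 3 peak_00003 chr1  37200 37500  37200        23 1.63e-26  258.
```

Each row is one enrichment interval; the amplitude is the maximum pileup
(here ≈ the planted amplitude), and a score of 217 means the summit bin's
Poisson p-value is 10^(−21.7). Where do the peaks fall?

```r
category_fractions(classify_peaks(peaks_wt, ann))
#> # A tibble: 4 × 4
#>   category       n fraction percent
#> 1 upstream     290   0.734     73.4
#> 2 intragenic    26   0.0658     6.6
#> 3 downstream    34   0.0861     8.6
#> 4 intergenic    45   0.114     11.4
```

— the TSS-dominated distribution typical of this mark (the generator plants
74.1 / 6.3 / 8.3 / 11.3%). The two-tier differential call and its summary:

```r
dc <- preferential_enrichment(peaks_wt, peaks_ko, ann)
summarize_differential(dc, peaks_wt, peaks_ko)
#>    metric                     value
#>  1 called_genes_wt            290
#>  2 called_genes_ko            290
#>  3 called_gene_difference_pct   0
#>  6 unique_wt_pct                3.4
#>  8 differential_wt             25
#> 10 differential_wt_pct          8.6
#> ...
```

All 10 + 10 planted unique and 15 + 15 planted preferential genes are
recovered (`dc$status` matches `land$truth$genes` exactly at jitter 0). The
QC arithmetic works directly on published count tables:

```r
compute_qc_stats(12000000, 35624, 10836399, 9244322, sample = "wt_h3k4me3")
#>   sample     ... clean_rate mapped_rate unique_mapped_rate
#> 1 wt_h3k4me3 ...       99.7       90.57              77.27
```

`autoplot()` / `plot_*()` functions draw the metagene profile, category
bars, chromosome densities and overlap charts; `tidy()`/`glance()` reshape
summaries broom-style.

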