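---
title: "Methods: differential H3K4me3 enrichment between two genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential H3K4me3 enrichment between two genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichdiff)
library(dplyr)
```

# The analysis

H3K4me3 is a histone modification that concentrates in narrow domains around
the transcription start sites (TSSs) of active genes, which makes it a good
readout for comparing the promoter state of two related tissues. This package
implements a complete desk-scale pipeline for that comparison between two
genotypes (labelled `wt` and `ko` throughout, after the wild-type vs knockout
design it models):

1. **Read-quality arithmetic** (`compute_qc_stats()`): the standard
   post-sequencing table — clean rate, mapped rate, unique mapped rate — from
   raw counts.
2. **Peak calling** (`call_peaks()`): a simplified MACS-style window-Poisson
   caller over paired treatment/input coverage in fixed-step (50 bp) wiggle
   bins.
3. **Genomic-context annotation** (`classify_peaks()`, `cpg_association()`,
   `chromosome_distribution()`, `metagene_profile()`): where peaks sit
   relative to genes and CpG islands.
4. **Gene calling and differential logic** (`call_genes()`,
   `unique_genes()`, `preferential_enrichment()`): which genes are enriched,
   and which differ between genotypes.
5. **Expression integration** (`call_differential_expression()`,
   `intersect_enrichment_expression()`): how enrichment differences relate to
   a precomputed differential-expression table.
6. **Bench-validation arithmetic** (`percent_of_input()`,
   `relative_expression()`, `compare_groups()`): ChIP-qPCR and qRT-PCR
   quantification and the matching group tests.

A seeded synthetic-data generator (`sim_config()`, `generate_genome()`,
`generate_peak_landscapes()`, `generate_coverage_tracks()`,
`generate_expression_table()`) produces inputs with known ground truth so the
whole pipeline can be exercised and verified on a laptop, without any
sequencing archive.

# The peak-calling model

Coverage is binned pileup sampled every 50 bp (`step = span`, the fixed-step
wiggle dialect), from 49-bp tags extended to 300 bp fragments. The control
(input) track is scaled to the treatment depth by the linear factor
$N_t/N_c$. For each bin with treatment count $k$ the local Poisson rate is

$$\lambda = \max(\bar c_{1\,\mathrm{kb}},\ \bar c_{10\,\mathrm{kb}},\ \bar c_{\mathrm{genome}}),$$

the scaled control mean over centred 1-kb and 10-kb windows and over the
whole genome. The local-maximum construction follows the dynamic-background
idea of MACS-type callers; the genome-wide floor prevents zero rates in
unsequenced regions. The bin p-value is the upper Poisson tail
$P(X \ge k;\lambda)$; bins with $p \le 10^{-5}$ are merged across gaps of at
most one bin (fixed-step quantisation otherwise fragments single summits),
and peaks shorter than 300 bp (the fragment extension) are dropped. Each peak
reports its summit (argmax bin), amplitude (maximum pileup), p-value at the
summit, and score $-10\log_{10} p$, capped at 3100 when $p$ underflows double
precision (the cap is configurable).

Deliberately **not** implemented: MACS's fragment-size model built from
mfold-bounded candidate regions. The extension length is a configuration
value instead; the `mfold` bounds are accepted and echoed into the run log,
and the caller warns when no region exceeds `mfold_low`. A `bandwidth`
parameter is likewise accepted and flagged as unused rather than silently
dropped. Duplicate filtering, paired-end input, and swap-based FDR are out of
scope.

Numerical choices: p-values are computed in log space (`ppois(..., log.p =
TRUE)`), so scores are exact even where $p$ underflows; the score cap applies
only to the reported score. Poisson tail values were verified against direct
summation of the mass function to $10^{-12}$ relative error.

# Annotation rules

Classification is **summit-based** and strand-aware, with priority
`upstream > intragenic > downstream > intergenic`:

* *upstream*: summit within 2 kb 5' of any TSS (inclusive);
* *intragenic*: summit inside any gene body;
* *downstream*: summit within 2 kb 3' of any TES (inclusive);
* *intergenic*: everything else — with equal window sizes this coincides
  with "at least 2 kb from every annotated gene interval".

The summit was chosen as the classified point because it is the visual "peak
location", and it makes the four categories mutually exclusive and
exhaustive; the reported `dist_to_gene` column lets users audit the distance
rule separately if they change the windows. The priority order resolves peaks
caught between a TES and the next gene's TSS in favour of TSS proximity,
because the TSS-proximal fraction is the analysis' headline statistic. This
tie-break is a declared design decision, not something the upstream analysis
specifies.

Gene calling uses the **peak interval**: a gene is called when a peak comes
within 1 kb of its TSS, boundaries inclusive ("within one kilobase" read as
$\le$). CpG association counts any overlap of at least 1 bp between the peak
interval and an island, which makes it invariant to island fragmentation.

# Differential logic

Two tiers, kept disjoint:

* **Unique** enrichment is presence/absence at the gene-call level: a gene
  called in exactly one genotype. A stricter reading — no overlapping peak
  anywhere near the gene — would shrink the sets; the call-set reading is
  implemented because uniqueness is defined over called genes.
* **Preferential** enrichment compares amplitudes: peaks are matched across
  genotypes when their intervals overlap or their summits fall within one
  bin (the original analysis matched peaks by eye, which has no formal rule;
  interval overlap is the obvious mechanisation). A matched pair within 1 kb
  of a gene's annotated interval (the gene body, deliberately distinct from
  the TSS rule above) makes the gene preferential when the amplitude ratio
  is at least 2 — inclusive, "at least two-fold" — and the larger amplitude
  is at least 10. When several pairs qualify for one gene the largest-ratio
  pair decides the direction.

Unique beats preferential for the same gene, so the five statuses partition
the gene set. Summary percentages are rounded half-up to one decimal,
matching how such tables are conventionally printed; `audit_published_counts()`
applies the same arithmetic to externally supplied counts.

# Expression integration

A gene is differentially expressed in the genotype where it is higher when
fold $\ge 1.5$ (inclusive) and $p < 0.01$ (strict) — the asymmetry mirrors
the wording "at least 1.5-fold" vs "P value < 0.01". Overlaps with the
enrichment sets enforce direction concordance: increased expression in a
genotype only counts against enrichment in that same genotype. Microarray
preprocessing is out of scope; the expression table is consumed as given.

# qPCR arithmetic

Percent of input corrects the input Ct for the chromatin fraction used
($\mathrm{Ct}_{\mathrm{adj}} = \overline{\mathrm{Ct}}_{\mathrm{input}} -
\log_E(1/f)$, $E$ the per-cycle efficiency, $f$ the input fraction) and
reports $100\,E^{\mathrm{Ct}_{\mathrm{adj}} - \overline{\mathrm{Ct}}_{\mathrm{chip}}}$
separately for the ChIP and IgG channels; IgG is displayed, never
subtracted. The input fraction has no default because assuming $f = 1$
silently inflates recoveries by orders of magnitude. Efficiency defaults to
2 (perfect doubling) and is configurable rather than estimated — no standard
curves are modelled. Relative expression uses the standard ΔΔCt model with a
required reference gene and calibrator condition; the calibrator's
geometric-mean fold is 1 by construction. Group comparisons use an
exact-permutation Mann-Whitney test (full enumeration up to a combined n of
12, tie-corrected normal approximation above) or Welch's t, with Bonferroni
adjustment `min(1, p * m)`.

# The synthetic-data generator

The generator emulates the *called-peak landscape* of a promoter mark in two
genotypes, not raw sequencing: no FASTQ reads, alignment, duplicates,
mappability, or broad-domain marks.

**Genome.** `n_genes` (default 300) non-overlapping genes of 2–8 kb on a
10-Mb chromosome, at least 5 kb apart so every 2-kb/1-kb window rule has an
unambiguous answer; strands random. CpG islands cover 90% of TSSs
(±500 bp) — promoter H3K4me3 is overwhelmingly CpG-associated — plus
intergenic islands for 40.1% of intergenic peaks.

**Peaks.** Every gene carries one TSS-proximal peak (summit 125–625 bp 5' of
the TSS); intragenic, downstream and intergenic peaks are added so the
emitted category mix matches the configured proportions (defaults 74.1 /
6.3 / 8.3 / 11.3%, the distribution reported for acinar-cell H3K4me3).
Amplitudes are lognormal with median 30; the dispersion (sdlog 0.3) was
fixed so that essentially every emitted peak sits above the caller's
detection limit — the generator's purpose is recovery testing of the
*differential* logic, so detectability must not be the varying quantity.
For the same reason planted unique amplitudes are floored at 12 and
preferential smaller-side amplitudes drawn from 12–20 (their larger side,
`preferential_fold` times that, is always ≥ 10, the reporting threshold the
differential rule uses). Shared peaks get amplitudes equal across genotypes
up to a ±10% log-uniform jitter (0 for exact-recovery runs); at the default
fold of 3 the jitter never pushes a planted ratio below the 2-fold call
threshold, which is why those defaults were chosen together.

**Coverage.** Each planted peak of amplitude $a$ contributes $\mathrm{round}(a)$
fragments whose centres are stratified-sampled within ±20 bp of the summit,
which itself sits at a bin centre. With 300-bp fragments this yields exactly
six full-height bins — a 300-bp plateau whose pileup equals the amplitude —
so a peak's length never falls below the caller's minimum by sampling
accident, and the measured amplitude reproduces the planted one up to
background. Background is uniform: 5000 fragments per condition (≈0.15 per
bin), added to the treatment and forming the entire control. This is sparser
than a real input library, matching the high signal concentration of a
sharply-peaked mark at this genome size.

**Expression.** A configurable fraction (default 0.17) of differentially
enriched genes get a concordant DE record (fold ≥ 1.5, p < 0.01); 60
background DE genes come from the non-differential pool, emulating the
empirically weak coupling between promoter-mark differences and steady-state
expression. Null genes get lognormal folds (sd 0.1 on the log scale) that
essentially never cross the DE threshold.

**Determinism.** One global seed; each component draws from a stream at a
fixed offset, so adding a generator never perturbs earlier ones. Identical
configs produce byte-identical BED/WIG/TSV serialisations.

**What passing tests do and do not show.** Exact truth recovery on this
landscape demonstrates that the calling, matching and threshold logic is
implemented correctly, with margins as analysed above. It does not
demonstrate performance on real data, where peak widths vary, amplitudes are
not plateaued, backgrounds are non-uniform, genes overlap, and the
visual-scan step being mechanised had human judgement in it.

# Problem sizes

The shipped tests and the acceptance script run the pipeline at one 10-Mb
chromosome × 300 genes (200,000 bins per track) for recovery, 1,000 random
peaks × 300 genes × 20 seeds for the classification oracles, and five 10-Mb
chromosomes (10⁶ bins) for the null-track type-I check — sizes chosen so a
full verification completes in minutes on a single core while keeping every
count large enough for the binomial-bound checks to bite.

# Known limitations

* The caller assumes fixed-step tracks with a single step size; variable-step
  data must be re-binned upstream.
* Peak matching across genotypes is geometric; biologically linked but
  shifted peaks (> 1 bin apart, non-overlapping) are treated as unmatched.
* `percent_of_input()` needs the true input fraction; published bar charts
  that omit it cannot be reproduced, only re-plotted in shape.
* The generator's plateau-shaped peaks are idealised; callers tuned on it
  will look better than they are on ragged real pileups.
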