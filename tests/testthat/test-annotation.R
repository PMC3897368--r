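test_that("single-peak classification follows the strand-aware window rules", {
  ann <- toy_annotation()
  # 500 bp 5' of the + strand TSS (gene A at 10000) -> upstream
  expect_equal(classify_peaks(toy_peak(9500), ann)$category, "upstream")
  # mid-gene -> intragenic
  expect_equal(classify_peaks(toy_peak(13000), ann)$category, "intragenic")
  # 1.5 kb 3' of the + strand TES (15999) -> downstream
  expect_equal(classify_peaks(toy_peak(17499), ann)$category, "downstream")
  # 3 kb from every gene -> intergenic
  expect_equal(classify_peaks(toy_peak(25000), ann)$category, "intergenic")
  # minus-strand gene B (TSS 45999): 500 bp 5' is at 46499
  expect_equal(classify_peaks(toy_peak(46499), ann)$category, "upstream")
  # minus-strand downstream: 1 kb 3' of TES (40000) is at 39000
  expect_equal(classify_peaks(toy_peak(39000), ann)$category, "downstream")
  # exactly 2000 bp 5' of gene A counts as upstream (inclusive window)
  expect_equal(classify_peaks(toy_peak(8000), ann)$category, "upstream")
  # 2001 bp away is intergenic
  expect_equal(classify_peaks(toy_peak(7999), ann)$category, "intergenic")
})

test_that("unknown chromosomes in peaks raise a mapping error listing them", {
  err <- expect_error(classify_peaks(toy_peak(500, chrom = "chrX"), toy_annotation()),
                      class = "enrichdiff_mapping_error")
  expect_match(conditionMessage(err), "chrX")
})

test_that("classification equals the quadratic-scan oracle on random landscapes", {
  cfg <- sim_config(n_genes = 120, chrom_length = 4e6, n_chromosomes = 2, seed = 31)
  ann <- generate_genome(cfg)
  for (seed in c(1, 2, 3)) {
    peaks <- withr::with_seed(seed, {
      n <- 400
      summit <- snapped <- sort(sample.int(4e6 - 400, n)) + 150L
      as_peak_set(tibble::tibble(
        peak_id = sprintf("r%03d", seq_len(n)),
        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        start = summit - 150L, end = summit + 150L, summit = summit,
        amplitude = 10, p_value = 1e-8, score = 80))
    })
    impl <- classify_peaks(peaks, ann)$category
    expect_equal(impl, classify_oracle(peaks, ann))
  }
})

test_that("category fractions sum to one and cover all four categories", {
  cfg <- tiny_config(seed = 44)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  fr <- category_fractions(classify_peaks(land$peaks_ko, ann))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  expect_setequal(fr$category, c("upstream", "intragenic", "downstream", "intergenic"))
})

test_that("cpg association hits the trivial extremes", {
  ann <- toy_annotation()
  inside <- toy_peak(10000) # overlaps the TSS island
  expect_equal(cpg_association(inside, ann)$percent, 100)
  outside <- toy_peak(30000)
  expect_equal(cpg_association(outside, ann)$percent, 0)
  both <- as_peak_set(dplyr::bind_rows(toy_peak(10000),
                                       toy_peak(30000, id = "p2")))
  expect_equal(cpg_association(both, ann)$percent, 50)
})

test_that("cpg association is invariant to peak order and island fragmentation", {
  cfg <- tiny_config(seed = 52)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  base <- cpg_association(land$peaks_wt, ann)
  shuffled <- land$peaks_wt[withr::with_seed(1, sample(nrow(land$peaks_wt))), ]
  expect_equal(cpg_association(shuffled, ann)$percent, base$percent)
  isl <- ann$cpg_islands
  mid <- as.integer((isl$start + isl$end) %/% 2)
  split_isl <- dplyr::bind_rows(
    dplyr::mutate(isl, end = mid),
    dplyr::mutate(isl, start = mid))
  split_isl <- split_isl[split_isl$end > split_isl$start, ]
  expect_equal(cpg_association(land$peaks_wt, split_isl)$n_overlapping,
               base$n_overlapping)
})

test_that("planted genome-wide and intergenic cpg fractions are recovered within binomial bounds", {
  cfg <- sim_config(seed = 42)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  cls <- classify_peaks(land$peaks_wt, ann)
  truth_flags <- land$truth$peaks[land$truth$peaks$genotype == "wt", ]
  # measured association equals the planted flags exactly
  measured <- cpg_association(cls, ann)
  expect_equal(measured$n_overlapping, sum(truth_flags$cpg_flag))
  # intergenic association close to the configured rate
  inter <- cpg_association(cls, ann, category_filter = "intergenic")
  n <- inter$n_peaks
  ci <- stats::qbinom(c(0.005, 0.995), n, cfg$intergenic_cpg_fraction) / n
  expect_gte(inter$n_overlapping / n, ci[1])
  expect_lte(inter$n_overlapping / n, ci[2])
})

test_that("an empty filtered set signals an undefined fraction rather than 0", {
  expect_error(cpg_association(classify_peaks(toy_peak(13000), toy_annotation()),
                               toy_annotation(), category_filter = "intergenic"),
               class = "enrichdiff_undefined_fraction")
})

test_that("chromosome densities normalise to length and keep empty chromosomes", {
  peaks <- as_peak_set(dplyr::bind_rows(
    purrr::map(seq_len(10), function(i) toy_peak(1000 * i + 500, id = sprintf("p%d", i)))))
  lens <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e7, 2e6))
  d <- chromosome_distribution(peaks, lens)
  expect_equal(d$density_per_mb[d$chrom == "chr1"], 1.0)
  expect_equal(d$n_peaks[d$chrom == "chr2"], 0)
  expect_equal(d$density_per_mb[d$chrom == "chr2"], 0)
  expect_error(chromosome_distribution(peaks, tibble::tibble(chrom = "chr2", length = 1e6)),
               class = "enrichdiff_mapping_error")
  empty <- peaks[0, ]
  expect_true(all(chromosome_distribution(empty, lens)$density_per_mb == 0))
})

test_that("uniform peak placement gives near-equal densities on equal chromosomes", {
  lens <- tibble::tibble(chrom = sprintf("chr%d", 1:4), length = rep(5e6, 4))
  peaks <- withr::with_seed(99, as_peak_set(tibble::tibble(
    peak_id = sprintf("p%04d", 1:2000),
    chrom = sample(lens$chrom, 2000, replace = TRUE),
    summit = sample.int(5e6 - 400, 2000) + 150L) |>
      dplyr::mutate(start = summit - 150L, end = summit + 150L,
                    amplitude = 10, p_value = NA_real_, score = NA_real_)))
  d <- chromosome_distribution(peaks, lens)
  expected <- 2000 / 4
  expect_true(all(abs(d$n_peaks - expected) < 3 * sqrt(expected)))
})
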