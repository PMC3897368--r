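test_that("gene calling honours the inclusive 1-kb TSS boundary", {
  ann <- toy_annotation()
  # gene A TSS at 10000; a peak whose last base sits exactly 1000 bp away
  p_at_1000 <- as_peak_set(tibble::tibble(
    peak_id = "b1", chrom = "chr1", start = 8700L, end = 9001L, summit = 8850L,
    amplitude = 15, p_value = 1e-8, score = 80))
  calls <- call_genes(p_at_1000, ann)
  expect_true("geneA" %in% calls$gene_id)
  expect_equal(calls$distance[calls$gene_id == "geneA"], 1000)
  p_at_1001 <- as_peak_set(tibble::tibble(
    peak_id = "b2", chrom = "chr1", start = 8700L, end = 9000L, summit = 8850L,
    amplitude = 15, p_value = 1e-8, score = 80))
  expect_false("geneA" %in% call_genes(p_at_1001, ann)$gene_id)
})

test_that("called-gene sets equal the all-pairs distance scan on random landscapes", {
  cfg <- sim_config(n_genes = 150, chrom_length = 5e6, seed = 61)
  ann <- generate_genome(cfg)
  for (seed in c(4, 5)) {
    peaks <- withr::with_seed(seed, {
      n <- 500
      summit <- sample.int(5e6 - 400, n) + 150L
      as_peak_set(tibble::tibble(
        peak_id = sprintf("r%03d", seq_len(n)), chrom = "chr1",
        start = summit - 150L, end = summit + 150L, summit = summit,
        amplitude = 10, p_value = 1e-8, score = 80))
    })
    expect_equal(sort(call_genes(peaks, ann)$gene_id),
                 call_genes_oracle(peaks, ann))
  }
})

test_that("unique gene partition obeys set arithmetic", {
  same <- tibble::tibble(gene_id = c("a", "b"), peak_id = "p", distance = 0,
                         amplitude = 10)
  u <- unique_genes(same, same)
  expect_equal(sum(u$set == "unique_wt"), 0)
  expect_equal(sum(u$set == "unique_ko"), 0)
  expect_setequal(u$gene_id[u$set == "shared"], c("a", "b"))
  disjoint_ko <- tibble::tibble(gene_id = c("c"), peak_id = "p", distance = 0,
                                amplitude = 10)
  u2 <- unique_genes(same, disjoint_ko)
  expect_equal(sum(u2$set == "shared"), 0)
  expect_setequal(u2$gene_id[u2$set == "unique_wt"], c("a", "b"))
  # |unique_wt| + |shared| = |calls_wt|
  expect_equal(sum(u2$set %in% c("unique_wt", "shared")), nrow(same))
})

test_that("preferential rule instances behave at and around the thresholds", {
  ann <- toy_annotation()
  mk <- function(amp, id) toy_peak(9500, amplitude = amp, id = id)
  check <- function(amp_wt, amp_ko, expected) {
    dc <- preferential_enrichment(mk(amp_wt, "w"), mk(amp_ko, "k"), ann)
    expect_equal(dc$status[dc$gene_id == "geneA"], expected)
  }
  check(25, 10, "preferential_wt")   # ratio 2.5, max >= 10
  check(18, 9, "preferential_wt")    # ratio exactly 2 counts (inclusive)
  check(8, 3, "unchanged")           # max < 10
  check(30, 20, "unchanged")         # ratio 1.5 < 2
  check(10, 25, "preferential_ko")   # symmetric direction
})

test_that("swapping genotype labels swaps the statuses exactly", {
  cfg <- tiny_config(seed = 71)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  fwd <- preferential_enrichment(land$peaks_wt, land$peaks_ko, ann)
  rev <- preferential_enrichment(land$peaks_ko, land$peaks_wt, ann)
  swap <- c(unique_wt = "unique_ko", unique_ko = "unique_wt",
            preferential_wt = "preferential_ko",
            preferential_ko = "preferential_wt", unchanged = "unchanged")
  expect_equal(rev$status, unname(swap[fwd$status]))
  expect_equal(rev$amp_wt, fwd$amp_ko)
})

test_that("raising amp_min or fold_min never increases the preferential count", {
  cfg <- tiny_config(seed = 72, amplitude_jitter = 0.1)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  n_pref <- function(fold, amp) {
    dc <- preferential_enrichment(land$peaks_wt, land$peaks_ko, ann,
                                  fold_min = fold, amp_min = amp)
    sum(grepl("^preferential", dc$status))
  }
  expect_true(n_pref(2, 10) >= n_pref(2.5, 10))
  expect_true(n_pref(2.5, 10) >= n_pref(3.5, 10))
  expect_true(n_pref(2, 10) >= n_pref(2, 25))
  expect_true(n_pref(2, 25) >= n_pref(2, 60))
})

test_that("every annotated gene receives exactly one status and sets reconcile", {
  cfg <- tiny_config(seed = 73)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  dc <- preferential_enrichment(land$peaks_wt, land$peaks_ko, ann)
  expect_equal(nrow(dc), nrow(ann$genes))
  expect_equal(anyDuplicated(dc$gene_id), 0)
  expect_true(all(dc$status %in% c("unique_wt", "unique_ko", "preferential_wt",
                                   "preferential_ko", "unchanged")))
  calls_wt <- call_genes(land$peaks_wt, ann)
  u <- unique_genes(calls_wt, call_genes(land$peaks_ko, ann))
  expect_equal(sum(u$set == "unique_wt") + sum(u$set == "shared"), nrow(calls_wt))
})

test_that("with +/-10% jitter and fold 3, preferential recovery stays sharp", {
  cfg <- sim_config(seed = 42, amplitude_jitter = 0.1, preferential_fold = 3)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  dc <- preferential_enrichment(land$peaks_wt, land$peaks_ko, ann)
  truth <- land$truth$genes
  for (gt in c("wt", "ko")) {
    s <- paste0("preferential_", gt)
    planted <- truth$gene_id[truth$enrichment_status == s]
    found <- dc$gene_id[dc$status == s]
    sens <- length(intersect(planted, found)) / length(planted)
    spec <- 1 - length(setdiff(found, planted)) /
      (nrow(truth) - length(planted))
    expect_gte(sens, 0.95)
    expect_gte(spec, 0.95)
  }
})

test_that("missing amplitudes are a data error naming the peak", {
  ann <- toy_annotation()
  bad <- toy_peak(9500)
  bad$amplitude <- NA_real_
  err <- expect_error(preferential_enrichment(bad, toy_peak(9500), ann),
                      class = "enrichdiff_data_error")
  expect_match(conditionMessage(err), "p1")
})

test_that("the differential summary reproduces its percentages from the calls", {
  cfg <- tiny_config(seed = 74)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  dc <- preferential_enrichment(land$peaks_wt, land$peaks_ko, ann)
  sm <- summarize_differential(dc, land$peaks_wt, land$peaks_ko)
  get <- function(m) sm$value[sm$metric == m]
  expect_equal(get("unique_wt_pct"),
               round(100 * get("unique_wt") / get("called_genes_wt") + 1e-9, 1))
  expect_equal(get("differential_wt"),
               sum(dc$status %in% c("unique_wt", "preferential_wt")))
  wide <- glance(sm)
  expect_equal(wide$called_genes_wt, get("called_genes_wt"))
})
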