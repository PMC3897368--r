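expr_row <- function(id, fold, dir, p) {
  tibble::tibble(gene_id = id, fold_change = fold, direction = dir, p_value = p)
}

test_that("the DE criterion is inclusive on fold and strict on p", {
  tab <- dplyr::bind_rows(
    expr_row("a", 1.6, "wt", 0.005),  # in
    expr_row("b", 1.5, "ko", 0.009),  # in: fold boundary inclusive
    expr_row("c", 2.0, "wt", 0.02),   # out: p not < 0.01
    expr_row("d", 2.0, "wt", 0.01),   # out: p boundary strict
    expr_row("e", 1.49, "ko", 0.001)) # out: fold below
  de <- call_differential_expression(tab)
  expect_setequal(de$gene_id, c("a", "b"))
  expect_equal(de$direction[de$gene_id == "b"], "ko")
})

test_that("duplicate gene ids are a data error listing them", {
  tab <- dplyr::bind_rows(expr_row("a", 2, "wt", 0.001),
                          expr_row("a", 1.7, "ko", 0.2))
  err <- expect_error(call_differential_expression(tab),
                      class = "enrichdiff_data_error")
  expect_match(conditionMessage(err), "a")
})

test_that("overlap reports enforce direction concordance and tiers", {
  dc <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    status = c("unique_wt", "preferential_wt", "unique_ko", "preferential_ko",
               "unchanged", "unchanged"))
  de <- dplyr::bind_rows(
    expr_row("g1", 2, "wt", 1e-3),   # unique_wt and up in wt -> counts
    expr_row("g2", 2, "wt", 1e-3),   # preferential tier only
    expr_row("g3", 2, "wt", 1e-3),   # enrichment ko, expression wt -> no
    expr_row("g5", 2, "wt", 1e-3),
    expr_row("g4", 2, "ko", 1e-3),   # concordant ko
    expr_row("g6", 2, "ko", 1e-3))
  de <- call_differential_expression(de)
  uniq <- intersect_enrichment_expression(de, dc, tier = "unique_only")
  expect_equal(uniq$n_overlap[uniq$genotype == "wt"], 1)
  expect_equal(uniq$n_overlap[uniq$genotype == "ko"], 0)
  both <- intersect_enrichment_expression(de, dc, tier = "unique_plus_preferential")
  expect_equal(both$n_overlap[both$genotype == "wt"], 2)
  expect_equal(both$n_overlap[both$genotype == "ko"], 1)
  expect_equal(both$percent[both$genotype == "wt"], 50) # 2 of 4 DE-wt genes
  # tier monotonicity: unique overlap never exceeds unique+preferential
  expect_true(all(both$n_overlap >= uniq$n_overlap))
})

test_that("genes present in only one table never crash the overlap", {
  dc <- tibble::tibble(gene_id = c("g1", "g2"), status = c("unique_wt", "unchanged"))
  de <- call_differential_expression(dplyr::bind_rows(
    expr_row("g1", 2, "wt", 1e-3), expr_row("zz_external", 3, "ko", 1e-4)))
  rep <- intersect_enrichment_expression(de, dc)
  expect_equal(rep$n_overlap[rep$genotype == "wt"], 1)
  expect_equal(rep$n_overlap[rep$genotype == "ko"], 0)
})

test_that("empty DE sets signal undefined percentages", {
  dc <- tibble::tibble(gene_id = "g1", status = "unique_wt")
  de <- call_differential_expression(expr_row("g1", 2, "wt", 1e-3))
  expect_error(intersect_enrichment_expression(de, dc),
               class = "enrichdiff_undefined_percentage")
})

test_that("exported gene lists partition the non-unchanged genes", {
  cfg <- tiny_config(seed = 81)
  ann <- generate_genome(cfg)
  land <- generate_peak_landscapes(ann, cfg)
  res <- generate_expression_table(land$truth, cfg)
  de <- call_differential_expression(res$expression)
  dc <- preferential_enrichment(land$peaks_wt, land$peaks_ko, ann)
  outdir <- withr::local_tempdir()
  manifest <- export_gene_lists(dc, de, outdir)
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  status_files <- c("unique_wt", "unique_ko", "preferential_wt", "preferential_ko")
  listed <- unlist(purrr::map(status_files, function(nm) {
    readLines(file.path(outdir, paste0(nm, ".txt")))
  }))
  expect_setequal(listed, dc$gene_id[dc$status != "unchanged"])
  json <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(json$unique_wt$n, sum(dc$status == "unique_wt"))
  # empty categories still appear
  dc_none <- dplyr::mutate(dc, status = "unchanged")
  m2 <- export_gene_lists(dc_none, de = NULL, outdir = withr::local_tempdir())
  expect_equal(sum(m2$n), 0)
  expect_setequal(m2$list_name, status_files)
})

test_that("audit of the published count table reproduces every printed percentage", {
  counts <- jsonlite::read_json(
    system.file("extdata", "published_counts.json", package = "enrichdiff"))
  audit <- audit_published_counts(counts)
  get <- function(m) audit$value[audit$metric == m]
  expect_equal(get("unique_wt_pct"), 4.2)
  expect_equal(get("unique_ko_pct"), 3.0)
  expect_equal(get("differential_wt_pct"), 6.3)
  expect_equal(get("differential_ko_pct"), 5.2)
  expect_equal(get("called_gene_difference_pct"), 1.3)
  expect_equal(get("unique_overlap_wt_pct"), 5.2)
  expect_equal(get("differential_overlap_wt_pct"), 17.3)
  expect_equal(get("unique_overlap_ko_pct"), 5.2)
  expect_equal(get("differential_overlap_ko_pct"), 10.8)
  expect_equal(round(get("peak_decrease_pct")), 2)
})
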