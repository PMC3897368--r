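#' Peak sets
#'
#' A `peak_set` is a tibble with one row per called or planted enrichment
#' interval: `peak_id`, `chrom`, `start`, `end` (0-based half-open), `summit`
#' (bp), `amplitude` (maximum binned pileup within the peak), `p_value` and
#' `score` (`-10 * log10(p)`; `NA` for planted peaks that were never tested).
#' Extra columns (planted_category, gene_id, cpg_flag, category, ...) ride
#' along through all verbs.
#'
#' @param x A data frame with at least the columns above.
#' @param genotype Optional label ("wt"/"ko") stored as an attribute.
#' @return A `peak_set` tibble.
#' @export
as_peak_set <- function(x, genotype = NULL) {
  assert_columns(x, c("peak_id", "chrom", "start", "end", "summit", "amplitude"),
                 "peak_set")
  bad <- x$start >= x$end | x$summit < x$start | x$summit >= x$end
  if (any(bad)) {
    abort(sprintf("invalid peak geometry for: %s",
                  paste(head(x$peak_id[bad], 5), collapse = ", ")),
          class = "enrichdiff_bad_input")
  }
  new_peak_set(as_tibble(x), genotype = genotype)
}

new_peak_set <- function(x, genotype = NULL) {
  out <- as_tibble(x)
  class(out) <- c("peak_set", class(out))
  attr(out, "genotype") <- genotype
  out
}

#' @export
print.peak_set <- function(x, ...) {
  if ("chrom" %in% names(x)) {
    gt <- attr(x, "genotype")
    cat(sprintf("<peak_set>%s %d peaks on %d chromosome(s)\n",
                if (!is.null(gt)) paste0(" [", gt, "]") else "",
                nrow(x), dplyr::n_distinct(x$chrom)))
  }
  NextMethod()
}
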