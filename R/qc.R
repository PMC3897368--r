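#' Read-quality summary arithmetic for ChIP-seq libraries
#'
#' Computes the standard post-sequencing quality table from raw counts:
#' `total_reads = raw_reads - low_quality`, and the three rates
#' `clean_rate = 100 * total_reads / raw_reads`,
#' `mapped_rate = 100 * mapped_reads / total_reads`,
#' `unique_mapped_rate = 100 * unique_mapped_reads / total_reads`, each
#' rounded half-up to two decimals. All arguments are vectorised, so a whole
#' sample table can be summarised in one call.
#'
#' @param raw_reads,low_quality,mapped_reads,unique_mapped_reads Non-negative
#'   read counts per library.
#' @param sample Optional sample labels.
#' @return A `qc_stats` tibble with one row per library: the six counts and
#'   three rates.
#' @export
#' @examples
#' compute_qc_stats(12e6, 35624, 10836399, 9244322)
compute_qc_stats <- function(raw_reads, low_quality, mapped_reads,
                             unique_mapped_reads, sample = NULL) {
  counts <- cbind(raw_reads, low_quality, mapped_reads, unique_mapped_reads)
  if (any(counts < 0)) {
    abort("read counts must be non-negative", class = "enrichdiff_bad_input")
  }
  if (any(low_quality > raw_reads)) {
    abort("low_quality cannot exceed raw_reads", class = "enrichdiff_bad_input")
  }
  total_reads <- raw_reads - low_quality
  if (any(mapped_reads > total_reads)) {
    abort("inconsistent counts: mapped_reads exceeds raw_reads - low_quality",
          class = "enrichdiff_inconsistent_counts")
  }
  if (any(unique_mapped_reads > mapped_reads)) {
    abort("inconsistent counts: unique_mapped_reads exceeds mapped_reads",
          class = "enrichdiff_inconsistent_counts")
  }
  out <- tibble(
    sample = sample %||% sprintf("library_%d", seq_along(raw_reads)),
    raw_reads = as.numeric(raw_reads),
    low_quality = as.numeric(low_quality),
    total_reads = as.numeric(total_reads),
    mapped_reads = as.numeric(mapped_reads),
    unique_mapped_reads = as.numeric(unique_mapped_reads),
    clean_rate = round_half_up(100 * total_reads / raw_reads, 2),
    mapped_rate = round_half_up(100 * mapped_reads / total_reads, 2),
    unique_mapped_rate = round_half_up(100 * unique_mapped_reads / total_reads, 2)
  )
  class(out) <- c("qc_stats", class(out))
  out
}

#' @export
tidy.qc_stats <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"sample",
                      names_to = "metric", values_to = "value")
}
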