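#' Parameters for the window-Poisson peak caller
#'
#' Defaults follow the MACS run the pipeline emulates: peak p-value threshold
#' 1e-5, mfold bounds 10-30, 50-bp fixed-step bins, minimum peak length equal
#' to the 300-bp fragment extension. The mfold bounds are accepted and echoed
#' into the run log for fidelity with the original caller's interface but are
#' only used to warn when no region exceeds `mfold_low` (this caller takes the
#' fragment extension from the track, so no fragment model is built from
#' mfold-selected candidates). `bandwidth` likewise plays no role in the
#' window-Poisson mechanism; supplying it is flagged, not silently dropped.
#'
#' @param p_threshold Per-bin Poisson p-value threshold (default 1e-5).
#' @param mfold_low,mfold_high Fold-enrichment bounds (defaults 10, 30).
#' @param bin_step Expected bin step in bp (default 50).
#' @param min_peak_length Minimum peak length in bp; shorter peaks are
#'   discarded (default 300, the fragment extension).
#' @param merge_gap_bins Significant bins separated by at most this many
#'   sub-threshold bins are merged (default 1).
#' @param window_small,window_large Local background window widths in bp for
#'   the Poisson rate (defaults 1000 and 10000).
#' @param score_cap Upper cap for `-10 * log10(p)` when p underflows
#'   (default 3100).
#' @param bandwidth Accepted for interface fidelity; unused.
#' @return A `peak_call_params` list.
#' @export
peak_call_params <- function(p_threshold = 1e-5, mfold_low = 10, mfold_high = 30,
                             bin_step = 50L, min_peak_length = 300L,
                             merge_gap_bins = 1L, window_small = 1000L,
                             window_large = 10000L, score_cap = 3100,
                             bandwidth = NULL) {
  if (p_threshold <= 0 || p_threshold >= 1) {
    abort("p_threshold must lie strictly between 0 and 1",
          class = "enrichdiff_bad_config")
  }
  if (mfold_low >= mfold_high) {
    abort("mfold_low must be smaller than mfold_high",
          class = "enrichdiff_bad_config")
  }
  structure(list(p_threshold = p_threshold, mfold_low = mfold_low,
                 mfold_high = mfold_high, bin_step = as.integer(bin_step),
                 min_peak_length = as.integer(min_peak_length),
                 merge_gap_bins = as.integer(merge_gap_bins),
                 window_small = as.integer(window_small),
                 window_large = as.integer(window_large),
                 score_cap = score_cap, bandwidth = bandwidth),
            class = "peak_call_params")
}

#' Call peaks from paired treatment and input coverage tracks
#'
#' A simplified MACS-style caller over fixed-step binned pileup. The control
#' track is scaled linearly to the treatment depth
#' (`total_reads_t / total_reads_c`); each bin's Poisson rate is the largest
#' of the scaled local control mean over a small and a large centred window
#' and the genome-wide scaled control mean (the local-rate floor prevents
#' zero-rate bins in unsequenced regions). The bin p-value is the upper-tail
#' Poisson probability P(X >= k), bins at or below the threshold are merged
#' across gaps of at most `merge_gap_bins`, short peaks are discarded, and
#' each peak reports its summit (argmax bin), amplitude (maximum treatment
#' pileup) and score `-10 * log10(p at summit)` capped at `score_cap`.
#'
#' @param treatment,control [coverage_track()]s sharing chromosome set and
#'   step; `control` must carry a positive `total_reads`.
#' @param params A [peak_call_params()].
#' @param log_path Optional path; when given, all parameters and scaling
#'   factors are echoed there as a JSON run log.
#' @return A `peak_set` tibble; the run log is attached as attribute
#'   `run_log`.
#' @export
call_peaks <- function(treatment, control, params = peak_call_params(),
                       log_path = NULL) {
  stopifnot(inherits(treatment, "coverage_track"),
            inherits(control, "coverage_track"),
            inherits(params, "peak_call_params"))
  if (track_step(treatment) != track_step(control)) {
    abort(sprintf("step mismatch: treatment %d bp vs control %d bp",
                  track_step(treatment), track_step(control)),
          class = "enrichdiff_format_error")
  }
  step <- track_step(treatment)
  if (nrow(control) == 0 || is.na(track_total_reads(control)) ||
      track_total_reads(control) <= 0) {
    abort("control track is empty or has no positive total_reads",
          class = "enrichdiff_config_error")
  }
  t_chroms <- unique(treatment$chrom)
  if (!setequal(t_chroms, unique(control$chrom))) {
    abort("treatment and control tracks must cover the same chromosome set",
          class = "enrichdiff_format_error")
  }
  if (!is.null(params$bandwidth)) {
    warn("bandwidth is accepted for interface fidelity but unused by the window-Poisson caller",
         class = "enrichdiff_unused_parameter")
  }

  bins <- bin_significance(treatment, control, params)
  scale <- attr(bins, "scale_factor")
  genome_mean <- attr(bins, "genome_mean")
  by_chrom <- split(bins, factor(bins$chrom, levels = t_chroms))

  res <- purrr::map(t_chroms, function(ch) {
    b <- by_chrom[[ch]]
    if (is.null(b) || nrow(b) == 0) return(NULL)
    tv <- b$count
    logp <- b$log_p
    sig <- logp <= log(params$p_threshold)
    if (!any(sig)) return(NULL)
    runs <- merge_runs(which(sig), params$merge_gap_bins)
    purrr::map(runs, function(r) {
      first <- r[1]; last <- r[2]
      len <- (last - first + 1L) * step
      if (len < params$min_peak_length) return(NULL)
      seg <- tv[first:last]
      s_idx <- first + which.max(seg) - 1L
      lp <- logp[s_idx]
      tibble(chrom = ch,
             start = (first - 1L) * step,
             end = last * step,
             summit = (s_idx - 1L) * step,
             amplitude = max(seg),
             p_value = exp(lp),
             score = min(-10 * lp / log(10), params$score_cap))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), amplitude = numeric(),
                  p_value = numeric(), score = numeric())
  }
  max_fold <- max(c(0, bins$count)) / genome_mean
  if (is.finite(max_fold) && max_fold < params$mfold_low) {
    warn(sprintf("no candidate region exceeds mfold_low = %g (max fold %.2f)",
                 params$mfold_low, max_fold),
         class = "enrichdiff_low_enrichment")
  }
  out <- res |>
    mutate(peak_id = sprintf("peak_%05d", dplyr::row_number()),
           start = as.integer(.data$start), end = as.integer(.data$end),
           summit = as.integer(.data$summit)) |>
    select("peak_id", "chrom", "start", "end", "summit", "amplitude",
           "p_value", "score")
  run_log <- c(unclass(params)[setdiff(names(params), "bandwidth")],
               list(bandwidth = params$bandwidth %||% NA,
                    scale_factor = scale, genome_mean = genome_mean,
                    n_peaks = nrow(out)))
  if (!is.null(log_path)) {
    jsonlite::write_json(run_log, log_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  out <- new_peak_set(out, genotype = attr(treatment, "genotype"))
  attr(out, "run_log") <- run_log
  out
}

#' Per-bin Poisson significance against the scaled control
#'
#' The first stage of [call_peaks()], exposed for inspection and calibration:
#' scales the control to the treatment depth, computes each bin's local
#' Poisson rate (the maximum of the small-window mean, the large-window mean
#' and the genome-wide control mean) and the upper-tail log p-value
#' P(X >= k) of the treatment count.
#'
#' @inheritParams call_peaks
#' @return A tibble with one row per bin: `chrom`, `pos`, `count` (rounded
#'   treatment pileup), `lambda` (scaled local rate) and `log_p` (natural-log
#'   upper-tail p-value). Attributes `scale_factor` and `genome_mean` carry
#'   the scaling.
#' @export
bin_significance <- function(treatment, control, params = peak_call_params()) {
  step <- track_step(treatment)
  t_chroms <- unique(treatment$chrom)
  scale <- track_total_reads(treatment) / track_total_reads(control)
  tt <- track_dense(treatment, t_chroms)
  cc <- track_dense(control, t_chroms)
  genome_mean <- scale * sum(unlist(cc)) / sum(lengths(cc))
  h1 <- max(1L, params$window_small %/% (2L * step))
  h2 <- max(1L, params$window_large %/% (2L * step))
  out <- purrr::map(t_chroms, function(ch) {
    tv <- tt[[ch]]
    cv <- cc[[ch]]
    n <- max(length(tv), length(cv))
    if (n == 0) return(NULL)
    length(tv) <- n; tv[is.na(tv)] <- 0
    length(cv) <- n; cv[is.na(cv)] <- 0
    sc <- scale * cv
    lambda <- pmax(centred_mean(sc, h1), centred_mean(sc, h2), genome_mean)
    k <- round(tv)
    tibble(chrom = ch, pos = (seq_len(n) - 1) * step, count = k,
           lambda = lambda,
           log_p = ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE))
  }) |> purrr::list_rbind()
  attr(out, "scale_factor") <- scale
  attr(out, "genome_mean") <- genome_mean
  out
}

# Mean of x over a window of half-width h bins centred on each bin; edge
# windows shrink to the available bins.
centred_mean <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Collapse sorted indices of significant bins into [first, last] runs, merging
# runs separated by at most `gap` sub-threshold bins.
merge_runs <- function(idx, gap) {
  brk <- which(diff(idx) > gap + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  purrr::map2(starts, ends, c)
}
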