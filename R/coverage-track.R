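#' Coverage tracks
#'
#' A `coverage_track` is a tibble of fixed-step binned read pileup: one row
#' per bin with columns `chrom`, `pos` (0-based bin start, a multiple of the
#' step) and `count` (pileup sampled at the bin start, >= 0). Track-level
#' metadata lives in attributes: `step` (= span, bp), `total_reads`,
#' `tag_size` (bp) and `extension` (fragment extension, bp).
#'
#' @param bins A data frame with columns chrom, pos, count.
#' @param step Bin step in bp (fixed-step dialect: step = span).
#' @param total_reads Library size behind the track (used for depth scaling).
#' @param tag_size Sequenced tag length in bp (default 49).
#' @param extension Fragment extension in bp (default 300).
#' @return A `coverage_track` tibble.
#' @export
coverage_track <- function(bins, step, total_reads = NA_real_,
                           tag_size = 49L, extension = 300L) {
  assert_columns(bins, c("chrom", "pos", "count"), "coverage_track")
  if (any(bins$count < 0)) {
    abort("coverage values must be non-negative", class = "enrichdiff_bad_input")
  }
  if (any(bins$pos %% step != 0)) {
    abort("bin positions must be multiples of the step", class = "enrichdiff_bad_input")
  }
  out <- as_tibble(bins)
  out$pos <- as.numeric(out$pos)
  out$count <- as.numeric(out$count)
  class(out) <- c("coverage_track", class(out))
  attr(out, "step") <- as.integer(step)
  attr(out, "total_reads") <- as.numeric(total_reads)
  attr(out, "tag_size") <- as.integer(tag_size)
  attr(out, "extension") <- as.integer(extension)
  out
}

track_step <- function(track) attr(track, "step")
track_total_reads <- function(track) attr(track, "total_reads")

#' @export
print.coverage_track <- function(x, ...) {
  if (!is.null(track_step(x))) {
    cat(sprintf("<coverage_track> step %d bp, %d bins, %s reads\n",
                track_step(x), nrow(x),
                format(track_total_reads(x), big.mark = ",")))
  }
  NextMethod()
}

# Dense per-chromosome count vectors (zero-filled from position 0), as a named
# list; used by the peak caller and the metagene profiler.
track_dense <- function(track, chroms = NULL) {
  step <- track_step(track)
  split_pos <- split(track$pos, track$chrom)
  split_cnt <- split(track$count, track$chrom)
  chroms <- chroms %||% names(split_pos)
  setNames(purrr::map(chroms, function(ch) {
    pos <- split_pos[[ch]]
    if (is.null(pos)) return(numeric(0))
    cnt <- split_cnt[[ch]]
    n <- max(pos) %/% step + 1L
    v <- numeric(n)
    v[pos %/% step + 1L] <- cnt
    v
  }), chroms)
}

#' Generate treatment and control coverage tracks from a peak landscape
#'
#' Emulates the binned pileup a peak caller sees. Each planted peak of
#' amplitude `a` contributes `round(a)` fragments whose centres are placed by
#' stratified sampling within +/- 20 bp of the summit and extended to
#' `fragment_extension` bp, producing a full-height plateau of
#' `fragment_extension / bin_step` bins whose pileup equals the amplitude.
#' Uniform background fragments (`reads_per_condition` of them) are added to
#' the treatment track; the control track holds an independent background of
#' the same size and nothing else.
#'
#' @param peaks A `peak_set` from [generate_peak_landscapes()].
#' @param config The matching [sim_config()].
#' @param genotype "wt" or "ko"; defaults to the peak set's genotype
#'   attribute. Selects the random stream so the two genotypes get
#'   independent, reproducible backgrounds.
#' @return A list with `treatment` and `control` [coverage_track()]s.
#' @export
generate_coverage_tracks <- function(peaks, config,
                                     genotype = attr(peaks, "genotype") %||% "wt") {
  stopifnot(inherits(config, "sim_config"))
  if (config$reads_per_condition <= 0) {
    abort("reads_per_condition must be positive: a zero-read track is empty",
          class = "enrichdiff_empty_track")
  }
  step <- config$bin_step
  ext <- config$fragment_extension
  bins_per_frag <- ext %/% step
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  n_bins <- as.integer(ceiling(config$chrom_length / step))

  stream <- if (identical(genotype, "ko")) "coverage_ko" else "coverage_wt"
  with_stream(config$seed, stream, {
    frag_bins <- function(first_bin, chrom_idx) {
      # each extended fragment covers exactly bins_per_frag sampled positions
      idx <- rep(first_bin, each = bins_per_frag) +
        rep.int(seq_len(bins_per_frag) - 1L, length(first_bin))
      ch <- rep(chrom_idx, each = bins_per_frag)
      keep <- idx >= 0L & idx < n_bins
      cbind(ch[keep], idx[keep])
    }
    accumulate <- function(pairs_list) {
      m <- do.call(rbind, pairs_list)
      counts <- matrix(0, nrow = n_bins, ncol = length(chroms))
      if (!is.null(m) && nrow(m)) {
        flat <- (m[, 1] - 1L) * n_bins + m[, 2] + 1L
        tab <- tabulate(flat, nbins = n_bins * length(chroms))
        counts[] <- tab
      }
      counts
    }

    # planted fragments (treatment only)
    n_frag <- round(peaks$amplitude)
    centre <- rep(peaks$summit, n_frag) - 20 +
      40 * (unlist(purrr::map(n_frag, function(n) seq_len(n) - runif(n))) /
              rep(n_frag, n_frag))
    frag_start <- centre - ext / 2
    peak_first <- as.integer(ceiling(frag_start / step))
    peak_chrom <- rep(match(peaks$chrom, chroms), n_frag)

    # background fragments for treatment, then control (fixed draw order)
    bg_draw <- function() {
      n <- config$reads_per_condition
      ch <- sample.int(length(chroms), n, replace = TRUE)
      p <- floor(runif(n, 0, config$chrom_length))
      list(first = as.integer(ceiling(p / step)), chrom = ch)
    }
    bg_t <- bg_draw()
    bg_c <- bg_draw()

    treat_counts <- accumulate(list(frag_bins(peak_first, peak_chrom),
                                    frag_bins(bg_t$first, bg_t$chrom)))
    ctrl_counts <- accumulate(list(frag_bins(bg_c$first, bg_c$chrom)))

    to_track <- function(counts, total) {
      bins <- tibble(
        chrom = rep(chroms, each = n_bins),
        pos = rep.int(seq_len(n_bins) - 1L, length(chroms)) * step,
        count = as.numeric(counts)
      )
      coverage_track(bins, step = step, total_reads = total,
                     tag_size = 49L, extension = ext)
    }
    list(
      treatment = to_track(treat_counts, sum(n_frag) + config$reads_per_condition),
      control = to_track(ctrl_counts, config$reads_per_condition)
    )
  })
}
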