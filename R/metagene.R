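#' Metagene signal profile around gene bodies
#'
#' Aggregates a coverage track over all genes into the classic TSS/TES
#' profile: `flank` bp upstream of the TSS at track resolution, the gene body
#' rescaled to `n_body_bins` positions, and `flank` bp downstream of the TES.
#' Minus-strand genes are reversed so "upstream" always means 5'. Genes whose
#' body is shorter than `n_body_bins * step` cannot be mapped onto the body
#' grid and are excluded (their number is reported); positions running off a
#' chromosome end are ignored in the average.
#'
#' @param signal A [coverage_track()].
#' @param annotation A `genome_annotation`.
#' @param flank Flank size in bp (default 5000).
#' @param n_body_bins Number of rescaled body positions (default 40).
#' @return A `metagene_profile` tibble: `segment` (upstream/body/downstream),
#'   `position` (bp relative to TSS for upstream, bin index for body, bp
#'   relative to TES for downstream) and `signal` (mean pileup across genes).
#'   Attributes `n_genes_used` and `n_genes_excluded` record eligibility.
#' @export
metagene_profile <- function(signal, annotation, flank = 5000L, n_body_bins = 40L) {
  stopifnot(inherits(signal, "coverage_track"))
  if (flank <= 0) abort("flank must be positive", class = "enrichdiff_bad_config")
  step <- track_step(signal)
  flank_bins <- as.integer(ceiling(flank / step))
  genes <- annotation$genes
  eligible <- (genes$end - genes$start) >= n_body_bins * step
  n_excluded <- sum(!eligible)
  if (n_excluded > 0) {
    rlang::inform(sprintf("metagene_profile: excluded %d gene(s) shorter than %d bp",
                          n_excluded, n_body_bins * step))
  }
  genes <- genes[eligible, ]
  if (nrow(genes) == 0) {
    abort("no genes are long enough for the requested body grid",
          class = "enrichdiff_empty_profile")
  }
  dense <- track_dense(signal)

  per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
    v <- dense[[genes$chrom[i]]]
    if (is.null(v)) v <- numeric(0)
    at <- function(bins) {
      out <- rep(NA_real_, length(bins))
      ok <- bins >= 0 & bins < length(v)
      out[ok] <- v[bins[ok] + 1L]
      out
    }
    bt <- genes$tss[i] %/% step
    be <- genes$tes[i] %/% step
    body_bins <- (genes$start[i] %/% step):((genes$end[i] - 1L) %/% step)
    if (genes$strand[i] == "+") {
      up <- at((bt - flank_bins):(bt - 1L))
      body <- at(body_bins)
      down <- at((be + 1L):(be + flank_bins))
    } else {
      up <- rev(at((bt + 1L):(bt + flank_bins)))
      body <- rev(at(body_bins))
      down <- rev(at((be - flank_bins):(be - 1L)))
    }
    body_scaled <- approx(seq(0, 1, length.out = length(body)), body,
                          xout = seq(0, 1, length.out = n_body_bins))$y
    c(up, body_scaled, down)
  })
  mat <- do.call(rbind, per_gene)
  prof <- colMeans(mat, na.rm = TRUE)

  out <- tibble(
    segment = rep(c("upstream", "body", "downstream"),
                  c(flank_bins, n_body_bins, flank_bins)),
    position = c(seq(-flank_bins, -1L) * step, seq_len(n_body_bins),
                 seq_len(flank_bins) * step),
    signal = prof
  )
  class(out) <- c("metagene_profile", class(out))
  attr(out, "flank") <- as.integer(flank)
  attr(out, "n_body_bins") <- as.integer(n_body_bins)
  attr(out, "step") <- step
  attr(out, "n_genes_used") <- nrow(genes)
  attr(out, "n_genes_excluded") <- n_excluded
  out
}
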