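#' Read and write fixed-step wiggle (WIG) coverage tracks
#'
#' Only the fixed-step WIG dialect is supported (`fixedStep` declaration lines
#' with `step` equal to `span`), matching the tracks a MACS-style caller
#' emits. Track metadata (total reads, tag size, extension) is carried in a
#' comment line so that `read_wiggle(write_wiggle(x))` reproduces the track
#' bit-exactly; wiggle files from other tools load with `total_reads = NA`
#' unless supplied.
#'
#' @param track A [coverage_track()].
#' @param path File path.
#' @param total_reads Optional library size to attach when the file carries no
#'   metadata comment.
#' @return `write_wiggle()` returns `path` invisibly; `read_wiggle()` returns
#'   a [coverage_track()].
#' @export
write_wiggle <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  step <- track_step(track)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# enrichdiff total_reads=%s tag_size=%d extension=%d",
                     format(track_total_reads(track), digits = 15,
                            scientific = FALSE, trim = TRUE),
                     attr(track, "tag_size"), attr(track, "extension")), con)
  for (ch in unique(track$chrom)) {
    rows <- track[track$chrom == ch, ]
    if (nrow(rows) == 0) next # empty chromosomes are omitted
    # one declaration per contiguous run of bins
    breaks <- c(0L, which(diff(rows$pos) != step), nrow(rows))
    for (b in seq_len(length(breaks) - 1L)) {
      idx <- (breaks[b] + 1L):breaks[b + 1L]
      writeLines(sprintf("fixedStep chrom=%s start=%.0f step=%d span=%d",
                         ch, rows$pos[idx[1]] + 1, step, step), con)
      writeLines(format_wig_values(rows$count[idx]), con)
    }
  }
  invisible(path)
}

format_wig_values <- function(v) {
  out <- character(length(v))
  whole <- v == floor(v) & abs(v) < 2^53
  out[whole] <- sprintf("%.0f", v[whole])
  out[!whole] <- sprintf("%.17g", v[!whole])
  out
}

#' @rdname write_wiggle
#' @export
read_wiggle <- function(path, total_reads = NULL) {
  lines <- readLines(path)
  meta <- list(total_reads = total_reads %||% NA_real_,
               tag_size = 49L, extension = 300L)
  m <- grep("^# enrichdiff ", lines)
  if (length(m)) {
    kv <- regmatches(lines[m[1]],
                     gregexpr("[a-z_]+=[-0-9.eE+NAna]+", lines[m[1]]))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
    }
    if (!is.null(total_reads)) meta$total_reads <- total_reads
  }

  var_at <- grep("^variableStep", lines)
  if (length(var_at)) {
    abort(sprintf("line %d: variableStep records are not supported (fixed-step dialect only)",
                  var_at[1]),
          class = "enrichdiff_wig_dialect")
  }
  is_decl <- startsWith(lines, "fixedStep")
  is_skip <- grepl("^(#|track|browser)", lines) | !nzchar(trimws(lines))
  decl_at <- which(is_decl)
  if (!length(decl_at)) {
    abort("no fixedStep declaration found: not a fixed-step wiggle file",
          class = "enrichdiff_wig_dialect")
  }
  val_at <- which(!is_decl & !is_skip)
  if (length(val_at) && val_at[1] < decl_at[1]) {
    abort(sprintf("line %d: value before any fixedStep declaration", val_at[1]),
          class = "enrichdiff_wig_parse")
  }

  decls <- purrr::map(decl_at, function(i) parse_decl_fields(lines[i], i))
  steps <- purrr::map_int(decls, function(f) as.integer(f[["step"]]))
  spans <- purrr::map_int(decls, function(f) {
    as.integer(f[["span"]] %||% f[["step"]])
  })
  bad_span <- which(steps != spans)
  if (length(bad_span)) {
    abort(sprintf("line %d: step (%d) must equal span (%d) in the fixed-step dialect",
                  decl_at[bad_span[1]], steps[bad_span[1]], spans[bad_span[1]]),
          class = "enrichdiff_wig_dialect")
  }
  if (length(unique(steps)) > 1) {
    abort(sprintf("line %d: step changes within the file",
                  decl_at[which(steps != steps[1])[1]]),
          class = "enrichdiff_wig_dialect")
  }
  step <- steps[1]

  values <- suppressWarnings(as.numeric(lines[val_at]))
  if (anyNA(values)) {
    bad <- val_at[which(is.na(values))[1]]
    abort(sprintf("line %d: expected a numeric value, got '%s'", bad, lines[bad]),
          class = "enrichdiff_wig_parse")
  }
  if (any(values < 0)) {
    bad <- val_at[which(values < 0)[1]]
    abort(sprintf("line %d: negative coverage value %s", bad, lines[bad]),
          class = "enrichdiff_wig_parse")
  }

  block <- findInterval(val_at, decl_at)
  n_per_block <- tabulate(block, nbins = length(decl_at))
  chrom <- rep(purrr::map_chr(decls, "chrom"), n_per_block)
  block_start <- purrr::map_dbl(decls, function(f) as.numeric(f[["start"]]) - 1)
  offset_in_block <- sequence(n_per_block) - 1
  pos <- rep(block_start, n_per_block) + offset_in_block * step

  coverage_track(tibble(chrom = chrom, pos = pos, count = values),
                 step = step, total_reads = meta$total_reads,
                 tag_size = as.integer(meta$tag_size),
                 extension = as.integer(meta$extension))
}

parse_decl_fields <- function(line, lineno) {
  kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ \t]+", line))[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  fields <- setNames(purrr::map_chr(parts, 2), purrr::map_chr(parts, 1))
  for (need in c("chrom", "start", "step")) {
    if (!need %in% names(fields)) {
      abort(sprintf("line %d: fixedStep declaration missing '%s'", lineno, need),
            class = "enrichdiff_wig_parse")
    }
  }
  as.list(fields)
}
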