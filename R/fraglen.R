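#' Fragment length distribution for one sample
#'
#' Tallies fragment lengths (`end - start`, or `|TLEN|` when computed from an
#' alignment file) into integer counts over `[min_len, max_len]`. Lengths
#' outside the range are tallied separately as underflow/overflow, never
#' silently discarded and never mixed into the in-range counts.
#'
#' @param x A fragment `data.frame` (see [fragments()]) or an integer vector
#'   of fragment lengths.
#' @param sample_id Sample identifier stored in the result.
#' @param min_len,max_len Inclusive length range of the tally (defaults 1
#'   and 500 bp, covering mono- and di-nucleosomal cfDNA fragments).
#' @return A `length_distribution`: list with `sample_id`, `counts` (named
#'   integer vector over `min_len:max_len`), `total` (sum of in-range
#'   counts), `n_underflow`, `n_overflow`.
#' @export
length_distribution <- function(x, sample_id = "sample",
                                min_len = 1L, max_len = 500L) {
  if (min_len > max_len) {
    fb_stop("min_len must be <= max_len", "fragbam_param_error")
  }
  lens <- if (is.data.frame(x)) {
    x <- validate_fragments(x)
    x$end - x$start
  } else {
    as.integer(x)
  }
  rng <- min_len:max_len
  in_range <- lens >= min_len & lens <= max_len
  counts <- tabulate(lens[in_range] - min_len + 1L, nbins = length(rng))
  names(counts) <- rng
  structure(list(sample_id = sample_id,
                 counts = counts,
                 total = sum(counts),
                 n_underflow = sum(lens < min_len),
                 n_overflow = sum(lens > max_len)),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("length_distribution '%s': %d fragment(s) in [%s, %s] bp",
              x$sample_id, x$total, names(x$counts)[1],
              names(x$counts)[length(x$counts)]))
  if (x$n_underflow + x$n_overflow > 0L) {
    cat(sprintf(" (+%d under, +%d over range)", x$n_underflow, x$n_overflow))
  }
  cat("\n")
  invisible(x)
}

#' Ratio of short cfDNA fragments
#'
#' The proportion of fragments strictly shorter than `threshold` bp
#' (default 150). Short-fragment enrichment is a hallmark of tumour-derived
#' and inflammation-associated cfDNA.
#'
#' @param dist A [length_distribution()].
#' @param threshold Length threshold in bp; fragments with length
#'   `< threshold` count as short.
#' @return Proportion in `[0, 1]`.
#' @export
short_fragment_ratio <- function(dist, threshold = 150L) {
  stopifnot(inherits(dist, "length_distribution"))
  if (dist$total == 0L) {
    fb_stop("short_fragment_ratio is undefined for an empty distribution",
            "fragbam_empty_error")
  }
  lens <- as.integer(names(dist$counts))
  sum(dist$counts[lens < threshold]) / dist$total
}

#' Per-length log2 enrichment of a sample against a cohort
#'
#' For each fragment length, the log2 ratio of the sample's length frequency
#' to the unweighted mean frequency across a cohort (each cohort member
#' counts once regardless of sequencing depth). A pseudocount on the
#' frequency scale (`pseudocount / total`) keeps all values finite.
#'
#' @param sample A [length_distribution()].
#' @param cohort Non-empty list of [length_distribution()] objects on the
#'   same length range.
#' @param pseudocount Pseudocount in fragment units (default 0.5).
#' @return Named numeric vector of log2 ratios, one per length.
#' @export
log2_enrichment <- function(sample, cohort, pseudocount = 0.5) {
  stopifnot(inherits(sample, "length_distribution"))
  if (length(cohort) == 0L) {
    fb_stop("cohort must be non-empty", "fragbam_param_error")
  }
  rng <- names(sample$counts)
  for (d in cohort) {
    stopifnot(inherits(d, "length_distribution"))
    if (!identical(names(d$counts), rng)) {
      fb_stop("all distributions must share the same length range",
              "fragbam_range_error")
    }
  }
  freq <- function(d) {
    tot <- max(d$total, 1L)
    d$counts / tot + pseudocount / tot
  }
  num <- freq(sample)
  den <- rowMeans(vapply(cohort, freq, numeric(length(rng))))
  stats::setNames(log2(num / den), rng)
}
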