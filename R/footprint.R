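#' A named set of genomic intervals (e.g. cell-type-specific DHSs)
#'
#' Intervals are stored as given (0-based half-open); profile computation
#' anchors each interval at its midpoint and extends by a fixed flank, so
#' input widths need not be equal.
#'
#' @param name Set name (e.g. a cell type).
#' @param contig,start,end Vectors defining the intervals, 0-based half-open.
#' @return An `interval_set` list with `name` and an `intervals` data frame.
#' @export
interval_set <- function(name, contig, start, end) {
  if (length(contig) == 0L) {
    fb_stop("interval set must be non-empty", "fragbam_param_error")
  }
  if (any(end <= start)) {
    fb_stop("interval end must exceed start", "fragbam_param_error")
  }
  structure(list(name = as.character(name),
                 intervals = data.frame(contig = as.character(contig),
                                        start = as.integer(start),
                                        end = as.integer(end),
                                        stringsAsFactors = FALSE)),
            class = "interval_set")
}

#' Read an interval set from a BED file
#'
#' @param path BED file path (3+ columns, 0-based half-open).
#' @param name Set name; defaults to the file name without extension.
#' @return An [interval_set()].
#' @export
read_interval_set <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  bed <- read_fragments(path, dialect = "BED3")
  interval_set(name, bed$contig, bed$start, bed$end)
}

#' Mean-normalized fragment coverage profile around interval midpoints
#'
#' Anchors every interval at its midpoint, extends by `flank` bp on each
#' side, divides the window into `bin`-bp bins, and counts the fragments
#' overlapping each bin (a fragment counts toward every bin it overlaps;
#' coverage is fragment-level, which is what de-identified data defines).
#' Per-bin counts are averaged over intervals, then divided by the profile's
#' own mean so samples of different depth are comparable.
#'
#' @param frags A fragment `data.frame`.
#' @param set An [interval_set()].
#' @param flank Half-window size in bp (default 1000).
#' @param bin Bin width in bp (default 10); must divide `2 * flank`.
#' @return Numeric vector of mean-normalized coverage, one value per bin
#'   from `-flank` to `+flank`, with attributes `flank` and `bin`. All-zero
#'   (with a warning) when no fragment overlaps any window.
#' @export
coverage_profile <- function(frags, set, flank = 1000L, bin = 10L) {
  stopifnot(inherits(set, "interval_set"))
  frags <- validate_fragments(frags)
  if ((2L * flank) %% bin != 0L) {
    fb_stop("bin width must divide the window size 2*flank",
            "fragbam_param_error")
  }
  iv <- set$intervals
  nbins <- as.integer(2L * flank / bin)
  center <- (iv$start + iv$end) %/% 2L
  # 1-based bin starts for every (interval, bin) combination
  w0 <- rep(center - flank, each = nbins)
  off <- rep.int(seq_len(nbins) - 1L, nrow(iv)) * bin
  bins <- GenomicRanges::GRanges(
    rep(iv$contig, each = nbins),
    IRanges::IRanges(start = w0 + off + 1L, width = bin))
  fr <- GenomicRanges::GRanges(frags$contig,
                               IRanges::IRanges(frags$start + 1L, frags$end))
  hits <- GenomicRanges::countOverlaps(bins, fr)
  prof <- rowMeans(matrix(hits, nrow = nbins))
  if (all(prof == 0)) {
    fb_warn("no fragments overlap the interval windows; profile is all zero",
            "fragbam_empty_profile_warning")
    cov <- prof
  } else {
    cov <- prof / mean(prof)
  }
  attr(cov, "flank") <- flank
  attr(cov, "bin") <- bin
  cov
}

#' Coverage dip depth of a profile
#'
#' Mean coverage over the outer flanks minus mean coverage over the central
#' window: positive values mean a coverage dip at the interval midpoints,
#' the signal left by nucleosome-depleted (open chromatin) regions in cfDNA.
#' Windows are expressed as fractions of the profile length.
#'
#' @param profile Numeric coverage profile (see [coverage_profile()]).
#' @param center_frac Fraction of bins forming the central window
#'   (default 0.2).
#' @param flank_frac Fraction of bins forming each outer flank
#'   (default 0.25). Requires `center_frac + 2 * flank_frac <= 1`.
#' @return Dip depth in mean-normalized coverage units.
#' @export
dip_depth <- function(profile, center_frac = 0.2, flank_frac = 0.25) {
  n <- length(profile)
  if (n == 0L) fb_stop("profile is empty", "fragbam_param_error")
  if (center_frac <= 0 || flank_frac <= 0 ||
      center_frac + 2 * flank_frac > 1 + 1e-9) {
    fb_stop("require 0 < center_frac, 0 < flank_frac, center_frac + 2*flank_frac <= 1",
            "fragbam_param_error")
  }
  nc <- max(1L, as.integer(round(center_frac * n)))
  nf <- max(1L, as.integer(round(flank_frac * n)))
  c0 <- (n - nc) %/% 2L
  center <- profile[(c0 + 1L):(c0 + nc)]
  flanks <- c(profile[seq_len(nf)], profile[(n - nf + 1L):n])
  mean(flanks) - mean(center)
}

#' z-score of a dip depth against a healthy cohort
#'
#' @param sample_dip Dip depth of the sample of interest.
#' @param healthy_dips Numeric vector of dip depths from healthy samples
#'   (>= 2 values with nonzero standard deviation).
#' @return `(sample_dip - mean(healthy_dips)) / sd(healthy_dips)` with the
#'   n-1 denominator.
#' @export
dip_zscore <- function(sample_dip, healthy_dips) {
  if (length(healthy_dips) < 2L) {
    fb_stop("healthy cohort must contain at least 2 dip depths",
            "fragbam_param_error")
  }
  s <- stats::sd(healthy_dips)
  if (!is.finite(s) || s == 0) {
    fb_stop("healthy cohort dip depths have zero standard deviation",
            "fragbam_degenerate_error")
  }
  (sample_dip - mean(healthy_dips)) / s
}

#' Dip signatures for a cohort of samples over one or more interval sets
#'
#' Convenience wrapper: computes each sample's dip depth per interval set
#' and z-scores every sample against the designated healthy samples
#' (leave-one-out when the sample itself is healthy).
#'
#' @param samples Named list of fragment `data.frame`s.
#' @param healthy_ids Names of the healthy reference samples (>= 3 for
#'   leave-one-out z-scores).
#' @param sets List of [interval_set()] objects.
#' @param flank,bin,center_frac,flank_frac Passed to [coverage_profile()]
#'   and [dip_depth()].
#' @return Data frame with columns `sample`, `set`, `dip_depth`, `z`
#'   (`NA` when the usable healthy cohort has fewer than 2 members).
#' @export
dip_signatures <- function(samples, healthy_ids, sets, flank = 1000L,
                           bin = 10L, center_frac = 0.2, flank_frac = 0.25) {
  stopifnot(is.list(samples), length(names(samples)) == length(samples))
  if (!all(healthy_ids %in% names(samples))) {
    fb_stop("healthy_ids must name entries of `samples`",
            "fragbam_param_error")
  }
  if (inherits(sets, "interval_set")) sets <- list(sets)
  rows <- list()
  for (set in sets) {
    dips <- vapply(samples, function(fr) {
      dip_depth(coverage_profile(fr, set, flank, bin),
                center_frac, flank_frac)
    }, numeric(1))
    for (id in names(samples)) {
      ref <- dips[setdiff(healthy_ids, id)]
      z <- if (length(ref) >= 2L && stats::sd(ref) > 0) {
        dip_zscore(dips[[id]], ref)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = id, set = set$name, dip_depth = dips[[id]], z = z,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
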