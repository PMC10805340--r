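#' Default cfDNA fragment-length mixture
#'
#' Two Gaussian components encoding the mono- and di-nucleosomal peaks that
#' dominate plasma cfDNA: 70% at 167 +/- 10 bp and 30% at 334 +/- 20 bp.
#'
#' @return Data frame with columns `weight`, `mean`, `sd`.
#' @export
default_length_mixture <- function() {
  data.frame(weight = c(0.7, 0.3), mean = c(167, 334), sd = c(10, 20))
}

#' Probability that a mixture-drawn fragment is shorter than a threshold
#'
#' Closed-form CDF of the rounded Gaussian length mixture at
#' `threshold - 0.5` (lengths are rounded to integers, so
#' `P(length < t) = P(X < t - 0.5)`). Used as the analytic oracle for the
#' simulator's short-fragment fraction.
#'
#' @param threshold Length threshold in bp.
#' @param mixture Mixture data frame (`weight`, `mean`, `sd`).
#' @return Probability in `[0, 1]`.
#' @export
mixture_short_fraction <- function(threshold = 150L,
                                   mixture = default_length_mixture()) {
  sum(mixture$weight * stats::pnorm(threshold - 0.5, mixture$mean, mixture$sd))
}

#' Generate a random reference genome as an indexed FASTA
#'
#' Writes i.i.d. uniform-ACGT contigs to a FASTA file, indexes it, and
#' returns the opened [ref_genome()]. Byte-identical output for a fixed
#' seed.
#'
#' @param contig_lengths Named integer vector of contig lengths (names are
#'   contig names).
#' @param path Output FASTA path.
#' @param seed Integer RNG seed.
#' @return A [ref_genome()] for the written file.
#' @export
make_reference <- function(contig_lengths, path, seed = 1L) {
  if (length(contig_lengths) == 0L || any(contig_lengths < 1L)) {
    fb_stop("contig lengths must be positive", "fragbam_param_error")
  }
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  }
  seqs <- withr::with_seed(derive_seed(seed, "reference"), {
    vapply(contig_lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(contig_lengths)
  Biostrings::writeXStringSet(dss, path)
  unlink(paste0(path, ".fai"))
  Rsamtools::indexFa(path)
  ref_genome(path)
}

# Flag fragment midpoints lying inside any dip interval (same contig).
midpoint_in_intervals <- function(contig, mid, intervals) {
  gr_mid <- GenomicRanges::GRanges(contig, IRanges::IRanges(mid + 1L, mid + 1L))
  gr_iv <- GenomicRanges::GRanges(intervals$contig,
                                  IRanges::IRanges(intervals$start + 1L,
                                                   intervals$end))
  GenomicRanges::countOverlaps(gr_mid, gr_iv) > 0L
}

#' Simulate de-identified cfDNA fragments for one sample
#'
#' Fragment lengths are drawn from a Gaussian mixture (rounded, clipped to
#' at least 1 bp and at most the contig length), start positions uniformly
#' over valid placements on contigs chosen proportionally to length. When a
#' dip specification is given, a fragment whose midpoint falls inside a dip
#' interval is rejected with probability `depletion` and its position
#' redrawn, emulating the cfDNA coverage dip at open-chromatin sites while
#' keeping the per-sample fragment count exact. MAPQ is 60 with probability
#' `p_mapq_high`, otherwise uniform on 0..59; strand is Bernoulli(0.5).
#' The RNG stream is derived from `(seed, sample_id)`, so cohorts are
#' reproducible sample by sample.
#'
#' @param ref A [ref_genome()] object.
#' @param n Number of fragments.
#' @param sample_id Sample identifier (also seeds the stream).
#' @param seed Integer base seed.
#' @param mixture Length mixture data frame (`weight`, `mean`, `sd`);
#'   weights must sum to 1.
#' @param p_mapq_high Probability of the high-quality MAPQ mass
#'   (default 0.9).
#' @param mapq_high The high-quality MAPQ value (default 60).
#' @param dip_intervals Optional [interval_set()] (or its `intervals` data
#'   frame) marking regions to deplete.
#' @param depletion Midpoint rejection probability in `[0, 1]` inside dip
#'   intervals (default 0).
#' @return A fragment `data.frame` of `n` rows.
#' @export
sample_fragments <- function(ref, n, sample_id = "sample", seed = 1L,
                             mixture = default_length_mixture(),
                             p_mapq_high = 0.9, mapq_high = 60L,
                             dip_intervals = NULL, depletion = 0) {
  stopifnot(inherits(ref, "ref_genome"))
  if (abs(sum(mixture$weight) - 1) > 1e-8) {
    fb_stop("mixture weights must sum to 1", "fragbam_param_error")
  }
  if (depletion < 0 || depletion > 1) {
    fb_stop("depletion must lie in [0, 1]", "fragbam_param_error")
  }
  if (inherits(dip_intervals, "interval_set")) {
    dip_intervals <- dip_intervals$intervals
  }
  clens <- ref$contigs$length
  if (max(clens) < 1L) {
    fb_stop("reference too short for any fragment", "fragbam_param_error")
  }
  withr::with_seed(derive_seed(seed, paste0("frags:", sample_id)), {
    comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
    len <- as.integer(round(stats::rnorm(n, mixture$mean[comp],
                                         mixture$sd[comp])))
    len <- pmax(1L, pmin(len, max(clens)))
    ci <- sample.int(length(clens), n, replace = TRUE, prob = clens)
    # a length longer than its contig is clipped to that contig
    len <- pmin(len, clens[ci])
    draw_start <- function(idx) {
      as.integer(floor(stats::runif(length(idx)) * (clens[ci[idx]] - len[idx] + 1L)))
    }
    start <- draw_start(seq_len(n))
    if (!is.null(dip_intervals) && depletion > 0) {
      # redraw-until-accept: each fragment faces the depletion coin only on
      # its freshly drawn position, never again once accepted
      active <- seq_len(n)
      for (iter in 1:1000) {
        mid <- start[active] + len[active] %/% 2L
        inside <- midpoint_in_intervals(ref$contigs$name[ci[active]], mid,
                                        dip_intervals)
        reject <- active[inside & stats::runif(length(active)) < depletion]
        if (!length(reject)) break
        start[reject] <- draw_start(reject)
        active <- reject
      }
    }
    mapq <- ifelse(stats::runif(n) < p_mapq_high, as.integer(mapq_high),
                   sample(0:59, n, replace = TRUE))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    fragments(ref$contigs$name[ci], start, start + len, mapq, strand)
  })
}

#' Simulate a cohort of FinaleDB-style fragment files
#'
#' Generates one TSV per sample under `outdir`, deterministic for a fixed
#' seed. Case samples may carry a planted coverage dip.
#'
#' @param ref A [ref_genome()] object.
#' @param outdir Output directory (created if needed).
#' @param n_healthy,n_case Number of healthy and case samples (paper-scale
#'   defaults: 3 healthy cohorts are typical references).
#' @param fragments_per_sample Fragments per sample.
#' @param seed Integer base seed.
#' @param dip_intervals,depletion Dip specification applied to case samples
#'   only (see [sample_fragments()]).
#' @param gzip Write `.tsv.gz` instead of plain `.tsv`.
#' @param ... Further arguments passed to [sample_fragments()].
#' @return Data frame with columns `sample`, `group`, `path`.
#' @export
simulate_cohort <- function(ref, outdir, n_healthy = 3L, n_case = 0L,
                            fragments_per_sample = 20000L, seed = 1L,
                            dip_intervals = NULL, depletion = 0,
                            gzip = FALSE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- c(if (n_healthy > 0L) sprintf("healthy%02d", seq_len(n_healthy)),
           if (n_case > 0L) sprintf("case%02d", seq_len(n_case)))
  groups <- rep(c("healthy", "case"), c(n_healthy, n_case))
  ext <- if (gzip) ".tsv.gz" else ".tsv"
  paths <- file.path(outdir, paste0(ids, ext))
  for (i in seq_along(ids)) {
    is_case <- groups[i] == "case"
    fr <- sample_fragments(
      ref, fragments_per_sample, sample_id = ids[i], seed = seed,
      dip_intervals = if (is_case) dip_intervals else NULL,
      depletion = if (is_case) depletion else 0, ...)
    write_fragments(fr, paths[i], "FINALE_TSV")
  }
  data.frame(sample = ids, group = groups, path = paths,
             stringsAsFactors = FALSE)
}

#' Generate a non-overlapping synthetic interval set
#'
#' Places `n` equal-width intervals at evenly spaced midpoints along the
#' longest contig, inset from the edges, for use as planted dip regions
#' (synthetic DHS stand-ins).
#'
#' @param ref A [ref_genome()] object.
#' @param n Number of intervals.
#' @param width Interval width in bp.
#' @param margin Distance in bp kept clear of the contig ends.
#' @param name Set name.
#' @return An [interval_set()].
#' @export
synthetic_interval_set <- function(ref, n = 200L, width = 400L,
                                   margin = 2000L, name = "synthetic_dhs") {
  stopifnot(inherits(ref, "ref_genome"))
  i <- which.max(ref$contigs$length)
  clen <- ref$contigs$length[i]
  usable <- clen - 2L * margin
  if (usable < n * width) {
    fb_stop("contig too short for the requested interval set",
            "fragbam_param_error")
  }
  centers <- margin + as.integer(round((seq_len(n) - 0.5) / n * usable))
  interval_set(name, rep(ref$contigs$name[i], n),
               centers - width %/% 2L, centers + width %/% 2L)
}
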