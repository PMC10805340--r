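#' Parameters for BAM-to-fragment extraction
#'
#' Defaults mirror common de-identification pipelines for cfDNA data:
#' minimum mapping quality 30, duplicates and secondary/supplementary
#' alignments removed, proper pairs required.
#'
#' @param min_mapq Minimum template MAPQ (the minimum over both mates when
#'   the mate quality is available via the `MQ` tag); default 30.
#' @param drop_duplicates Drop duplicate-flagged templates (default `TRUE`).
#' @param drop_secondary_supplementary Drop secondary and supplementary
#'   alignments (default `TRUE`).
#' @param require_proper_pair Keep only proper pairs (default `TRUE`).
#' @return An `extraction_params` list.
#' @export
extraction_params <- function(min_mapq = 30L, drop_duplicates = TRUE,
                              drop_secondary_supplementary = TRUE,
                              require_proper_pair = TRUE) {
  if (!is_count(min_mapq) || min_mapq < 0L) {
    fb_stop("min_mapq must be a non-negative integer", "fragbam_param_error")
  }
  structure(list(min_mapq = as.integer(min_mapq),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_secondary_supplementary = isTRUE(drop_secondary_supplementary),
                 require_proper_pair = isTRUE(require_proper_pair)),
            class = "extraction_params")
}

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' De-identify a paired-end BAM into fragment records
#'
#' Reduces an alignment file to non-sensitive fragment coordinates, one
#' fragment per template. The fragment is emitted from the leftmost mate
#' only (the mate with TLEN > 0): `start = POS - 1`, `end = start + TLEN`,
#' strand `+` if the first-in-pair mate maps forward else `-`, and MAPQ the
#' minimum over the emitting record's quality and the mate quality when an
#' `MQ` tag is present. This leftmost-mate rule is single-emission by
#' construction (exactly one mate of a proper pair has positive TLEN) and
#' needs no mate lookup, so the input need not be coordinate-sorted.
#' Records failing any filter contribute no fragment; every drop reason is
#' counted in the summary attached as attribute `summary`.
#'
#' @param bam Path to a BAM (or SAM, converted on the fly) file.
#' @param params An [extraction_params()] object.
#' @return A fragment `data.frame` with attribute `summary`, a named list of
#'   counts: `records`, `single_end`, `unmapped`, `secondary_supplementary`,
#'   `duplicate`, `improper`, `low_mapq`, `tlen_zero_templates`,
#'   `fragments`.
#' @export
bam_to_fragments <- function(bam, params = extraction_params()) {
  if (!file.exists(bam)) {
    fb_stop(sprintf("file not found: %s", bam), "fragbam_io_error")
  }
  if (grepl("\\.sam$", bam)) {
    dest <- tempfile()
    bam <- tryCatch(Rsamtools::asBam(bam, dest, overwrite = TRUE,
                                     indexDestination = FALSE),
                    error = function(e) {
                      fb_stop(sprintf("cannot read alignment file: %s",
                                      conditionMessage(e)), "fragbam_io_error")
                    })
    on.exit(unlink(c(bam, paste0(bam, ".bai"))))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "isize"),
    tag = "MQ")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  n <- length(flag)
  summary <- list(records = n, single_end = 0L, unmapped = 0L,
                  secondary_supplementary = 0L, duplicate = 0L,
                  improper = 0L, low_mapq = 0L, tlen_zero_templates = 0L,
                  fragments = 0L)
  if (n == 0L) {
    out <- fragments()
    attr(out, "summary") <- summary
    return(out)
  }
  single <- !has_flag(flag, FLAG_PAIRED)
  summary$single_end <- sum(single)
  if (summary$single_end > 0L) {
    fb_warn(sprintf("skipped %d single-end record(s)", summary$single_end),
            "fragbam_single_end_warning")
  }
  keep <- !single
  bad <- has_flag(flag, FLAG_UNMAPPED) | has_flag(flag, FLAG_MATE_UNMAPPED)
  summary$unmapped <- sum(keep & bad)
  keep <- keep & !bad
  if (params$drop_secondary_supplementary) {
    bad <- has_flag(flag, FLAG_SECONDARY) | has_flag(flag, FLAG_SUPPLEMENTARY)
    summary$secondary_supplementary <- sum(keep & bad)
    keep <- keep & !bad
  }
  if (params$drop_duplicates) {
    bad <- has_flag(flag, FLAG_DUP)
    summary$duplicate <- sum(keep & bad)
    keep <- keep & !bad
  }
  if (params$require_proper_pair) {
    bad <- !has_flag(flag, FLAG_PROPER)
    summary$improper <- sum(keep & bad)
    keep <- keep & !bad
  }
  mq_tag <- res$tag$MQ
  mapq <- res$mapq
  tmpl_mapq <- if (is.null(mq_tag)) mapq else pmin(mapq, ifelse(is.na(mq_tag), mapq, mq_tag))
  # unknown quality (NA) never passes a positive min-MAPQ filter
  bad <- if (params$min_mapq > 0L) {
    is.na(tmpl_mapq) | tmpl_mapq < params$min_mapq
  } else {
    rep(FALSE, n)
  }
  # count low-MAPQ drops per template, not per record
  summary$low_mapq <- sum(keep & bad & res$isize > 0L)
  keep <- keep & !bad
  # templates where no mate carries a positive TLEN are fully ambiguous
  summary$tlen_zero_templates <- sum(keep & res$isize == 0L) %/% 2L
  emit <- keep & res$isize > 0L
  strand <- ifelse(
    (has_flag(flag, FLAG_FIRST) & has_flag(flag, FLAG_REVERSE)) |
      (has_flag(flag, FLAG_SECOND) & has_flag(flag, FLAG_MATE_REVERSE)),
    "-", "+")
  out <- fragments(as.character(res$rname[emit]),
                   res$pos[emit] - 1L,
                   res$pos[emit] - 1L + res$isize[emit],
                   tmpl_mapq[emit],
                   strand[emit])
  summary$fragments <- nrow(out)
  attr(out, "summary") <- summary
  out
}
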