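#' Open an indexed reference genome
#'
#' Wraps a FASTA file with its `.fai` index for random-access sequence
#' retrieval. The index is created on the fly if missing; its contig order
#' defines the alignment-header order and the coordinate sort order.
#'
#' @param fasta Path to a FASTA file (a `.fai` index is created if absent).
#' @return A `ref_genome` object with elements `fasta` (path) and `contigs`
#'   (data frame of `name`, `length` in `.fai` order).
#' @export
ref_genome <- function(fasta) {
  if (!file.exists(fasta)) {
    fb_stop(sprintf("reference FASTA not found: %s", fasta), "fragbam_io_error")
  }
  fai <- paste0(fasta, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(fasta)
  idx <- Rsamtools::scanFaIndex(fasta)
  contigs <- data.frame(
    name = as.character(GenomicRanges::seqnames(idx)),
    length = IRanges::width(idx),
    stringsAsFactors = FALSE
  )
  if (nrow(contigs) == 0L) {
    fb_stop("reference genome has no contigs", "fragbam_reference_error")
  }
  structure(list(fasta = fasta, contigs = contigs), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("ref_genome: %s (%d contig(s), %s bp)\n", x$fasta,
              nrow(x$contigs), format(sum(x$contigs$length), big.mark = ",")))
  invisible(x)
}

contig_length <- function(ref, contig) {
  i <- match(contig, ref$contigs$name)
  if (anyNA(i)) {
    fb_stop(sprintf("contig not found in reference: %s",
                    contig[which(is.na(i))[1]]), "fragbam_contig_error")
  }
  ref$contigs$length[i]
}

#' Fetch reference sequence for 0-based half-open intervals
#'
#' @param ref A [ref_genome()] object.
#' @param contig Contig name(s).
#' @param start 0-based inclusive start(s).
#' @param end 0-based exclusive end(s).
#' @return Uppercase DNA string(s) over ACGTN, one per interval, each of
#'   length `end - start`.
#' @export
ref_seq <- function(ref, contig, start, end) {
  stopifnot(inherits(ref, "ref_genome"))
  len <- contig_length(ref, contig)
  if (any(start < 0L) || any(end > len) || any(end <= start)) {
    bad <- which(start < 0L | end > len | end <= start)[1]
    fb_stop(sprintf("interval %s:%d-%d out of contig bounds (length %d)",
                    contig[bad], start[bad], end[bad], len[bad]),
            "fragbam_coordinate_error")
  }
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  unname(toupper(as.character(Rsamtools::scanFa(ref$fasta, param = gr))))
}

#' Reverse complement of DNA sequences
#'
#' Standard reverse complement over the alphabet ACGTN (case-insensitive
#' input, uppercase output; N is its own complement).
#'
#' @param seq Character vector of DNA strings.
#' @return Reverse-complemented uppercase strings.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character())
  if (any(grepl("[^ACGTNacgtn]", seq))) {
    fb_stop("sequence contains characters outside ACGTN",
            "fragbam_sequence_error")
  }
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))))
}
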