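# SAM flag bitfield constants
FLAG_PAIRED <- 1L
FLAG_PROPER <- 2L
FLAG_REVERSE <- 16L
FLAG_MATE_REVERSE <- 32L
FLAG_FIRST <- 64L
FLAG_SECOND <- 128L
FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_SECONDARY <- 256L
FLAG_DUP <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

# Leftmost mate of a '+' (or unknown) strand fragment: paired, proper,
# mate-reverse, first-in-pair = 99; its mate 147. For '-' strand fragments
# the first-in-pair is the rightmost (reverse) mate: leftmost 163, rightmost 83.
FLAG_LEFT_PLUS <- FLAG_PAIRED + FLAG_PROPER + FLAG_MATE_REVERSE + FLAG_FIRST      # 99
FLAG_RIGHT_PLUS <- FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE + FLAG_SECOND         # 147
FLAG_LEFT_MINUS <- FLAG_PAIRED + FLAG_PROPER + FLAG_MATE_REVERSE + FLAG_SECOND    # 163
FLAG_RIGHT_MINUS <- FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE + FLAG_FIRST         # 83

#' Parameters for fragment-to-alignment reconstruction
#'
#' @param read_length Length in bp of each synthetic mate (default 60, a
#'   typical cfDNA sequencing read length). A fragment shorter than
#'   `read_length` gets mates of the fragment length, so mates always exactly
#'   delimit the fragment and TLEN is lossless.
#' @param base_quality_char Single printable character filling the QUAL
#'   string (default `"I"`, Phred Q40). `*` is avoided because some tools
#'   reject missing qualities.
#' @param default_mapq MAPQ assigned when the fragment record carries none
#'   (default 60).
#' @param min_mapq Fragments with a known MAPQ below this are dropped
#'   (default 0 = keep all).
#' @param sample_name Sample name used for the read group and QNAME prefix.
#' @return A `recon_params` list.
#' @export
recon_params <- function(read_length = 60L, base_quality_char = "I",
                         default_mapq = 60L, min_mapq = 0L,
                         sample_name = "sample") {
  if (!is_count(read_length) || read_length < 1L) {
    fb_stop("read_length must be a positive integer", "fragbam_param_error")
  }
  if (nchar(base_quality_char) != 1L ||
      utf8ToInt(base_quality_char) < 33L || utf8ToInt(base_quality_char) > 126L) {
    fb_stop("base_quality_char must be one printable Phred+33 character",
            "fragbam_param_error")
  }
  if (!is_count(default_mapq) || default_mapq < 0L || default_mapq > 255L) {
    fb_stop("default_mapq must lie in 0..255", "fragbam_param_error")
  }
  if (!is_count(min_mapq) || min_mapq < 0L) {
    fb_stop("min_mapq must be a non-negative integer", "fragbam_param_error")
  }
  structure(list(read_length = as.integer(read_length),
                 base_quality_char = base_quality_char,
                 default_mapq = as.integer(default_mapq),
                 min_mapq = as.integer(min_mapq),
                 sample_name = as.character(sample_name)),
            class = "recon_params")
}

#' Build an alignment header for a reference genome
#'
#' Produces SAM header lines: `@HD` declaring coordinate sorting, one `@SQ`
#' per contig in reference order with its exact length, one `@RG` carrying
#' the sample name, and a `@PG` line recording the tool and command line.
#'
#' @param ref A [ref_genome()] object with at least one contig.
#' @param sample_name Sample name for the read group.
#' @param command_line Optional command line recorded in the `@PG` line.
#' @return Character vector of SAM header lines.
#' @export
build_header <- function(ref, sample_name = "sample", command_line = "fragbam") {
  stopifnot(inherits(ref, "ref_genome"))
  if (nrow(ref$contigs) == 0L) {
    fb_stop("reference genome has no contigs", "fragbam_reference_error")
  }
  ver <- as.character(utils::packageVersion("fragbam"))
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$contigs$name, ref$contigs$length),
    sprintf("@RG\tID:%s\tSM:%s", sample_name, sample_name),
    sprintf("@PG\tID:fragbam\tPN:fragbam\tVN:%s\tCL:%s", ver, command_line))
}

# Vectorized pair builder: one fragment row -> two alignment records.
# Returns a data.frame of 2n rows (left mate, then right mate, per fragment,
# before sorting) with all SAM columns.
pair_table <- function(frags, ref, params, serial_start = 1L) {
  n <- nrow(frags)
  if (n == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      contig = character(), pos = integer(), mapq = integer(),
                      cigar = character(), mate_contig = character(),
                      mate_pos = integer(), tlen = integer(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  L <- frags$end - frags$start
  R <- pmin(params$read_length, L)
  left_pos <- frags$start + 1L              # 1-based leftmost
  right_pos <- frags$end - R + 1L
  left_seq <- ref_seq(ref, frags$contig, frags$start, frags$start + R)
  right_seq <- reverse_complement(ref_seq(ref, frags$contig, frags$end - R,
                                          frags$end))
  minus <- frags$strand == "-"
  left_flag <- ifelse(minus, FLAG_LEFT_MINUS, FLAG_LEFT_PLUS)
  right_flag <- ifelse(minus, FLAG_RIGHT_MINUS, FLAG_RIGHT_PLUS)
  mapq <- ifelse(is.na(frags$mapq), params$default_mapq, frags$mapq)
  qname <- sprintf("%s:%09d", params$sample_name,
                   seq.int(serial_start, length.out = n))
  cigar <- sprintf("%dM", R)
  qual <- strrep(params$base_quality_char, R)
  data.frame(
    qname = rep(qname, 2L),
    flag = c(left_flag, right_flag),
    contig = rep(frags$contig, 2L),
    pos = c(left_pos, right_pos),
    mapq = rep(mapq, 2L),
    cigar = rep(cigar, 2L),
    mate_contig = "=",
    mate_pos = c(right_pos, left_pos),
    tlen = c(L, -L),
    seq = c(left_seq, right_seq),
    qual = rep(qual, 2L),
    stringsAsFactors = FALSE
  )
}

#' Convert one fragment into a synthetic paired-end alignment pair
#'
#' The two mates exactly delimit the fragment: the leftmost mate starts at
#' the fragment start on the forward strand; the rightmost mate ends at the
#' fragment end and is reverse-complemented. Each mate is
#' `min(read_length, fragment length)` bp of pure reference sequence with an
#' all-match CIGAR; `|TLEN|` equals the fragment length on both mates. For
#' `+` (or unknown) strand the leftmost mate is first-in-pair; for `-` strand
#' the rightmost mate is.
#'
#' @param frag A one-row fragment `data.frame`.
#' @param ref A [ref_genome()] object.
#' @param params A [recon_params()] object.
#' @param serial Integer serial used to derive the shared QNAME.
#' @return A two-row data frame (leftmost mate first) with SAM record
#'   columns `qname`, `flag`, `contig`, `pos`, `mapq`, `cigar`,
#'   `mate_contig`, `mate_pos`, `tlen`, `seq`, `qual`.
#' @export
fragment_to_pair <- function(frag, ref, params = recon_params(), serial = 1L) {
  frag <- validate_fragments(as.data.frame(frag))
  if (nrow(frag) != 1L) {
    fb_stop("fragment_to_pair expects exactly one fragment",
            "fragbam_param_error")
  }
  len <- contig_length(ref, frag$contig)
  if (frag$start < 0L || frag$end > len) {
    fb_stop(sprintf("fragment %s:%d-%d out of contig bounds (length %d)",
                    frag$contig, frag$start, frag$end, len),
            "fragbam_coordinate_error")
  }
  pair_table(frag, ref, params, serial_start = as.integer(serial))
}

sam_record_lines <- function(recs, sample_name) {
  if (nrow(recs) == 0L) return(character())
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tMQ:i:%d\tRG:Z:%s",
          recs$qname, recs$flag, recs$contig, recs$pos, recs$mapq, recs$cigar,
          recs$mate_contig, recs$mate_pos, recs$tlen, recs$seq, recs$qual,
          recs$mapq, sample_name)
}

#' Reconstruct a coordinate-sorted paired-end alignment file from fragments
#'
#' The core forward direction: each surviving fragment becomes exactly two
#' alignment records whose sequence is taken verbatim from the reference
#' genome, written as a coordinate-sorted SAM or BAM (BAM output is indexed).
#' Fragments with a known MAPQ below `params$min_mapq` and fragments whose
#' interval falls outside their contig (or names an unknown contig) are
#' dropped and counted; drops are reported in the summary, never silent.
#'
#' @param frags A fragment `data.frame` (see [read_fragments()]).
#' @param ref A [ref_genome()] object.
#' @param out Output path; `.sam` suffix writes SAM text, anything else BAM.
#' @param params A [recon_params()] object.
#' @param format `"auto"` (from the `out` suffix), `"bam"`, or `"sam"`.
#' @param command_line Command line recorded in the header `@PG` line.
#' @return A list: `path`, `fragments_read`, `fragments_written`,
#'   `dropped_min_mapq`, `dropped_coordinates`.
#' @export
reconstruct_bam <- function(frags, ref, out, params = recon_params(),
                            format = c("auto", "bam", "sam"),
                            command_line = "fragbam reconstruct") {
  frags <- validate_fragments(frags)
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.sam$", out)) "sam" else "bam"
  n_read <- nrow(frags)

  # coordinate validity against the .fai
  ci <- match(frags$contig, ref$contigs$name)
  ok_coord <- !is.na(ci) & frags$start >= 0L &
    frags$end <= ref$contigs$length[ifelse(is.na(ci), 1L, ci)]
  dropped_coord <- sum(!ok_coord)
  frags <- frags[ok_coord, , drop = FALSE]
  ci <- ci[ok_coord]

  # minimum-MAPQ filter: only fragments with a *known* low MAPQ are dropped
  low <- !is.na(frags$mapq) & frags$mapq < params$min_mapq
  dropped_mapq <- sum(low)
  frags <- frags[!low, , drop = FALSE]
  ci <- ci[!low]

  recs <- pair_table(frags, ref, params)
  ord <- order(rep(ci, 2L), recs$pos, recs$qname, recs$flag, method = "radix")
  recs <- recs[ord, , drop = FALSE]

  header <- build_header(ref, params$sample_name, command_line)
  sam_tmp <- tempfile(fileext = ".sam")
  writeLines(c(header, sam_record_lines(recs, params$sample_name)), sam_tmp)

  if (format == "sam") {
    if (!file.copy(sam_tmp, out, overwrite = TRUE)) {
      unlink(sam_tmp)
      fb_stop(sprintf("cannot write %s", out), "fragbam_io_error")
    }
    unlink(sam_tmp)
  } else {
    dest <- sub("\\.bam$", "", out)
    tryCatch(
      Rsamtools::asBam(sam_tmp, dest, overwrite = TRUE,
                       indexDestination = TRUE),
      error = function(e) {
        unlink(sam_tmp)
        unlink(c(out, paste0(out, ".bai")))
        fb_stop(sprintf("BAM conversion failed: %s", conditionMessage(e)),
                "fragbam_io_error")
      })
    unlink(sam_tmp)
  }
  list(path = out,
       fragments_read = n_read,
       fragments_written = nrow(frags),
       dropped_min_mapq = dropped_mapq,
       dropped_coordinates = dropped_coord)
}
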