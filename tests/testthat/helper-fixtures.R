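# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures are stored.

# Write named sequences to a temporary FASTA and open it as a reference.
tiny_ref <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), fa)
  ref_genome(fa)
}

# Canonical sortable key for comparing fragment sets field by field.
frag_key <- function(frags) {
  mq <- ifelse(is.na(frags$mapq), "NA", as.character(frags$mapq))
  sort(paste(frags$contig, frags$start, frags$end, mq, frags$strand,
             sep = ":"))
}

# Independent reverse-complement oracle (chartr-based, no Biostrings).
revcomp_oracle <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Read all alignment records of a BAM into a data frame (independent of the
# reconstruction path: plain scanBam field dump).
scan_records <- function(bam) {
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize",
             "seq", "qual")))[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             contig = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, cigar = res$cigar, tlen = res$isize,
             seq = as.character(res$seq), qual = as.character(res$qual),
             stringsAsFactors = FALSE)
}

# Write SAM text (header + records) and convert to BAM, for hand-crafted
# alignment fixtures.
sam_to_bam <- function(header, records) {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, records), sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = FALSE)
}
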