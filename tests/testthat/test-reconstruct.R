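test_that("reverse complement handles ACGTN and rejects the rest", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("NNA"), "TNN")
  expect_equal(reverse_complement("acgtn"), "NACGT")
  expect_error(reverse_complement("ACGU"), class = "fragbam_sequence_error")
  # property: agrees with an independent chartr-based oracle
  set.seed(42)
  rand <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1), TRUE),
          collapse = "")
  }, character(1))
  expect_equal(reverse_complement(rand), revcomp_oracle(rand))
})

test_that("header mirrors the reference index and declares sorting", {
  ref <- tiny_ref(list(chrT = "ACGTACGTAC", chrU = strrep("ACGT", 5)))
  h <- build_header(ref, "s1", "cmd")
  expect_equal(h[1], "@HD\tVN:1.6\tSO:coordinate")
  expect_equal(h[2], "@SQ\tSN:chrT\tLN:10")
  expect_equal(h[3], "@SQ\tSN:chrU\tLN:20")
  expect_match(h[4], "^@RG\tID:s1\tSM:s1$")
  expect_match(h[5], "^@PG\tID:fragbam")
})

test_that("a fragment becomes a proper pair that exactly delimits it", {
  ref <- tiny_ref(list(chrT = "ACGTACGTAC"))
  p <- recon_params(read_length = 4L, sample_name = "s")

  pair <- fragment_to_pair(fragments("chrT", 2L, 8L, 37L, "+"), ref, p, 1L)
  left <- pair[1, ]; right <- pair[2, ]
  expect_equal(left$pos, 3L)
  expect_equal(left$flag, 99L)     # 1+2+32+64
  expect_equal(left$cigar, "4M")
  expect_equal(left$seq, "GTAC")
  expect_equal(left$tlen, 6L)
  expect_equal(left$mate_pos, 5L)
  expect_equal(right$pos, 5L)
  expect_equal(right$flag, 147L)   # 1+2+16+128
  expect_equal(right$seq, "ACGT")  # revcomp of ref[4,8) = "ACGT"
  expect_equal(right$tlen, -6L)
  expect_equal(right$mate_pos, 3L)
  expect_equal(pair$mapq, c(37L, 37L))
  expect_equal(unique(pair$qname), "s:000000001")

  # '-' strand swaps first/second-in-pair, nothing else
  pair_m <- fragment_to_pair(fragments("chrT", 2L, 8L, 37L, "-"), ref, p, 1L)
  expect_equal(pair_m$flag, c(163L, 83L))  # 1+2+32+128 and 1+2+16+64
  expect_equal(pair_m$pos, pair$pos)
  expect_equal(pair_m$seq, pair$seq)
  expect_equal(abs(pair_m$tlen), abs(pair$tlen))

  # short fragment: R = min(read_length, L), fully overlapping mates allowed
  pair_s <- fragment_to_pair(fragments("chrT", 2L, 5L), ref, p, 1L)
  expect_equal(pair_s$cigar, c("3M", "3M"))
  expect_equal(pair_s$pos, c(3L, 3L))
  expect_equal(abs(pair_s$tlen), c(3L, 3L))

  # out-of-bounds and unknown contigs are named errors
  expect_error(fragment_to_pair(fragments("chrT", 5L, 20L), ref, p),
               class = "fragbam_coordinate_error")
  expect_error(fragment_to_pair(fragments("chrZ", 2L, 8L), ref, p),
               class = "fragbam_contig_error")
})

test_that("unknown MAPQ and strand fall back to documented defaults", {
  ref <- tiny_ref(list(chrT = "ACGTACGTAC"))
  p <- recon_params(read_length = 4L, default_mapq = 42L)
  pair <- fragment_to_pair(fragments("chrT", 2L, 8L), ref, p, 1L)
  expect_equal(pair$mapq, c(42L, 42L))
  # strand '.' is treated as '+' for pair-order assignment
  expect_equal(pair$flag, c(99L, 147L))
})

test_that("reconstructed files are sorted, complete, and faithful", {
  ref <- make_reference(c(chrA = 80000L, chrB = 50000L),
                        tempfile(fileext = ".fa"), seed = 3)
  fr <- sample_fragments(ref, 3000L, "fid", seed = 3)
  bam <- tempfile(fileext = ".bam")
  s <- reconstruct_bam(fr, ref, bam, recon_params(sample_name = "fid"))
  expect_equal(s$fragments_read, 3000L)
  expect_equal(s$fragments_written, 3000L)
  recs <- scan_records(bam)
  expect_equal(nrow(recs), 6000L)

  # coordinate sorted by (contig order, pos)
  ci <- match(recs$contig, ref$contigs$name)
  expect_true(all(diff(order(ci, recs$pos)) == 1L))

  # |TLEN| conservation against the input fragments, pair by pair
  left <- recs[recs$tlen > 0, ]
  left <- left[order(left$qname), ]
  serial <- as.integer(sub(".*:", "", left$qname))
  expect_equal(left$tlen, (fr$end - fr$start)[serial])
  expect_equal(left$pos - 1L, fr$start[serial])

  # sequence fidelity vs an independent whole-FASTA reader
  genome <- Biostrings::readDNAStringSet(ref$fasta)
  names(genome) <- sub(" .*", "", names(genome))
  idx <- sample(nrow(left), 200)
  for (i in idx) {
    expect_equal(left$seq[i],
                 as.character(Biostrings::subseq(
                   genome[[left$contig[i]]], left$pos[i],
                   left$pos[i] + nchar(left$seq[i]) - 1L)))
  }
  right <- recs[recs$tlen < 0, ]
  ridx <- sample(nrow(right), 200)
  for (i in ridx) {
    expect_equal(right$seq[i], revcomp_oracle(
      as.character(Biostrings::subseq(
        genome[[right$contig[i]]], right$pos[i],
        right$pos[i] + nchar(right$seq[i]) - 1L))))
  }

  # flag algebra: paired+proper everywhere, first XOR second within a pair,
  # read-reverse of one mate equals mate-reverse of the other
  expect_true(all(bitwAnd(recs$flag, 3L) == 3L))
  by_q <- split(recs$flag, recs$qname)
  expect_true(all(vapply(by_q, function(f) {
    length(f) == 2L &&
      bitwAnd(f[1], 64L) != bitwAnd(f[2], 64L) &&
      (bitwAnd(f[1], 16L) != 0L) == (bitwAnd(f[2], 32L) != 0L) &&
      (bitwAnd(f[2], 16L) != 0L) == (bitwAnd(f[1], 32L) != 0L)
  }, logical(1))))
})

test_that("known-MAPQ fragments below min_mapq are dropped and counted", {
  ref <- make_reference(c(chrA = 50000L), tempfile(fileext = ".fa"), seed = 5)
  fr <- sample_fragments(ref, 2000L, "mq", seed = 5, p_mapq_high = 0.5)
  bam <- tempfile(fileext = ".bam")
  s <- reconstruct_bam(fr, ref, bam, recon_params(min_mapq = 30L))
  expected <- sum(fr$mapq >= 30L)
  expect_equal(s$fragments_written, expected)
  expect_equal(s$dropped_min_mapq, 2000L - expected)
  expect_equal(nrow(scan_records(bam)), 2L * expected)
})

test_that("out-of-bounds fragments are dropped with a count, not an abort", {
  ref <- tiny_ref(list(chrT = strrep("ACGT", 100)))
  fr <- fragments(c("chrT", "chrT", "chrZ"), c(0L, 10L, 0L),
                  c(100L, 5000L, 50L))
  s <- reconstruct_bam(fr, ref, tempfile(fileext = ".bam"))
  expect_equal(s$fragments_written, 1L)
  expect_equal(s$dropped_coordinates, 2L)
})

test_that("an empty fragment set yields a valid header-only file", {
  ref <- tiny_ref(list(chrT = "ACGTACGTAC"))
  bam <- tempfile(fileext = ".bam")
  s <- reconstruct_bam(fragments(), ref, bam)
  expect_equal(s$fragments_written, 0L)
  expect_equal(nrow(scan_records(bam)), 0L)
  h <- Rsamtools::scanBamHeader(bam)[[1]]
  expect_equal(unname(h$targets["chrT"]), 10L)
})

test_that("reconstruction is deterministic down to record content", {
  ref <- make_reference(c(chrA = 40000L), tempfile(fileext = ".fa"), seed = 9)
  fr <- sample_fragments(ref, 1000L, "det", seed = 9)
  b1 <- tempfile(fileext = ".bam"); b2 <- tempfile(fileext = ".bam")
  reconstruct_bam(fr, ref, b1)
  reconstruct_bam(fr, ref, b2)
  expect_identical(scan_records(b1), scan_records(b2))
})

test_that("SAM output is honored and equivalent to BAM output", {
  ref <- tiny_ref(list(chrT = strrep("ACGT", 50)))
  fr <- fragments(c("chrT", "chrT"), c(10L, 30L), c(180L, 197L),
                  c(60L, 31L), c("+", "-"))
  sam <- tempfile(fileext = ".sam")
  reconstruct_bam(fr, ref, sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@HD\tVN:1.6\tSO:coordinate$", lines)))
  bam <- tempfile(fileext = ".bam")
  reconstruct_bam(fr, ref, bam)
  body <- lines[!grepl("^@", lines)]
  expect_equal(length(body), 2L * nrow(fr))
  expect_identical(vapply(strsplit(body, "\t"), `[[`, character(1), 1),
                   scan_records(bam)$qname)
})
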