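test_that("synthetic references are deterministic, indexed, and unbiased", {
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  r1 <- make_reference(c(chrT = 10L), fa1, seed = 1)
  r2 <- make_reference(c(chrT = 10L), fa2, seed = 1)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_equal(r1$contigs$length, 10L)
  expect_equal(nchar(ref_seq(r1, "chrT", 0L, 10L)), 10L)

  # .fai lengths equal the requested lengths, in order
  r3 <- make_reference(c(a = 1000L, b = 2500L), tempfile(fileext = ".fa"),
                       seed = 2)
  fai <- read.table(paste0(r3$fasta, ".fai"))
  expect_equal(fai$V1, c("a", "b"))
  expect_equal(fai$V2, c(1000L, 2500L))

  # GC fraction of a 100 kb contig ~ 0.5 within 3 sigma binomial
  r4 <- make_reference(c(big = 100000L), tempfile(fileext = ".fa"), seed = 3)
  seq <- ref_seq(r4, "big", 0L, 100000L)
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))
})

test_that("fragment sampling is deterministic per (seed, sample_id)", {
  ref <- make_reference(c(chrA = 50000L), tempfile(fileext = ".fa"), seed = 4)
  a <- sample_fragments(ref, 500L, "s1", seed = 4)
  b <- sample_fragments(ref, 500L, "s1", seed = 4)
  c <- sample_fragments(ref, 500L, "s2", seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # byte-identical TSV outputs
  t1 <- tempfile(); t2 <- tempfile()
  write_fragments(a, t1); write_fragments(b, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("a degenerate mixture produces a single exact length", {
  ref <- make_reference(c(chrA = 20000L), tempfile(fileext = ".fa"), seed = 5)
  fr <- sample_fragments(ref, 300L, "deg", seed = 5,
                         mixture = data.frame(weight = 1, mean = 167, sd = 0))
  expect_true(all(fr$end - fr$start == 167L))
})

test_that("the empirical short fraction matches the closed-form mixture CDF", {
  ref <- make_reference(c(chrA = 500000L), tempfile(fileext = ".fa"), seed = 6)
  n <- 50000L
  fr <- sample_fragments(ref, n, "cdf", seed = 6)
  p <- mixture_short_fraction(150L)
  emp <- mean(fr$end - fr$start < 150L)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("mapq and strand follow the cohort specification", {
  ref <- make_reference(c(chrA = 200000L), tempfile(fileext = ".fa"), seed = 7)
  n <- 20000L
  fr <- sample_fragments(ref, n, "spec", seed = 7)
  p_high <- mean(fr$mapq == 60L)
  expect_lt(abs(p_high - 0.9), 3 * sqrt(0.9 * 0.1 / n))
  expect_true(all(fr$mapq[fr$mapq != 60L] < 60L))
  p_plus <- mean(fr$strand == "+")
  expect_lt(abs(p_plus - 0.5), 3 * sqrt(0.25 / n))
})

test_that("total depletion leaves no fragment midpoint inside dip intervals", {
  ref <- make_reference(c(chrA = 300000L), tempfile(fileext = ".fa"), seed = 8)
  set <- synthetic_interval_set(ref, n = 50L, width = 400L)
  fr <- sample_fragments(ref, 10000L, "hard", seed = 8,
                         dip_intervals = set, depletion = 1.0)
  mid <- fr$start + (fr$end - fr$start) %/% 2L
  iv <- set$intervals
  inside <- vapply(seq_len(nrow(fr)), function(i) {
    any(iv$start <= mid[i] & mid[i] < iv$end)
  }, logical(1))
  expect_equal(sum(inside), 0L)
})

test_that("partial depletion thins midpoint density by the stated fraction", {
  ref <- make_reference(c(chrA = 1000000L), tempfile(fileext = ".fa"),
                        seed = 9)
  set <- synthetic_interval_set(ref, n = 200L, width = 400L)
  n <- 50000L
  fr <- sample_fragments(ref, n, "thin", seed = 9,
                         dip_intervals = set, depletion = 0.3)
  mid <- fr$start + (fr$end - fr$start) %/% 2L
  iv_width <- sum(set$intervals$end - set$intervals$start)
  genome <- ref$contigs$length
  gr_mid <- GenomicRanges::GRanges("chrA", IRanges::IRanges(mid + 1L, mid + 1L))
  gr_iv <- GenomicRanges::GRanges(set$intervals$contig,
                                  IRanges::IRanges(set$intervals$start + 1L,
                                                   set$intervals$end))
  n_inside <- sum(GenomicRanges::countOverlaps(gr_mid, gr_iv) > 0)
  # rejected mass is redistributed genome-wide; expected inside fraction
  p_iv <- iv_width / genome
  p_expect <- p_iv * 0.7 / (1 - 0.3 * p_iv)
  expect_lt(abs(n_inside / n - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("simulate_cohort writes deterministic per-sample TSVs", {
  ref <- make_reference(c(chrA = 100000L), tempfile(fileext = ".fa"),
                        seed = 10)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- simulate_cohort(ref, d1, n_healthy = 2L, n_case = 1L,
                        fragments_per_sample = 500L, seed = 10)
  c2 <- simulate_cohort(ref, d2, n_healthy = 2L, n_case = 1L,
                        fragments_per_sample = 500L, seed = 10)
  expect_equal(c1$sample, c("healthy01", "healthy02", "case01"))
  expect_equal(c1$group, c("healthy", "healthy", "case"))
  for (i in seq_len(nrow(c1))) {
    expect_identical(readLines(c1$path[i]), readLines(c2$path[i]))
  }
  # every written file reads back as 500 valid fragments
  expect_true(all(vapply(c1$path, function(p) nrow(read_fragments(p)),
                         integer(1)) == 500L))
})
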