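#' Construct a table of de-identified cfDNA fragments
#'
#' A fragment record is the non-sensitive unit of cfDNA fragmentomics data:
#' a genomic interval in 0-based half-open coordinates, optionally carrying a
#' mapping quality and a strand. Fragment tables are plain data frames with
#' columns `contig`, `start`, `end`, `mapq`, `strand`; `mapq` is `NA` when
#' unknown and `strand` is `"."` when unknown.
#'
#' @param contig Character vector of contig names.
#' @param start Integer vector, 0-based inclusive start coordinates (>= 0).
#' @param end Integer vector, 0-based exclusive end coordinates (> start).
#' @param mapq Integer vector of mapping qualities in 0..255, `NA` = unknown.
#' @param strand Character vector over `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with columns `contig`, `start`, `end`, `mapq`,
#'   `strand`, one row per fragment.
#' @examples
#' fragments("chr1", 100L, 267L, 60L, "+")
#' @export
fragments <- function(contig = character(), start = integer(), end = integer(),
                      mapq = NA_integer_, strand = ".") {
  n <- length(contig)
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    mapq = as.integer(rep_len(mapq, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE
  )
  validate_fragments(df)
}

#' Validate a fragment table
#'
#' Checks the fragment invariants: `end > start`, `mapq` in 0..255 (or `NA`),
#' `strand` one of `+`, `-`, `.`. Called by every function that accepts
#' fragments, so invalid records never propagate.
#'
#' @param frags A fragment `data.frame` (see [fragments()]).
#' @return The validated data frame, invisibly usable in pipelines.
#' @export
validate_fragments <- function(frags) {
  need <- c("contig", "start", "end", "mapq", "strand")
  if (!all(need %in% names(frags))) {
    fb_stop(paste0("fragment table must have columns: ",
                   paste(need, collapse = ", ")), "fragbam_type_error")
  }
  if (nrow(frags) == 0L) return(frags)
  if (any(is.na(frags$start)) || any(is.na(frags$end)) ||
      any(frags$start < 0L)) {
    fb_stop("fragment coordinates must be non-negative integers",
            "fragbam_type_error")
  }
  bad <- which(frags$end <= frags$start)
  if (length(bad)) {
    fb_stop(sprintf("fragment %d has end <= start (%d <= %d)",
                    bad[1], frags$end[bad[1]], frags$start[bad[1]]),
            "fragbam_type_error")
  }
  mq <- frags$mapq[!is.na(frags$mapq)]
  if (length(mq) && (any(mq < 0L) || any(mq > 255L))) {
    fb_stop("mapq must lie in 0..255", "fragbam_type_error")
  }
  if (!all(frags$strand %in% c("+", "-", "."))) {
    fb_stop("strand must be one of '+', '-', '.'", "fragbam_type_error")
  }
  frags
}

# Registered dialects: ordered column roles for each tabular fragment format.
FRAG_DIALECTS <- c("BED3", "BEDPE", "FINALE_TSV")

normalize_dialect <- function(dialect) {
  d <- toupper(dialect)
  d <- switch(d, BED = "BED3", TSV = "FINALE_TSV", FINALE = "FINALE_TSV", d)
  if (!d %in% c(FRAG_DIALECTS, "AUTO")) {
    fb_stop(sprintf("unknown dialect '%s'", dialect), "fragbam_dialect_error")
  }
  d
}

looks_integer <- function(x) !is.na(suppressWarnings(as.integer(x)))

#' Detect the dialect of a fragment-coordinate line
#'
#' Decides among the three supported tabular formats from a single data line:
#' 3 columns is BED3; 5 columns whose 4th parses as an integer and whose 5th
#' is a strand symbol is FinaleDB-style TSV; 6 or more columns whose
#' coordinate columns (2, 3, 5, 6) parse as integers is BEDPE.
#'
#' @param line A tab-separated, non-comment data line.
#' @return One of `"BED3"`, `"FINALE_TSV"`, `"BEDPE"`.
#' @examples
#' detect_dialect("chr1\t100\t267")
#' detect_dialect("chr1\t100\t267\t60\t+")
#' @export
detect_dialect <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  n <- length(f)
  if (n == 3L) return("BED3")
  if (n == 5L && looks_integer(f[2]) && looks_integer(f[3]) &&
      looks_integer(f[4]) && f[5] %in% c("+", "-", ".")) {
    return("FINALE_TSV")
  }
  if (n >= 6L && all(looks_integer(f[c(2, 3, 5, 6)]))) return("BEDPE")
  fb_stop(sprintf("cannot detect fragment dialect from line: '%s'", line),
          "fragbam_dialect_error")
}

# Open a text connection, sniffing gzip/bgzip magic bytes (1f 8b).
open_text <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

parse_int_col <- function(x, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    fb_stop(sprintf("line %d: non-integer %s '%s'",
                    lineno[bad[1]], what, x[bad[1]]), "fragbam_parse_error")
  }
  v
}

#' Read fragment records from a BED, BEDPE, or FinaleDB-style TSV file
#'
#' All coordinates are interpreted as 0-based half-open (the BED convention);
#' pass `one_based = TRUE` for files that use 1-based inclusive starts. Lines
#' starting with `#` or `track` are skipped; gzip/bgzip compression is
#' detected from magic bytes. BEDPE rows are collapsed to the outer fragment
#' span (min start, max end); rows whose two ends map to different contigs
#' are skipped and counted (see the `skipped_intercontig` attribute), never
#' silently dropped.
#'
#' @param path Path to a fragment file, optionally gzip/bgzip-compressed.
#' @param dialect `"auto"` (default) to detect from the first data line, or
#'   one of `"BED3"`/`"bed"`, `"BEDPE"`, `"FINALE_TSV"`/`"tsv"`.
#' @param one_based Set `TRUE` if start coordinates are 1-based inclusive.
#' @return A fragment `data.frame` (see [fragments()]) in file order, with
#'   attributes `dialect` and `skipped_intercontig`.
#' @export
read_fragments <- function(path, dialect = "auto", one_based = FALSE) {
  if (!file.exists(path)) {
    fb_stop(sprintf("file not found: %s", path), "fragbam_io_error")
  }
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  dialect <- normalize_dialect(dialect)
  skipped <- 0L
  if (length(lines) == 0L) {
    out <- fragments()
    attr(out, "dialect") <- if (dialect == "AUTO") NA_character_ else dialect
    attr(out, "skipped_intercontig") <- 0L
    return(out)
  }
  if (dialect == "AUTO") dialect <- detect_dialect(lines[1])

  f <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(f)
  min_cols <- switch(dialect, BED3 = 3L, FINALE_TSV = 5L, BEDPE = 6L)
  if (any(ncols < min_cols)) {
    bad <- which(ncols < min_cols)[1]
    fb_stop(sprintf("line %d: expected >= %d columns for %s, found %d",
                    lineno[bad], min_cols, dialect, ncols[bad]),
            "fragbam_parse_error")
  }
  col <- function(i) vapply(f, `[[`, character(1), i)

  if (dialect == "BEDPE") {
    c1 <- col(1); c2 <- col(4)
    s1 <- parse_int_col(col(2), lineno, "coordinate")
    e1 <- parse_int_col(col(3), lineno, "coordinate")
    s2 <- parse_int_col(col(5), lineno, "coordinate")
    e2 <- parse_int_col(col(6), lineno, "coordinate")
    inter <- c1 != c2
    skipped <- sum(inter)
    if (skipped > 0L) {
      fb_warn(sprintf("skipped %d inter-contig BEDPE record(s)", skipped),
              "fragbam_intercontig_warning")
    }
    contig <- c1[!inter]
    start <- pmin(s1, s2)[!inter]
    end <- pmax(e1, e2)[!inter]
    lineno <- lineno[!inter]
    mapq <- rep(NA_integer_, length(contig))
    strand <- rep(".", length(contig))
  } else {
    contig <- col(1)
    start <- parse_int_col(col(2), lineno, "coordinate")
    end <- parse_int_col(col(3), lineno, "coordinate")
    if (dialect == "FINALE_TSV") {
      raw_mq <- col(4)
      mapq <- ifelse(raw_mq == ".", NA_integer_,
                     parse_int_col(ifelse(raw_mq == ".", NA, raw_mq),
                                   lineno, "mapq"))
      strand <- col(5)
      if (!all(strand %in% c("+", "-", "."))) {
        bad <- which(!strand %in% c("+", "-", "."))[1]
        fb_stop(sprintf("line %d: invalid strand '%s'",
                        lineno[bad], strand[bad]), "fragbam_parse_error")
      }
    } else {
      mapq <- rep(NA_integer_, length(contig))
      strand <- rep(".", length(contig))
    }
  }
  if (one_based) start <- start - 1L
  bad <- which(start >= end)
  if (length(bad)) {
    fb_stop(sprintf("line %d: start >= end (%d >= %d)",
                    lineno[bad[1]], start[bad[1]], end[bad[1]]),
            "fragbam_parse_error")
  }
  out <- fragments(contig, start, end, mapq, strand)
  attr(out, "dialect") <- dialect
  attr(out, "skipped_intercontig") <- skipped
  out
}

#' Write fragment records to a tabular fragment file
#'
#' The inverse of [read_fragments()]: serializes fragments in the requested
#' dialect, tab-separated, 0-based half-open. In FinaleDB-style TSV output an
#' unknown MAPQ is written as `0` (so unknown quality can never slip past a
#' minimum-MAPQ filter) and unknown strand as `.`. BED3 carries coordinates
#' only; BEDPE writes the fragment span on both ends (coordinates only).
#' Output is gzip-compressed when `path` ends in `.gz`.
#'
#' @param frags A fragment `data.frame`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param dialect One of `"FINALE_TSV"` (default), `"BED3"`, `"BEDPE"`.
#' @return The number of records written.
#' @export
write_fragments <- function(frags, path, dialect = "FINALE_TSV") {
  frags <- validate_fragments(frags)
  dialect <- normalize_dialect(dialect)
  if (dialect == "AUTO") {
    fb_stop("write_fragments requires an explicit dialect",
            "fragbam_dialect_error")
  }
  lines <- if (nrow(frags) == 0L) {
    character()
  } else if (dialect == "BED3") {
    sprintf("%s\t%d\t%d", frags$contig, frags$start, frags$end)
  } else if (dialect == "BEDPE") {
    sprintf("%s\t%d\t%d\t%s\t%d\t%d", frags$contig, frags$start, frags$end,
            frags$contig, frags$start, frags$end)
  } else {
    mq <- ifelse(is.na(frags$mapq), 0L, frags$mapq)
    sprintf("%s\t%d\t%d\t%d\t%s", frags$contig, frags$start, frags$end,
            mq, frags$strand)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  tryCatch({
    writeLines(lines, con)
  }, error = function(e) {
    fb_stop(sprintf("cannot write %s: %s", path, conditionMessage(e)),
            "fragbam_io_error")
  }, finally = close(con))
  nrow(frags)
}
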