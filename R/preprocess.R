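# Read cleaning, tag collapsing, length distribution and genome matching.

#' Clean raw small-RNA reads
#'
#' Reproduces the standard small-RNA cleanup: the 3' adapter is located as the
#' leftmost read suffix that is an exact prefix of the adapter (seed of at
#' least `seed_len` nt) and trimmed off; reads containing the 5' adapter are
#' discarded as ligation artifacts; reads with any base call below `min_qual`
#' or containing N are discarded; inserts outside `[min_len, max_len]` are
#' discarded. Reads with no 3'-adapter seed are dropped too (the insert is
#' presumed longer than `max_len`).
#'
#' Each read is accounted to exactly one drop reason, tested in the order
#' 5'-adapter, no 3'-adapter, quality, N, length, so
#' raw = clean + sum(dropped).
#'
#' @param reads data frame from [read_fastq()] (`quality` may be `NA` or
#'   missing, in which case the quality filter is a pass-through).
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 optional 5' adapter sequence; reads containing it are
#'   discarded.
#' @param min_len,max_len insert length window kept (defaults 18 and 30 nt).
#' @param min_qual minimum Phred score; any lower base call drops the read.
#' @param seed_len minimum exact adapter prefix length required for trimming.
#' @return list with `sequences` (clean insert sequences, one per surviving
#'   read) and `stats`, a one-row data frame of the read accounting.
#' @export
clean_reads <- function(reads, adapter3, adapter5 = NULL,
                        min_len = 18L, max_len = 30L, min_qual = 20L,
                        seed_len = 6L) {
  if (is.null(adapter3) || !nzchar(adapter3)) stop("adapter3 must be non-empty")
  adapter3 <- toupper(adapter3)
  seqs <- toupper(reads$sequence)
  qual <- if ("quality" %in% names(reads)) reads$quality else NULL
  n_raw <- length(seqs)
  alive <- rep(TRUE, n_raw)
  drop <- c(adapter5 = 0L, no_adapter3 = 0L, quality = 0L,
            has_n = 0L, length = 0L)

  if (!is.null(adapter5) && nzchar(adapter5)) {
    hit5 <- grepl(toupper(adapter5), seqs, fixed = TRUE)
    drop["adapter5"] <- sum(hit5 & alive)
    alive <- alive & !hit5
  }

  # locate the 3' adapter: leftmost seed occurrence whose read suffix is
  # consistent with the adapter (either a prefix of it, or starting with the
  # full adapter); one fallback to the next seed occurrence
  seed <- substr(adapter3, 1L, seed_len)
  pos <- find_adapter_start(seqs, adapter3, seed)
  no_ad <- is.na(pos)
  drop["no_adapter3"] <- sum(no_ad & alive)
  alive <- alive & !no_ad
  ins <- substr(seqs, 1L, ifelse(is.na(pos), 0L, pos - 1L))

  if (!is.null(qual) && !all(is.na(qual))) {
    qins <- substr(qual, 1L, ifelse(is.na(pos), 0L, pos - 1L))
    # any base below min_qual: any ASCII char in [chr(33) .. chr(33+min_qual-1)]
    if (min_qual > 0L) {
      low_class <- sprintf("[\\x21-\\x%x]", 32L + min_qual)
      lowq <- grepl(low_class, qins, perl = TRUE)
      drop["quality"] <- sum(lowq & alive)
      alive <- alive & !lowq
    }
  }

  has_n <- grepl("N", ins, fixed = TRUE)
  drop["has_n"] <- sum(has_n & alive)
  alive <- alive & !has_n

  len <- nchar(ins)
  badlen <- len < min_len | len > max_len
  drop["length"] <- sum(badlen & alive)
  alive <- alive & !badlen

  stats <- data.frame(raw_reads = n_raw, clean_reads = sum(alive),
                      dropped_adapter5 = drop[["adapter5"]],
                      dropped_no_adapter3 = drop[["no_adapter3"]],
                      dropped_quality = drop[["quality"]],
                      dropped_n = drop[["has_n"]],
                      dropped_length = drop[["length"]])
  list(sequences = ins[alive], stats = stats)
}

# Leftmost plausible adapter start (1-based position in the read); NA when the
# seed is absent or the suffix disagrees with the adapter at both the first
# and second seed occurrence.
find_adapter_start <- function(seqs, adapter3, seed) {
  p <- regexpr(seed, seqs, fixed = TRUE)
  p[p < 0L] <- NA_integer_
  ok <- adapter_consistent(seqs, p, adapter3)
  retry <- which(!is.na(p) & !ok)
  if (length(retry)) {
    sub2 <- substr(seqs[retry], p[retry] + 1L, nchar(seqs[retry]))
    p2 <- regexpr(seed, sub2, fixed = TRUE)
    p2 <- ifelse(p2 < 0L, NA_integer_, p[retry] + p2)
    ok2 <- adapter_consistent(seqs[retry], p2, adapter3)
    p[retry] <- ifelse(!is.na(p2) & ok2, p2, NA_integer_)
  }
  p
}

adapter_consistent <- function(seqs, p, adapter3) {
  suffix <- substr(seqs, p, nchar(seqs))
  out <- startsWith(adapter3, suffix) | startsWith(suffix, adapter3)
  out[is.na(p)] <- FALSE
  out
}

#' Collapse clean reads into unique sequence tags
#'
#' @param libraries named list: library id -> character vector of clean read
#'   sequences.
#' @return a tag table: data frame with column `sequence` plus one integer
#'   count column per library, one row per distinct sequence, sorted
#'   lexicographically by sequence. Per-library counts sum to the number of
#'   clean reads.
#' @export
collapse_tags <- function(libraries) {
  stopifnot(is.list(libraries), length(libraries) > 0L,
            !is.null(names(libraries)), all(nzchar(names(libraries))))
  all_seqs <- sort(unique(unlist(libraries, use.names = FALSE)))
  out <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(libraries)) {
    tb <- table(factor(libraries[[lib]], levels = all_seqs))
    out[[lib]] <- as.integer(tb)
  }
  out
}

#' Library ids of a tag table
#' @param tags a tag table from [collapse_tags()].
#' @return character vector of library id columns.
#' @export
tag_libraries <- function(tags) {
  setdiff(names(tags), "sequence")
}

#' Read-weighted length distribution of a tag table
#'
#' @param tags tag table.
#' @param range lengths to report (default 18:30); lengths outside the range
#'   but present in the data are appended.
#' @return data frame with `length`, one read-count column per library, and
#'   `total`.
#' @export
length_distribution <- function(tags, range = 18:30) {
  libs <- tag_libraries(tags)
  len <- nchar(tags$sequence)
  lens <- sort(union(range, unique(len)))
  out <- data.frame(length = lens)
  for (lib in libs) {
    out[[lib]] <- as.integer(vapply(
      lens, function(L) sum(tags[[lib]][len == L]), numeric(1)))
  }
  out$total <- as.integer(rowSums(out[, libs, drop = FALSE]))
  out
}

#' Match tags against a genome reference
#'
#' A tag matches when its sequence or reverse complement occurs in any genome
#' record with at most `max_mismatch` substitutions. With the default
#' `max_mismatch = 0` the search is an exact substring scan (contractually
#' equivalent to the naive position-by-position scan).
#'
#' @param tags tag table.
#' @param genome a `reference_set` of genome records.
#' @param max_mismatch allowed substitutions (default 0).
#' @return list with `matched` (logical per tag), `matched_reads` and
#'   `clean_reads` (named per-library totals), and `percent`
#'   (matched reads / clean reads x 100, per library).
#' @export
match_genome <- function(tags, genome, max_mismatch = 0L) {
  stopifnot(inherits(genome, "reference_set"), length(genome$ids) > 0L)
  libs <- tag_libraries(tags)
  seqs <- tags$sequence
  if (max_mismatch == 0L) {
    fwd <- cpp_find_exact(seqs, genome$sequences)
    rev <- cpp_find_exact(revcomp(seqs), genome$sequences)
  } else {
    fwd <- cpp_find_mismatch(seqs, genome$sequences, max_mismatch)
    rev <- cpp_find_mismatch(revcomp(seqs), genome$sequences, max_mismatch)
  }
  matched <- !is.na(fwd) | !is.na(rev)
  counts <- as.matrix(tags[, libs, drop = FALSE])
  matched_reads <- colSums(counts[matched, , drop = FALSE])
  clean_reads <- colSums(counts)
  list(matched = matched,
       matched_reads = matched_reads,
       clean_reads = clean_reads,
       percent = genome_match_percent(matched_reads, clean_reads))
}

#' Genome-matched read percentage
#'
#' @param matched_reads number of reads matching the genome.
#' @param clean_reads total clean reads (denominator).
#' @return `matched_reads / clean_reads * 100`.
#' @export
genome_match_percent <- function(matched_reads, clean_reads) {
  if (any(clean_reads <= 0)) stop("clean_reads must be positive")
  matched_reads / clean_reads * 100
}

#' Per-library summary of preprocessing
#'
#' @param library_id library identifier.
#' @param clean_stats `stats` element from [clean_reads()].
#' @param unique_tags number of distinct tags with nonzero count.
#' @param genome_matched_reads reads matching the genome (optional).
#' @return one-row data frame (raw, clean, unique tags, genome-matched).
#' @export
library_summary <- function(library_id, clean_stats, unique_tags = NA_integer_,
                            genome_matched_reads = NA_integer_) {
  data.frame(library_id = library_id,
             raw_reads = clean_stats$raw_reads,
             clean_reads = clean_stats$clean_reads,
             unique_tags = unique_tags,
             genome_matched_reads = genome_matched_reads)
}
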