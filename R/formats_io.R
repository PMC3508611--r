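# Readers/writers for the external formats the pipeline touches. All other
# modules consume/produce the plain data frames defined here.

#' Read a 4-line-record FASTQ file
#'
#' Parses Sanger/Phred+33 FASTQ. N-containing reads are retained here;
#' filtering is the preprocessing step's job, so I/O stays policy-free.
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @return a data frame with columns `id`, `sequence`, `quality` (one row per
#'   record, input order preserved). `quality` is the raw ASCII string.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", n,
         " lines (truncated record starting at line ", (n %/% 4L) * 4L + 1L, ")")
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- toupper(lines[seq(2L, n, by = 4L)])
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("malformed FASTQ: header at line ", (bad[1L] - 1L) * 4L + 1L,
         " does not start with '@'")
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop("malformed FASTQ: separator at line ", (bad[1L] - 1L) * 4L + 3L,
         " does not start with '+'")
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("malformed FASTQ: quality at line ", (bad[1L] - 1L) * 4L + 4L,
         " has length ", nchar(qual[bad[1L]]), " but sequence has length ",
         nchar(seqs[bad[1L]]))
  }
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) {
    stop("malformed FASTQ: empty sequence at line ", (bad[1L] - 1L) * 4L + 2L)
  }
  data.frame(id = sub("^@", "", hdr), sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data frame with columns `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1L, length.out = nrow(reads), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length.out = nrow(reads), by = 4L)] <- reads$sequence
  out[seq(3L, length.out = nrow(reads), by = 4L)] <- "+"
  out[seq(4L, length.out = nrow(reads), by = 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA reference set
#'
#' Sequences are upper-cased and U residues normalized to T so a single
#' alphabet flows through the pipeline. The record id is the first
#' whitespace-delimited header token; the remainder is kept as a description
#' but never used for joins.
#'
#' @param path FASTA file.
#' @param category one of the closed reference-set vocabulary:
#'   `r paste(REF_CATEGORIES, collapse = ", ")`.
#' @return an object of class `reference_set`: a list with `category`, `ids`,
#'   `sequences` (named character vector) and `descriptions`.
#' @export
read_fasta <- function(path, category = "genome") {
  category <- match.arg(category, REF_CATEGORIES)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(ss))))
  names(seqs) <- ids
  reference_set(seqs, category, descriptions = desc)
}

#' Construct a reference set from in-memory sequences
#'
#' @param sequences named character vector (names are record ids).
#' @param category reference-set category.
#' @param descriptions optional character vector of header remainders.
#' @return a `reference_set` object.
#' @export
reference_set <- function(sequences, category = "genome",
                          descriptions = NULL) {
  category <- match.arg(category, REF_CATEGORIES)
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("reference sequences must be named by record id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("U", "T", toupper(as.character(sequences)))
  names(seqs) <- ids
  structure(list(category = category, ids = ids, sequences = seqs,
                 descriptions = descriptions %||% rep("", length(ids))),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>", x$category, "-", length(x$ids), "record(s)\n")
  invisible(x)
}

#' Write a reference set to FASTA
#'
#' @param refset a `reference_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refset, path) {
  ss <- Biostrings::BStringSet(refset$sequences)
  names(ss) <- refset$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a feature-by-library count table as TSV
#'
#' Rows are sorted lexicographically by feature id so output is deterministic.
#'
#' @param table data frame whose first column is `feature_id` and remaining
#'   columns are per-library non-negative integer counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(is.data.frame(table), names(table)[1L] == "feature_id")
  counts <- table[, -1L, drop = FALSE]
  if (nrow(table) && (any(counts < 0) || any(counts != round(counts)))) {
    stop("counts must be non-negative integers")
  }
  table <- table[order(table$feature_id, method = "radix"), , drop = FALSE]
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV path with a header row of library ids.
#' @return data frame with `feature_id` plus one integer column per library.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "feature_id") {
    stop("count table must have 'feature_id' as its first column: ", path)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
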