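# Hierarchical annotation: every tag is assigned to exactly one class by the
# fixed priority rule GenBank ncRNA > Rfam ncRNA > known miRNA > repeat >
# exon > intron; anything left is unannotated.

# category -> reference set(s) consulted, in priority order; the known-miRNA
# class matches against hairpin precursors (degradation/isomiR logic) as well
# as mature sequences
PRIORITY_SOURCES <- list(
  rRNA_etc_genbank = "genbank_ncrna",
  rRNA_etc_rfam = "rfam_ncrna",
  known_miRNA = c("known_mirna_hairpin", "known_mirna_mature"),
  "repeat" = "repeat",
  exon = "exon",
  intron = "intron")

#' Classify tags by the priority annotation rule
#'
#' A tag "matches" a reference category when it is a substring of a reference
#' record on either strand (degradation-fragment logic), allowing
#' `max_mismatch` substitutions. Categories are tested in strict priority
#' order and the first match wins. Ties inside a category resolve to the
#' lexicographically smallest reference id (reporting only).
#'
#' @param tags tag table from [collapse_tags()].
#' @param refsets named list of `reference_set` objects; recognized names (in
#'   priority order): `genbank_ncrna`, `rfam_ncrna`, `known_mirna_mature`,
#'   `repeat`, `exon`, `intron`. Missing sets are skipped.
#' @param max_mismatch allowed substitutions (default 0 = exact substring).
#' @return data frame with `sequence`, `category` (one of
#'   `r paste(ANNOT_CATEGORIES, collapse = ", ")`) and `matched_id` (empty
#'   string iff unannotated).
#' @export
classify_tags <- function(tags, refsets, max_mismatch = 0L) {
  seqs <- tags$sequence
  n <- length(seqs)
  category <- rep("unannotated", n)
  matched_id <- rep("", n)
  pending <- rep(TRUE, n)
  for (cat in names(PRIORITY_SOURCES)) {
    sets <- refsets[PRIORITY_SOURCES[[cat]]]
    sets <- sets[!vapply(sets, is.null, logical(1))]
    if (!length(sets) || !any(pending)) next
    stopifnot(all(vapply(sets, inherits, logical(1), "reference_set")))
    refseq <- unlist(lapply(sets, `[[`, "sequences"), use.names = FALSE)
    ids <- unlist(lapply(sets, `[[`, "ids"), use.names = FALSE)
    ord <- order(ids, method = "radix")  # lexicographic tie rule
    refseq <- refseq[ord]
    ids <- ids[ord]
    idx <- which(pending)
    if (max_mismatch == 0L) {
      fwd <- cpp_find_exact(seqs[idx], refseq)
      rev <- cpp_find_exact(revcomp(seqs[idx]), refseq)
    } else {
      fwd <- cpp_find_mismatch(seqs[idx], refseq, max_mismatch)
      rev <- cpp_find_mismatch(revcomp(seqs[idx]), refseq, max_mismatch)
    }
    best <- pmin(fwd, rev, na.rm = TRUE)
    hit <- !is.na(best)
    category[idx[hit]] <- cat
    matched_id[idx[hit]] <- ids[best[hit]]
    pending[idx[hit]] <- FALSE
  }
  data.frame(sequence = seqs, category = category, matched_id = matched_id,
             stringsAsFactors = FALSE)
}

#' Class-frequency table (unique-tag % and read %)
#'
#' @param annotations data frame from [classify_tags()] (same row order as
#'   `tags`).
#' @param tags tag table the annotations refer to.
#' @return data frame with `category`, `tag_percent` and `read_percent`; both
#'   percentage columns sum to 100 within rounding.
#' @export
class_frequencies <- function(annotations, tags) {
  stopifnot(nrow(annotations) == nrow(tags),
            all(annotations$sequence == tags$sequence))
  libs <- tag_libraries(tags)
  reads <- rowSums(tags[, libs, drop = FALSE])
  cats <- factor(annotations$category, levels = ANNOT_CATEGORIES)
  tag_n <- tapply(rep(1L, nrow(tags)), cats, sum, default = 0L)
  read_n <- tapply(reads, cats, sum, default = 0)
  data.frame(category = ANNOT_CATEGORIES,
             unique_tags = as.integer(tag_n),
             reads = as.numeric(read_n),
             tag_percent = as.numeric(tag_n) / sum(tag_n) * 100,
             read_percent = as.numeric(read_n) / sum(read_n) * 100,
             row.names = NULL)
}
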