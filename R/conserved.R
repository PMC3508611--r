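# Conserved miRNA identification, family grouping, isomiR end heterogeneity
# and arm-usage analysis.

#' Match tags against a known mature miRNA catalog
#'
#' Each tag is aligned (ungapped, length-matched sliding with terminal
#' overhangs) against every catalog mature sequence; a hit is emitted when
#' mismatches <= `max_mm` OR identity > `min_identity`, where identity =
#' matched positions / alignment columns. Each tag keeps only its best hit
#' (fewest mismatches, then highest identity, then lexicographically smallest
#' catalog id), so the result is independent of tag and catalog input order.
#'
#' @param tags tag table from [collapse_tags()].
#' @param mature_catalog `reference_set` of category `known_mirna_mature`.
#' @param max_mm mismatch allowance (default 2).
#' @param min_identity identity threshold (default 0.90, strict inequality).
#' @param max_shift maximum terminal shift explored (default 5 nt).
#' @param min_overlap minimum aligned overlap (default 16 nt) — keeps the
#'   mismatch rule from firing on short chance overlaps.
#' @return data frame with `sequence`, `mirna_id`, `mismatches`, `identity`,
#'   one row per tag with a qualifying hit.
#' @export
match_conserved <- function(tags, mature_catalog, max_mm = 2L,
                            min_identity = 0.90, max_shift = 5L,
                            min_overlap = 16L) {
  stopifnot(inherits(mature_catalog, "reference_set"))
  ord <- order(mature_catalog$ids, method = "radix")
  mats <- mature_catalog$sequences[ord]
  ids <- mature_catalog$ids[ord]
  res <- cpp_conserved_best(tags$sequence, mats, max_shift, min_overlap)
  keep <- !is.na(res$idx) &
    (res$mismatches <= max_mm | res$identity > min_identity)
  data.frame(sequence = tags$sequence[keep],
             mirna_id = ids[res$idx[keep]],
             mismatches = res$mismatches[keep],
             identity = res$identity[keep],
             stringsAsFactors = FALSE)
}

#' Per-miRNA count table from conserved hits
#'
#' Sums the counts of all tags assigned to each catalog miRNA.
#'
#' @param hits data frame from [match_conserved()].
#' @param tags the tag table the hits refer to.
#' @return count table data frame: `feature_id` (miRNA id) plus one count
#'   column per library.
#' @export
mirna_counts <- function(hits, tags) {
  libs <- tag_libraries(tags)
  m <- merge(hits[, c("sequence", "mirna_id")], tags, by = "sequence")
  ids <- sort(unique(m$mirna_id))
  out <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  for (lib in libs) {
    s <- tapply(m[[lib]], factor(m$mirna_id, levels = ids), sum, default = 0)
    out[[lib]] <- as.integer(s)
  }
  out
}

#' Normalize a miRNA id to its family stem name
#'
#' Strips the species prefix (e.g. `lpa-`), a trailing star marker, the arm
#' suffix (`-3p`/`-5p`), a single-digit paralog copy suffix (e.g. `miR-7-2` ->
#' `miR-7`), and trailing letter variants after the family number (`miR-124a`
#' -> `miR-124`, `let-7i` -> `let-7`). Extend via `extra_rules`, a named
#' character vector of regex -> replacement applied first.
#'
#' @param ids character vector of miRNA ids.
#' @param extra_rules optional named character vector of substitutions.
#' @return character vector of family names.
#' @export
mirna_family <- function(ids, extra_rules = NULL) {
  x <- ids
  if (!is.null(extra_rules)) {
    for (k in seq_along(extra_rules)) {
      x <- sub(names(extra_rules)[k], extra_rules[[k]], x)
    }
  }
  x <- sub("^[A-Za-z]{2,4}-(?=(miR|let|lin|mir))", "", x, perl = TRUE)
  x <- sub("\\*$", "", x)
  x <- sub("-(3p|5p)$", "", x)
  x <- sub("^(.*[0-9][a-z]?)-[0-9]$", "\\1", x)   # paralog copy number
  x <- sub("([0-9])[a-z]+$", "\\1", x)           # letter variants
  x
}

#' Group conserved hits into miRNA families
#'
#' @param counts per-miRNA count table from [mirna_counts()].
#' @param extra_rules passed to [mirna_family()].
#' @return data frame with `family`, `n_members`, `member_ids`
#'   (comma-separated) and per-library read totals; family totals equal the
#'   sum of member totals.
#' @export
group_families <- function(counts, extra_rules = NULL) {
  libs <- setdiff(names(counts), "feature_id")
  fam <- mirna_family(counts$feature_id, extra_rules)
  fams <- sort(unique(fam))
  f <- factor(fam, levels = fams)
  out <- data.frame(family = fams,
                    n_members = as.integer(table(f)),
                    member_ids = vapply(split(counts$feature_id, f),
                                        paste, character(1), collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (lib in libs) {
    out[[lib]] <- as.numeric(tapply(counts[[lib]], f, sum, default = 0))
  }
  out
}

#' IsomiR end heterogeneity on one precursor
#'
#' Maps tags exactly (0 mismatches) within the precursor and keys isoforms by
#' their 5' and 3' offsets relative to the annotated mature sequence. Offsets
#' are in nt; negative = upstream of the annotated end.
#'
#' @param precursor precursor (hairpin) sequence.
#' @param tags tag table; only tags occurring exactly in the precursor are
#'   used.
#' @param annotated_mature annotated mature sequence; must occur in the
#'   precursor.
#' @return list with `isoforms` (data frame: sequence, start_offset,
#'   end_offset, count), `predominant` (row index of the max-count isoform),
#'   `n_distinct_5p`, `n_distinct_3p`.
#' @export
end_heterogeneity <- function(precursor, tags, annotated_mature) {
  precursor <- chartr("U", "T", toupper(precursor))
  annotated_mature <- chartr("U", "T", toupper(annotated_mature))
  m0 <- cpp_locate_first(annotated_mature, precursor)
  if (is.na(m0)) stop("annotated mature sequence not found in precursor")
  m_end <- m0 + nchar(annotated_mature) - 1L
  pos <- cpp_locate_first(tags$sequence, precursor)
  keep <- !is.na(pos)
  if (!any(keep)) {
    return(list(isoforms = data.frame(sequence = character(),
                                      start_offset = integer(),
                                      end_offset = integer(),
                                      count = integer()),
                predominant = NA_integer_,
                n_distinct_5p = 0L, n_distinct_3p = 0L))
  }
  libs <- tag_libraries(tags)
  counts <- rowSums(tags[keep, libs, drop = FALSE])
  iso <- data.frame(sequence = tags$sequence[keep],
                    start_offset = pos[keep] - m0,
                    end_offset = (pos[keep] + nchar(tags$sequence[keep]) - 1L) -
                      m_end,
                    count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  iso <- iso[order(-iso$count, iso$start_offset, iso$end_offset), ]
  rownames(iso) <- NULL
  list(isoforms = iso,
       predominant = 1L,
       n_distinct_5p = length(unique(iso$start_offset)),
       n_distinct_3p = length(unique(iso$end_offset)))
}

#' Detect arm switching on a hairpin precursor
#'
#' The precursor is folded (built-in stacking model) to locate the terminal
#' loop; tags mapping entirely 5' of the loop belong to the 5p arm, entirely
#' 3' to the 3p arm, and loop-straddling or loop-only reads are excluded. The
#' dominant arm is the one with the larger read count; ties resolve to the
#' annotated arm (no switch flagged).
#'
#' @param precursor hairpin sequence.
#' @param tags tag table (tags mapped exactly, 0 mismatches).
#' @param annotated_arm `"5p"` or `"3p"`.
#' @param fold optional precomputed [fold_hairpin()] result for `precursor`.
#' @return list with `dominant_arm`, `annotated_arm`, `switched` (logical; NA
#'   when no arm reads at all), `reads_5p`, `reads_3p`.
#' @export
detect_arm_switch <- function(precursor, tags, annotated_arm,
                              fold = NULL) {
  annotated_arm <- match.arg(annotated_arm, c("5p", "3p"))
  precursor <- chartr("U", "T", toupper(precursor))
  if (is.null(fold)) fold <- fold_hairpin(precursor)
  loop <- terminal_loop(fold$structure)
  if (is.null(loop)) stop("no stem detected in precursor structure")
  pos <- cpp_locate_first(tags$sequence, precursor)
  keep <- !is.na(pos)
  libs <- tag_libraries(tags)
  counts <- rowSums(tags[, libs, drop = FALSE])
  starts <- pos[keep]
  ends <- starts + nchar(tags$sequence[keep]) - 1L
  cnt <- counts[keep]
  r5 <- sum(cnt[ends < loop[1L]])
  r3 <- sum(cnt[starts > loop[2L]])
  if (r5 + r3 == 0) {
    return(list(dominant_arm = NA_character_, annotated_arm = annotated_arm,
                switched = NA, reads_5p = 0, reads_3p = 0))
  }
  dominant <- if (r5 > r3) "5p" else if (r3 > r5) "3p" else annotated_arm
  list(dominant_arm = dominant, annotated_arm = annotated_arm,
       switched = dominant != annotated_arm, reads_5p = r5, reads_3p = r3)
}

# Innermost base pair of the structure = the pair closing the terminal loop.
# Returns c(loop_start, loop_end) in 1-based sequence coordinates (the
# unpaired stretch between the innermost pair), or NULL when nothing pairs.
terminal_loop <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  opens <- which(ch == "(")
  closes <- which(ch == ")")
  if (!length(opens)) return(NULL)
  i <- max(opens)
  j <- min(closes[closes > i])
  c(i + 1L, j - 1L)
}
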