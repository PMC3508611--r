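# Novel miRNA prediction: precursor folding, the six hairpin candidacy
# criteria, MFE/AMFE/MFEI, and cross-library merging.

#' Fold a candidate precursor into its minimum-free-energy hairpin
#'
#' The default engine is the package's deterministic base-pair stacking model
#' (dynamic program over all nested structures; stacked G:C pairs score -3,
#' stacked A:U/G:U pairs -1, loop-closing pairs 0, minimum loop 3 nt), which
#' defines the energy scale used by every hairpin criterion and by the
#' synthetic generator's build-time verification. `engine = "vienna"` calls an
#' installed `RNAfold` binary instead (nearest-neighbor thermodynamics) for
#' cross-checking.
#'
#' @param sequence nucleotide sequence (A/C/G/T or U; 40-400 nt is the
#'   intended range).
#' @param engine `"stack"` (default) or `"vienna"`.
#' @return object of class `fold_result`: list with `sequence`, `structure`
#'   (dot-bracket, same length as the sequence) and `mfe` (<= 0).
#' @export
fold_hairpin <- function(sequence, engine = c("stack", "vienna")) {
  engine <- match.arg(engine)
  seq <- chartr("U", "T", toupper(sequence))
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGT/U symbols")
  }
  if (engine == "stack") {
    r <- cpp_fold_stack(seq)
    structure(list(sequence = seq, structure = r$structure, mfe = r$mfe),
              class = "fold_result")
  } else {
    if (Sys.which("RNAfold") == "") stop("RNAfold binary not found on PATH")
    out <- system2("RNAfold", args = "--noPS", input = chartr("T", "U", seq),
                   stdout = TRUE)
    line <- out[2L]
    db <- sub("\\s.*$", "", line)
    mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
    structure(list(sequence = seq, structure = db, mfe = mfe),
              class = "fold_result")
  }
}

#' @export
print.fold_result <- function(x, ...) {
  cat(chartr("T", "U", x$sequence), "\n", x$structure,
      sprintf(" (%.2f)\n", x$mfe), sep = "")
  invisible(x)
}

# partner[i] = paired position of i (1-based), NA if unpaired
pairing_table <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Adjusted MFE and minimal folding free energy index
#'
#' AMFE = |MFE| / length x 100; MFEI = AMFE / GC%, with GC on the 0-100
#' scale. Both are reported positive.
#'
#' @param mfe minimum free energy (kcal/mol, <= 0).
#' @param sequence the folded sequence.
#' @return named numeric: `amfe`, `mfei`, `gc_percent`.
#' @export
compute_mfei <- function(mfe, sequence) {
  seq <- chartr("U", "T", toupper(sequence))
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  gc <- sum(strsplit(seq, "")[[1L]] %in% c("G", "C")) / n * 100
  if (gc == 0) stop("GC content is zero; MFEI undefined")
  amfe <- abs(mfe) / n * 100
  c(amfe = amfe, mfei = amfe / gc, gc_percent = gc)
}

#' Evaluate the six hairpin candidacy criteria
#'
#' Criteria: (1) the putative mature sequence is 20-24 nt and resides on a
#' stem arm (entirely outside the terminal loop, at least half its bases
#' paired); (2) its read count is at least `min_count`; (3) precursor MFE is
#' at or below `mfe_max`; (4) the largest bulge (unpaired run) within the
#' mature span is at most `max_bulge` nt; (5) mature and star lengths differ
#' by at most `max_size_diff` nt and the intervening spacing is at most
#' `max_spacing` nt; (6) duplex asymmetry (difference in unpaired bases
#' between the mature and star spans) is at most `max_asym` nt. When no stem
#' is detected the stem-dependent criteria fail but the candidate is retained
#' with its flags.
#'
#' @param reads data frame with `sequence` and `count` of reads mapped to the
#'   precursor; the most abundant read occurring exactly in the precursor is
#'   taken as the putative mature (ties break to the lexicographically
#'   smallest sequence).
#' @param fold a [fold_hairpin()] result for the precursor.
#' @param min_count,mfe_max,max_bulge,max_size_diff,max_spacing,max_asym
#'   thresholds (defaults 5, -18 kcal/mol, 4, 5, 35, 5 nt).
#' @return object of class `hairpin_candidate`: list with `precursor`,
#'   `fold`, `mature` (sequence, start, arm), `star` (sequence, start; NULL
#'   when no stem), `mature_read_count`, `criteria` (named logical),
#'   `passed_all`, `mfe`, `amfe`, `mfei`.
#' @export
evaluate_criteria <- function(reads, fold, min_count = 5, mfe_max = -18,
                              max_bulge = 4, max_size_diff = 5,
                              max_spacing = 35, max_asym = 5) {
  stopifnot(inherits(fold, "fold_result"),
            all(c("sequence", "count") %in% names(reads)))
  prec <- fold$sequence
  reads <- reads[order(-reads$count, reads$sequence), , drop = FALSE]
  pos <- cpp_locate_first(reads$sequence, prec)
  in_prec <- which(!is.na(pos))
  if (!length(in_prec)) stop("no read maps within the precursor")
  mi <- in_prec[1L]
  mature_seq <- reads$sequence[mi]
  m_start <- pos[mi]
  m_end <- m_start + nchar(mature_seq) - 1L
  m_len <- nchar(mature_seq)
  count <- reads$count[mi]

  partner <- pairing_table(fold$structure)
  loop <- terminal_loop(fold$structure)
  has_stem <- !is.null(loop)

  arm <- NA_character_
  star <- NULL
  star_len <- NA_integer_
  spacing <- NA_integer_
  bulge <- NA_integer_
  asym <- NA_integer_
  frac_paired <- 0
  if (has_stem) {
    if (m_end < loop[1L]) arm <- "5p"
    if (m_start > loop[2L]) arm <- "3p"
    mp <- partner[m_start:m_end]
    frac_paired <- mean(!is.na(mp))
    r <- rle(is.na(mp))
    bulge <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (any(!is.na(mp))) {
      s_lo <- min(mp, na.rm = TRUE)
      s_hi <- max(mp, na.rm = TRUE)
      star_len <- s_hi - s_lo + 1L
      star <- list(sequence = substr(prec, s_lo, s_hi), start = s_lo)
      spacing <- if (s_lo > m_end) s_lo - m_end - 1L else m_start - s_hi - 1L
      spacing <- max(spacing, 0L)
      sp <- partner[s_lo:s_hi]
      asym <- abs(sum(is.na(mp)) - sum(is.na(sp)))
    }
  }

  criteria <- c(
    mature_size_stem = isTRUE(m_len >= 20 && m_len <= 24 && !is.na(arm) &&
                                frac_paired >= 0.5),
    mature_count = count >= min_count,
    mfe = fold$mfe <= mfe_max,
    bulge = isTRUE(!is.na(bulge) && bulge <= max_bulge),
    size_spacing = isTRUE(!is.na(star_len) &&
                            abs(m_len - star_len) <= max_size_diff &&
                            !is.na(spacing) && spacing <= max_spacing),
    asymmetry = isTRUE(!is.na(asym) && asym <= max_asym)
  )
  ix <- compute_mfei(fold$mfe, prec)
  structure(list(precursor = prec, fold = fold,
                 mature = list(sequence = mature_seq, start = m_start,
                               arm = arm),
                 star = star, mature_read_count = count,
                 criteria = criteria, passed_all = all(criteria),
                 mfe = fold$mfe, amfe = unname(ix["amfe"]),
                 mfei = unname(ix["mfei"])),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("<hairpin_candidate> mature", x$mature$sequence,
      sprintf("(arm %s, count %d)\n", x$mature$arm, x$mature_read_count))
  cat(sprintf("  MFE %.2f  AMFE %.3f  MFEI %.4f  passed_all: %s\n",
              x$mfe, x$amfe, x$mfei, x$passed_all))
  cat("  criteria:", paste(names(x$criteria)[!x$criteria], collapse = ", "),
      if (all(x$criteria)) "(all pass)" else "(failing)", "\n")
  invisible(x)
}

#' Filter candidates on the MFEI cutoff
#'
#' @param candidates data frame with an `mfei` column, or a list of
#'   `hairpin_candidate` objects.
#' @param cutoff minimum MFEI retained (default 0.97, inclusive).
#' @return the retained candidates, input order preserved.
#' @export
filter_mfei <- function(candidates, cutoff = 0.97) {
  if (is.data.frame(candidates)) {
    candidates[candidates$mfei >= cutoff, , drop = FALSE]
  } else {
    candidates[vapply(candidates, function(x) x$mfei, numeric(1)) >= cutoff]
  }
}

#' Merge per-library novel miRNA sets
#'
#' Identity across libraries is exact mature-sequence equality.
#'
#' @param matures_a,matures_b character vectors of mature sequences predicted
#'   in each library (duplicates are collapsed).
#' @return list with `n_a`, `n_b`, `shared` (intersection), `n_shared`, and
#'   `union_count` = |A| + |B| - |A n B|.
#' @export
merge_libraries <- function(matures_a, matures_b) {
  a <- unique(matures_a)
  b <- unique(matures_b)
  shared <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), shared = shared,
       n_shared = length(shared),
       union_count = length(a) + length(b) - length(shared))
}

#' Predict novel miRNA candidates from tags and a genome
#'
#' Maps candidate tags exactly onto the genome (both strands), merges
#' overlapping mapped tags into loci, takes the most abundant tag of each
#' locus as the putative mature, extracts two flanking windows (mature near
#' the window 3' end and near the 5' end), folds both and keeps the
#' lower-MFE hairpin, then evaluates the six candidacy criteria and the
#' MFE/AMFE/MFEI statistics.
#'
#' @param tags tag table (pass the unannotated subset for a real run).
#' @param genome `reference_set` of genome records.
#' @param library library column to use for counts; default sums all
#'   libraries.
#' @param flank flanking window length on the far side of the mature
#'   (default 100 nt).
#' @param near near-side margin (default 15 nt).
#' @param min_count,mfe_max,max_bulge,max_size_diff,max_spacing,max_asym
#'   criteria thresholds, passed to [evaluate_criteria()].
#' @return data frame with one row per locus: mature sequence and locus
#'   (record, strand, 0-based half-open start/end), counts, precursor,
#'   structure, mfe, amfe, mfei, one logical column per criterion, and
#'   `passed_all`.
#' @export
predict_novel <- function(tags, genome, library = NULL, flank = 100L,
                          near = 15L, min_count = 5, mfe_max = -18,
                          max_bulge = 4, max_size_diff = 5, max_spacing = 35,
                          max_asym = 5) {
  stopifnot(inherits(genome, "reference_set"))
  libs <- tag_libraries(tags)
  counts <- if (is.null(library)) {
    rowSums(tags[, libs, drop = FALSE])
  } else {
    tags[[library]]
  }
  keep <- counts > 0
  tags <- tags[keep, , drop = FALSE]
  counts <- counts[keep]
  rows <- list()
  for (rec in genome$ids) {
    rseq <- genome$sequences[[rec]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tags$sequence else revcomp(tags$sequence)
      pos <- cpp_locate_first(q, rseq)
      hit <- which(!is.na(pos))
      if (!length(hit)) next
      starts <- pos[hit]
      ends <- starts + nchar(tags$sequence[hit]) - 1L
      ord <- order(starts, ends)
      hit <- hit[ord]; starts <- starts[ord]; ends <- ends[ord]
      # merge overlapping mapped tags into loci
      locus <- cumsum(c(1L, as.integer(starts[-1L] >
                                         cummax(ends[-length(ends)]))))
      for (l in unique(locus)) {
        sel <- which(locus == l)
        cnt <- counts[hit[sel]]
        top <- sel[order(-cnt, tags$sequence[hit[sel]])][1L]
        m_start <- starts[top]
        m_end <- ends[top]
        w1 <- c(max(1L, m_start - flank), min(nchar(rseq), m_end + near))
        w2 <- c(max(1L, m_start - near), min(nchar(rseq), m_end + flank))
        best <- NULL
        for (w in list(w1, w2)) {
          wseq <- substr(rseq, w[1L], w[2L])
          if (strand == "-") wseq <- as.character(revcomp(wseq))
          f <- fold_hairpin(wseq)
          if (is.null(best) || f$mfe < best$mfe) best <- f
        }
        loc_reads <- data.frame(sequence = tags$sequence[hit[sel]],
                                count = as.numeric(cnt),
                                stringsAsFactors = FALSE)
        cand <- evaluate_criteria(loc_reads, best, min_count = min_count,
                                  mfe_max = mfe_max, max_bulge = max_bulge,
                                  max_size_diff = max_size_diff,
                                  max_spacing = max_spacing,
                                  max_asym = max_asym)
        rows[[length(rows) + 1L]] <- data.frame(
          record = rec, strand = strand,
          start = m_start - 1L, end = m_end,   # 0-based half-open
          mature = cand$mature$sequence, arm = cand$mature$arm,
          count = cand$mature_read_count,
          precursor = cand$precursor, structure = cand$fold$structure,
          mfe = cand$mfe, amfe = cand$amfe, mfei = cand$mfei,
          t(as.data.frame(cand$criteria)),
          passed_all = cand$passed_all,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(record = character(), strand = character(),
                      start = integer(), end = integer(),
                      mature = character(), arm = character(),
                      count = numeric(), precursor = character(),
                      structure = character(), mfe = numeric(),
                      amfe = numeric(), mfei = numeric(),
                      passed_all = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
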