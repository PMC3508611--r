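# Rule-based miRNA target-site scanning: ungapped antiparallel duplexes
# scored with G:U wobbles as half mismatches.

DUPLEX_COLS <- c("site_start", "mismatch_total", "mismatch_1_12",
                 "mm_at_10_11", "max_adjacent_mm_2_12", "energy",
                 "perfect_energy")

#' Score a single miRNA/site duplex
#'
#' The site must have the same length as the miRNA (ungapped duplex). miRNA
#' position p (1-based from the miRNA 5' end) faces site position L - p + 1
#' (antiparallel). Watson-Crick pairs count 0, G:U wobbles 0.5, anything else
#' 1 mismatch. Pair energies are GC -3, AU -2, GU -1, mismatch 0; the energy
#' ratio is the duplex energy over the energy of the miRNA bound to its
#' perfect complement.
#'
#' @param mirna miRNA sequence (5' to 3').
#' @param site target site sequence (5' to 3', same length).
#' @return one-row data frame with the mismatch ledger (`mismatch_total`,
#'   `mismatch_1_12`, `mm_at_10_11`, `max_adjacent_mm_2_12`), `energy`,
#'   `perfect_energy`, `energy_ratio`, and `pass` (all five rules).
#' @export
score_duplex <- function(mirna, site) {
  mirna <- chartr("U", "T", toupper(mirna))
  site <- chartr("U", "T", toupper(site))
  if (nchar(mirna) != nchar(site)) {
    stop("site length (", nchar(site), ") must equal miRNA length (",
         nchar(mirna), ")")
  }
  m <- cpp_scan_duplex(mirna, site)
  df <- as.data.frame(m)
  df$site_start <- NULL
  df$energy_ratio <- ifelse(df$perfect_energy == 0, 0,
                            df$energy / df$perfect_energy)
  df$pass <- duplex_rules_pass(df)
  df
}

# The five duplex rules (the energy-ratio threshold is rule five).
duplex_rules_pass <- function(df, max_mm_total = 4, max_mm_1_12 = 2.5,
                              max_adjacent = 2, min_energy_ratio = 0.75) {
  df$mismatch_total <= max_mm_total &
    df$mm_at_10_11 == 0 &
    df$max_adjacent_mm_2_12 <= max_adjacent &
    df$mismatch_1_12 <= max_mm_1_12 &
    df$energy_ratio >= min_energy_ratio
}

#' Scan a transcript for miRNA target sites
#'
#' Every window of miRNA length is scored as an ungapped duplex; windows
#' passing all five rules (total mismatches <= 4 with G:U = 0.5, no mismatch
#' at positions 10-11, no run of three or more mismatched positions within
#' 2-12, at most 2.5 mismatches in positions 1-12, duplex energy at least
#' 75% of the perfect-complement energy) are returned sorted by position.
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript (mRNA/3'UTR) sequence, at least as long as
#'   the miRNA; scanning is sense-strand only.
#' @param max_mm_total,max_mm_1_12,max_adjacent,min_energy_ratio rule
#'   thresholds (defaults 4, 2.5, 2, 0.75).
#' @return data frame of passing windows: `site_start` (0-based), `site`
#'   sequence, the mismatch ledger, `energy`, `perfect_energy`,
#'   `energy_ratio`.
#' @export
scan_transcript <- function(mirna, transcript, max_mm_total = 4,
                            max_mm_1_12 = 2.5, max_adjacent = 2,
                            min_energy_ratio = 0.75) {
  mirna <- chartr("U", "T", toupper(mirna))
  transcript <- chartr("U", "T", toupper(transcript))
  if (nchar(transcript) < nchar(mirna)) {
    stop("transcript (", nchar(transcript),
         " nt) is shorter than the miRNA (", nchar(mirna), " nt)")
  }
  df <- as.data.frame(cpp_scan_duplex(mirna, transcript))
  df$energy_ratio <- ifelse(df$perfect_energy == 0, 0,
                            df$energy / df$perfect_energy)
  keep <- duplex_rules_pass(df, max_mm_total, max_mm_1_12, max_adjacent,
                            min_energy_ratio)
  df <- df[keep, , drop = FALSE]
  df$site <- substr(rep(transcript, nrow(df)), df$site_start,
                    df$site_start + nchar(mirna) - 1L)
  df$site_start <- df$site_start - 1L  # 0-based
  rownames(df) <- NULL
  df[, c("site_start", "site", "mismatch_total", "mismatch_1_12",
         "mm_at_10_11", "max_adjacent_mm_2_12", "energy", "perfect_energy",
         "energy_ratio")]
}

#' Scan many miRNAs against many transcripts
#'
#' @param mirnas `reference_set` of mature miRNAs.
#' @param transcripts `reference_set` of transcript sequences.
#' @param ... thresholds passed to [scan_transcript()].
#' @return data frame with `mirna_id`, `transcript_id` and the
#'   [scan_transcript()] columns for every passing site.
#' @export
scan_targets <- function(mirnas, transcripts, ...) {
  stopifnot(inherits(mirnas, "reference_set"),
            inherits(transcripts, "reference_set"))
  out <- list()
  for (mid in mirnas$ids) {
    for (tid in transcripts$ids) {
      hits <- scan_transcript(mirnas$sequences[[mid]],
                              transcripts$sequences[[tid]], ...)
      if (nrow(hits)) {
        out[[length(out) + 1L]] <- cbind(
          data.frame(mirna_id = mid, transcript_id = tid,
                     stringsAsFactors = FALSE), hits)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site = character(),
                      mismatch_total = numeric(), mismatch_1_12 = numeric(),
                      mm_at_10_11 = numeric(),
                      max_adjacent_mm_2_12 = numeric(), energy = numeric(),
                      perfect_energy = numeric(), energy_ratio = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
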