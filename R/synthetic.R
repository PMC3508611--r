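# Seed-deterministic synthetic data: a toy genome with planted miRNA
# hairpins, contaminant reference sets, two-condition read libraries with
# known fold changes, and qPCR CT tables -- plus machine-readable truth.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: two skin
#' libraries ("white" and "brown") of 1e5 reads at desk scale, tag lengths
#' concentrated at 22 nt, a minority of planted miRNAs with condition fold
#' changes in the 2-48 range (defaults plant FC 5 and 8), adapter-flanked
#' reads, and contaminant ncRNA/repeat/exon/intron fragments.
#'
#' @param n_reads reads per library (default 1e5).
#' @param n_mirnas number of planted miRNA precursors (default 30).
#' @param fc_spec data frame with columns `id`, `fc` (>= 1) and `direction`
#'   (`"white"` or `"brown"`); miRNAs not listed have true FC 1. Default:
#'   eight planted changes, four per direction, FCs 5 and 8.
#' @param error_rate per-base substitution probability (default 0.005).
#' @param modal_length most frequent mature length (default 22 nt).
#' @param adapter3,adapter5 adapter sequences (Illumina small-RNA defaults).
#' @param class_props named proportions of clean reads per class: `mirna`,
#'   `genbank_ncrna`, `rfam_ncrna`, `repeat`, `exon`, `intron`, `random`;
#'   must sum to 1.
#' @param libraries names of the two condition libraries.
#' @param adapter5_rate,no_adapter_rate,low_quality_rate rates of planted
#'   artifact reads (5'-adapter contaminants, adapter-free reads, reads with
#'   one low-quality base call).
#' @param seed integer seed; every generator operation is deterministic in it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1e5L, n_mirnas = 30L, fc_spec = NULL,
                       error_rate = 0.005, modal_length = 22L,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       class_props = c(mirna = 0.40, genbank_ncrna = 0.12,
                                       rfam_ncrna = 0.08, "repeat" = 0.06,
                                       exon = 0.05, intron = 0.04,
                                       random = 0.25),
                       libraries = c("white", "brown"),
                       adapter5_rate = 0.002, no_adapter_rate = 0.002,
                       low_quality_rate = 0.005, seed = 1L) {
  if (is.null(fc_spec)) {
    fc_spec <- data.frame(
      id = paste0("sim-miR-", 1:8),
      fc = c(5, 8, 5, 8, 5, 8, 5, 8),
      direction = rep(c("white", "brown"), each = 4),
      stringsAsFactors = FALSE)
  }
  stopifnot(n_reads > 0, n_mirnas >= nrow(fc_spec),
            error_rate >= 0, error_rate <= 0.05, all(fc_spec$fc >= 1),
            abs(sum(class_props) - 1) < 1e-8, length(libraries) == 2L)
  structure(list(n_reads = as.integer(n_reads),
                 n_mirnas = as.integer(n_mirnas), fc_spec = fc_spec,
                 error_rate = error_rate,
                 modal_length = as.integer(modal_length),
                 adapter3 = adapter3, adapter5 = adapter5,
                 class_props = class_props, libraries = libraries,
                 adapter5_rate = adapter5_rate,
                 no_adapter_rate = no_adapter_rate,
                 low_quality_rate = low_quality_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(n, len, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  chars <- sample(alphabet, sum(len), replace = TRUE, prob = prob)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  s <- paste(chars, collapse = "")
  substring(s, starts, ends)
}

# Design one criterion-passing precursor: inert A/C flanks and loop so the
# fold is exactly the designed mature/star stem.
design_precursor <- function(mature_len, arm) {
  mature <- random_seq(1L, mature_len)
  gc <- compute_gc(mature)
  while (gc < 0.40 || gc > 0.65) {
    mature <- random_seq(1L, mature_len)
    gc <- compute_gc(mature)
  }
  loop <- random_seq(1L, 12L, alphabet = c("A", "C"))
  flank5 <- random_seq(1L, 10L, alphabet = c("A", "C"))
  flank3 <- random_seq(1L, 10L, alphabet = c("A", "C"))
  star <- as.character(revcomp(mature))
  prec <- if (arm == "5p") {
    paste0(flank5, mature, loop, star, flank3)
  } else {
    paste0(flank5, star, loop, mature, flank3)
  }
  list(mature = mature, precursor = prec, arm = arm)
}

compute_gc <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  mean(v %in% c("G", "C"))
}

#' Build the synthetic genome, reference sets and truth
#'
#' Plants `n_mirnas` designed stem-loop precursors (each verified at build
#' time to pass all six hairpin criteria with MFE <= -18 and MFEI >= 0.97
#' under the package's folding model) separated by random spacers, appends
#' AT-rich repeat decoy loci, and emits contaminant reference sets. Every
#' planted mature sequence is verified to occur exactly once in the genome.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`reference_set`), `refsets` (named list of
#'   `reference_set`s: genbank_ncrna, rfam_ncrna, known_mirna_mature,
#'   known_mirna_hairpin, repeat, exon, intron), and `truth` (planted miRNA
#'   table with per-condition proportions and fold changes, class
#'   proportions, seed).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mirnas
  lens <- sample(c(20:24), n, replace = TRUE,
                 prob = length_weights(20:24, config$modal_length))
  arms <- rep(c("5p", "3p"), length.out = n)
  mirnas <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:50) {
      d <- design_precursor(lens[i], arms[i])
      f <- fold_hairpin(d$precursor)
      cand <- evaluate_criteria(
        data.frame(sequence = d$mature, count = 10), f)
      ix <- compute_mfei(f$mfe, d$precursor)
      if (cand$passed_all && ix[["mfei"]] >= 0.97 && f$mfe <= -18) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to design a criterion-passing precursor; ",
                  "try another seed")
    mirnas[[i]] <- d
  }

  # AT-rich repeat decoys: abundant, genome-resident, fold poorly
  n_rep <- 3L
  repeats <- random_seq(n_rep, 120L, prob = c(0.4, 0.1, 0.1, 0.4))
  names(repeats) <- paste0("sim-repeat-", seq_len(n_rep))

  spacers <- random_seq(n + n_rep + 1L, sample(150:250, n + n_rep + 1L,
                                               replace = TRUE))
  pieces <- character(0)
  for (i in seq_len(n)) {
    pieces <- c(pieces, spacers[i], mirnas[[i]]$precursor)
  }
  for (j in seq_len(n_rep)) {
    pieces <- c(pieces, spacers[n + j], repeats[[j]])
  }
  pieces <- c(pieces, spacers[n + n_rep + 1L])
  chrom <- paste(pieces, collapse = "")
  genome <- reference_set(c(synth_chr1 = chrom), "genome")

  matures <- vapply(mirnas, `[[`, character(1), "mature")
  precs <- vapply(mirnas, `[[`, character(1), "precursor")
  ids <- paste0("sim-miR-", seq_len(n))
  # each mature occurs exactly once on the sense strand; its reverse
  # complement (the designed star) also occurs exactly once, in the same
  # precursor
  occ <- cpp_count_occurrences(matures, chrom)
  occ_rc <- cpp_count_occurrences(as.character(revcomp(matures)), chrom)
  if (any(occ != 1L) || any(occ_rc != 1L)) {
    stop("planted mature sequence does not occur exactly once in the ",
         "genome; try another seed")
  }

  # per-condition proportions: base weights log-normal, fold changes applied
  # symmetrically (sqrt(FC) up / down), background absorbs the remainder
  w <- exp(rnorm(n, sd = 0.8))
  w <- w / sum(w) * config$class_props[["mirna"]]
  fc <- rep(1, n)
  dirv <- rep(NA_character_, n)
  m <- match(config$fc_spec$id, ids)
  if (anyNA(m)) stop("fc_spec ids must be sim-miR-1..n")
  fc[m] <- config$fc_spec$fc
  dirv[m] <- config$fc_spec$direction
  up_w <- ifelse(is.na(dirv), 1, ifelse(dirv == config$libraries[1L],
                                        sqrt(fc), 1 / sqrt(fc)))
  prop_a <- w * up_w
  prop_b <- w / up_w
  # rescale so neither library's miRNA mass exceeds its class share; the same
  # factor applies to both libraries, so per-miRNA cross-library ratios (the
  # planted fold changes) are preserved exactly
  rescale <- config$class_props[["mirna"]] / max(sum(prop_a), sum(prop_b))
  prop_a <- prop_a * rescale
  prop_b <- prop_b * rescale

  truth_mirnas <- data.frame(
    id = ids, mature = matures, precursor = precs,
    arm = vapply(mirnas, `[[`, character(1), "arm"),
    length = nchar(matures),
    prop_a = prop_a, prop_b = prop_b,
    fc = fc, direction = dirv, stringsAsFactors = FALSE)
  names(truth_mirnas)[names(truth_mirnas) == "prop_a"] <-
    paste0("prop_", config$libraries[1L])
  names(truth_mirnas)[names(truth_mirnas) == "prop_b"] <-
    paste0("prop_", config$libraries[2L])

  refsets <- list(
    genbank_ncrna = reference_set(
      stats::setNames(random_seq(5L, sample(80:150, 5L, replace = TRUE)),
                      paste0("sim-rRNA-", 1:5)), "genbank_ncrna"),
    rfam_ncrna = reference_set(
      stats::setNames(random_seq(4L, sample(70:120, 4L, replace = TRUE)),
                      paste0("sim-snoRNA-", 1:4)), "rfam_ncrna"),
    known_mirna_mature = reference_set(
      stats::setNames(matures, ids), "known_mirna_mature"),
    known_mirna_hairpin = reference_set(
      stats::setNames(precs, sub("miR", "mir", ids)), "known_mirna_hairpin"),
    "repeat" = reference_set(repeats, "repeat"),
    exon = reference_set(
      stats::setNames(random_seq(4L, sample(200:400, 4L, replace = TRUE)),
                      paste0("sim-exon-", 1:4)), "exon"),
    intron = reference_set(
      stats::setNames(random_seq(4L, sample(200:400, 4L, replace = TRUE)),
                      paste0("sim-intron-", 1:4)), "intron"))

  truth <- list(mirnas = truth_mirnas, class_props = config$class_props,
                libraries = config$libraries, seed = config$seed)
  list(genome = genome, refsets = refsets, truth = truth)
}

length_weights <- function(lens, modal) {
  w <- 0.5^abs(lens - modal)
  w / sum(w)
}

#' Simulate the two condition read libraries
#'
#' Read counts per planted miRNA are drawn multinomially from the
#' condition-specific proportions encoding the fold-change spec. miRNA reads
#' are the mature sequence with end-offset noise (5' offset 0/+1/-1 with
#' probabilities 0.9/0.05/0.05; 3' offset 0/+1/-1/+2/-2 with probabilities
#' 0.7/0.1/0.1/0.05/0.05 -- 3'-biased, as observed in sequenced isomiRs),
#' substitution errors at `error_rate`, then the 3' adapter appended.
#' Background reads are fragments of the contaminant references and random
#' sequence (including out-of-range lengths), and small planted fractions of
#' 5'-adapter contaminants, adapter-free reads and low-quality reads.
#'
#' @param sim output of [build_genome()].
#' @param config the same [sim_config()].
#' @param offsets_off disable end-offset noise (used to verify the noise-free
#'   contract).
#' @return named list (per library) of read data frames suitable for
#'   [write_fastq()].
#' @export
simulate_libraries <- function(sim, config, offsets_off = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  tm <- truth$mirnas
  out <- list()
  for (lib in config$libraries) {
    props <- tm[[paste0("prop_", lib)]]
    cp <- config$class_props
    other <- c(cp[["genbank_ncrna"]], cp[["rfam_ncrna"]], cp[["repeat"]],
               cp[["exon"]], cp[["intron"]])
    p_all <- c(props, other, 1 - sum(props) - sum(other))
    counts <- as.vector(rmultinom(1L, config$n_reads, p_all))
    n_mir <- nrow(tm)
    inserts <- character(0)

    for (i in seq_len(n_mir)) {
      ci <- counts[i]
      if (ci == 0L) next
      if (offsets_off) {
        inserts <- c(inserts, rep(tm$mature[i], ci))
        next
      }
      off5 <- sample(c(0L, 1L, -1L), ci, replace = TRUE,
                     prob = c(0.9, 0.05, 0.05))
      off3 <- sample(c(0L, 1L, -1L, 2L, -2L), ci, replace = TRUE,
                     prob = c(0.7, 0.1, 0.1, 0.05, 0.05))
      p0 <- cpp_locate_first(tm$mature[i], tm$precursor[i])
      s <- p0 + off5
      e <- p0 + nchar(tm$mature[i]) - 1L + off3
      inserts <- c(inserts, substring(tm$precursor[i], s, e))
    }

    cont_sets <- c("genbank_ncrna", "rfam_ncrna", "repeat", "exon", "intron")
    for (k in seq_along(cont_sets)) {
      ck <- counts[n_mir + k]
      if (ck == 0L) next
      rs <- sim$refsets[[cont_sets[k]]]
      rec <- sample(length(rs$ids), ck, replace = TRUE)
      flen <- sample(18:26, ck, replace = TRUE,
                     prob = length_weights(18:26, config$modal_length))
      rl <- nchar(rs$sequences)[rec]
      st <- 1L + floor(runif(ck) * pmax(1L, rl - flen + 1L))
      inserts <- c(inserts, substring(rs$sequences[rec], st, st + flen - 1L))
    }

    n_rand <- counts[length(counts)]
    if (n_rand > 0L) {
      rlen <- sample(c(15:17, 18:30, 31:40), n_rand, replace = TRUE,
                     prob = c(rep(0.05 / 3, 3),
                              0.85 * length_weights(18:30,
                                                    config$modal_length),
                              rep(0.10 / 10, 10)))
      inserts <- c(inserts, random_seq(n_rand, rlen))
    }

    inserts <- apply_substitution_errors(inserts, config$error_rate)
    reads <- paste0(inserts, config$adapter3)

    n_tot <- length(reads)
    # planted artifacts
    n5 <- rbinom(1L, n_tot, config$adapter5_rate)
    if (n5 > 0L) {
      idx <- sample(n_tot, n5)
      reads[idx] <- paste0(config$adapter5, reads[idx])
    }
    n_na <- rbinom(1L, n_tot, config$no_adapter_rate)
    if (n_na > 0L) {
      idx <- sample(n_tot, n_na)
      reads[idx] <- random_seq(n_na, 40L)
    }
    qual <- strrep("I", nchar(reads))
    n_lq <- rbinom(1L, n_tot, config$low_quality_rate)
    if (n_lq > 0L) {
      idx <- sample(n_tot, n_lq)
      pos <- 1L + floor(runif(n_lq) * nchar(inserts[idx]))
      substr(qual[idx], pos, pos) <- "#"
    }
    perm <- sample.int(n_tot)
    out[[lib]] <- data.frame(
      id = sprintf("sim_%s_%07d", lib, seq_len(n_tot)),
      sequence = reads[perm], quality = qual[perm],
      stringsAsFactors = FALSE)
  }
  out
}

apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(1L, sum(lens), rate)
  if (n_err == 0L) return(seqs)
  ridx <- sample.int(length(seqs), n_err, replace = TRUE,
                     prob = lens / sum(lens))
  pos <- 1L + floor(runif(n_err) * lens[ridx])
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    old <- substr(seqs[ridx[k]], pos[k], pos[k])
    substr(seqs[ridx[k]], pos[k], pos[k]) <- sample(setdiff(bases, old), 1L)
  }
  seqs
}

#' Generate a qPCR CT table consistent with the planted fold changes
#'
#' CT values follow ct_ref + noise for the reference assay (U6) and
#' ct_ref - log2(expression) + offset + noise for each target, so
#' [ddct_relative_quantity()] / [qpcr_relative_quantity()] recover the
#' planted condition ratios up to noise.
#'
#' @param sim output of [build_genome()].
#' @param config the [sim_config()].
#' @param n_replicates biological replicates per condition (default 4).
#' @param noise_sd CT noise standard deviation in cycles (default 0.2; 0
#'   gives exact recovery).
#' @param assays which planted miRNA ids to assay (default: the fc_spec ids).
#' @return data frame with `sample`, `condition`, `assay`, `ct`.
#' @export
make_qpcr_table <- function(sim, config, n_replicates = 4L, noise_sd = 0.2,
                            assays = NULL) {
  set.seed(config$seed + 2L)
  tm <- sim$truth$mirnas
  if (is.null(assays)) assays <- config$fc_spec$id
  stopifnot(all(assays %in% tm$id))
  rows <- list()
  for (lib in config$libraries) {
    props <- tm[[paste0("prop_", lib)]]
    for (r in seq_len(n_replicates)) {
      sample_id <- sprintf("%s_%d", lib, r)
      ct_ref <- 20 + rnorm(1L, sd = noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, condition = lib, assay = "U6", ct = ct_ref,
        stringsAsFactors = FALSE)
      for (a in assays) {
        expr <- props[tm$id == a]
        ct <- ct_ref - log2(expr) + rnorm(1L, sd = noise_sd) - 10
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, condition = lib, assay = a, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build genome, libraries and qPCR table in one call
#'
#' @param config a [sim_config()].
#' @param ... passed to [make_qpcr_table()].
#' @return list with `genome`, `refsets`, `truth`, `reads` (per-library read
#'   data frames) and `ct` (CT table).
#' @export
simulate_dataset <- function(config = sim_config(), ...) {
  sim <- build_genome(config)
  reads <- simulate_libraries(sim, config)
  ct <- make_qpcr_table(sim, config, ...)
  c(sim, list(reads = reads, ct = ct))
}
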