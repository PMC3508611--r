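# Recovery studies on synthetic data: how well the pipeline recalls planted
# fold changes and planted hairpin loci under the generator's conditions.

#' Differential-expression recovery study
#'
#' Runs `n_replicates` independent simulations (genome + two libraries at the
#' configured depth), pushes each through cleaning, tag collapsing, conserved
#' matching and [differential_expression()], and scores the calls against the
#' planted truth: recall = fraction of planted miRNAs with true FC at or
#' above `fc_floor` that are called differential in the right direction pool;
#' false-call rate = fraction of true-FC-1 miRNAs called differential.
#'
#' @param n_replicates number of simulation replicates (default 20).
#' @param config base [sim_config()]; each replicate uses `seed + replicate`.
#' @param seed base seed.
#' @param fc_floor planted fold change defining a positive (default 5).
#' @param min_fc,alpha differential gates (defaults 2 and 0.01).
#' @return data frame with one row per replicate: `recall`,
#'   `false_call_rate`, `n_planted`, `n_null`.
#' @export
de_recovery_study <- function(n_replicates = 20L, config = sim_config(),
                              seed = config$seed, fc_floor = 5,
                              min_fc = 2, alpha = 0.01) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 1000L * r)
    sim <- build_genome(cfg)
    reads <- simulate_libraries(sim, cfg)
    cl <- lapply(reads, clean_reads, adapter3 = cfg$adapter3,
                 adapter5 = cfg$adapter5)
    tags <- collapse_tags(lapply(cl, `[[`, "sequences"))
    hits <- match_conserved(tags, sim$refsets$known_mirna_mature)
    counts <- mirna_counts(hits, tags)
    totals <- vapply(cl, function(x) x$stats$clean_reads, numeric(1))
    de <- differential_expression(counts, totals, min_fc = min_fc,
                                  alpha = alpha)
    called <- de$mirna_id[de$significant]
    tm <- sim$truth$mirnas
    planted <- tm$id[tm$fc >= fc_floor]
    nulls <- tm$id[tm$fc == 1]
    out[[r]] <- data.frame(
      recall = mean(planted %in% called),
      false_call_rate = mean(nulls %in% called),
      n_planted = length(planted), n_null = length(nulls))
  }
  do.call(rbind, out)
}

#' Hairpin (novel miRNA) recovery study
#'
#' Simulates a dataset, maps the cleaned tags onto the synthetic genome and
#' runs [predict_novel()]. A planted precursor counts as recovered when some
#' candidate passing all six criteria with MFEI at or above `mfei_min` has
#' its putative mature inside that precursor; precision is the fraction of
#' passing candidates whose mature lies inside any planted precursor.
#'
#' @param n_replicates simulation replicates (default 5).
#' @param config base [sim_config()]; each replicate uses `seed + replicate`.
#' @param seed base seed.
#' @param min_count mature-count floor defining an eligible planted locus
#'   (default 5; loci sequenced below it are excluded from the denominator).
#' @param mfei_min MFEI cutoff (default 0.97).
#' @return data frame with one row per replicate: `recall`, `precision`,
#'   `n_eligible`, `n_predicted`.
#' @export
hairpin_recovery_study <- function(n_replicates = 5L, config = sim_config(),
                                   seed = config$seed, min_count = 5,
                                   mfei_min = 0.97) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 1000L * r)
    sim <- build_genome(cfg)
    reads <- simulate_libraries(sim, cfg)
    cl <- lapply(reads, clean_reads, adapter3 = cfg$adapter3,
                 adapter5 = cfg$adapter5)
    tags <- collapse_tags(lapply(cl, `[[`, "sequences"))
    gm <- match_genome(tags, sim$genome)
    cand <- predict_novel(tags[gm$matched, , drop = FALSE], sim$genome,
                          min_count = min_count)
    pass <- cand[cand$passed_all & cand$mfei >= mfei_min, , drop = FALSE]
    tm <- sim$truth$mirnas
    libs <- tag_libraries(tags)
    mature_count <- vapply(tm$mature, function(m) {
      i <- match(m, tags$sequence)
      if (is.na(i)) 0 else sum(tags[i, libs])
    }, numeric(1))
    eligible <- tm$precursor[mature_count >= min_count]
    recovered <- vapply(eligible, function(p) {
      any(vapply(pass$mature, grepl, logical(1), x = p, fixed = TRUE))
    }, logical(1))
    in_planted <- vapply(pass$mature, function(m) {
      any(vapply(tm$precursor, grepl, logical(1), pattern = m,
                 fixed = TRUE))
    }, logical(1))
    out[[r]] <- data.frame(
      recall = mean(recovered),
      precision = if (nrow(pass)) mean(in_planted) else NA_real_,
      n_eligible = length(eligible), n_predicted = nrow(pass))
  }
  do.call(rbind, out)
}
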