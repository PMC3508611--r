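mk_catalog <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- paste0("sim-miR-", seq_along(seqs))
  reference_set(stats::setNames(seqs, ids), "known_mirna_mature")
}

test_that("exact and near matches hit; three substitutions do not", {
  mat <- "GCATTCAGGCTAGCATGGACTC"  # aperiodic 22-mer
  cat <- mk_catalog(mat)
  hit <- match_conserved(tiny_tags(mat, 1L, 0L), cat)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$mismatches, 0L)
  expect_equal(hit$identity, 1.0)

  two_mm <- mat
  substr(two_mm, 3, 3) <- "T"    # A -> T
  substr(two_mm, 10, 10) <- "A"  # C -> A
  expect_identical(match_conserved(tiny_tags(two_mm, 1L, 0L),
                                   cat)$mismatches, 2L)

  three_mm <- two_mm
  substr(three_mm, 15, 15) <- "G"  # A -> G
  # 3 substitutions on a 22-mer: 19/22 = 0.864 identity, both rules fail
  expect_identical(nrow(match_conserved(tiny_tags(three_mm, 1L, 0L), cat)),
                   0L)
})

test_that("identity > 0.90 on a 22-mer needs at least 20 matching positions", {
  expect_true(20 / 22 > 0.90)
  expect_false(19 / 22 > 0.90)
})

test_that("best-hit selection is deterministic and order-independent", {
  mat <- "GCATTCAGGCTAGCATGGACTC"
  near <- mat
  substr(near, 5, 5) <- "G"  # T -> G
  # two catalog entries, one exact (later id), one 1-mm (earlier id)
  cat1 <- mk_catalog(c(near, mat), ids = c("sim-miR-a", "sim-miR-b"))
  cat2 <- mk_catalog(c(mat, near), ids = c("sim-miR-b", "sim-miR-a"))
  h1 <- match_conserved(tiny_tags(mat, 1L, 0L), cat1)
  h2 <- match_conserved(tiny_tags(mat, 1L, 0L), cat2)
  expect_identical(h1$mirna_id, "sim-miR-b")  # fewest mismatches wins
  expect_identical(h1, h2)

  # equal-quality tie resolves to the lexicographically smallest id
  cat3 <- mk_catalog(c(mat, mat), ids = c("sim-miR-z", "sim-miR-a"))
  expect_identical(match_conserved(tiny_tags(mat, 1L, 0L), cat3)$mirna_id,
                   "sim-miR-a")
})

test_that("planted catalog-derived tags with up to two errors are all recovered", {
  set.seed(14)
  cat <- mk_catalog(random_dna(20, 22))
  tags <- character(0)
  truth <- character(0)
  for (i in 1:20) {
    s <- cat$sequences[[i]]
    nerr <- sample(0:2, 1)
    for (p in sample(22, nerr)) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    tags <- c(tags, s)
    truth <- c(truth, cat$ids[i])
  }
  hits <- match_conserved(tiny_tags(tags, rep(1L, 20), rep(0L, 20)), cat)
  expect_identical(nrow(hits), 20L)
  expect_identical(hits$mirna_id, truth)
})

test_that("family grouping strips variants and conserves read totals", {
  expect_identical(mirna_family(c("let-7a", "let-7i")), c("let-7", "let-7"))
  expect_identical(mirna_family(c("miR-124a", "miR-124b")),
                   c("miR-124", "miR-124"))
  expect_identical(mirna_family("lpa-miR-27a-3p"), "miR-27")
  expect_identical(mirna_family("miR-424*"), "miR-424")
  expect_identical(mirna_family("miR-1224"), "miR-1224")  # no false stripping
  expect_identical(mirna_family("miR-7-1"), "miR-7")

  counts <- data.frame(feature_id = c("let-7a", "let-7i", "miR-124a"),
                       white = c(10L, 5L, 2L), brown = c(1L, 2L, 3L),
                       stringsAsFactors = FALSE)
  fam <- group_families(counts)
  expect_identical(fam$family, c("let-7", "miR-124"))
  expect_identical(fam$n_members, c(2L, 1L))
  expect_equal(sum(fam$white), sum(counts$white))
  expect_equal(fam$white[fam$family == "let-7"], 15)
})

test_that("isomiR profiles key on end offsets and flag the predominant read", {
  prec <- paste0("AACCAACCAA", "ACGTACGTACGTACGTACGTAC", "AACCAACCAACC",
                 "GTACGTACGTACGTACGTACGT", "AACCAACCAA")
  mature <- "ACGTACGTACGTACGTACGTAC"

  one <- end_heterogeneity(prec, tiny_tags(mature, 3L, 0L), mature)
  expect_identical(nrow(one$isoforms), 1L)
  expect_identical(c(one$isoforms$start_offset, one$isoforms$end_offset),
                   c(0L, 0L))

  plus1 <- paste0(mature, "A")  # one extra templated 3' base
  two <- end_heterogeneity(prec, tiny_tags(c(mature, plus1),
                                           c(3L, 7L), c(0L, 0L)), mature)
  expect_identical(two$isoforms$sequence[two$predominant], plus1)
  expect_identical(two$isoforms$end_offset[two$predominant], 1L)
  expect_identical(two$n_distinct_5p, 1L)
  expect_identical(two$n_distinct_3p, 2L)

  expect_error(end_heterogeneity(prec, tiny_tags(mature, 1L, 0L),
                                 "GGGGGGGGGGGGGGGGGGGGGG"),
               "not found")
})

test_that("synthetic 3'-biased trimming yields more distinct 3' than 5' ends", {
  cfg <- small_config(n_reads = 50000L, seed = 9L)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim, cfg)
  cl <- lapply(reads, clean_reads, adapter3 = cfg$adapter3)
  tags <- collapse_tags(lapply(cl, `[[`, "sequences"))
  tm <- sim$truth$mirnas
  n5 <- n3 <- 0
  for (i in seq_len(nrow(tm))) {
    prof <- end_heterogeneity(tm$precursor[i], tags, tm$mature[i])
    n5 <- n5 + prof$n_distinct_5p
    n3 <- n3 + prof$n_distinct_3p
  }
  expect_gt(n3, n5)
})

test_that("arm switching is flagged, ties keep the annotated arm, loop-only reads give no call", {
  stem5 <- "GCATTCAGGCTAGCATGGACTC"  # asymmetric: distinct from its revcomp
  prec <- paste0("AACCAACC", stem5, "AACAACAACAAC",
                 as.character(revcomp(stem5)), "AACCAACC")
  tag3p <- substr(as.character(revcomp(stem5)), 1, 18)

  sw <- detect_arm_switch(prec, tiny_tags(tag3p, 100L, 0L), "5p")
  expect_identical(sw$dominant_arm, "3p")
  expect_true(sw$switched)

  tag5p <- substr(stem5, 1, 18)
  tie <- detect_arm_switch(prec, tiny_tags(c(tag5p, tag3p),
                                           c(50L, 50L), c(0L, 0L)), "5p")
  expect_identical(tie$dominant_arm, "5p")
  expect_false(tie$switched)

  loop_tag <- "ACAACAACAA"  # maps inside the loop only
  none <- detect_arm_switch(prec, tiny_tags(loop_tag, 10L, 0L), "5p")
  expect_true(is.na(none$switched))
})

test_that("a planted arm-switched precursor is flagged on synthetic data", {
  cfg <- small_config(seed = 17L)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim, cfg)
  cl <- lapply(reads, clean_reads, adapter3 = cfg$adapter3)
  tags <- collapse_tags(lapply(cl, `[[`, "sequences"))
  tm <- sim$truth$mirnas
  # reads were planted on tm$arm; annotating the opposite arm must flag a
  # switch for abundantly sequenced precursors
  i <- which.max(tm[[paste0("prop_", cfg$libraries[1])]])
  wrong <- if (tm$arm[i] == "5p") "3p" else "5p"
  sw <- detect_arm_switch(tm$precursor[i], tags, wrong)
  expect_true(sw$switched)
  ok <- detect_arm_switch(tm$precursor[i], tags, tm$arm[i])
  expect_false(ok$switched)
})
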