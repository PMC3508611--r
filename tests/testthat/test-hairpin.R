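perfect_stem <- function(stem_len = 20, loop = "AACAACAA") {
  stem <- paste(rep(c("G", "C"), length.out = stem_len), collapse = "")
  paste0(stem, loop, as.character(revcomp(stem)))
}

test_that("poly-A folds unpaired at zero energy; designed stems pair up", {
  f <- fold_hairpin(strrep("A", 60))
  expect_equal(f$mfe, 0)
  expect_true(all(strsplit(f$structure, "")[[1]] == "."))

  hp <- fold_hairpin(perfect_stem(20))
  expect_identical(nchar(hp$structure), nchar(hp$sequence))
  expect_gte(sum(strsplit(hp$structure, "")[[1]] == "("), 18)
  expect_lt(hp$mfe, -18)

  expect_error(fold_hairpin("ACGTNACGT"), "non-ACGT")
  # balanced brackets
  ch <- strsplit(hp$structure, "")[[1]]
  expect_identical(sum(ch == "("), sum(ch == ")"))
})

test_that("a designed hairpin folds below its shuffled sequences", {
  set.seed(19)
  hp <- perfect_stem(20)
  mfe <- fold_hairpin(hp)$mfe
  for (i in 1:20) {
    shuf <- paste(sample(strsplit(hp, "")[[1]]), collapse = "")
    expect_lt(mfe, fold_hairpin(shuf)$mfe)
  }
})

test_that("folding agrees qualitatively with an independent thermodynamic folder", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not on PATH")
  hp <- perfect_stem(20)
  v <- fold_hairpin(hp, engine = "vienna")
  s <- fold_hairpin(hp, engine = "stack")
  expect_identical(nchar(v$structure), nchar(hp))
  expect_lt(v$mfe, -18)
  # both engines pair most of the designed stem
  expect_gte(sum(strsplit(v$structure, "")[[1]] == "("), 15)
  expect_gte(sum(strsplit(s$structure, "")[[1]] == "("), 15)
})

test_that("MFEI arithmetic follows the definition", {
  expect_equal(unname(compute_mfei(0, "ACGTACGT")["mfei"]), 0)
  r <- compute_mfei(-40, paste(rep(c("G", "A"), 50), collapse = ""))  # GC 50%
  expect_equal(unname(r["amfe"]), 40)
  expect_equal(unname(r["mfei"]), 0.8)

  # 80-mer at GC 43.75% (35 GC bases), mfe -34.83
  seq80 <- paste0(strrep("G", 35), strrep("A", 45))
  r2 <- compute_mfei(-34.83, seq80)
  expect_equal(unname(r2["amfe"]), 34.83 / 80 * 100)
  expect_equal(unname(r2["mfei"]), (34.83 / 80 * 100) / 43.75,
               tolerance = 1e-12)
  expect_equal(unname(r2["mfei"]), 0.9952, tolerance = 1e-3)

  expect_error(compute_mfei(-10, "ATATAT"), "GC")
})

test_that("MFEI is invariant when sequence doubles and MFE scales by two", {
  s <- perfect_stem(16)
  m1 <- compute_mfei(-30, s)["mfei"]
  m2 <- compute_mfei(-60, paste0(s, s))["mfei"]
  expect_equal(unname(m1), unname(m2))
})

test_that("criterion boundaries behave as stated", {
  prec_for <- function(mature_len) {
    mature <- paste(rep(c("G", "A", "C", "T"), length.out = mature_len),
                    collapse = "")
    list(mature = mature,
         fold = fold_hairpin(paste0("AACCAACCAA", mature, "AACAACAACAAC",
                                    as.character(revcomp(mature)),
                                    "AACCAACCAA")))
  }
  p19 <- prec_for(19)
  c19 <- evaluate_criteria(data.frame(sequence = p19$mature, count = 10),
                           p19$fold)
  expect_false(c19$criteria[["mature_size_stem"]])

  p22 <- prec_for(22)
  c22 <- evaluate_criteria(data.frame(sequence = p22$mature, count = 10),
                           p22$fold)
  expect_true(c22$criteria[["mature_size_stem"]])
  expect_true(c22$passed_all)

  # count boundary: "should not be below 5"
  c4 <- evaluate_criteria(data.frame(sequence = p22$mature, count = 4),
                          p22$fold)
  expect_false(c4$criteria[["mature_count"]])
  c5 <- evaluate_criteria(data.frame(sequence = p22$mature, count = 5),
                          p22$fold)
  expect_true(c5$criteria[["mature_count"]])

  # MFE boundary at -18
  fake <- p22$fold
  fake$mfe <- -17.9
  expect_false(evaluate_criteria(
    data.frame(sequence = p22$mature, count = 10),
    fake)$criteria[["mfe"]])
  fake$mfe <- -18
  expect_true(evaluate_criteria(
    data.frame(sequence = p22$mature, count = 10),
    fake)$criteria[["mfe"]])
})

test_that("criterion evaluation ignores read input order", {
  mature <- paste(rep(c("G", "A", "C", "T"), length.out = 22), collapse = "")
  fold <- fold_hairpin(paste0("AACCAACCAA", mature, "AACAACAACAAC",
                              as.character(revcomp(mature)), "AACCAACCAA"))
  reads <- data.frame(sequence = c(mature, substr(mature, 1, 20)),
                      count = c(9, 4))
  a <- evaluate_criteria(reads, fold)
  b <- evaluate_criteria(reads[2:1, ], fold)
  expect_identical(a$mature$sequence, b$mature$sequence)
  expect_identical(a$criteria, b$criteria)
})

test_that("an unstructured candidate fails stem criteria but is retained", {
  seq <- strrep("AC", 40)  # cannot pair at all
  f <- fold_hairpin(seq)
  cand <- evaluate_criteria(
    data.frame(sequence = substr(seq, 11, 32), count = 10), f)
  expect_false(cand$passed_all)
  expect_false(cand$criteria[["mature_size_stem"]])
  expect_false(cand$criteria[["size_spacing"]])
  expect_true(cand$criteria[["mature_count"]])
})

test_that("the MFEI filter keeps >= cutoff, and degenerate cutoffs work", {
  cands <- data.frame(mature = c("a", "b", "c"),
                      mfei = c(0.9699, 0.97, 1.2))
  kept <- filter_mfei(cands)
  expect_identical(kept$mature, c("b", "c"))
  expect_identical(nrow(filter_mfei(cands, 0)), 3L)
  expect_identical(nrow(filter_mfei(cands, Inf)), 0L)
  expect_identical(nrow(filter_mfei(cands[0, ], 0.97)), 0L)
})

test_that("library merging computes union by inclusion-exclusion", {
  m <- merge_libraries(c("AA", "CC"), c("GG", "TT", "AT"))
  expect_identical(m$union_count, 5L)
  s <- merge_libraries(c("AA", "CC"), c("AA", "CC", "GG"))
  expect_identical(s$union_count, 3L)
  expect_identical(s$n_shared, 2L)
})

test_that("planted hairpins are recovered with good precision at depth 1e5", {
  st <- hairpin_recovery_study(n_replicates = 2L,
                               config = sim_config(n_reads = 1e5L),
                               seed = 100L)
  expect_gte(mean(st$recall), 0.8)
  expect_gte(mean(st$precision), 0.8)
})
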