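AD3 <- "TGGAATTCTCGGGTGCCAAGG"

fq <- function(seqs, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  data.frame(id = paste0("r", seq_along(seqs)), sequence = seqs,
             quality = qual, stringsAsFactors = FALSE)
}

test_that("3' adapter trimming recovers the planted insert", {
  insert <- "ACGTACGTACGTACGTACGTAC"  # 22-mer
  r <- clean_reads(fq(paste0(insert, AD3)), AD3)
  expect_identical(r$sequences, insert)
  expect_identical(r$stats$clean_reads, 1L)

  # truncated adapter (>= 6 nt seed) still trims
  r2 <- clean_reads(fq(paste0(insert, substr(AD3, 1, 7))), AD3)
  expect_identical(r2$sequences, insert)
})

test_that("length, adapter and quality filters drop reads for the right reasons", {
  reads <- fq(c(
    paste0(substr("ACGTACGTACGTACGTA", 1, 17), AD3),   # 17 nt -> length
    strrep("ACGT", 10),                                 # no adapter seed
    paste0("ACGGANNGTACGTACGTACGTA", AD3),              # N in insert
    paste0("ACGTACGTACGTACGTACGTAC", AD3)))             # clean
  reads$quality[4] <- strrep("I", nchar(reads$sequence[4]))
  r <- clean_reads(reads, AD3)
  expect_identical(r$stats$dropped_length, 1L)
  expect_identical(r$stats$dropped_no_adapter3, 1L)
  expect_identical(r$stats$dropped_n, 1L)
  expect_identical(r$stats$clean_reads, 1L)

  # any base below Q20 drops the read; 5' adapter contaminants are dropped
  lowq <- fq(paste0("ACGTACGTACGTACGTACGTAC", AD3))
  substr(lowq$quality, 3, 3) <- "#"
  expect_identical(clean_reads(lowq, AD3)$stats$dropped_quality, 1L)
  ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  r5 <- clean_reads(fq(paste0(ad5, "ACGTACGTACGTACGTACGTAC", AD3)), AD3,
                    adapter5 = ad5)
  expect_identical(r5$stats$dropped_adapter5, 1L)
})

test_that("read accounting conserves: raw = clean + dropped", {
  cfg <- small_config()
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim, cfg)
  for (lib in names(reads)) {
    s <- clean_reads(reads[[lib]], cfg$adapter3, cfg$adapter5)$stats
    expect_identical(
      s$raw_reads,
      s$clean_reads + s$dropped_adapter5 + s$dropped_no_adapter3 +
        s$dropped_quality + s$dropped_n + s$dropped_length)
  }
})

test_that("collapsing tags preserves counts and the clean-read multiset", {
  t1 <- collapse_tags(list(lib = c(rep("ACGTACGTACGTACGTAG", 3),
                                   "TTACGTACGTACGTACGT")))
  expect_setequal(t1$lib, c(3L, 1L))

  shared <- "ACGTACGTACGTACGTAG"
  t2 <- collapse_tags(list(white = c(shared, shared), brown = shared))
  expect_identical(nrow(t2), 1L)
  expect_identical(c(t2$white, t2$brown), c(2L, 1L))

  set.seed(8)
  seqs <- sample(random_dna(50, 22), 500, replace = TRUE)
  t3 <- collapse_tags(list(lib = seqs))
  expect_identical(sum(t3$lib), length(seqs))
  expect_setequal(rep(t3$sequence, t3$lib), seqs)  # expand reproduces multiset
})

test_that("length distribution is read-weighted with mode at the planted modal length", {
  t1 <- tiny_tags("ACGTACGTACGTACGTACGTAC", 5L, 0L)  # single 22-mer, count 5
  ld <- length_distribution(t1)
  expect_identical(ld$total[ld$length == 22], 5L)
  expect_identical(sum(ld$total), 5L)
  expect_true(all(18:30 %in% ld$length))

  cfg <- small_config()
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim, cfg)
  cl <- lapply(reads, clean_reads, adapter3 = cfg$adapter3)
  tags <- collapse_tags(lapply(cl, `[[`, "sequences"))
  ld2 <- length_distribution(tags)
  expect_identical(ld2$length[which.max(ld2$total)], cfg$modal_length)

  perm <- tags[sample.int(nrow(tags)), ]
  expect_identical(length_distribution(perm), ld2)
})

test_that("genome matching equals the naive substring scan", {
  set.seed(21)
  genome <- reference_set(
    c(chrA = paste(random_dna(1, 4000), collapse = ""),
      chrB = paste(random_dna(1, 3000), collapse = "")), "genome")
  planted_fwd <- substr(genome$sequences[["chrA"]], 101, 122)
  planted_rev <- paste(rev(chartr(
    "ACGT", "TGCA", strsplit(substr(genome$sequences[["chrB"]], 51, 72),
                             "")[[1]])), collapse = "")
  tags <- tiny_tags(c(planted_fwd, planted_rev, random_dna(40, 22)),
                    rep(1L, 42), rep(1L, 42))
  gm <- match_genome(tags, genome)
  oracle <- vapply(tags$sequence, naive_genome_match,
                   logical(1), records = genome$sequences)
  expect_identical(unname(gm$matched), unname(oracle))
  expect_true(gm$matched[1] && gm$matched[2])
  expect_equal(unname(gm$percent["white"]),
               sum(tags$white[oracle]) / sum(tags$white) * 100)
})

test_that("the genome-match percentage is matched reads over clean reads x 100", {
  expect_equal(genome_match_percent(50, 200), 25)
  expect_error(genome_match_percent(1, 0), "positive")
})
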