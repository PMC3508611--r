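test_that("a perfect complement passes every rule at energy ratio 1", {
  set.seed(2)
  mir <- random_dna(1, 22)
  site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                collapse = "")
  s <- score_duplex(mir, site)
  expect_equal(s$mismatch_total, 0)
  expect_equal(s$energy_ratio, 1)
  expect_true(s$pass)
})

test_that("protected positions 10-11 are fatal", {
  mir <- strrep("AG", 11)
  site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                collapse = "")
  # mutate the site base opposite miRNA position 10 (a G) to A: G:A neither
  # pairs nor wobbles
  L <- 22
  k <- L - 10 + 1
  bad <- site
  substr(bad, k, k) <- "A"
  s <- score_duplex(mir, bad)
  expect_identical(s$mm_at_10_11, 1)
  expect_false(s$pass)
})

test_that("G:U wobbles count half and agree with the per-position recount", {
  set.seed(23)
  for (i in 1:10) {
    mir <- random_dna(1, 22)
    site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                  collapse = "")
    # turn U:A pairs into U:G wobbles on the site side
    mv <- strsplit(mir, "")[[1]]
    t_pos <- which(mv == "T")
    t_pos <- t_pos[seq_len(min(8, length(t_pos)))]
    sv <- strsplit(site, "")[[1]]
    for (p in t_pos) sv[22 - p + 1] <- "G"
    site2 <- paste(sv, collapse = "")
    s <- score_duplex(mir, site2)
    o <- duplex_recount(mir, site2)
    expect_equal(s$mismatch_total, o$total)
    expect_equal(s$mismatch_1_12, o$mm_1_12)
    expect_equal(s$mm_at_10_11, o$mm_10_11)
    expect_equal(s$max_adjacent_mm_2_12, o$max_run)
    expect_equal(s$energy, o$energy)
    expect_equal(s$energy_ratio, o$ratio)
  }
})

test_that("eight G:U wobbles total 4.0 mismatches and pass the total rule", {
  mir <- paste0(strrep("T", 8), strrep("A", 6), strrep("C", 8))
  site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                collapse = "")
  sv <- strsplit(site, "")[[1]]
  # miRNA positions 1..8 are T (pairing A); make the opposite bases G -> T:G
  for (p in 1:8) sv[22 - p + 1] <- "G"
  s <- score_duplex(mir, paste(sv, collapse = ""))
  expect_equal(s$mismatch_total, 4.0)
  o <- duplex_recount(mir, paste(sv, collapse = ""))
  expect_equal(s$mismatch_total, o$total)
})

test_that("site/miRNA length mismatch and short transcripts are errors", {
  expect_error(score_duplex("ACGTACGT", "ACGT"), "length")
  expect_error(scan_transcript(strrep("ACGT", 6), "ACGTT"), "shorter")
})

test_that("an embedded perfect complement is found at exactly its window", {
  set.seed(31)
  mir <- random_dna(1, 22)
  tr <- random_dna(1, 800)
  site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                collapse = "")
  substr(tr, 301, 322) <- site
  hits <- scan_transcript(mir, tr)
  expect_true(300 %in% hits$site_start)  # 0-based
  expect_equal(hits$site_start + 1, duplex_scan_oracle(mir, tr))
})

test_that("the scanner equals the brute-force oracle on random 2 kb instances", {
  set.seed(37)
  for (i in 1:3) {
    mir <- random_dna(1, 22)
    tr <- random_dna(1, 2000)
    # embed a perfect site and a near-miss (2 G:U) site
    site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                  collapse = "")
    substr(tr, 100, 121) <- site
    wob <- strsplit(site, "")[[1]]
    tpos <- which(strsplit(mir, "")[[1]] == "T")
    for (p in tpos[seq_len(min(2, length(tpos)))]) wob[22 - p + 1] <- "G"
    substr(tr, 900, 921) <- paste(wob, collapse = "")
    hits <- scan_transcript(mir, tr)
    expect_equal(hits$site_start + 1, duplex_scan_oracle(mir, tr))
  }
})

test_that("rule evaluation is monotone: extra mismatches never rescue a duplex", {
  set.seed(41)
  for (i in 1:25) {
    mir <- random_dna(1, 22)
    site <- paste(rev(chartr("ACGT", "TGCA", strsplit(mir, "")[[1]])),
                  collapse = "")
    sv <- strsplit(site, "")[[1]]
    # random starting damage
    for (p in sample(22, sample(0:4, 1))) sv[p] <- sample(c("A", "C"), 1)
    before <- score_duplex(mir, paste(sv, collapse = ""))
    # add one more mismatch at a currently-matching position
    mv <- strsplit(mir, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    matching <- which(vapply(1:22, function(k) {
      comp[[mv[k]]] == sv[22 - k + 1]
    }, logical(1)))
    if (!length(matching)) next
    k <- sample(matching, 1)
    sv[22 - k + 1] <- setdiff(c("A", "C", "G", "T"),
                              c(comp[[mv[k]]],
                                if (mv[k] %in% c("G", "T"))
                                  c(G = "T", T = "G")[[mv[k]]]))[1]
    after <- score_duplex(mir, paste(sv, collapse = ""))
    if (!before$pass) expect_false(after$pass)
    expect_gte(after$mismatch_total, before$mismatch_total)
  }
})

test_that("scanning many miRNAs against many transcripts tabulates ids", {
  set.seed(43)
  mirs <- reference_set(c(m1 = random_dna(1, 22), m2 = random_dna(1, 21)),
                        "known_mirna_mature")
  site1 <- paste(rev(chartr("ACGT", "TGCA",
                            strsplit(mirs$sequences[["m1"]], "")[[1]])),
                 collapse = "")
  tr <- random_dna(1, 500)
  substr(tr, 201, 222) <- site1
  trs <- reference_set(c(t1 = tr, t2 = random_dna(1, 300)), "transcript")
  hits <- scan_targets(mirs, trs)
  expect_true(all(c("mirna_id", "transcript_id") %in% names(hits)))
  expect_true(any(hits$mirna_id == "m1" & hits$transcript_id == "t1" &
                    hits$site_start == 200))
})
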