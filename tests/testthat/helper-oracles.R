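# Independent brute-force oracles and tiny fixture builders shared across
# the suite. These deliberately avoid the package's own code paths.

# direct summation of the Audic-Claverie posterior mass function
ac_direct <- function(x, n1, y, n2) {
  pmf <- function(yy) {
    exp(yy * log(n2 / n1) + lgamma(x + yy + 1) - lgamma(x + 1) -
          lgamma(yy + 1) - (x + yy + 1) * log(1 + n2 / n1))
  }
  lower <- sum(pmf(0:y))
  upper <- if (y == 0) 1 else 1 - sum(pmf(0:(y - 1)))
  min(1, 2 * min(lower, upper))
}

# position-by-position recount of one ungapped duplex
duplex_recount <- function(mirna, site) {
  L <- nchar(mirna)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mv <- strsplit(mirna, "")[[1]]
  sv <- strsplit(site, "")[[1]]
  wgt <- numeric(L)
  en <- 0
  for (k in 1:L) {
    a <- mv[k]
    b <- sv[L - k + 1]
    if (comp[[a]] == b) {
      wgt[k] <- 0
      en <- en + if (a %in% c("G", "C")) -3 else -2
    } else if ((a == "G" && b == "T") || (a == "T" && b == "G")) {
      wgt[k] <- 0.5
      en <- en - 1
    } else {
      wgt[k] <- 1
    }
  }
  perfect <- sum(ifelse(mv %in% c("G", "C"), -3, -2))
  runs <- rle(wgt[2:min(12, L)] >= 0.5)
  maxrun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  list(total = sum(wgt), mm_1_12 = sum(wgt[1:min(12, L)]),
       mm_10_11 = sum(wgt[10:min(11, L)] >= 0.5), max_run = maxrun,
       energy = en, perfect = perfect, ratio = en / perfect)
}

# all passing window starts (1-based) by exhaustive scan
duplex_scan_oracle <- function(mirna, transcript) {
  L <- nchar(mirna)
  hits <- integer(0)
  for (w in seq_len(nchar(transcript) - L + 1)) {
    r <- duplex_recount(mirna, substr(transcript, w, w + L - 1))
    if (r$total <= 4 && r$mm_10_11 == 0 && r$max_run <= 2 &&
          r$mm_1_12 <= 2.5 && r$ratio >= 0.75) {
      hits <- c(hits, w)
    }
  }
  hits
}

# naive O(n*m) exact substring scan of tag (either strand) against records
naive_genome_match <- function(tag, records) {
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(tag, "")[[1]])),
              collapse = "")
  any(vapply(records, function(r) {
    grepl(tag, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE)
  }, logical(1)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# minimal two-library tag table
tiny_tags <- function(seqs, white, brown) {
  data.frame(sequence = seqs, white = white, brown = brown,
             stringsAsFactors = FALSE)
}

small_config <- function(n_reads = 20000L, seed = 42L, ...) {
  sim_config(n_reads = n_reads, seed = seed, ...)
}
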