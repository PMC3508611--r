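#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t k = 0; k < r.size(); ++k) r[k] = comp(r[k]);
    out[i] = r;
  }
  return out;
}

// First reference (1-based, in the given order) containing the query as an
// exact substring; NA if none.
// [[Rcpp::export]]
IntegerVector cpp_find_exact(CharacterVector queries, CharacterVector refs) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  IntegerVector out(nq, NA_INTEGER);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) {
      if (rs[j].find(q) != std::string::npos) { out[i] = j + 1; break; }
    }
  }
  return out;
}

// Naive mismatch-tolerant substring search (substitutions only).
// [[Rcpp::export]]
IntegerVector cpp_find_mismatch(CharacterVector queries, CharacterVector refs,
                                int max_mm) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  IntegerVector out(nq, NA_INTEGER);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int lq = (int) q.size();
    bool hit = false;
    for (int j = 0; j < nr && !hit; ++j) {
      const std::string &r = rs[j];
      int lr = (int) r.size();
      for (int p = 0; p + lq <= lr && !hit; ++p) {
        int mm = 0;
        for (int k = 0; k < lq; ++k) {
          if (q[k] != r[p + k] && ++mm > max_mm) break;
        }
        if (mm <= max_mm) { out[i] = j + 1; hit = true; }
      }
    }
  }
  return out;
}

// 1-based start of the first exact occurrence of each query in ref; NA if none.
// [[Rcpp::export]]
IntegerVector cpp_locate_first(CharacterVector queries, std::string ref) {
  int nq = queries.size();
  IntegerVector out(nq, NA_INTEGER);
  for (int i = 0; i < nq; ++i) {
    size_t p = ref.find(as<std::string>(queries[i]));
    if (p != std::string::npos) out[i] = (int) p + 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_count_occurrences(CharacterVector queries, std::string ref) {
  int nq = queries.size();
  IntegerVector out(nq, 0);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    if (q.empty()) continue;
    size_t p = ref.find(q);
    int cnt = 0;
    while (p != std::string::npos) {
      ++cnt;
      p = ref.find(q, p + 1);  // overlapping occurrences count
    }
    out[i] = cnt;
  }
  return out;
}

// Ungapped sliding alignment of each tag against each catalog mature sequence,
// shifting by up to max_shift either way (terminal overhangs allowed).
// Mismatches = substitutions in the overlap; identity = matches / alignment
// columns (union span, so overhangs dilute identity). Best hit per tag:
// fewest mismatches, then highest identity, then first catalog entry (callers
// pre-sort the catalog lexicographically by id).
// [[Rcpp::export]]
DataFrame cpp_conserved_best(CharacterVector tags, CharacterVector mats,
                             int max_shift, int min_overlap) {
  int nt = tags.size(), nm = mats.size();
  std::vector<std::string> ms(nm);
  for (int j = 0; j < nm; ++j) ms[j] = as<std::string>(mats[j]);
  IntegerVector best_idx(nt, NA_INTEGER), best_mm(nt, NA_INTEGER);
  NumericVector best_id(nt, NA_REAL);
  for (int i = 0; i < nt; ++i) {
    std::string t = as<std::string>(tags[i]);
    int lt = (int) t.size();
    int bmm = INT_MAX;
    double bid = -1.0;
    int bj = -1;
    for (int j = 0; j < nm; ++j) {
      const std::string &m = ms[j];
      int lm = (int) m.size();
      for (int o = -max_shift; o <= max_shift; ++o) {
        // tag position k aligns mature position k + o
        int k0 = std::max(0, -o), k1 = std::min(lt, lm - o);
        int ov = k1 - k0;
        if (ov < min_overlap) continue;
        int match = 0;
        for (int k = k0; k < k1; ++k)
          if (t[k] == m[k + o]) ++match;
        int mm = ov - match;
        // columns = union of the two spans on the mature coordinate axis:
        // tag covers [o, o+lt), mature covers [0, lm)
        int aln_len = std::max(o + lt, lm) - std::min(o, 0);
        double ident = (double) match / (double) aln_len;
        if (mm < bmm || (mm == bmm && ident > bid)) {
          bmm = mm;
          bid = ident;
          bj = j;
        }
      }
    }
    if (bj >= 0) {
      best_idx[i] = bj + 1;
      best_mm[i] = bmm;
      best_id[i] = bid;
    }
  }
  return DataFrame::create(_["idx"] = best_idx, _["mismatches"] = best_mm,
                           _["identity"] = best_id);
}

// Score every length-L window of a transcript as an ungapped antiparallel
// duplex against the miRNA. Position p (1-based from the miRNA 5' end) faces
// site base L - p (0-based). Watson-Crick = match, G:U wobble = 0.5 mismatch,
// anything else = 1. Pair energies: GC -3, AU -2, GU -1, mismatch 0.
// [[Rcpp::export]]
NumericMatrix cpp_scan_duplex(std::string mirna, std::string transcript) {
  int L = (int) mirna.size();
  int nT = (int) transcript.size();
  int nw = nT - L + 1;
  if (nw < 1) nw = 0;
  NumericMatrix out(nw, 7);
  colnames(out) = CharacterVector::create("site_start", "mismatch_total",
                                          "mismatch_1_12", "mm_at_10_11",
                                          "max_adjacent_mm_2_12", "energy",
                                          "perfect_energy");
  double perfect = 0.0;
  for (int k = 0; k < L; ++k)
    perfect += (mirna[k] == 'G' || mirna[k] == 'C') ? -3.0 : -2.0;
  for (int w = 0; w < nw; ++w) {
    double mm_total = 0.0, mm_1_12 = 0.0, energy = 0.0;
    int mm_10_11 = 0, max_run = 0, run = 0;
    for (int k = 0; k < L; ++k) {
      int pos = k + 1;
      char a = mirna[k];
      char b = transcript[w + (L - 1 - k)];  // antiparallel
      double wgt;
      if (comp(a) == b && a != 'N' && b != 'N') {
        wgt = 0.0;
        energy += (a == 'G' || a == 'C') ? -3.0 : -2.0;
      } else if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) {
        wgt = 0.5;
        energy += -1.0;
      } else {
        wgt = 1.0;
      }
      mm_total += wgt;
      if (pos <= 12) mm_1_12 += wgt;
      if (pos == 10 || pos == 11) mm_10_11 += (wgt >= 0.5) ? 1 : 0;
      if (pos >= 2 && pos <= 12) {
        if (wgt >= 0.5) {
          if (++run > max_run) max_run = run;
        } else {
          run = 0;
        }
      }
    }
    out(w, 0) = w + 1;
    out(w, 1) = mm_total;
    out(w, 2) = mm_1_12;
    out(w, 3) = mm_10_11;
    out(w, 4) = max_run;
    out(w, 5) = energy;
    out(w, 6) = perfect;
  }
  return out;
}
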