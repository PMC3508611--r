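#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Base-pair stacking model over the DNA alphabet (T stands for U):
// a pair contributes energy only when stacked directly on the adjacent pair,
// -3 for G:C, -1 for A:T and G:T (wobble). Loop-closing / lone pairs score 0.
// Minimum hairpin loop length is 3 nt.

static const double INF = std::numeric_limits<double>::infinity();
static const int MIN_LOOP = 3;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

static inline double stack_e(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  return -1.0;
}

// [[Rcpp::export]]
List cpp_fold_stack(std::string s) {
  const int n = (int) s.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  std::vector<double> W((size_t) n * n, 0.0), V((size_t) n * n, INF);
  auto at = [n](int i, int j) { return (size_t) i * n + j; };

  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V: best energy given (i,j) paired
      if (can_pair(s[i], s[j])) {
        double v = W[at(i + 1, j - 1)];  // close without stacking credit
        if (j - 1 - (i + 1) > MIN_LOOP && V[at(i + 1, j - 1)] < INF) {
          double vs = V[at(i + 1, j - 1)] + stack_e(s[i], s[j]);
          if (vs < v) v = vs;
        }
        V[at(i, j)] = v;
      }
      double w = W[at(i + 1, j)];
      if (W[at(i, j - 1)] < w) w = W[at(i, j - 1)];
      if (V[at(i, j)] < w) w = V[at(i, j)];
      for (int k = i; k < j; ++k) {
        double b = W[at(i, k)] + W[at(k + 1, j)];
        if (b < w) w = b;
      }
      W[at(i, j)] = w;
    }
  }

  // traceback
  std::string db(n, '.');
  std::vector<std::array<int, 3>> todo;  // {i, j, state}; state 0 = W, 1 = V
  todo.push_back({0, n - 1, 0});
  while (!todo.empty()) {
    auto t = todo.back();
    todo.pop_back();
    int i = t[0], j = t[1], st = t[2];
    if (j - i <= MIN_LOOP) continue;
    if (st == 0) {
      double w = W[at(i, j)];
      if (w == 0.0) continue;  // nothing gained by pairing: leave unpaired
      if (w == W[at(i + 1, j)]) { todo.push_back({i + 1, j, 0}); continue; }
      if (w == W[at(i, j - 1)]) { todo.push_back({i, j - 1, 0}); continue; }
      if (w == V[at(i, j)]) { todo.push_back({i, j, 1}); continue; }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        if (w == W[at(i, k)] + W[at(k + 1, j)]) {
          todo.push_back({i, k, 0});
          todo.push_back({k + 1, j, 0});
          done = true;
        }
      }
    } else {
      db[i] = '(';
      db[j] = ')';
      double v = V[at(i, j)];
      if (j - 1 - (i + 1) > MIN_LOOP && V[at(i + 1, j - 1)] < INF &&
          v == V[at(i + 1, j - 1)] + stack_e(s[i], s[j])) {
        todo.push_back({i + 1, j - 1, 1});
      } else {
        todo.push_back({i + 1, j - 1, 0});
      }
    }
  }

  return List::create(_["structure"] = db, _["mfe"] = W[at(0, n - 1)]);
}
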