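#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) with a minimum hairpin
// loop of `min_loop` unpaired bases and an optional hairpin-initiation
// penalty q charged once per terminal loop. Pair weights: GC = 3, AU = 2,
// GU = 1. With q = 0 this is pure weighted pair maximization.
//
// Three-matrix decomposition (the penalty must be amortized across a
// helix, so intermediate scores have to be allowed to go negative):
//   C[i][j] = best score of [i..j] with (i,j) paired
//           = w(i,j) + max(-q, N[i+1][j-1])
//   N[i][j] = best score of [i..j] containing at least one pair
//           = max(N[i+1][j], max_k C[i][k] + M[k+1][j])
//   M[i][j] = best overall = max(0, N[i][j])
// Traceback is deterministic: pairing position i with the smallest
// admissible partner k is preferred whenever it attains the optimum.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

static const int NEG = -1000000000;

// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(std::string seq, int min_loop, int q) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c == 'T') seq[i] = 'U';
    else if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("invalid base '%s' (alphabet is A, C, G, U/T)",
           std::string(1, c).c_str());
  }
  std::vector<std::vector<int> > C(n, std::vector<int>(n, NEG));
  std::vector<std::vector<int> > N(n, std::vector<int>(n, NEG));
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // C: (i, j) paired
      int w = pair_weight(seq[i], seq[j]);
      if (w > 0) {
        int inner = -q;  // hairpin closure
        if (j - i - 1 > min_loop + 1 && N[i + 1][j - 1] > inner)
          inner = N[i + 1][j - 1];
        C[i][j] = w + inner;
      }
      // N: at least one pair
      int best = (i + 1 <= j) ? N[i + 1][j] : NEG;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (C[i][k] == NEG) continue;
        int cand = C[i][k] + (k + 1 <= j ? M[k + 1][j] : 0);
        if (cand > best) best = cand;
      }
      N[i][j] = best;
      M[i][j] = best > 0 ? best : 0;
    }
  }
  // traceback over states: 0 = M, 1 = C, 2 = N
  IntegerVector partner(n, 0);
  std::string db(n, '.');
  struct Frame { int state, i, j; };
  std::stack<Frame> todo;
  if (n > min_loop + 1) todo.push(Frame{0, 0, n - 1});
  while (!todo.empty()) {
    Frame f = todo.top();
    todo.pop();
    int i = f.i, j = f.j;
    if (i >= j || j - i <= min_loop) continue;
    if (f.state == 0) {          // M
      if (M[i][j] == 0) continue;
      todo.push(Frame{2, i, j});
    } else if (f.state == 1) {   // C: (i, j) is paired
      partner[i] = j + 1;
      partner[j] = i + 1;
      db[i] = '(';
      db[j] = ')';
      int w = pair_weight(seq[i], seq[j]);
      if (j - i - 1 > min_loop + 1 && C[i][j] == w + N[i + 1][j - 1]) {
        todo.push(Frame{2, i + 1, j - 1});
      }                           // else: hairpin loop, interior unpaired
    } else {                      // N
      bool done = false;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (C[i][k] == NEG) continue;
        int cand = C[i][k] + (k + 1 <= j ? M[k + 1][j] : 0);
        if (cand == N[i][j]) {
          todo.push(Frame{1, i, k});
          if (k + 1 <= j) todo.push(Frame{0, k + 1, j});
          done = true;
          break;
        }
      }
      if (!done) todo.push(Frame{2, i + 1, j});
    }
  }
  return List::create(_["structure"] = db,
                      _["score"] = (n > 0 ? M[0][n - 1] : 0),
                      _["partner"] = partner);
}
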