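#include <Rcpp.h>
using namespace Rcpp;

// Allowed base pairs: Watson-Crick (AU, GC) plus wobble (GU).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

static void traceback(int i, int j, const std::string &s,
                      const std::vector<std::vector<int> > &N,
                      int min_loop, std::string &db) {
  if (i >= j || j - i <= min_loop) return;
  // Prefer pairing the leftmost 5' index, with the smallest partner k,
  // whenever a pairing branch attains the optimum; ties are deterministic.
  for (int k = i + min_loop + 1; k <= j; ++k) {
    if (!can_pair(s[i], s[k])) continue;
    int inside = (k - 1 >= i + 1) ? N[i + 1][k - 1] : 0;
    int outside = (k + 1 <= j) ? N[k + 1][j] : 0;
    if (inside + outside + 1 == N[i][j]) {
      db[i] = '(';
      db[k] = ')';
      traceback(i + 1, k - 1, s, N, min_loop, db);
      traceback(k + 1, j, s, N, min_loop, db);
      return;
    }
  }
  traceback(i + 1, j, s, N, min_loop, db);
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  if (n == 0) stop("empty sequence");
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inside = (k - 1 >= i + 1) ? N[i + 1][k - 1] : 0;
        int outside = (k + 1 <= j) ? N[k + 1][j] : 0;
        if (inside + outside + 1 > best) best = inside + outside + 1;
      }
      N[i][j] = best;
    }
  }
  std::string db(n, '.');
  if (n > 1) traceback(0, n - 1, seq, N, min_loop, db);
  return List::create(_["structure"] = db,
                      _["pair_count"] = (n > 1) ? N[0][n - 1] : 0);
}
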