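#include <Rcpp.h>
using namespace Rcpp;

// Conglomerate distance of one query word against many words.
// Sequences are integer-coded; rows of `words` and `query` must have
// equal length L. d = L - (1/L) * sum(run_length^2) over maximal runs
// of matching positions.
// [[Rcpp::export]]
NumericVector cpp_cong_dist_batch(IntegerMatrix words, IntegerVector query) {
  int K = words.nrow(), L = words.ncol();
  if (query.size() != L) stop("query length differs from word length");
  NumericVector out(K);
  for (int i = 0; i < K; ++i) {
    double acc = 0.0;
    int run = 0;
    for (int j = 0; j < L; ++j) {
      if (words(i, j) == query[j]) {
        ++run;
      } else {
        acc += (double)run * run;
        run = 0;
      }
    }
    acc += (double)run * run;
    out[i] = (double)L - acc / (double)L;
  }
  return out;
}

static inline double subst(int a, int b, double match, double mismatch) {
  return a == b ? match : mismatch;
}

// Smith-Waterman local alignment score over integer token strings.
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b,
                    double match, double mismatch, double gap) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double h = d;
      if (u > h) h = u;
      if (l > h) h = l;
      if (h < 0.0) h = 0.0;
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Full Smith-Waterman with traceback. Returns list(score, a_idx, b_idx)
// where a_idx/b_idx are 1-based indices into a and b along the local
// alignment path, 0 denoting a gap in that row. Deterministic
// tie-breaking: the best cell with the smallest i, then smallest j;
// traceback prefers diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b,
                  double match, double mismatch, double gap) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = H(i - 1, j - 1) + subst(a[i - 1], b[j - 1], match, mismatch);
      double u = H(i - 1, j) + gap;
      double l = H(i, j - 1) + gap;
      double h = d;
      if (u > h) h = u;
      if (l > h) h = l;
      if (h < 0.0) h = 0.0;
      H(i, j) = h;
      if (h > best + 1e-12) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> ai, bj_v;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H(i, j) > 1e-12) {
    double h = H(i, j);
    double d = H(i - 1, j - 1) + subst(a[i - 1], b[j - 1], match, mismatch);
    if (std::abs(h - d) < 1e-12) {
      ai.push_back(i); bj_v.push_back(j); --i; --j;
    } else if (std::abs(h - (H(i - 1, j) + gap)) < 1e-12) {
      ai.push_back(i); bj_v.push_back(0); --i;
    } else {
      ai.push_back(0); bj_v.push_back(j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj_v.begin(), bj_v.end());
  return List::create(_["score"] = best,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bj_v));
}
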