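#include <Rcpp.h>
using namespace Rcpp;

// Sliding similarity profile k(x) between a sequence and itself shifted by r:
// k(x) = (1/l) * #{ i < l : s[x+i] == s[x+r+i] }, 0-based x.
// Positions whose window pair touches an ambiguous symbol (NA, coded < 0)
// are disqualified (k = -1): N never matches and never counts.
static std::vector<double> similarity_profile(const IntegerVector& s,
                                              int r, int l) {
  int n = s.size();
  int nx = n - r - l + 1;
  std::vector<double> k;
  if (nx <= 0) return k;
  k.resize(nx);
  // incremental match/ambiguity counts over the length-l window
  int matches = 0, bad = 0;
  for (int i = 0; i < l; ++i) {
    bool na = (s[i] == NA_INTEGER || s[r + i] == NA_INTEGER);
    if (na) ++bad;
    else if (s[i] == s[r + i]) ++matches;
  }
  for (int x = 0; x < nx; ++x) {
    k[x] = (bad > 0) ? -1.0 : (double)matches / l;
    if (x + 1 < nx) {
      // slide: drop position x, add position x + l
      bool na_out = (s[x] == NA_INTEGER || s[x + r] == NA_INTEGER);
      if (na_out) --bad;
      else if (s[x] == s[x + r]) --matches;
      bool na_in = (s[x + l] == NA_INTEGER || s[x + r + l] == NA_INTEGER);
      if (na_in) ++bad;
      else if (s[x + l] == s[x + r + l]) ++matches;
    }
  }
  return k;
}

// Weighted-interval-scheduling DP over left-site start positions:
//   S[x] = max(S[x-1], S[x-l] + k(x) * 1[k(x) >= qc]),  S[x<0] = 0,
// with backtracking. Ties prefer S[x-1] (leftmost-minimal selection).
// Returns 1-based selected left-site starts, the pair count, and mean
// similarity of the selected pairs.
// [[Rcpp::export]]
List dp_max_pairs_cpp(IntegerVector s, int r, int l, double qc) {
  std::vector<double> k = similarity_profile(s, r, l);
  int nx = (int)k.size();
  if (nx <= 0)
    return List::create(_["positions"] = IntegerVector(0),
                        _["n"] = 0, _["total"] = 0.0, _["qbar"] = NA_REAL);
  const double eps = 1e-9;
  std::vector<double> S(nx, 0.0);
  std::vector<unsigned char> take(nx, 0);
  for (int x = 0; x < nx; ++x) {
    double skip = (x > 0) ? S[x - 1] : 0.0;
    double acc = -1.0;
    if (k[x] >= qc - eps && k[x] >= 0.0) {
      double prev = (x - l >= 0) ? S[x - l] : 0.0;
      acc = prev + k[x];
    }
    if (acc > skip + eps) { S[x] = acc; take[x] = 1; }
    else { S[x] = skip; take[x] = 0; }
  }
  std::vector<int> pos;
  double total = 0.0;
  int x = nx - 1;
  while (x >= 0) {
    if (take[x]) { pos.push_back(x + 1); total += k[x]; x -= l; }
    else --x;
  }
  std::reverse(pos.begin(), pos.end());
  int n = (int)pos.size();
  return List::create(_["positions"] = wrap(pos),
                      _["n"] = n,
                      _["total"] = total,
                      _["qbar"] = n > 0 ? total / n : NA_REAL);
}

// Batch version over a list of integer-coded sequences (the Markov null
// ensemble): per-sequence pair counts and total similarity at (r, l, qc).
// [[Rcpp::export]]
List dp_count_batch_cpp(List seqs, int r, int l, double qc) {
  int m = seqs.size();
  IntegerVector n(m);
  NumericVector total(m);
  const double eps = 1e-9;
  for (int j = 0; j < m; ++j) {
    IntegerVector s = seqs[j];
    std::vector<double> k = similarity_profile(s, r, l);
    int nx = (int)k.size();
    if (nx <= 0) { n[j] = 0; total[j] = 0.0; continue; }
    std::vector<double> S(nx, 0.0);
    std::vector<int> cnt(nx, 0);
    std::vector<double> qs(nx, 0.0);
    for (int x = 0; x < nx; ++x) {
      double skip = (x > 0) ? S[x - 1] : 0.0;
      int skip_c = (x > 0) ? cnt[x - 1] : 0;
      double skip_q = (x > 0) ? qs[x - 1] : 0.0;
      double acc = -1.0;
      if (k[x] >= qc - eps && k[x] >= 0.0)
        acc = ((x - l >= 0) ? S[x - l] : 0.0) + k[x];
      if (acc > skip + eps) {
        S[x] = acc;
        cnt[x] = ((x - l >= 0) ? cnt[x - l] : 0) + 1;
        qs[x] = ((x - l >= 0) ? qs[x - l] : 0.0) + k[x];
      } else { S[x] = skip; cnt[x] = skip_c; qs[x] = skip_q; }
    }
    n[j] = cnt[nx - 1];
    total[j] = qs[nx - 1];
  }
  return List::create(_["n"] = n, _["total"] = total);
}

// First-order Markov sampler using R's RNG (reproducible via set.seed).
// p0: initial distribution (4), trans: 4x4 row-stochastic conditional.
// Returns a list of integer vectors coded 1..4.
// [[Rcpp::export]]
List markov_sample_cpp(NumericVector p0, NumericMatrix trans,
                       int len, int n) {
  RNGScope scope;
  // cumulative distributions
  double c0[4];
  double ct[4][4];
  double acc = 0.0;
  for (int a = 0; a < 4; ++a) { acc += p0[a]; c0[a] = acc; }
  for (int a = 0; a < 4; ++a) {
    acc = 0.0;
    for (int b = 0; b < 4; ++b) { acc += trans(a, b); ct[a][b] = acc; }
  }
  List out(n);
  for (int j = 0; j < n; ++j) {
    IntegerVector s(len);
    double u = unif_rand();
    int cur = 0;
    while (cur < 3 && u > c0[cur]) ++cur;
    s[0] = cur + 1;
    for (int i = 1; i < len; ++i) {
      u = unif_rand();
      int nxt = 0;
      while (nxt < 3 && u > ct[cur][nxt]) ++nxt;
      s[i] = nxt + 1;
      cur = nxt;
    }
    out[j] = s;
  }
  return out;
}
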