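#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Sufficient statistics for one family (node, parent set) on integer-coded
// data with NAs. Rows incomplete on the family are dropped. Returns
//   loglik : sum over observed parent configs j and states k of
//            n_jk * log(n_jk / n_j)   (0 log 0 = 0)
//   q      : number of parent configurations with observed support
//   n      : number of family-complete rows
// [[Rcpp::export]]
NumericVector cpp_family_stats(IntegerMatrix data, IntegerVector cards,
                               int node, IntegerVector parents) {
  int n = data.nrow();
  int v = node - 1;
  int r = cards[v];
  int np = parents.size();
  std::unordered_map<long long, int> cfg_index;
  std::vector<int> counts; // flat: cfg * r + state
  for (int i = 0; i < n; ++i) {
    int s = data(i, v);
    if (s == NA_INTEGER) continue;
    long long code = 0, stride = 1;
    bool ok = true;
    for (int m = 0; m < np; ++m) {
      int p = parents[m] - 1;
      int sp = data(i, p);
      if (sp == NA_INTEGER) { ok = false; break; }
      code += (long long)(sp - 1) * stride;
      stride *= cards[p];
    }
    if (!ok) continue;
    auto it = cfg_index.find(code);
    int idx;
    if (it == cfg_index.end()) {
      idx = cfg_index.size();
      cfg_index[code] = idx;
      counts.resize((idx + 1) * r, 0);
    } else {
      idx = it->second;
    }
    counts[idx * r + (s - 1)] += 1;
  }
  int q = cfg_index.size();
  double loglik = 0.0;
  long long N = 0;
  for (int j = 0; j < q; ++j) {
    long long nj = 0;
    for (int k = 0; k < r; ++k) nj += counts[j * r + k];
    N += nj;
    for (int k = 0; k < r; ++k) {
      int njk = counts[j * r + k];
      if (njk > 0) loglik += njk * std::log((double)njk / (double)nj);
    }
  }
  return NumericVector::create(loglik, (double)q, (double)N);
}
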