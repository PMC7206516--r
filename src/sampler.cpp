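#include <Rcpp.h>
using namespace Rcpp;

// A compiled discrete Bayesian network is passed from R as a list:
//   order   : 1-based node indices in topological order
//   parents : list of 1-based integer vectors (parent indices per node)
//   cards   : per-node state counts
//   cpts    : per-node numeric matrix, q x r; row index is the mixed-radix
//             code of the parent states with the FIRST parent fastest.
// The R-side structures are unpacked once into flat C++ vectors so the
// per-sample loops touch plain arrays only.

struct CompiledNet {
  int V;
  std::vector<int> order;               // 0-based, topological
  std::vector<std::vector<int> > pa;    // 0-based parent indices
  std::vector<int> cards;
  std::vector<const double *> cpt;      // column-major q x r
  std::vector<int> q;                   // rows of each cpt

  explicit CompiledNet(List model) {
    IntegerVector ord = model["order"];
    List parents = model["parents"];
    IntegerVector cd = model["cards"];
    List cpts = model["cpts"];
    V = cd.size();
    order.resize(V);
    cards.assign(cd.begin(), cd.end());
    pa.resize(V);
    cpt.resize(V);
    q.resize(V);
    for (int i = 0; i < V; ++i) order[i] = ord[i] - 1;
    for (int v = 0; v < V; ++v) {
      IntegerVector p = parents[v];
      pa[v].resize(p.size());
      for (int m = 0; m < p.size(); ++m) pa[v][m] = p[m] - 1;
      NumericMatrix m = cpts[v];
      cpt[v] = REAL((SEXP)m);
      q[v] = m.nrow();
    }
  }

  inline int parent_row(int v, const int *state) const {
    int row = 0, stride = 1;
    for (size_t m = 0; m < pa[v].size(); ++m) {
      int p = pa[v][m];
      row += (state[p] - 1) * stride;
      stride *= cards[p];
    }
    return row;
  }

  // draw a 1-based state of node v given its parent row
  inline int draw(int v, int row, double u) const {
    const double *col = cpt[v] + row; // element (row, k) at row + k * q
    int r = cards[v];
    double acc = 0.0;
    for (int k = 0; k < r; ++k) {
      acc += col[(size_t)k * q[v]];
      if (u <= acc) return k + 1;
    }
    return r; // numerical slack: clamp to last state
  }

  inline double prob(int v, int row, int state) const {
    return cpt[v][row + (size_t)(state - 1) * q[v]];
  }
};

// Ancestral (logic) sampling: n joint draws, no evidence.
// [[Rcpp::export]]
IntegerMatrix cpp_logic_sample(List model, int n) {
  CompiledNet net(model);
  IntegerMatrix out(n, net.V);
  std::vector<int> state(net.V);
  for (int i = 0; i < n; ++i) {
    for (int oi = 0; oi < net.V; ++oi) {
      int v = net.order[oi];
      int row = net.parent_row(v, state.data());
      state[v] = net.draw(v, row, unif_rand());
      out(i, v) = state[v];
    }
  }
  return out;
}

// Likelihood weighting split into `repeats` independent blocks of
// `n_samples` draws. evidence[v] is the clamped 1-based state or NA.
// Returns `posterior` (repeats x r_target, unnormalized weighted counts)
// and `total_weight` per repeat.
// [[Rcpp::export]]
List cpp_likelihood_weighting(List model, IntegerVector evidence, int target,
                              int n_samples, int repeats) {
  CompiledNet net(model);
  int t = target - 1;
  int rt = net.cards[t];
  NumericMatrix post(repeats, rt);
  NumericVector totw(repeats);
  std::vector<int> state(net.V);
  std::vector<int> ev(net.V);
  for (int v = 0; v < net.V; ++v) ev[v] = evidence[v]; // NA stays NA
  for (int rep = 0; rep < repeats; ++rep) {
    for (int i = 0; i < n_samples; ++i) {
      double w = 1.0;
      for (int oi = 0; oi < net.V; ++oi) {
        int v = net.order[oi];
        int row = net.parent_row(v, state.data());
        if (ev[v] != NA_INTEGER) {
          state[v] = ev[v];
          w *= net.prob(v, row, state[v]);
        } else {
          state[v] = net.draw(v, row, unif_rand());
        }
      }
      if (w > 0.0) {
        post(rep, state[t] - 1) += w;
        totw[rep] += w;
      }
    }
  }
  return List::create(_["posterior"] = post, _["total_weight"] = totw);
}
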