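#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous Metropolis-style sweep over all nodes in a fresh uniformly
// random order. The network is given as a CSR adjacency list with edge
// multiplicity: a self-loop lists the node itself twice (both edge-ends),
// a k-fold multi-link lists the neighbour k times. All randomness comes
// from R's RNG stream (unif_rand), so results are reproducible under
// set.seed() and can be replayed call-for-call from R code.
static void one_sweep(const int n, const int *ptr, const int *adj,
                      int *s, const double temp, const double field,
                      int *order) {
  for (int i = 0; i < n; ++i) order[i] = i;
  // Fisher-Yates with one uniform draw per swap
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i; // guard: unif_rand() must stay below 1
    const int tmp = order[i]; order[i] = order[j]; order[j] = tmp;
  }
  for (int v = 0; v < n; ++v) {
    const int node = order[v];
    long G = 0;
    for (int e = ptr[node]; e < ptr[node + 1]; ++e) G += s[adj[e]];
    const double E = 2.0 * s[node] * ((double)G + field);
    const double u = unif_rand(); // fresh draw every visit (fixed stream layout)
    // exp() only evaluated when E > 0: avoids overflow of -E/T at tiny T
    if (E <= 0.0 || u < std::exp(-E / temp)) s[node] = -s[node];
  }
}

// [[Rcpp::export]]
IntegerVector ising_sweeps_cpp(IntegerVector ptr, IntegerVector adj,
                               IntegerVector spins, double temp,
                               double field, int n_sweeps) {
  const int n = spins.size();
  IntegerVector s = clone(spins);
  std::vector<int> order(n);
  for (int k = 0; k < n_sweeps; ++k)
    one_sweep(n, ptr.begin(), adj.begin(), s.begin(), temp, field,
              order.data());
  return s;
}

// Quasi-static sweep: the spin state is carried over between grid points;
// magnetisation is recorded after sweeps_per_step full passes at each
// (T, H) pair. Tgrid and Hgrid have one entry per recorded step.
// [[Rcpp::export]]
NumericVector sweep_curve_cpp(IntegerVector ptr, IntegerVector adj,
                              IntegerVector spins, NumericVector Tgrid,
                              NumericVector Hgrid, int sweeps_per_step) {
  const int n = spins.size();
  const int nstep = Tgrid.size();
  IntegerVector s = clone(spins);
  std::vector<int> order(n);
  NumericVector M(nstep);
  for (int k = 0; k < nstep; ++k) {
    for (int r = 0; r < sweeps_per_step; ++r)
      one_sweep(n, ptr.begin(), adj.begin(), s.begin(), Tgrid[k], Hgrid[k],
                order.data());
    long tot = 0;
    for (int i = 0; i < n; ++i) tot += s[i];
    M[k] = (double)tot / n;
  }
  return M;
}
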