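#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Wrap a phase difference to (-pi, pi].
static inline double wrap_pi(double d) {
  double w = d - 2.0 * M_PI * std::floor((d + M_PI) / (2.0 * M_PI));
  // w is now in [-pi, pi); fold the lower boundary onto +pi
  if (w == -M_PI) w = M_PI;
  return w;
}

static inline int sgn(double x) {
  return (x > 0) - (x < 0);
}

// PLI between two instantaneous-phase series: |mean(sign(wrapped dphi))|,
// with sign(0) contributing 0.
// [[Rcpp::export]]
double cpp_pli_pair(NumericVector a, NumericVector b) {
  R_xlen_t n = a.size();
  long s = 0;
  for (R_xlen_t t = 0; t < n; ++t)
    s += sgn(wrap_pi(a[t] - b[t]));
  return std::fabs((double)s / (double)n);
}

// All-pairs PLI over a channels x samples phase matrix.
// [[Rcpp::export]]
NumericMatrix cpp_pli_matrix(NumericMatrix phase) {
  int nc = phase.nrow();
  R_xlen_t ns = phase.ncol();
  NumericMatrix out(nc, nc);
  for (int i = 0; i < nc; ++i) {
    for (int j = i + 1; j < nc; ++j) {
      long s = 0;
      for (R_xlen_t t = 0; t < ns; ++t)
        s += sgn(wrap_pi(phase(i, t) - phase(j, t)));
      double v = std::fabs((double)s / (double)ns);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Unweighted all-pairs shortest-path lengths by BFS from every source.
// Unreachable pairs come back as +Inf; the diagonal is 0.
// [[Rcpp::export]]
NumericMatrix cpp_graph_dist(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nbr[i].push_back(j);
  NumericMatrix dist(n, n);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::vector<int> d(n);
  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), -1);
    d[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t k = 0; k < nbr[u].size(); ++k) {
        int v = nbr[u][k];
        if (d[v] < 0) { d[v] = d[u] + 1; q.push(v); }
      }
    }
    for (int j = 0; j < n; ++j)
      if (d[j] >= 0) dist(s, j) = d[j];
  }
  return dist;
}

// Global efficiency: mean over ordered pairs of 1/L_ij, 1/Inf = 0.
static double geff(const std::vector< std::vector<int> > &nbr, int n) {
  if (n < 2) return 0.0;
  double acc = 0.0;
  std::vector<int> d(n);
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), -1);
    d[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t k = 0; k < nbr[u].size(); ++k) {
        int v = nbr[u][k];
        if (d[v] < 0) { d[v] = d[u] + 1; q.push(v); }
      }
    }
    for (int j = 0; j < n; ++j)
      if (j != s && d[j] > 0) acc += 1.0 / (double)d[j];
  }
  return acc / ((double)n * (n - 1));
}

// [[Rcpp::export]]
double cpp_global_efficiency(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nbr[i].push_back(j);
  return geff(nbr, n);
}

// Nodal local efficiency: global efficiency of the subgraph induced on
// each node's neighbors; 0 for nodes with fewer than 2 neighbors.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix adj) {
  int n = adj.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && j != i) nb.push_back(j);
    int m = (int)nb.size();
    if (m < 2) { out[i] = 0.0; continue; }
    std::vector< std::vector<int> > nbr(m);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (a != b && adj(nb[a], nb[b]) != 0) nbr[a].push_back(b);
    out[i] = geff(nbr, m);
  }
  return out;
}

// Degree-preserving double-edge-swap (Maslov-Sneppen) randomization.
// Attempts swaps (a-b, c-d) -> (a-d, c-b) until `nswap` succeed or
// `max_tries` attempts are spent; draws come from R's RNG so results
// are reproducible under set.seed(). Returns the rewired adjacency and
// the number of successful swaps.
// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix adj, int nswap, int max_tries) {
  int n = adj.nrow();
  IntegerMatrix A = clone(adj);
  std::vector<int> ea, eb;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0) { ea.push_back(i); eb.push_back(j); }
  int m = (int)ea.size();
  int done = 0, tries = 0;
  if (m >= 2) {
    while (done < nswap && tries < max_tries) {
      ++tries;
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 == e2) continue;
      int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      // randomly flip one edge's orientation so both pairings are reachable
      if (unif_rand() < 0.5) std::swap(c, d);
      if (a == c || a == d || b == c || b == d) continue;
      if (A(a, d) != 0 || A(c, b) != 0) continue;
      A(a, b) = A(b, a) = 0;
      A(c, d) = A(d, c) = 0;
      A(a, d) = A(d, a) = 1;
      A(c, b) = A(b, c) = 1;
      ea[e1] = std::min(a, d); eb[e1] = std::max(a, d);
      ea[e2] = std::min(c, b); eb[e2] = std::max(c, b);
      ++done;
    }
  }
  return List::create(_["adjacency"] = A, _["swaps"] = done);
}
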