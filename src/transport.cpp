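// Exact discrete optimal transport by the transportation simplex
// (MODI / u-v method) with a north-west-corner start.
//
// Solves  min sum_ij f_ij c_ij  s.t.  sum_j f_ij = a_i, sum_i f_ij = b_j,
// f >= 0, with sum(a) == sum(b).  Supplies and demands are perturbed by a
// tiny epsilon cascade so the basis stays non-degenerate (Orden's trick);
// the resulting cost error is O(eps * max|c|), far below the solver's
// optimality tolerance.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Arc {
  int i, j;       // row node, col node
  double flow;
};

}  // namespace

// [[Rcpp::export(name = ".transport_cost_cpp")]]
double transport_cost_cpp(NumericMatrix cost,
                          NumericVector supply,
                          NumericVector demand) {
  const int n = cost.nrow(), m = cost.ncol();
  if (supply.size() != n || demand.size() != m)
    stop("supply/demand sizes do not match the cost matrix");

  // normalise both sides to total mass 1
  double sa = 0.0, sb = 0.0;
  for (int i = 0; i < n; ++i) sa += supply[i];
  for (int j = 0; j < m; ++j) sb += demand[j];
  if (sa <= 0 || sb <= 0) stop("supplies and demands must have positive mass");

  std::vector<double> a(n), b(m);
  const double eps = 1e-11 / (n + m);
  double extra = 0.0;
  for (int j = 0; j < m; ++j) {
    b[j] = demand[j] / sb + eps * (j + 1);
    extra += eps * (j + 1);
  }
  for (int i = 0; i < n; ++i) a[i] = supply[i] / sa;
  a[n - 1] += extra;  // keep the system balanced after perturbation

  double cmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      if (!std::isfinite(cost(i, j))) stop("non-finite cost entry");
      cmax = std::max(cmax, std::fabs(cost(i, j)));
    }
  const double tol = 1e-10 * (1.0 + cmax);

  // ---- north-west corner initial basis (a spanning tree of n + m - 1 arcs)
  std::vector<Arc> basis;
  basis.reserve(n + m - 1);
  {
    std::vector<double> ra = a, rb = b;
    int i = 0, j = 0;
    while (i < n && j < m) {
      double f = std::min(ra[i], rb[j]);
      basis.push_back({i, j, f});
      ra[i] -= f;
      rb[j] -= f;
      if (i == n - 1 && j == m - 1) break;
      if (ra[i] <= rb[j]) ++i; else ++j;
    }
  }
  if ((int)basis.size() != n + m - 1)
    stop("degenerate initial basis (internal error)");

  // adjacency: node ids 0..n-1 rows, n..n+m-1 cols; values are basis indices
  std::vector<std::vector<int>> adj(n + m);
  auto rebuild_adj = [&]() {
    for (auto& v : adj) v.clear();
    for (int k = 0; k < (int)basis.size(); ++k) {
      adj[basis[k].i].push_back(k);
      adj[n + basis[k].j].push_back(k);
    }
  };
  rebuild_adj();

  std::vector<double> u(n), v(m);
  std::vector<int> stack_node, stack_arc;
  std::vector<int> parent_arc(n + m), parent_node(n + m);
  std::vector<char> seen(n + m);

  const long max_iter = 1000L * (n + m) + 10000L;
  long iter = 0;

  for (;; ++iter) {
    if (iter > max_iter)
      stop("transport solver failed to converge (iteration cap reached)");

    // ---- potentials via DFS over the basis tree
    std::fill(seen.begin(), seen.end(), 0);
    u[0] = 0.0;
    seen[0] = 1;
    stack_node.clear();
    stack_node.push_back(0);
    while (!stack_node.empty()) {
      int node = stack_node.back();
      stack_node.pop_back();
      for (int k : adj[node]) {
        const Arc& arc = basis[k];
        int other = (node == arc.i) ? n + arc.j : arc.i;
        if (seen[other]) continue;
        seen[other] = 1;
        if (other >= n) v[other - n] = cost(arc.i, arc.j) - u[arc.i];
        else u[other] = cost(arc.i, arc.j) - v[basis[k].j];
        stack_node.push_back(other);
      }
    }

    // ---- entering arc: most negative reduced cost
    double best = -tol;
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      const double ui = u[i];
      for (int j = 0; j < m; ++j) {
        double red = cost(i, j) - ui - v[j];
        if (red < best) { best = red; bi = i; bj = j; }
      }
    }
    if (bi < 0) break;  // optimal

    // ---- unique tree path from row bi to col bj (BFS)
    std::fill(seen.begin(), seen.end(), 0);
    std::fill(parent_arc.begin(), parent_arc.end(), -1);
    seen[bi] = 1;
    stack_node.clear();
    stack_node.push_back(bi);
    const int target = n + bj;
    while (!stack_node.empty() && !seen[target]) {
      int node = stack_node.back();
      stack_node.pop_back();
      for (int k : adj[node]) {
        const Arc& arc = basis[k];
        int other = (node == arc.i) ? n + arc.j : arc.i;
        if (seen[other]) continue;
        seen[other] = 1;
        parent_arc[other] = k;
        parent_node[other] = node;
        stack_node.push_back(other);
      }
    }
    if (!seen[target]) stop("basis lost connectivity (internal error)");

    // path arcs from bj back to bi; signs alternate -, +, -, ... starting
    // at the arc adjacent to the entering arc's column end
    stack_arc.clear();
    for (int node = target; node != bi; node = parent_node[node])
      stack_arc.push_back(parent_arc[node]);

    double theta = std::numeric_limits<double>::infinity();
    int leave = -1;
    for (int t = 0; t < (int)stack_arc.size(); t += 2) {  // minus positions
      int k = stack_arc[t];
      if (basis[k].flow < theta) { theta = basis[k].flow; leave = k; }
    }
    if (leave < 0) stop("unbounded pivot (internal error)");

    for (int t = 0; t < (int)stack_arc.size(); ++t) {
      int k = stack_arc[t];
      basis[k].flow += (t % 2 == 0) ? -theta : theta;
    }
    basis[leave] = {bi, bj, theta};
    rebuild_adj();
  }

  double total = 0.0;
  for (const Arc& arc : basis) total += arc.flow * cost(arc.i, arc.j);
  return total;
}

// Euclidean pairwise cost matrix between two point sets (rows = points).
// [[Rcpp::export(name = ".euclidean_cost_cpp")]]
NumericMatrix euclidean_cost_cpp(NumericMatrix x, NumericMatrix y) {
  const int n = x.nrow(), m = y.nrow(), d = x.ncol();
  if (y.ncol() != d) stop("dimension mismatch between point sets");
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = x(i, k) - y(j, k);
        s += diff * diff;
      }
      out(i, j) = std::sqrt(s);
    }
  }
  return out;
}
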