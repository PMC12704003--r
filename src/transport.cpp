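#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact solver for the discrete transportation problem
//   min sum_ij T_ij c_ij  s.t.  T >= 0, T 1 = a, T' 1 = b
// via the transportation (network) simplex: a row-minimum greedy start,
// block-cyclic pricing, a rooted basis tree (parent / predecessor-arc /
// depth) so that pivot cycles are found by climbing to the lowest common
// ancestor and dual updates touch only the re-hung subtree, and a
// lexicographic-style marginal perturbation to rule out degenerate
// cycling. The optimal basis found under the perturbed marginals is
// re-solved exactly for the original marginals (a basis' reduced costs do
// not depend on the right-hand side), so the returned objective is exact
// up to floating-point round-off.

namespace {

struct Simplex {
  int m, n, nb;                 // nb = m + n - 1 basic arcs
  const double *cost;           // column-major m x n block
  std::vector<double> a, b;     // perturbed marginals
  std::vector<int> br, bc;      // basic arc endpoints (row, col)
  std::vector<double> bf;       // basic arc flows
  std::vector<std::vector<int>> adj; // node -> incident basic arc ids
                                     // nodes: rows 0..m-1, cols m..m+n-1
  std::vector<double> u, v;     // duals
  std::vector<int> parent, pred, depth; // rooted at node 0
  std::vector<int> stack_buf, arcs_a, arcs_b, path_arcs;

  double c(int i, int j) const { return cost[(size_t)j * m + i]; }
  int other_end(int aid, int node) const {
    return node == br[aid] ? m + bc[aid] : br[aid];
  }

  // row-minimum starting basis: rows in order, each row poured greedily
  // into its cheapest still-active column; crossing out one line per
  // allocation keeps the arcs a spanning tree (as with north-west corner)
  // but starts far closer to optimal
  void init_rowmin() {
    br.resize(nb); bc.resize(nb); bf.resize(nb);
    adj.assign(m + n, {});
    std::vector<double> brem = b;
    std::vector<int> cols(n);
    for (int j = 0; j < n; ++j) cols[j] = j;
    int ncols = n, i = 0, t = 0;
    double ai = a[0];
    while (true) {
      int bestp = 0; double bestc = R_PosInf;
      for (int p = 0; p < ncols; ++p) {
        double cc = c(i, cols[p]);
        if (cc < bestc) { bestc = cc; bestp = p; }
      }
      int j = cols[bestp];
      double bj = brem[j];
      double f = std::min(ai, bj);
      br[t] = i; bc[t] = j; bf[t] = f;
      adj[i].push_back(t); adj[m + j].push_back(t);
      ++t;
      bool lastrow = (i == m - 1), lastcol = (ncols == 1);
      if (lastrow && lastcol) break;
      if (lastcol || (!lastrow && ai <= bj)) {
        brem[j] = bj - ai;        // row i exhausted
        ++i; ai = a[i];
      } else {
        ai -= bj;                 // column j exhausted
        cols[bestp] = cols[--ncols];
      }
    }
  }

  // root the basis tree at node 0; set parent/pred/depth and all duals
  void root_tree() {
    u.assign(m, 0.0); v.assign(n, 0.0);
    parent.assign(m + n, -1); pred.assign(m + n, -1);
    depth.assign(m + n, 0);
    std::vector<char> seen(m + n, 0);
    stack_buf.clear(); stack_buf.push_back(0);
    seen[0] = 1;
    for (size_t h = 0; h < stack_buf.size(); ++h) {
      int node = stack_buf[h];
      for (int aid : adj[node]) {
        int oth = other_end(aid, node);
        if (seen[oth]) continue;
        seen[oth] = 1;
        parent[oth] = node; pred[oth] = aid;
        depth[oth] = depth[node] + 1;
        if (oth >= m) v[oth - m] = c(br[aid], bc[aid]) - u[br[aid]];
        else          u[oth]     = c(br[aid], bc[aid]) - v[bc[aid]];
        stack_buf.push_back(oth);
      }
    }
  }

  // returns number of pivots, or -1 on failure
  long run() {
    root_tree();
    double cmax = 0.0;
    for (size_t q = 0; q < (size_t)m * n; ++q)
      cmax = std::max(cmax, std::fabs(cost[q]));
    const double tol = std::max(1e-14, 1e-10 * cmax);
    long pivots = 0;
    const long maxit = 2000L * (m + n) + 10000L;

    // block-cyclic pricing: scan one block of arcs, collect its negative
    // reduced-cost arcs, pivot through them (re-checked under the current
    // duals), then move on; optimal once a full wrap finds nothing
    const size_t total = (size_t)m * n;
    const size_t block = std::max((size_t)256, total / 24);
    std::vector<std::pair<double, int>> cand; cand.reserve(block);
    size_t cursor = 0, clean = 0;

    while (pivots < maxit) {
      cand.clear();
      size_t stop = std::min(block, total - cursor);
      for (size_t s = 0; s < stop; ++s) {
        size_t q = cursor + s;
        int j = (int)(q / m), i = (int)(q - (size_t)j * m);
        double rc = cost[q] - u[i] - v[j];
        if (rc < -tol) cand.emplace_back(rc, (int)q);
      }
      cursor += stop; if (cursor >= total) cursor = 0;
      if (cand.empty()) {
        clean += stop;
        if (clean >= total) return pivots; // optimal
        continue;
      }
      clean = 0;
      std::sort(cand.begin(), cand.end());
      for (size_t ci = 0; ci < cand.size() && pivots < maxit; ++ci) {
        int q = cand[ci].second;
        int ej = q / m, ei = q - ej * m;
        if (c(ei, ej) - u[ei] - v[ej] >= -tol)
          continue;               // stale candidate under current duals

        // pivot cycle: entering arc (ei, m+ej) + tree path between its
        // endpoints, found by climbing to the lowest common ancestor.
        // path_arcs runs from the ej side to the ei side, so the cells
        // alternate -,+,-,... starting at the arc incident to ej.
        arcs_a.clear(); arcs_b.clear();
        int na = ei, nb2 = m + ej;
        while (depth[na] > depth[nb2]) { arcs_a.push_back(pred[na]); na = parent[na]; }
        while (depth[nb2] > depth[na]) { arcs_b.push_back(pred[nb2]); nb2 = parent[nb2]; }
        while (na != nb2) {
          arcs_a.push_back(pred[na]);  na = parent[na];
          arcs_b.push_back(pred[nb2]); nb2 = parent[nb2];
        }
        path_arcs = arcs_b;
        path_arcs.insert(path_arcs.end(), arcs_a.rbegin(), arcs_a.rend());

        double theta = R_PosInf; int leave = -1;
        for (size_t s = 0; s < path_arcs.size(); s += 2) {
          int aid = path_arcs[s];
          if (bf[aid] < theta) { theta = bf[aid]; leave = aid; }
        }
        for (size_t s = 0; s < path_arcs.size(); ++s) {
          int aid = path_arcs[s];
          if (s % 2 == 0) bf[aid] -= theta; else bf[aid] += theta;
        }

        // the detached component is the subtree below the leaving arc's
        // deeper endpoint (it cannot contain the root); record it before
        // the slot is overwritten
        int lp = br[leave], lq = m + bc[leave];
        int child = depth[lp] > depth[lq] ? lp : lq;

        // entering arc replaces the leaving arc in the same slot
        drop_arc(br[leave], leave); drop_arc(m + bc[leave], leave);
        br[leave] = ei; bc[leave] = ej; bf[leave] = theta;
        adj[ei].push_back(leave); adj[m + ej].push_back(leave);

        // re-hang the detached subtree from the entering arc: exactly one
        // of its endpoints lies in the subtree; re-anchor there and
        // rebuild parent/pred/depth/duals inside by traversal (the
        // entering arc itself is excluded, so traversal stays inside)
        int x, px;
        if (in_subtree(ei, child, leave)) { x = ei; px = m + ej; }
        else                              { x = m + ej; px = ei; }
        parent[x] = px; pred[x] = leave; depth[x] = depth[px] + 1;
        if (x >= m) v[x - m] = c(ei, ej) - u[ei];
        else        u[x]     = c(ei, ej) - v[ej];
        stack_buf.clear(); stack_buf.push_back(x);
        for (size_t h = 0; h < stack_buf.size(); ++h) {
          int node = stack_buf[h];
          for (int aid : adj[node]) {
            if (aid == leave && node == x) continue;
            int oth = other_end(aid, node);
            if (oth == parent[node] && aid == pred[node]) continue;
            parent[oth] = node; pred[oth] = aid;
            depth[oth] = depth[node] + 1;
            if (oth >= m) v[oth - m] = c(br[aid], bc[aid]) - u[br[aid]];
            else          u[oth]     = c(br[aid], bc[aid]) - v[bc[aid]];
            stack_buf.push_back(oth);
          }
        }
        ++pivots;
      }
    }
    return -1;
  }

  // does `node` lie in the subtree rooted at `child` once arc `cut` is
  // removed? climb from node towards the root; the subtree is entered
  // exactly when `child` is met before the root
  bool in_subtree(int node, int child, int cut) {
    (void)cut;
    while (node != -1) {
      if (node == child) return true;
      node = parent[node];
    }
    return false;
  }

  void drop_arc(int node, int aid) {
    auto &lst = adj[node];
    lst.erase(std::find(lst.begin(), lst.end(), aid));
  }

  // exact flows for the original (unperturbed) marginals on the final
  // basis tree, by leaf elimination; returns the objective
  double exact_objective(const std::vector<double> &a0,
                         const std::vector<double> &b0) {
    std::vector<double> rem(m + n);
    for (int i = 0; i < m; ++i) rem[i] = a0[i];
    for (int j = 0; j < n; ++j) rem[m + j] = b0[j];
    std::vector<int> deg(m + n);
    std::vector<char> done_arc(nb, 0);
    std::vector<int> stk;
    for (int node = 0; node < m + n; ++node) {
      deg[node] = (int)adj[node].size();
      if (deg[node] == 1) stk.push_back(node);
    }
    double obj = 0.0;
    int processed = 0;
    while (!stk.empty()) {
      int node = stk.back(); stk.pop_back();
      if (deg[node] != 1) continue;
      int aid = -1;
      for (int cnd : adj[node]) if (!done_arc[cnd]) { aid = cnd; break; }
      if (aid < 0) continue;
      double f = rem[node];
      if (f < 0) f = 0.0; // round-off guard on degenerate arcs
      obj += f * c(br[aid], bc[aid]);
      int oth = other_end(aid, node);
      rem[oth] -= f;
      done_arc[aid] = 1; ++processed;
      deg[node] = 0;
      if (--deg[oth] == 1) stk.push_back(oth);
    }
    if (processed != nb) Rcpp::stop("internal error: basis is not a tree");
    return obj;
  }
};

double solve_pair(int m, int n, const double *cost,
                  const double *a0, const double *b0) {
  if (m == 1) { // forced plan
    double s = 0.0; for (int j = 0; j < n; ++j) s += b0[j] * cost[(size_t)j];
    return s;
  }
  if (n == 1) {
    double s = 0.0; for (int i = 0; i < m; ++i) s += a0[i] * cost[i];
    return s;
  }
  Simplex sp;
  sp.m = m; sp.n = n; sp.nb = m + n - 1; sp.cost = cost;
  // balance-preserving perturbation: distinct increments on rows, total
  // added to the last column
  const double eps = 1e-11;
  sp.a.assign(a0, a0 + m); sp.b.assign(b0, b0 + n);
  double add = 0.0;
  for (int i = 0; i < m; ++i) { double d = eps * (i + 1); sp.a[i] += d; add += d; }
  sp.b[n - 1] += add;
  sp.init_rowmin();
  if (sp.run() < 0) Rcpp::stop("transportation simplex failed to converge");
  std::vector<double> av(a0, a0 + m), bv(b0, b0 + n);
  return sp.exact_objective(av, bv);
}

} // namespace

//' @keywords internal
// [[Rcpp::export(name = ".emd_cpp")]]
double emd_cpp(NumericVector a, NumericVector b, NumericMatrix C) {
  int m = a.size(), n = b.size();
  if (C.nrow() != m || C.ncol() != n)
    stop("cost matrix dimensions do not match the two mass vectors");
  double sa = 0.0, sb = 0.0;
  for (double x : a) { if (x < 0) stop("negative mass"); sa += x; }
  for (double x : b) { if (x < 0) stop("negative mass"); sb += x; }
  if (sa <= 0 || sb <= 0) stop("mass vectors must have positive total");
  if (std::fabs(sa - sb) > 1e-6 * std::max(sa, sb))
    stop("unbalanced transport problem: mass totals differ");
  std::vector<double> av(m), bv(n);
  for (int i = 0; i < m; ++i) av[i] = a[i] / sa;
  for (int j = 0; j < n; ++j) bv[j] = b[j] / sb;
  return solve_pair(m, n, REAL(C), av.data(), bv.data());
}

// Pairwise OT distances over gene supports sharing one cell-cell cost
// matrix. supports holds 1-based cell indices per gene; masses the matching
// positive weights (each summing to 1). The per-pair cost block is gathered
// into a reusable buffer so no matrix copies survive the call.
// [[Rcpp::export(name = ".pairwise_emd_cpp")]]
NumericMatrix pairwise_emd_cpp(NumericMatrix Cfull, List supports, List masses) {
  int p = supports.size();
  if (masses.size() != p) stop("supports and masses length mismatch");
  int ncell = Cfull.nrow();
  if (Cfull.ncol() != ncell) stop("cost matrix must be square");
  std::vector<std::vector<int>> sup(p);
  std::vector<std::vector<double>> mas(p);
  for (int g = 0; g < p; ++g) {
    IntegerVector s = supports[g];
    NumericVector w = masses[g];
    if (s.size() != w.size() || s.size() == 0)
      stop("support/mass mismatch for gene %d", g + 1);
    double tot = 0.0;
    sup[g].resize(s.size()); mas[g].resize(s.size());
    for (int t = 0; t < s.size(); ++t) {
      int idx = s[t];
      if (idx < 1 || idx > ncell) stop("support index out of range");
      sup[g][t] = idx - 1;
      if (w[t] <= 0) stop("non-positive mass in gene %d", g + 1);
      mas[g][t] = w[t]; tot += w[t];
    }
    for (double &x : mas[g]) x /= tot;
  }
  NumericMatrix D(p, p);
  const double *CF = REAL(Cfull);
  std::vector<double> block;
  for (int gi = 0; gi < p; ++gi) {
    const auto &si = sup[gi];
    for (int gj = gi + 1; gj < p; ++gj) {
      const auto &sj = sup[gj];
      int m = (int)si.size(), n = (int)sj.size();
      block.resize((size_t)m * n);
      for (int jj = 0; jj < n; ++jj) {
        const double *colbase = CF + (size_t)sj[jj] * ncell;
        double *dst = block.data() + (size_t)jj * m;
        for (int ii = 0; ii < m; ++ii) dst[ii] = colbase[si[ii]];
      }
      double d = solve_pair(m, n, block.data(), mas[gi].data(), mas[gj].data());
      D(gi, gj) = d; D(gj, gi) = d;
    }
    if (gi % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return D;
}
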