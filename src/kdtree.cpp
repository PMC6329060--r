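#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Small static 3-d kd-tree for nearest-neighbour correspondence lookup
// (used by the ICP symmetry-plane refinement and seed snapping).

namespace {

struct KDTree {
  const double *pts; // column-major n x 3
  int n;
  std::vector<int> idx;   // permutation, tree stored as balanced implicit ranges
  std::vector<int> axis_of; // split axis per range midpoint (stored on the fly)

  double coord(int p, int ax) const { return pts[p + (R_xlen_t)ax * n]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    const double *P = pts;
    const int N = n;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [P, N, ax](int a, int b) {
                       return P[a + (R_xlen_t)ax * N] < P[b + (R_xlen_t)ax * N];
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(const double q[3], int lo, int hi, int depth,
             int &best, double &bestd2) const {
    if (hi <= lo) return;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    int p = idx[mid];
    double dx = q[0] - coord(p, 0);
    double dy = q[1] - coord(p, 1);
    double dz = q[2] - coord(p, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2) { bestd2 = d2; best = p; }
    double diff = q[ax] - coord(p, ax);
    int nearLo, nearHi, farLo, farHi;
    if (diff < 0) { nearLo = lo; nearHi = mid; farLo = mid + 1; farHi = hi; }
    else { nearLo = mid + 1; nearHi = hi; farLo = lo; farHi = mid; }
    query(q, nearLo, nearHi, depth + 1, best, bestd2);
    if (diff * diff < bestd2) query(q, farLo, farHi, depth + 1, best, bestd2);
  }
};

} // namespace

// For each row of `query`, the index (1-based) of the nearest row of `ref`
// and the distance to it.

// [[Rcpp::export(name = ".nn_match")]]
List nn_match(NumericMatrix ref, NumericMatrix query) {
  if (ref.ncol() != 3 || query.ncol() != 3) stop("points must be n x 3");
  int n = ref.nrow(), m = query.nrow();
  if (n < 1) stop("empty reference set");
  KDTree tree;
  tree.pts = REAL(ref);
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.build(0, n, 0);

  IntegerVector out_idx(m);
  NumericVector out_dist(m);
  for (int i = 0; i < m; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    int best = -1;
    double bestd2 = R_PosInf;
    tree.query(q, 0, n, 0, best, bestd2);
    out_idx[i] = best + 1;
    out_dist[i] = std::sqrt(bestd2);
  }
  return List::create(_["idx"] = out_idx, _["dist"] = out_dist);
}
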