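#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Marching tetrahedra on a regular scalar grid.
//
// Each grid cell is split into six tetrahedra sharing the cell's main
// diagonal (corner 0 -> corner 6).  Face diagonals induced by this split are
// identical on the shared faces of neighbouring cells, so the extracted
// surface is watertight.  Iso-vertices are placed on cut edges by linear
// interpolation and welded through a global edge hash, giving a shared-vertex
// triangle mesh in continuous 0-based index coordinates.

namespace {

// cell corner offsets, bit order (x, y, z)
const int CO[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// six tetrahedra around the 0-6 diagonal
const int TET[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

struct Builder {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  uint64_t nvox;

  // iso-vertex on edge between global corners a and b (linear indices),
  // with corner coordinates pa/pb and values va/vb straddling the level
  int edge_vertex(uint64_t a, uint64_t b, const double *pa, const double *pb,
                  double va, double vb, double level) {
    uint64_t lo = a < b ? a : b, hi = a < b ? b : a;
    uint64_t key = lo * nvox + hi;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vert.emplace(key, id);
    return id;
  }

  // add a triangle, flipping winding so the normal points from the inside
  // (value >= level) side toward the outside side
  void add_tri(int i0, int i1, int i2, const double out_dir[3]) {
    double e1x = vx[i1] - vx[i0], e1y = vy[i1] - vy[i0], e1z = vz[i1] - vz[i0];
    double e2x = vx[i2] - vx[i0], e2y = vy[i2] - vy[i0], e2z = vz[i2] - vz[i0];
    double nx = e1y * e2z - e1z * e2y;
    double ny = e1z * e2x - e1x * e2z;
    double nz = e1x * e2y - e1y * e2x;
    double d = nx * out_dir[0] + ny * out_dir[1] + nz * out_dir[2];
    if (d < 0) std::swap(i1, i2);
    fa.push_back(i0); fb.push_back(i1); fc.push_back(i2);
  }
};

} // namespace

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector vol, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("grid must be at least 2 voxels per axis");
  const double *v = REAL(vol);
  Builder B;
  B.nvox = (uint64_t)nx * ny * nz;

  double cpos[8][3];
  double cval[8];
  uint64_t clin[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      uint64_t base = (uint64_t)nx * (j + (uint64_t)ny * k);
      for (int i = 0; i + 1 < nx; ++i) {
        // gather corners
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + CO[c][0], cj = j + CO[c][1], ck = k + CO[c][2];
          uint64_t lin = (uint64_t)ci + (uint64_t)nx * (cj + (uint64_t)ny * ck);
          clin[c] = lin;
          cval[c] = v[lin];
          cpos[c][0] = ci; cpos[c][1] = cj; cpos[c][2] = ck;
          if (cval[c] >= level) any_in = true; else any_out = true;
        }
        (void)base;
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int id[4] = {TET[t][0], TET[t][1], TET[t][2], TET[t][3]};
          int ins[4], outs[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[id[c]] >= level) ins[ni++] = id[c];
            else outs[no++] = id[c];
          }
          if (ni == 0 || ni == 4) continue;

          // outward direction: centroid(outside) - centroid(inside)
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) cin[d] += cpos[ins[c]][d] / ni;
          for (int c = 0; c < no; ++c)
            for (int d = 0; d < 3; ++d) cout[d] += cpos[outs[c]][d] / no;
          double od[3] = {cout[0] - cin[0], cout[1] - cin[1], cout[2] - cin[2]};

          if (ni == 1) {
            int a = ins[0];
            int e0 = B.edge_vertex(clin[a], clin[outs[0]], cpos[a], cpos[outs[0]], cval[a], cval[outs[0]], level);
            int e1 = B.edge_vertex(clin[a], clin[outs[1]], cpos[a], cpos[outs[1]], cval[a], cval[outs[1]], level);
            int e2 = B.edge_vertex(clin[a], clin[outs[2]], cpos[a], cpos[outs[2]], cval[a], cval[outs[2]], level);
            B.add_tri(e0, e1, e2, od);
          } else if (ni == 3) {
            int a = outs[0];
            int e0 = B.edge_vertex(clin[a], clin[ins[0]], cpos[a], cpos[ins[0]], cval[a], cval[ins[0]], level);
            int e1 = B.edge_vertex(clin[a], clin[ins[1]], cpos[a], cpos[ins[1]], cval[a], cval[ins[1]], level);
            int e2 = B.edge_vertex(clin[a], clin[ins[2]], cpos[a], cpos[ins[2]], cval[a], cval[ins[2]], level);
            B.add_tri(e0, e1, e2, od);
          } else { // ni == 2: quad in cyclic order AC, AD, BD, BC
            int A = ins[0], Bc = ins[1], C = outs[0], D = outs[1];
            int q0 = B.edge_vertex(clin[A], clin[C], cpos[A], cpos[C], cval[A], cval[C], level);
            int q1 = B.edge_vertex(clin[A], clin[D], cpos[A], cpos[D], cval[A], cval[D], level);
            int q2 = B.edge_vertex(clin[Bc], clin[D], cpos[Bc], cpos[D], cval[Bc], cval[D], level);
            int q3 = B.edge_vertex(clin[Bc], clin[C], cpos[Bc], cpos[C], cval[Bc], cval[C], level);
            B.add_tri(q0, q1, q2, od);
            B.add_tri(q0, q2, q3, od);
          }
        }
      }
    }
  }

  int nvert = (int)B.vx.size();
  int nface = (int)B.fa.size();
  NumericMatrix V(nvert, 3);
  IntegerMatrix F(nface, 3);
  for (int r = 0; r < nvert; ++r) {
    V(r, 0) = B.vx[r]; V(r, 1) = B.vy[r]; V(r, 2) = B.vz[r];
  }
  for (int r = 0; r < nface; ++r) {
    F(r, 0) = B.fa[r] + 1; F(r, 1) = B.fb[r] + 1; F(r, 2) = B.fc[r] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
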