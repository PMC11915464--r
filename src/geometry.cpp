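// Low-level geometry kernels: iso-surfacing (marching tetrahedra), capsule
// signed-distance voxelization, winding-number re-voxelization, edge-collapse
// decimation, triangle-triangle intersection census, point/ray vs mesh queries
// and tolerance-based vertex welding.  All meshes are 0-indexed here; the R
// layer converts to/from 1-based indices.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <functional>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------- utilities

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// squared distance from point p to segment [a,b]
static double point_seg_dist2(const double* p, const double* a, const double* b) {
  double ab[3], ap[3];
  sub3(b, a, ab); sub3(p, a, ap);
  double denom = dot3(ab, ab);
  double t = denom > 0 ? dot3(ap, ab) / denom : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double d[3] = { ap[0] - t * ab[0], ap[1] - t * ab[1], ap[2] - t * ab[2] };
  return dot3(d, d);
}

// closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision Detection)
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3]; sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; i++) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3]; sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; i++) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; i++) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; i++) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// ------------------------------------------------------- marching tetrahedra
//
// Each grid cube is split into six positively oriented tetrahedra sharing the
// body diagonal; iso-vertices are keyed on the global grid-node pair of the
// crossing edge, which makes the output watertight by construction.
// "Inside" means field value > level.

static const int TET6[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};
// even permutations used to rotate one marked vertex (or pair) to slot 0 (0,1)
static const int PERM1[4][4] = {
  {0, 1, 2, 3}, {1, 0, 3, 2}, {2, 3, 0, 1}, {3, 2, 1, 0}
};
static const int PERM2[6][4] = {
  {0, 1, 2, 3}, {0, 2, 3, 1}, {0, 3, 1, 2},
  {1, 2, 0, 3}, {1, 3, 2, 0}, {2, 3, 0, 1}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> verts;      // xyz triplets
  std::vector<int> tris;          // index triplets
};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, NumericVector spacing,
                        double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double* f = REAL(field);
  double fmin = R_PosInf, fmax = R_NegInf;
  for (R_xlen_t i = 0; i < field.size(); i++) {
    if (f[i] < fmin) fmin = f[i];
    if (f[i] > fmax) fmax = f[i];
  }
  const double snap = (fmax > fmin) ? 1e-9 * (fmax - fmin) : 1e-12;
  const uint64_t nnode = (uint64_t)nx * ny * nz;

  MTState st;
  st.verts.reserve(1 << 16);
  st.tris.reserve(1 << 16);

  auto nodeval = [&](uint64_t id) {
    double v = f[id];
    if (std::fabs(v - level) < snap) v = level + snap;  // avoid exact hits
    return v;
  };
  auto vert_on_edge = [&](uint64_t a, uint64_t b) -> int {
    uint64_t lo = a < b ? a : b, hi = a < b ? b : a;
    uint64_t key = lo * nnode + hi;
    auto it = st.edge_vert.find(key);
    if (it != st.edge_vert.end()) return it->second;
    double va = nodeval(lo), vb = nodeval(hi);
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0; else if (t > 1) t = 1;
    int ia = (int)(lo % nx), ja = (int)((lo / nx) % ny), ka = (int)(lo / ((uint64_t)nx * ny));
    int ib = (int)(hi % nx), jb = (int)((hi / nx) % ny), kb = (int)(hi / ((uint64_t)nx * ny));
    double px = ox + sx * (ia + t * (ib - ia));
    double py = oy + sy * (ja + t * (jb - ja));
    double pz = oz + sz * (ka + t * (kb - ka));
    int id = (int)(st.verts.size() / 3);
    st.verts.push_back(px); st.verts.push_back(py); st.verts.push_back(pz);
    st.edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c) {
    st.tris.push_back(a); st.tris.push_back(b); st.tris.push_back(c);
  };

  uint64_t corner[8];
  for (int k = 0; k + 1 < nz; k++) {
    for (int j = 0; j + 1 < ny; j++) {
      uint64_t base0 = (uint64_t)nx * (j + (uint64_t)ny * k);
      for (int i = 0; i + 1 < nx; i++) {
        // cube corners: bit0 -> +x, bit1 -> +y, bit2 -> +z
        corner[0] = base0 + i;
        corner[1] = corner[0] + 1;
        corner[2] = corner[0] + nx;
        corner[3] = corner[2] + 1;
        corner[4] = corner[0] + (uint64_t)nx * ny;
        corner[5] = corner[4] + 1;
        corner[6] = corner[4] + nx;
        corner[7] = corner[6] + 1;
        // fast reject: all on one side
        int npos = 0;
        for (int c = 0; c < 8; c++) if (nodeval(corner[c]) > level) npos++;
        if (npos == 0 || npos == 8) continue;
        for (int t = 0; t < 6; t++) {
          uint64_t tv[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; c++) {
            tv[c] = corner[TET6[t][c]];
            in[c] = nodeval(tv[c]) > level;
            if (in[c]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int mark = -1;
            for (int c = 0; c < 4; c++)
              if (in[c] == (nin == 1)) { mark = c; break; }
            const int* pm = PERM1[mark];
            uint64_t A = tv[pm[0]], B = tv[pm[1]], C = tv[pm[2]], D = tv[pm[3]];
            int vab = vert_on_edge(A, B), vac = vert_on_edge(A, C), vad = vert_on_edge(A, D);
            if (nin == 1) emit(vab, vac, vad);       // inside vertex at A
            else emit(vab, vad, vac);                 // outside vertex at A
          } else {                                    // nin == 2
            int a = -1, b = -1;
            for (int c = 0; c < 4; c++) if (in[c]) { if (a < 0) a = c; else b = c; }
            int pi = -1;
            for (int c = 0; c < 6; c++)
              if ((PERM2[c][0] == a && PERM2[c][1] == b) ||
                  (PERM2[c][0] == b && PERM2[c][1] == a)) { pi = c; break; }
            const int* pm = PERM2[pi];
            uint64_t A = tv[pm[0]], B = tv[pm[1]], C = tv[pm[2]], D = tv[pm[3]];
            int vac = vert_on_edge(A, C), vad = vert_on_edge(A, D);
            int vbd = vert_on_edge(B, D), vbc = vert_on_edge(B, C);
            emit(vac, vad, vbd);
            emit(vac, vbd, vbc);
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  int nv = (int)(st.verts.size() / 3), nf = (int)(st.tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; i++)
    for (int c = 0; c < 3; c++) V(i, c) = st.verts[3 * i + c];
  for (int i = 0; i < nf; i++)
    for (int c = 0; c < 3; c++) Fm(i, c) = st.tris[3 * i + c];
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ------------------------------------------------- capsule SDF voxelization
// field = max over capsules of (radius - distance to segment); positive inside
// the strut union.  Only voxels in each capsule's padded bounding box are
// touched; everywhere else keeps a negative far value.

// [[Rcpp::export]]
NumericVector cpp_capsule_field(NumericMatrix seg_a, NumericMatrix seg_b,
                                NumericVector radius, IntegerVector dims,
                                NumericVector origin, double pitch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector field((R_xlen_t)nx * ny * nz);
  std::fill(field.begin(), field.end(), -4.0 * pitch);
  const int ncap = seg_a.nrow();
  for (int s = 0; s < ncap; s++) {
    double a[3] = { seg_a(s, 0), seg_a(s, 1), seg_a(s, 2) };
    double b[3] = { seg_b(s, 0), seg_b(s, 1), seg_b(s, 2) };
    double r = radius[s], pad = r + 3.0 * pitch;
    int i0 = std::max(0, (int)std::floor((std::min(a[0], b[0]) - pad - ox) / pitch));
    int i1 = std::min(nx - 1, (int)std::ceil((std::max(a[0], b[0]) + pad - ox) / pitch));
    int j0 = std::max(0, (int)std::floor((std::min(a[1], b[1]) - pad - oy) / pitch));
    int j1 = std::min(ny - 1, (int)std::ceil((std::max(a[1], b[1]) + pad - oy) / pitch));
    int k0 = std::max(0, (int)std::floor((std::min(a[2], b[2]) - pad - oz) / pitch));
    int k1 = std::min(nz - 1, (int)std::ceil((std::max(a[2], b[2]) + pad - oz) / pitch));
    for (int k = k0; k <= k1; k++) {
      for (int j = j0; j <= j1; j++) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double p[3];
        p[1] = oy + pitch * j; p[2] = oz + pitch * k;
        for (int i = i0; i <= i1; i++) {
          p[0] = ox + pitch * i;
          double val = r - std::sqrt(point_seg_dist2(p, a, b));
          if (val > field[base + i]) field[base + i] = val;
        }
      }
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return field;
}

// ------------------------------------------ 3D connected component labeling

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; dz++) {
        int kk = k + dz; if (kk < 0 || kk >= nz) continue;
        for (int dy = -1; dy <= 1; dy++) {
          int jj = j + dy; if (jj < 0 || jj >= ny) continue;
          for (int dx2 = -1; dx2 <= 1; dx2++) {
            int ii = i + dx2; if (ii < 0 || ii >= nx) continue;
            int manh = std::abs(dx2) + std::abs(dy) + std::abs(dz);
            if (manh == 0) continue;
            if (connectivity == 6 && manh != 1) continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
          }
        }
      }
    }
  }
  return lab;
}

// ------------------------------------------------- edge-collapse decimation
// Shortest-edge-first collapse to the edge midpoint with manifold link-
// condition and triangle-flip guards; preserves closedness.

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_edges) {
  const int nv0 = Vin.nrow(), nf0 = Fin.nrow();
  std::vector<double> V(nv0 * 3);
  for (int i = 0; i < nv0; i++)
    for (int c = 0; c < 3; c++) V[3 * i + c] = Vin(i, c);
  std::vector<int> F(nf0 * 3);
  for (int i = 0; i < nf0; i++)
    for (int c = 0; c < 3; c++) F[3 * i + c] = Fin(i, c);
  std::vector<bool> falive(nf0, true), valive(nv0, true);
  std::vector<std::vector<int>> vfaces(nv0);
  for (int i = 0; i < nf0; i++)
    for (int c = 0; c < 3; c++) vfaces[F[3 * i + c]].push_back(i);

  long edge_count = (long)nf0 * 3 / 2;
  typedef std::pair<double, std::pair<int, int>> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> heap;
  auto elen2 = [&](int a, int b) {
    double d[3] = { V[3*a] - V[3*b], V[3*a+1] - V[3*b+1], V[3*a+2] - V[3*b+2] };
    return dot3(d, d);
  };
  auto push_edges_of = [&](int u) {
    for (size_t fi = 0; fi < vfaces[u].size(); fi++) {
      int f = vfaces[u][fi];
      if (!falive[f]) continue;
      for (int c = 0; c < 3; c++) {
        int a = F[3 * f + c], b = F[3 * f + (c + 1) % 3];
        if (a == u || b == u) {
          int lo = std::min(a, b), hi = std::max(a, b);
          heap.push(std::make_pair(elen2(lo, hi), std::make_pair(lo, hi)));
        }
      }
    }
  };
  for (int i = 0; i < nf0; i++)
    for (int c = 0; c < 3; c++) {
      int a = F[3 * i + c], b = F[3 * i + (c + 1) % 3];
      if (a < b) heap.push(std::make_pair(elen2(a, b), std::make_pair(a, b)));
    }

  auto neighbors = [&](int u) {
    std::vector<int> nb;
    for (size_t fi = 0; fi < vfaces[u].size(); fi++) {
      int f = vfaces[u][fi];
      if (!falive[f]) continue;
      for (int c = 0; c < 3; c++) {
        int w = F[3 * f + c];
        if (w != u) nb.push_back(w);
      }
    }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    return nb;
  };

  int guard = 0;
  while (edge_count > target_edges && !heap.empty()) {
    if (++guard % 4096 == 0) Rcpp::checkUserInterrupt();
    QE top = heap.top(); heap.pop();
    int u = top.second.first, v = top.second.second;
    if (!valive[u] || !valive[v]) continue;
    // verify edge still exists and priority is current
    bool exists = false;
    for (size_t fi = 0; fi < vfaces[u].size() && !exists; fi++) {
      int f = vfaces[u][fi];
      if (!falive[f]) continue;
      for (int c = 0; c < 3; c++)
        if (F[3 * f + c] == v) { exists = true; break; }
    }
    if (!exists) continue;
    double cur = elen2(u, v);
    if (top.first < cur * (1 - 1e-12)) continue;   // stale entry

    // link condition: common neighbours must be exactly the 2 opposite verts
    std::vector<int> nu = neighbors(u), nv = neighbors(v), common;
    std::set_intersection(nu.begin(), nu.end(), nv.begin(), nv.end(),
                          std::back_inserter(common));
    std::vector<int> shared_faces;
    for (size_t fi = 0; fi < vfaces[u].size(); fi++) {
      int f = vfaces[u][fi];
      if (!falive[f]) continue;
      bool hasv = false;
      for (int c = 0; c < 3; c++) if (F[3 * f + c] == v) hasv = true;
      if (hasv) shared_faces.push_back(f);
    }
    if (shared_faces.size() != 2) continue;        // boundary or non-manifold
    if (common.size() != 2) continue;

    double mid[3] = { 0.5 * (V[3*u] + V[3*v]), 0.5 * (V[3*u+1] + V[3*v+1]),
                      0.5 * (V[3*u+2] + V[3*v+2]) };
    // flip guard: every surviving face keeps normal direction
    bool ok = true;
    for (int which = 0; which < 2 && ok; which++) {
      int w = which == 0 ? u : v;
      for (size_t fi = 0; fi < vfaces[w].size() && ok; fi++) {
        int f = vfaces[w][fi];
        if (!falive[f]) continue;
        bool shared = false;
        for (size_t s = 0; s < shared_faces.size(); s++)
          if (shared_faces[s] == f) shared = true;
        if (shared) continue;
        double p[3][3], q[3][3];
        for (int c = 0; c < 3; c++) {
          int vid = F[3 * f + c];
          for (int d = 0; d < 3; d++) {
            p[c][d] = V[3 * vid + d];
            q[c][d] = (vid == u || vid == v) ? mid[d] : V[3 * vid + d];
          }
        }
        double e1[3], e2[3], n0[3], e3[3], e4[3], n1[3];
        sub3(p[1], p[0], e1); sub3(p[2], p[0], e2); cross3(e1, e2, n0);
        sub3(q[1], q[0], e3); sub3(q[2], q[0], e4); cross3(e3, e4, n1);
        double nn0 = norm3(n0), nn1 = norm3(n1);
        if (nn1 < 1e-14 || dot3(n0, n1) <= 1e-10 * nn0 * nn1) ok = false;
      }
    }
    if (!ok) continue;

    // collapse v into u, u moves to midpoint
    for (int d = 0; d < 3; d++) V[3 * u + d] = mid[d];
    valive[v] = false;
    for (size_t s = 0; s < shared_faces.size(); s++) falive[shared_faces[s]] = false;
    for (size_t fi = 0; fi < vfaces[v].size(); fi++) {
      int f = vfaces[v][fi];
      if (!falive[f]) continue;
      for (int c = 0; c < 3; c++) if (F[3 * f + c] == v) F[3 * f + c] = u;
      vfaces[u].push_back(f);
    }
    vfaces[v].clear();
    edge_count -= 3;
    push_edges_of(u);
  }

  // compact result
  std::vector<int> vmap(nv0, -1);
  std::vector<double> Vout;
  std::vector<int> Fout;
  for (int i = 0; i < nf0; i++) {
    if (!falive[i]) continue;
    for (int c = 0; c < 3; c++) {
      int vid = F[3 * i + c];
      if (vmap[vid] < 0) {
        vmap[vid] = (int)(Vout.size() / 3);
        Vout.push_back(V[3 * vid]); Vout.push_back(V[3 * vid + 1]); Vout.push_back(V[3 * vid + 2]);
      }
      Fout.push_back(vmap[vid]);
    }
  }
  int nv = (int)(Vout.size() / 3), nf = (int)(Fout.size() / 3);
  NumericMatrix VV(nv, 3);
  IntegerMatrix FF(nf, 3);
  for (int i = 0; i < nv; i++)
    for (int c = 0; c < 3; c++) VV(i, c) = Vout[3 * i + c];
  for (int i = 0; i < nf; i++)
    for (int c = 0; c < 3; c++) FF(i, c) = Fout[3 * i + c];
  return List::create(_["vertices"] = VV, _["faces"] = FF,
                      _["edge_count"] = (double)edge_count);
}

// ------------------------------------- triangle-triangle intersection count
// Moller's interval-overlap test with a coplanar 2D fallback; candidate pairs
// from a uniform spatial hash; pairs sharing a vertex index are skipped.

static bool tri_tri_overlap(const double* p1, const double* q1, const double* r1,
                            const double* p2, const double* q2, const double* r2,
                            double eps);

static double orient2d(const double* a, const double* b, const double* c,
                       int i0, int i1) {
  return (b[i0] - a[i0]) * (c[i1] - a[i1]) - (b[i1] - a[i1]) * (c[i0] - a[i0]);
}

static bool coplanar_tri_tri(const double* n,
                             const double* p1, const double* q1, const double* r1,
                             const double* p2, const double* q2, const double* r2,
                             double eps) {
  // project to dominant axis plane
  double ax = std::fabs(n[0]), ay = std::fabs(n[1]), az = std::fabs(n[2]);
  int i0, i1;
  if (ax >= ay && ax >= az) { i0 = 1; i1 = 2; }
  else if (ay >= az) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  const double* T1[3] = { p1, q1, r1 };
  const double* T2[3] = { p2, q2, r2 };
  // separating axis test on the 6 edges, 2D
  for (int t = 0; t < 2; t++) {
    const double** A = t == 0 ? T1 : T2;
    const double** B = t == 0 ? T2 : T1;
    for (int e = 0; e < 3; e++) {
      const double* a = A[e];
      const double* b = A[(e + 1) % 3];
      double minA = R_PosInf, maxA = R_NegInf, minB = R_PosInf, maxB = R_NegInf;
      for (int k = 0; k < 3; k++) {
        double va = -(A[k][i1] - a[i1]) * (b[i0] - a[i0]) + (A[k][i0] - a[i0]) * (b[i1] - a[i1]);
        double vb = -(B[k][i1] - a[i1]) * (b[i0] - a[i0]) + (B[k][i0] - a[i0]) * (b[i1] - a[i1]);
        // projection onto edge-normal axis
        va = (A[k][i0] - a[i0]) * (a[i1] - b[i1]) + (A[k][i1] - a[i1]) * (b[i0] - a[i0]);
        vb = (B[k][i0] - a[i0]) * (a[i1] - b[i1]) + (B[k][i1] - a[i1]) * (b[i0] - a[i0]);
        minA = std::min(minA, va); maxA = std::max(maxA, va);
        minB = std::min(minB, vb); maxB = std::max(maxB, vb);
      }
      if (maxB < minA - eps || minB > maxA + eps) return false;
    }
  }
  return true;
}

static bool tri_tri_overlap(const double* p1, const double* q1, const double* r1,
                            const double* p2, const double* q2, const double* r2,
                            double eps) {
  double e1[3], e2[3], n1[3];
  sub3(q1, p1, e1); sub3(r1, p1, e2); cross3(e1, e2, n1);
  double dp2 = dot3(n1, p2) - dot3(n1, p1);
  double dq2 = dot3(n1, q2) - dot3(n1, p1);
  double dr2 = dot3(n1, r2) - dot3(n1, p1);
  double s1 = norm3(n1) * eps;
  if ((dp2 > s1 && dq2 > s1 && dr2 > s1) || (dp2 < -s1 && dq2 < -s1 && dr2 < -s1))
    return false;
  double e3[3], e4[3], n2[3];
  sub3(q2, p2, e3); sub3(r2, p2, e4); cross3(e3, e4, n2);
  double dp1 = dot3(n2, p1) - dot3(n2, p2);
  double dq1 = dot3(n2, q1) - dot3(n2, p2);
  double dr1 = dot3(n2, r1) - dot3(n2, p2);
  double s2 = norm3(n2) * eps;
  if ((dp1 > s2 && dq1 > s2 && dr1 > s2) || (dp1 < -s2 && dq1 < -s2 && dr1 < -s2))
    return false;
  if (std::fabs(dp2) <= s1 && std::fabs(dq2) <= s1 && std::fabs(dr2) <= s1)
    return coplanar_tri_tri(n1, p1, q1, r1, p2, q2, r2, eps);
  // interval overlap along the plane-intersection line
  double d[3]; cross3(n1, n2, d);
  int axis = 0;
  if (std::fabs(d[1]) > std::fabs(d[axis])) axis = 1;
  if (std::fabs(d[2]) > std::fabs(d[axis])) axis = 2;
  auto interval = [&](const double* a, const double* b, const double* c,
                      double da, double db, double dc, double* lo, double* hi) -> bool {
    // project on axis; compute intersection segment parameter range
    double pa = a[axis], pb = b[axis], pc = c[axis];
    double t[2]; int cnt = 0;
    const double* P[3] = { a, b, c };
    double D[3] = { da, db, dc };
    double PP[3] = { pa, pb, pc };
    for (int e = 0; e < 3; e++) {
      int u = e, v = (e + 1) % 3;
      if ((D[u] > 0 && D[v] < 0) || (D[u] < 0 && D[v] > 0) ||
          (std::fabs(D[u]) <= 0 && std::fabs(D[v]) > 0)) {
        double tt = D[u] / (D[u] - D[v]);
        if (cnt < 2) t[cnt++] = PP[u] + tt * (PP[v] - PP[u]);
      } else if (std::fabs(D[u]) == 0 && cnt < 2) {
        t[cnt++] = PP[u];
      }
      (void)P;
    }
    if (cnt < 2) return false;
    *lo = std::min(t[0], t[1]); *hi = std::max(t[0], t[1]);
    return true;
  };
  double lo1, hi1, lo2, hi2;
  if (!interval(p1, q1, r1, dp1, dq1, dr1, &lo1, &hi1)) return false;
  if (!interval(p2, q2, r2, dp2, dq2, dr2, &lo2, &hi2)) return false;
  double tol = eps * (std::fabs(hi1 - lo1) + std::fabs(hi2 - lo2) + 1.0);
  return !(hi1 < lo2 + tol || hi2 < lo1 + tol);
}

// [[Rcpp::export]]
List cpp_self_intersections(NumericMatrix V, IntegerMatrix Fm, int max_report) {
  const int nf = Fm.nrow();
  if (nf == 0)
    return List::create(_["count"] = 0, _["pairs"] = IntegerMatrix(0, 2));
  // bounding boxes + hash grid
  std::vector<double> bmin(nf * 3), bmax(nf * 3);
  double gmin[3] = { R_PosInf, R_PosInf, R_PosInf };
  double gmax[3] = { R_NegInf, R_NegInf, R_NegInf };
  double mean_size = 0;
  for (int i = 0; i < nf; i++) {
    for (int c = 0; c < 3; c++) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int k = 0; k < 3; k++) {
        double v = V(Fm(i, k), c);
        lo = std::min(lo, v); hi = std::max(hi, v);
      }
      bmin[3 * i + c] = lo; bmax[3 * i + c] = hi;
      gmin[c] = std::min(gmin[c], lo); gmax[c] = std::max(gmax[c], hi);
      mean_size += hi - lo;
    }
  }
  mean_size /= (3.0 * nf);
  double cell = std::max(mean_size * 2.0, 1e-9);
  double diag = 0;
  for (int c = 0; c < 3; c++) diag += (gmax[c] - gmin[c]) * (gmax[c] - gmin[c]);
  diag = std::sqrt(diag);
  double eps = 1e-10 * std::max(diag, 1e-9);

  std::unordered_map<uint64_t, std::vector<int>> grid;
  // cell indices are non-negative (coords >= gmin), so this packing is exact
  auto cellkey = [&](int ix, int iy, int iz) {
    return ((uint64_t)ix << 42) | ((uint64_t)iy << 21) | (uint64_t)iz;
  };
  for (int i = 0; i < nf; i++) {
    int x0 = (int)std::floor((bmin[3*i] - gmin[0]) / cell);
    int x1 = (int)std::floor((bmax[3*i] - gmin[0]) / cell);
    int y0 = (int)std::floor((bmin[3*i+1] - gmin[1]) / cell);
    int y1 = (int)std::floor((bmax[3*i+1] - gmin[1]) / cell);
    int z0 = (int)std::floor((bmin[3*i+2] - gmin[2]) / cell);
    int z1 = (int)std::floor((bmax[3*i+2] - gmin[2]) / cell);
    for (int x = x0; x <= x1; x++)
      for (int y = y0; y <= y1; y++)
        for (int z = z0; z <= z1; z++)
          grid[cellkey(x, y, z)].push_back(i);
  }
  long count = 0;
  std::vector<std::pair<int,int>> pairs;
  long iter = 0;
  for (auto it = grid.begin(); it != grid.end(); ++it) {
    const std::vector<int>& fs = it->second;
    for (size_t a = 0; a < fs.size(); a++) {
      for (size_t b = a + 1; b < fs.size(); b++) {
        int i = std::min(fs[a], fs[b]), j = std::max(fs[a], fs[b]);
        // bbox reject
        bool rej = false;
        for (int c = 0; c < 3; c++)
          if (bmin[3*i+c] > bmax[3*j+c] + eps || bmin[3*j+c] > bmax[3*i+c] + eps) rej = true;
        if (rej) continue;
        // dedupe across cells without a global set: handle the pair only in
        // the cell containing the min corner of the bbox overlap
        int ox = (int)std::floor((std::max(bmin[3*i], bmin[3*j]) - gmin[0]) / cell);
        int oy = (int)std::floor((std::max(bmin[3*i+1], bmin[3*j+1]) - gmin[1]) / cell);
        int oz = (int)std::floor((std::max(bmin[3*i+2], bmin[3*j+2]) - gmin[2]) / cell);
        if (cellkey(ox, oy, oz) != it->first) continue;
        // skip shared vertices
        bool share = false;
        for (int u = 0; u < 3 && !share; u++)
          for (int v = 0; v < 3; v++)
            if (Fm(i, u) == Fm(j, v)) { share = true; break; }
        if (share) continue;
        double t1[3][3], t2[3][3];
        for (int c = 0; c < 3; c++)
          for (int d = 0; d < 3; d++) {
            t1[c][d] = V(Fm(i, c), d);
            t2[c][d] = V(Fm(j, c), d);
          }
        // skip degenerate triangles (reported separately as zero-area)
        double e1[3], e2[3], nn[3];
        sub3(t1[1], t1[0], e1); sub3(t1[2], t1[0], e2); cross3(e1, e2, nn);
        if (norm3(nn) < 1e-20) continue;
        sub3(t2[1], t2[0], e1); sub3(t2[2], t2[0], e2); cross3(e1, e2, nn);
        if (norm3(nn) < 1e-20) continue;
        if (tri_tri_overlap(t1[0], t1[1], t1[2], t2[0], t2[1], t2[2], eps)) {
          count++;
          if ((int)pairs.size() < max_report) pairs.push_back(std::make_pair(i, j));
        }
        if (++iter % 100000 == 0) Rcpp::checkUserInterrupt();
      }
    }
  }
  IntegerMatrix P((int)pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); k++) {
    P((int)k, 0) = pairs[k].first; P((int)k, 1) = pairs[k].second;
  }
  return List::create(_["count"] = (double)count, _["pairs"] = P);
}

// -------------------------------------------------- point-to-mesh proximity

// [[Rcpp::export]]
List cpp_point_mesh_nearest(NumericMatrix P, NumericMatrix V, IntegerMatrix Fm) {
  const int np = P.nrow(), nf = Fm.nrow();
  NumericMatrix out(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  for (int p = 0; p < np; p++) {
    double pt[3] = { P(p, 0), P(p, 1), P(p, 2) };
    double best = R_PosInf, bq[3] = {0, 0, 0};
    int bf = -1;
    for (int f = 0; f < nf; f++) {
      double a[3] = { V(Fm(f,0),0), V(Fm(f,0),1), V(Fm(f,0),2) };
      double b[3] = { V(Fm(f,1),0), V(Fm(f,1),1), V(Fm(f,1),2) };
      double c[3] = { V(Fm(f,2),0), V(Fm(f,2),1), V(Fm(f,2),2) };
      double q[3];
      closest_on_tri(pt, a, b, c, q);
      double d[3]; sub3(pt, q, d);
      double dd = dot3(d, d);
      if (dd < best) { best = dd; bq[0]=q[0]; bq[1]=q[1]; bq[2]=q[2]; bf = f; }
    }
    out(p, 0) = bq[0]; out(p, 1) = bq[1]; out(p, 2) = bq[2];
    dist[p] = std::sqrt(best);
    face[p] = bf;
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["points"] = out, _["dist"] = dist, _["face"] = face);
}

// -------------------------------------------------------- ray-mesh casting
// Moller-Trumbore; returns nearest hit in [tmin, tmax] and total hit count.

// [[Rcpp::export]]
List cpp_ray_mesh(NumericMatrix orig, NumericMatrix dir, NumericMatrix V,
                  IntegerMatrix Fm, double tmin, double tmax) {
  const int nr = orig.nrow(), nf = Fm.nrow();
  NumericVector thit(nr, NA_REAL);
  IntegerVector fhit(nr, -1), nhits(nr, 0);
  for (int r = 0; r < nr; r++) {
    double o[3] = { orig(r,0), orig(r,1), orig(r,2) };
    double d[3] = { dir(r,0), dir(r,1), dir(r,2) };
    double best = R_PosInf;
    int bestf = -1, cnt = 0;
    for (int f = 0; f < nf; f++) {
      double a[3] = { V(Fm(f,0),0), V(Fm(f,0),1), V(Fm(f,0),2) };
      double e1[3] = { V(Fm(f,1),0)-a[0], V(Fm(f,1),1)-a[1], V(Fm(f,1),2)-a[2] };
      double e2[3] = { V(Fm(f,2),0)-a[0], V(Fm(f,2),1)-a[1], V(Fm(f,2),2)-a[2] };
      double pv[3]; cross3(d, e2, pv);
      double det = dot3(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double tv[3] = { o[0]-a[0], o[1]-a[1], o[2]-a[2] };
      double u = dot3(tv, pv) * inv;
      if (u < -1e-12 || u > 1 + 1e-12) continue;
      double qv[3]; cross3(tv, e1, qv);
      double v = dot3(d, qv) * inv;
      if (v < -1e-12 || u + v > 1 + 1e-12) continue;
      double t = dot3(e2, qv) * inv;
      if (t < tmin || t > tmax) continue;
      cnt++;
      if (t < best) { best = t; bestf = f; }
    }
    if (bestf >= 0) { thit[r] = best; fhit[r] = bestf; }
    nhits[r] = cnt;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = thit, _["face"] = fhit, _["n_hits"] = nhits);
}

// ------------------------------------------------------------ vertex welding
// single-linkage clusters of vertices within `tol`; returns 0-based cluster id

// [[Rcpp::export]]
IntegerVector cpp_weld_clusters(NumericMatrix V, double tol) {
  const int n = V.nrow();
  if (tol == 0) {
    // exact duplicates: hash the coordinate bit patterns
    std::unordered_map<std::string, int> seen;
    seen.reserve(n * 2);
    IntegerVector out(n);
    int next = 0;
    std::string key(24, '\0');
    for (int i = 0; i < n; i++) {
      double c[3] = { V(i, 0), V(i, 1), V(i, 2) };
      std::memcpy(&key[0], c, 24);
      auto it = seen.find(key);
      if (it == seen.end()) { seen.emplace(key, next); out[i] = next; next++; }
      else out[i] = it->second;
    }
    return out;
  }
  std::vector<int> parent(n);
  for (int i = 0; i < n; i++) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  double cell = tol > 0 ? tol : 1.0;
  std::unordered_map<uint64_t, std::vector<int>> grid;
  auto key = [&](long ix, long iy, long iz) {
    return ((uint64_t)(uint32_t)(int)ix << 42) ^ ((uint64_t)(uint32_t)(int)iy << 21) ^
           (uint64_t)(uint32_t)(int)iz;
  };
  std::vector<long> gx(n), gy(n), gz(n);
  for (int i = 0; i < n; i++) {
    gx[i] = (long)std::floor(V(i, 0) / cell);
    gy[i] = (long)std::floor(V(i, 1) / cell);
    gz[i] = (long)std::floor(V(i, 2) / cell);
    grid[key(gx[i], gy[i], gz[i])].push_back(i);
  }
  double tol2 = tol * tol;
  for (int i = 0; i < n; i++) {
    for (int dx = -1; dx <= 1; dx++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dz = -1; dz <= 1; dz++) {
          auto it = grid.find(key(gx[i] + dx, gy[i] + dy, gz[i] + dz));
          if (it == grid.end()) continue;
          for (size_t s = 0; s < it->second.size(); s++) {
            int j = it->second[s];
            if (j <= i) continue;
            double d0 = V(i,0) - V(j,0), d1 = V(i,1) - V(j,1), d2 = V(i,2) - V(j,2);
            double dd = d0 * d0 + d1 * d1 + d2 * d2;
            if ((tol == 0 && dd == 0) || (tol > 0 && dd <= tol2)) unite(i, j);
          }
        }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector out(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; i++) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = next; out[i] = next; next++; }
    else out[i] = it->second;
  }
  return out;
}

// -------------------------------------- winding-number re-voxelization field
// Occupancy by signed z-column crossings (generalized winding along +z), then
// a narrow-band unsigned distance to the input soup gives a signed field
// (positive inside) suitable for marching tetrahedra.

// [[Rcpp::export]]
NumericVector cpp_resolidify_field(NumericMatrix V, IntegerMatrix Fm,
                                   IntegerVector dims, NumericVector origin,
                                   double pitch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nf = Fm.nrow();
  // tiny deterministic shear to dodge edge-exact column hits
  const double ex = 1e-7 * pitch, ey = 2.3e-7 * pitch;
  std::vector<std::vector<std::pair<double, int>>> cols((size_t)nx * ny);
  for (int f = 0; f < nf; f++) {
    double a[3] = { V(Fm(f,0),0), V(Fm(f,0),1), V(Fm(f,0),2) };
    double b[3] = { V(Fm(f,1),0), V(Fm(f,1),1), V(Fm(f,1),2) };
    double c[3] = { V(Fm(f,2),0), V(Fm(f,2),1), V(Fm(f,2),2) };
    double e1[3], e2[3], n[3];
    sub3(b, a, e1); sub3(c, a, e2); cross3(e1, e2, n);
    if (std::fabs(n[2]) < 1e-18) continue;          // vertical face: no z crossing
    int sgn = n[2] < 0 ? 1 : -1;                    // entering solid when nz < 0
    double xmin = std::min(a[0], std::min(b[0], c[0]));
    double xmax = std::max(a[0], std::max(b[0], c[0]));
    double ymin = std::min(a[1], std::min(b[1], c[1]));
    double ymax = std::max(a[1], std::max(b[1], c[1]));
    int i0 = std::max(0, (int)std::ceil((xmin - ox) / pitch - 1e-12));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - ox) / pitch + 1e-12));
    int j0 = std::max(0, (int)std::ceil((ymin - oy) / pitch - 1e-12));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - oy) / pitch + 1e-12));
    for (int j = j0; j <= j1; j++) {
      double py = oy + pitch * j + ey;
      for (int i = i0; i <= i1; i++) {
        double px = ox + pitch * i + ex;
        // barycentric in xy
        double d00 = (b[0]-a[0]) * (c[1]-a[1]) - (c[0]-a[0]) * (b[1]-a[1]);
        if (std::fabs(d00) < 1e-18) continue;
        double l1 = ((px-a[0]) * (c[1]-a[1]) - (c[0]-a[0]) * (py-a[1])) / d00;
        double l2 = ((b[0]-a[0]) * (py-a[1]) - (px-a[0]) * (b[1]-a[1])) / d00;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        double zc = a[2] + l1 * (b[2]-a[2]) + l2 * (c[2]-a[2]);
        cols[(size_t)i + (size_t)nx * j].push_back(std::make_pair(zc, sgn));
      }
    }
    if (f % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector field((R_xlen_t)nx * ny * nz);
  std::vector<signed char> occ((size_t)nx * ny * nz, 0);
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) {
      std::vector<std::pair<double, int>>& cr = cols[(size_t)i + (size_t)nx * j];
      std::sort(cr.begin(), cr.end());
      size_t ci = 0;
      int wind = 0;
      for (int k = 0; k < nz; k++) {
        double zc = oz + pitch * k;
        while (ci < cr.size() && cr[ci].first < zc) { wind += cr[ci].second; ci++; }
        occ[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = wind > 0 ? 1 : 0;
      }
    }
  }
  // triangle buckets for band distance
  double cell = 2.0 * pitch;
  std::unordered_map<uint64_t, std::vector<int>> grid;
  auto key = [&](int ix, int iy, int iz) {
    return ((uint64_t)(uint32_t)ix << 42) ^ ((uint64_t)(uint32_t)iy << 21) ^ (uint64_t)(uint32_t)iz;
  };
  for (int f = 0; f < nf; f++) {
    double lo[3] = { R_PosInf, R_PosInf, R_PosInf }, hi[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int k = 0; k < 3; k++)
      for (int c = 0; c < 3; c++) {
        double v = V(Fm(f, k), c);
        lo[c] = std::min(lo[c], v); hi[c] = std::max(hi[c], v);
      }
    int x0 = (int)std::floor((lo[0] - ox) / cell), x1 = (int)std::floor((hi[0] - ox) / cell);
    int y0 = (int)std::floor((lo[1] - oy) / cell), y1 = (int)std::floor((hi[1] - oy) / cell);
    int z0 = (int)std::floor((lo[2] - oz) / cell), z1 = (int)std::floor((hi[2] - oz) / cell);
    for (int x = x0; x <= x1; x++)
      for (int y = y0; y <= y1; y++)
        for (int z = z0; z <= z1; z++)
          grid[key(x, y, z)].push_back(f);
  }
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        size_t idx = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        signed char o = occ[idx];
        // band = voxel with any 6-neighbour of opposite occupancy
        bool band = false;
        if (i > 0 && occ[idx - 1] != o) band = true;
        else if (i + 1 < nx && occ[idx + 1] != o) band = true;
        else if (j > 0 && occ[idx - nx] != o) band = true;
        else if (j + 1 < ny && occ[idx + nx] != o) band = true;
        else if (k > 0 && occ[idx - (size_t)nx * ny] != o) band = true;
        else if (k + 1 < nz && occ[idx + (size_t)nx * ny] != o) band = true;
        if (!band) {
          field[idx] = o ? pitch : -pitch;
          continue;
        }
        double p[3] = { ox + pitch * i, oy + pitch * j, oz + pitch * k };
        int cx = (int)std::floor((p[0] - ox) / cell);
        int cy = (int)std::floor((p[1] - oy) / cell);
        int cz = (int)std::floor((p[2] - oz) / cell);
        double best = 4.0 * pitch * pitch;
        for (int dx = -1; dx <= 1; dx++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dz = -1; dz <= 1; dz++) {
              auto it = grid.find(key(cx + dx, cy + dy, cz + dz));
              if (it == grid.end()) continue;
              for (size_t s = 0; s < it->second.size(); s++) {
                int f = it->second[s];
                double a[3] = { V(Fm(f,0),0), V(Fm(f,0),1), V(Fm(f,0),2) };
                double b[3] = { V(Fm(f,1),0), V(Fm(f,1),1), V(Fm(f,1),2) };
                double c[3] = { V(Fm(f,2),0), V(Fm(f,2),1), V(Fm(f,2),2) };
                double q[3];
                closest_on_tri(p, a, b, c, q);
                double d[3]; sub3(p, q, d);
                double dd = dot3(d, d);
                if (dd < best) best = dd;
              }
            }
        double dist = std::sqrt(best);
        field[idx] = o ? dist : -dist;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return field;
}
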