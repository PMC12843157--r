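#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// label codes shared with R side: 0 = EMPTY, 1 = INTERIOR/occupied, 2 = SHELL
static const unsigned char L_EMPTY = 0;
static const unsigned char L_INTERIOR = 1;
static const unsigned char L_SHELL = 2;

static inline R_xlen_t vox(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
}

// Half-open voxel membership [lo, hi) with a small guard so coordinates that
// are exact multiples of the voxel size (nozzle planes, sampled path vertices)
// index deterministically even after large exact translations.
static inline int vindex(double p, double org, double vs) {
  return (int)std::floor((p - org) / vs + 1e-6);
}

// [[Rcpp::export]]
RawVector cpp_stamp_points(NumericMatrix pts, NumericVector origin, double vs,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  RawVector occ((R_xlen_t)nx * ny * nz);
  for (int i = 0; i < pts.nrow(); ++i) {
    int ix = vindex(pts(i, 0), origin[0], vs);
    int iy = vindex(pts(i, 1), origin[1], vs);
    int iz = vindex(pts(i, 2), origin[2], vs);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      stop("point %d falls outside the voxel grid", i + 1);
    occ[vox(ix, iy, iz, nx, ny)] = L_INTERIOR;
  }
  return occ;
}

// One separable pass of a Chebyshev (cube) max/min filter along one axis.
static void axis_filter(std::vector<unsigned char> &a, int nx, int ny, int nz,
                        int axis, int r, bool dilate) {
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int la = n[axis];
  R_xlen_t sa = stride[axis];
  int b0 = axis == 0 ? 1 : 0, b1 = axis == 2 ? 1 : 2;
  std::vector<unsigned char> line(la);
  for (int j = 0; j < n[b1]; ++j) {
    for (int i = 0; i < n[b0]; ++i) {
      R_xlen_t base = (R_xlen_t)i * stride[b0] + (R_xlen_t)j * stride[b1];
      for (int k = 0; k < la; ++k) line[k] = a[base + (R_xlen_t)k * sa];
      for (int k = 0; k < la; ++k) {
        int lo = std::max(0, k - r), hi = std::min(la - 1, k + r);
        unsigned char v = dilate ? 0 : 1;
        if (!dilate && (k - r < 0 || k + r > la - 1)) v = 0; // outside grid is EMPTY
        else {
          for (int m = lo; m <= hi; ++m) {
            if (dilate) { if (line[m]) { v = 1; break; } }
            else        { if (!line[m]) { v = 0; break; } }
          }
        }
        a[base + (R_xlen_t)k * sa] = v;
      }
    }
  }
}

// [[Rcpp::export]]
RawVector cpp_binary_close(RawVector occ, IntegerVector dims, int r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<unsigned char> a(occ.size());
  for (R_xlen_t i = 0; i < occ.size(); ++i) a[i] = occ[i] ? 1 : 0;
  if (r > 0) {
    for (int ax = 0; ax < 3; ++ax) axis_filter(a, nx, ny, nz, ax, r, true);
    for (int ax = 0; ax < 3; ++ax) axis_filter(a, nx, ny, nz, ax, r, false);
  }
  RawVector out(occ.size());
  for (R_xlen_t i = 0; i < occ.size(); ++i)
    out[i] = (a[i] || occ[i]) ? L_INTERIOR : L_EMPTY; // closing is extensive
  return out;
}

// [[Rcpp::export]]
RawVector cpp_classify(RawVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> ext(n, 0);
  std::queue<R_xlen_t> q;
  // seed the 6-connected exterior flood fill from every boundary voxel
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1)
          continue;
        R_xlen_t i = vox(x, y, z, nx, ny);
        if (!occ[i] && !ext[i]) { ext[i] = 1; q.push(i); }
      }
  const int dx6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    R_xlen_t i = q.front(); q.pop();
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx6[k], yy = y + dy6[k], zz = z + dz6[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      R_xlen_t j = vox(xx, yy, zz, nx, ny);
      if (!occ[j] && !ext[j]) { ext[j] = 1; q.push(j); }
    }
  }
  RawVector lab(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = vox(x, y, z, nx, ny);
        if (!occ[i]) { lab[i] = L_EMPTY; continue; }
        bool shell = false;
        for (int dz = -1; dz <= 1 && !shell; ++dz)
          for (int dy = -1; dy <= 1 && !shell; ++dy)
            for (int dx = -1; dx <= 1 && !shell; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
                shell = true; // grid border counts as exterior
                continue;
              }
              if (ext[vox(xx, yy, zz, nx, ny)]) shell = true;
            }
        lab[i] = shell ? L_SHELL : L_INTERIOR;
      }
  return lab;
}

// 26-connected components of occupied voxels; labels 1..k, 0 for empty.
// [[Rcpp::export]]
IntegerVector cpp_components(RawVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(n);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!occ[s] || comp[s]) continue;
    comp[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int z = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t j = vox(xx, yy, zz, nx, ny);
            if (occ[j] && !comp[j]) { comp[j] = next; q.push(j); }
          }
    }
  }
  comp.attr("n_components") = next;
  return comp;
}

// For each point, the component label of its voxel, or of the nearest occupied
// voxel within a Chebyshev search radius (spatial-index assignment of corrected
// points that sit just outside the shell).
// [[Rcpp::export]]
IntegerVector cpp_point_component(IntegerVector comp, IntegerVector dims,
                                  NumericVector origin, double vs,
                                  NumericMatrix pts, int maxR) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    int ix = vindex(pts(i, 0), origin[0], vs);
    int iy = vindex(pts(i, 1), origin[1], vs);
    int iz = vindex(pts(i, 2), origin[2], vs);
    int best = 0;
    double bestd2 = R_PosInf;
    for (int r = 0; r <= maxR && best == 0; ++r) {
      for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            int xx = ix + dx, yy = iy + dy, zz = iz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int c = comp[vox(xx, yy, zz, nx, ny)];
            if (!c) continue;
            double cx = origin[0] + (xx + 0.5) * vs;
            double cy = origin[1] + (yy + 0.5) * vs;
            double cz = origin[2] + (zz + 0.5) * vs;
            double d2 = (pts(i, 0) - cx) * (pts(i, 0) - cx) +
                        (pts(i, 1) - cy) * (pts(i, 1) - cy) +
                        (pts(i, 2) - cz) * (pts(i, 2) - cz);
            if (d2 < bestd2) { bestd2 = d2; best = c; }
          }
    }
    out[i] = best;
  }
  return out;
}

// ---- marching tetrahedra on the binary occupancy (iso-level 0.5) ----------
// The voxel-center lattice is decomposed into six tetrahedra per cell around
// the main diagonal; iso-vertices sit at edge midpoints, shared through a map
// so the mesh is watertight by construction.

struct MTState {
  std::unordered_map<uint64_t, int> edgeVertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
};

static void emit_tri(MTState &st, int a, int b, int c,
                     double insx, double insy, double insz) {
  // orient so the normal points away from the inside of the solid
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
  double cx = (st.vx[a] + st.vx[b] + st.vx[c]) / 3.0;
  double cy = (st.vy[a] + st.vy[b] + st.vy[c]) / 3.0;
  double cz = (st.vz[a] + st.vz[b] + st.vz[c]) / 3.0;
  double dot = nxv * (insx - cx) + nyv * (insy - cy) + nzv * (insz - cz);
  if (dot > 0) std::swap(b, c);
  st.f1.push_back(a + 1); st.f2.push_back(b + 1); st.f3.push_back(c + 1);
}

// [[Rcpp::export]]
List cpp_marching_tetra(RawVector occ, IntegerVector dims, NumericVector origin,
                        double vs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // tetrahedra around main diagonal v0-v6 (consistent with face diagonals of
  // neighbouring cells)
  static const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  MTState st;
  // lattice vertex linear index
  auto lid = [&](int x, int y, int z) {
    return (int64_t)z * nx * ny + (int64_t)y * nx + x;
  };
  // cache of lattice coords addressed by lattice id would be huge; instead we
  // compute coordinates on the fly via a second map from id to coord.
  // Simpler: store coordinates indexed by lattice id lazily in hash map.
  std::unordered_map<int64_t, size_t> coordIdx;
  std::vector<double> cx_, cy_, cz_;
  auto coord = [&](int64_t id) -> size_t {
    auto it = coordIdx.find(id);
    if (it != coordIdx.end()) return it->second;
    int z = (int)(id / ((int64_t)nx * ny));
    int rem = (int)(id % ((int64_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    size_t k = cx_.size();
    cx_.push_back(origin[0] + (x + 0.5) * vs);
    cy_.push_back(origin[1] + (y + 0.5) * vs);
    cz_.push_back(origin[2] + (z + 0.5) * vs);
    coordIdx.emplace(id, k);
    return k;
  };
  // local edge-vertex helper working on global lattice ids
  std::unordered_map<uint64_t, int> edgeMap;
  auto evert = [&](int64_t ia, int64_t ib) {
    int64_t a = std::min(ia, ib), b = std::max(ia, ib);
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)(b & 0xffffffff);
    auto it = edgeMap.find(key);
    if (it != edgeMap.end()) return it->second;
    size_t ka = coord(a), kb = coord(b);
    int id = (int)st.vx.size();
    st.vx.push_back(0.5 * (cx_[ka] + cx_[kb]));
    st.vy.push_back(0.5 * (cy_[ka] + cy_[kb]));
    st.vz.push_back(0.5 * (cz_[ka] + cz_[kb]));
    edgeMap.emplace(key, id);
    return id;
  };
  const int corner[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                            {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        unsigned char v[8];
        int64_t id8[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int xx = x + corner[c][0], yy = y + corner[c][1], zz = z + corner[c][2];
          id8[c] = lid(xx, yy, zz);
          v[c] = occ[vox(xx, yy, zz, nx, ny)] ? 1 : 0;
          any = any || v[c]; all = all && v[c];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int tv[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (v[tv[k]]) ins[ni++] = tv[k]; else outs[no++] = tv[k];
          }
          if (ni == 0 || ni == 4) continue;
          // centroid of inside lattice vertices (for orientation)
          double ix = 0, iy = 0, iz = 0;
          for (int k = 0; k < ni; ++k) {
            size_t kk = coord(id8[ins[k]]);
            ix += cx_[kk]; iy += cy_[kk]; iz += cz_[kk];
          }
          ix /= ni; iy /= ni; iz /= ni;
          if (ni == 1) {
            int a = evert(id8[ins[0]], id8[outs[0]]);
            int b = evert(id8[ins[0]], id8[outs[1]]);
            int c = evert(id8[ins[0]], id8[outs[2]]);
            emit_tri(st, a, b, c, ix, iy, iz);
          } else if (ni == 3) {
            int a = evert(id8[ins[0]], id8[outs[0]]);
            int b = evert(id8[ins[1]], id8[outs[0]]);
            int c = evert(id8[ins[2]], id8[outs[0]]);
            emit_tri(st, a, b, c, ix, iy, iz);
          } else { // 2-2: quad m11 m12 m22 m21
            int m11 = evert(id8[ins[0]], id8[outs[0]]);
            int m12 = evert(id8[ins[0]], id8[outs[1]]);
            int m22 = evert(id8[ins[1]], id8[outs[1]]);
            int m21 = evert(id8[ins[1]], id8[outs[0]]);
            emit_tri(st, m11, m12, m22, ix, iy, iz);
            emit_tri(st, m11, m22, m21, ix, iy, iz);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0)=st.vx[i]; V(i,1)=st.vy[i]; V(i,2)=st.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0)=st.f1[i]; F(i,1)=st.f2[i]; F(i,2)=st.f3[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
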