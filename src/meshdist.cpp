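#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
};
static inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(const V3 &a, double s) { return V3(a.x*s, a.y*s, a.z*s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 normalize(const V3 &a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : a;
}

// Closest point on triangle (a,b,c) to p; region code:
// 0 vert a, 1 vert b, 2 vert c, 3 edge ab, 4 edge bc, 5 edge ca, 6 face.
static V3 closest_on_tri(const V3 &p, const V3 &a, const V3 &b, const V3 &c,
                         int &region) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { region = 0; return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { region = 1; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    region = 3; return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { region = 2; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    region = 5; return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    region = 4; return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  region = 6; return a + ab * v + ac * w;
}

struct MeshIndex {
  std::vector<V3> V;
  std::vector<int> F; // 3 per face, 0-based
  std::vector<V3> faceNormal;           // unit
  std::vector<V3> vertexNormal;         // angle-weighted, unit
  std::map<std::pair<int,int>, V3> edgeNormal; // sum of adjacent face normals, unit
};

static void build_index(NumericMatrix Vm, IntegerMatrix Fm, MeshIndex &M) {
  int nv = Vm.nrow(), nf = Fm.nrow();
  M.V.resize(nv);
  for (int i = 0; i < nv; ++i) M.V[i] = V3(Vm(i,0), Vm(i,1), Vm(i,2));
  M.F.resize(3 * nf);
  M.faceNormal.resize(nf);
  M.vertexNormal.assign(nv, V3());
  std::map<std::pair<int,int>, V3> esum;
  for (int f = 0; f < nf; ++f) {
    int i0 = Fm(f,0) - 1, i1 = Fm(f,1) - 1, i2 = Fm(f,2) - 1;
    M.F[3*f] = i0; M.F[3*f+1] = i1; M.F[3*f+2] = i2;
    V3 n = cross(M.V[i1] - M.V[i0], M.V[i2] - M.V[i0]);
    double a2 = norm(n);
    if (a2 <= 1e-14)
      stop("degenerate triangle %d in reference mesh", f + 1);
    M.faceNormal[f] = n * (1.0 / a2);
    // angle weights at each corner
    int idx[3] = {i0, i1, i2};
    for (int k = 0; k < 3; ++k) {
      V3 e1 = M.V[idx[(k+1)%3]] - M.V[idx[k]];
      V3 e2 = M.V[idx[(k+2)%3]] - M.V[idx[k]];
      double cosang = dot(normalize(e1), normalize(e2));
      cosang = std::max(-1.0, std::min(1.0, cosang));
      double ang = std::acos(cosang);
      M.vertexNormal[idx[k]] = M.vertexNormal[idx[k]] + M.faceNormal[f] * ang;
    }
    for (int k = 0; k < 3; ++k) {
      int u = idx[k], v = idx[(k+1)%3];
      std::pair<int,int> key(std::min(u,v), std::max(u,v));
      auto it = esum.find(key);
      if (it == esum.end()) esum[key] = M.faceNormal[f];
      else it->second = it->second + M.faceNormal[f];
    }
  }
  for (int i = 0; i < nv; ++i) M.vertexNormal[i] = normalize(M.vertexNormal[i]);
  for (auto &kv : esum) M.edgeNormal[kv.first] = normalize(kv.second);
}

static V3 pseudo_normal(const MeshIndex &M, int f, int region) {
  int i0 = M.F[3*f], i1 = M.F[3*f+1], i2 = M.F[3*f+2];
  switch (region) {
  case 0: return M.vertexNormal[i0];
  case 1: return M.vertexNormal[i1];
  case 2: return M.vertexNormal[i2];
  case 3: return M.edgeNormal.at({std::min(i0,i1), std::max(i0,i1)});
  case 4: return M.edgeNormal.at({std::min(i1,i2), std::max(i1,i2)});
  case 5: return M.edgeNormal.at({std::min(i0,i2), std::max(i0,i2)});
  default: return M.faceNormal[f];
  }
}

struct Best {
  double d2 = R_PosInf;
  int tri = -1;
  V3 cp;
  int region = 6;
};

static inline void consider(const MeshIndex &M, const V3 &p, int f, Best &b) {
  int region;
  V3 cp = closest_on_tri(p, M.V[M.F[3*f]], M.V[M.F[3*f+1]], M.V[M.F[3*f+2]], region);
  V3 d = p - cp;
  double d2 = dot(d, d);
  if (d2 < b.d2 || (d2 == b.d2 && f < b.tri)) {
    b.d2 = d2; b.tri = f; b.cp = cp; b.region = region;
  }
}

// Uniform grid over triangle bounding boxes.
struct TriGrid {
  double ox, oy, oz, cell;
  int gx, gy, gz;
  std::vector<std::vector<int>> cells;
  int at(int x, int y, int z) const { return (z * gy + y) * gx + x; }
};

static void build_grid(const MeshIndex &M, TriGrid &G) {
  int nf = (int)M.F.size() / 3;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (auto &v : M.V) {
    lo[0] = std::min(lo[0], v.x); hi[0] = std::max(hi[0], v.x);
    lo[1] = std::min(lo[1], v.y); hi[1] = std::max(hi[1], v.y);
    lo[2] = std::min(lo[2], v.z); hi[2] = std::max(hi[2], v.z);
  }
  double ext = std::max(hi[0]-lo[0], std::max(hi[1]-lo[1], hi[2]-lo[2]));
  if (ext <= 0) ext = 1.0;
  double cell = ext / std::max(1.0, std::cbrt((double)nf));
  G.cell = cell;
  G.ox = lo[0] - 0.5 * cell; G.oy = lo[1] - 0.5 * cell; G.oz = lo[2] - 0.5 * cell;
  G.gx = std::max(1, (int)std::ceil((hi[0] - G.ox) / cell) + 1);
  G.gy = std::max(1, (int)std::ceil((hi[1] - G.oy) / cell) + 1);
  G.gz = std::max(1, (int)std::ceil((hi[2] - G.oz) / cell) + 1);
  G.cells.assign((size_t)G.gx * G.gy * G.gz, {});
  for (int f = 0; f < nf; ++f) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int k = 0; k < 3; ++k) {
      const V3 &v = M.V[M.F[3*f+k]];
      double c[3] = {v.x, v.y, v.z};
      for (int a = 0; a < 3; ++a) {
        tlo[a] = std::min(tlo[a], c[a]); thi[a] = std::max(thi[a], c[a]);
      }
    }
    int x0 = (int)((tlo[0] - G.ox) / cell), x1 = (int)((thi[0] - G.ox) / cell);
    int y0 = (int)((tlo[1] - G.oy) / cell), y1 = (int)((thi[1] - G.oy) / cell);
    int z0 = (int)((tlo[2] - G.oz) / cell), z1 = (int)((thi[2] - G.oz) / cell);
    for (int z = std::max(0, z0); z <= std::min(G.gz - 1, z1); ++z)
      for (int y = std::max(0, y0); y <= std::min(G.gy - 1, y1); ++y)
        for (int x = std::max(0, x0); x <= std::min(G.gx - 1, x1); ++x)
          G.cells[G.at(x, y, z)].push_back(f);
  }
}

// method: 0 = exhaustive scan over all triangles (oracle route),
//         1 = uniform-grid spatial index with expanding ring search.
// Both use the identical per-triangle kernel and the identical lowest-index
// tie-break, so their results agree exactly.
// [[Rcpp::export]]
List cpp_mesh_distance(NumericMatrix Vm, IntegerMatrix Fm, NumericMatrix P,
                       int method) {
  MeshIndex M;
  build_index(Vm, Fm, M);
  int nf = Fm.nrow(), np = P.nrow();
  TriGrid G;
  if (method == 1) build_grid(M, G);
  NumericVector dist(np);
  IntegerVector tri(np);
  NumericMatrix CP(np, 3);
  std::vector<int> seen(nf, -1);
  for (int i = 0; i < np; ++i) {
    V3 p(P(i,0), P(i,1), P(i,2));
    Best b;
    if (method == 0) {
      for (int f = 0; f < nf; ++f) consider(M, p, f, b);
    } else {
      int cxi = (int)std::floor((p.x - G.ox) / G.cell);
      int cyi = (int)std::floor((p.y - G.oy) / G.cell);
      int czi = (int)std::floor((p.z - G.oz) / G.cell);
      cxi = std::max(0, std::min(G.gx - 1, cxi));
      cyi = std::max(0, std::min(G.gy - 1, cyi));
      czi = std::max(0, std::min(G.gz - 1, czi));
      int rmax = G.gx + G.gy + G.gz;
      for (int r = 0; r <= rmax; ++r) {
        // conservative lower bound on the distance to any cell in ring r
        double lb = (r - 1) * G.cell;
        if (b.tri >= 0 && lb > 0 && lb * lb > b.d2) break;
        bool any = false;
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx) {
              if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
                continue;
              int x = cxi + dx, y = cyi + dy, z = czi + dz;
              if (x < 0 || y < 0 || z < 0 || x >= G.gx || y >= G.gy || z >= G.gz)
                continue;
              any = true;
              for (int f : G.cells[G.at(x, y, z)]) {
                if (seen[f] == i) continue;
                seen[f] = i;
                consider(M, p, f, b);
              }
            }
        if (!any && b.tri >= 0) break;
      }
    }
    double d = std::sqrt(b.d2);
    double s = 0.0;
    if (d > 0) {
      V3 n = pseudo_normal(M, b.tri, b.region);
      double dp = dot(p - b.cp, n);
      s = dp > 0 ? 1.0 : (dp < 0 ? -1.0 : 1.0);
    }
    dist[i] = s == 0.0 ? 0.0 : s * d;
    tri[i] = b.tri + 1;
    CP(i,0) = b.cp.x; CP(i,1) = b.cp.y; CP(i,2) = b.cp.z;
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri,
                      _["closest"] = CP);
}
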