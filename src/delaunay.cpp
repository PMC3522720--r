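// Incremental (Bowyer-Watson) 3D Delaunay tessellation.
//
// Points are jittered by a tiny deterministic amount to break cospherical
// ties; the caller handles degenerate inputs (< 4 points, rank-deficient
// configurations) with a distance-graph fallback.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct Tet {
  int v[4];
  double cc[3];
  double r2;
  bool alive;
};

// circumsphere of four points; returns false if (near) flat
static bool circumsphere(const std::vector<std::array<double,3>> &P,
                         int a, int b, int c, int d, double cc[3], double &r2) {
  double A[3][3], rhs[3];
  const std::array<double,3> &p0 = P[a];
  const int idx[3] = {b, c, d};
  for (int k = 0; k < 3; ++k) {
    double s = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[k][j] = 2.0 * (P[idx[k]][j] - p0[j]);
      s += P[idx[k]][j] * P[idx[k]][j] - p0[j] * p0[j];
    }
    rhs[k] = s;
  }
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  if (std::fabs(det) < 1e-12) return false;
  double x[3];
  for (int j = 0; j < 3; ++j) {
    double B[3][3];
    for (int r = 0; r < 3; ++r)
      for (int cjj = 0; cjj < 3; ++cjj)
        B[r][cjj] = (cjj == j) ? rhs[r] : A[r][cjj];
    double dj = B[0][0]*(B[1][1]*B[2][2]-B[1][2]*B[2][1])
              - B[0][1]*(B[1][0]*B[2][2]-B[1][2]*B[2][0])
              + B[0][2]*(B[1][0]*B[2][1]-B[1][1]*B[2][0]);
    x[j] = dj / det;
  }
  cc[0] = x[0]; cc[1] = x[1]; cc[2] = x[2];
  double dx = cc[0]-p0[0], dy = cc[1]-p0[1], dz = cc[2]-p0[2];
  r2 = dx*dx + dy*dy + dz*dz;
  return true;
}

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix pts, double jitter = 1e-9) {
  int n = pts.nrow();
  std::vector<std::array<double,3>> P(n + 4);
  // deterministic xorshift jitter, independent of R's RNG state
  uint64_t s = 88172645463325252ULL;
  auto rnd = [&s]() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (double)(s % 1000000ULL) / 1000000.0 - 0.5;
  };
  double lo[3] = {1e300,1e300,1e300}, hi[3] = {-1e300,-1e300,-1e300};
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) {
      P[i][j] = pts(i, j) + jitter * rnd();
      lo[j] = std::min(lo[j], P[i][j]);
      hi[j] = std::max(hi[j], P[i][j]);
    }
  }
  double cx = (lo[0]+hi[0])/2, cy = (lo[1]+hi[1])/2, cz = (lo[2]+hi[2])/2;
  double span = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1.0});
  double R = 1000.0 * span;
  // big regular tetrahedron around the cloud
  P[n]     = {cx + R,  cy + R,  cz + R};
  P[n + 1] = {cx + R,  cy - R,  cz - R};
  P[n + 2] = {cx - R,  cy + R,  cz - R};
  P[n + 3] = {cx - R,  cy - R,  cz + R};

  std::vector<Tet> tets;
  {
    Tet t; t.v[0]=n; t.v[1]=n+1; t.v[2]=n+2; t.v[3]=n+3; t.alive=true;
    if (!circumsphere(P, t.v[0], t.v[1], t.v[2], t.v[3], t.cc, t.r2))
      stop("degenerate super-tetrahedron");
    tets.push_back(t);
  }
  for (int ip = 0; ip < n; ++ip) {
    std::vector<int> bad;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double dx = P[ip][0]-tets[t].cc[0], dy = P[ip][1]-tets[t].cc[1],
             dz = P[ip][2]-tets[t].cc[2];
      if (dx*dx + dy*dy + dz*dz < tets[t].r2 - 1e-12) bad.push_back((int)t);
    }
    // boundary faces = faces of bad tets appearing exactly once
    std::map<std::array<int,3>, int> faceCount;
    static const int F[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
    for (int t : bad) {
      for (int f = 0; f < 4; ++f) {
        std::array<int,3> face = {tets[t].v[F[f][0]], tets[t].v[F[f][1]],
                                  tets[t].v[F[f][2]]};
        std::sort(face.begin(), face.end());
        faceCount[face]++;
      }
      tets[t].alive = false;
    }
    for (auto &fc : faceCount) {
      if (fc.second != 1) continue;
      Tet t;
      t.v[0] = fc.first[0]; t.v[1] = fc.first[1]; t.v[2] = fc.first[2];
      t.v[3] = ip; t.alive = true;
      if (!circumsphere(P, t.v[0], t.v[1], t.v[2], t.v[3], t.cc, t.r2)) {
        // flat sliver: mark so it is always re-opened
        t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
        t.r2 = 1e300;
      }
      tets.push_back(t);
    }
  }
  std::map<std::pair<int,int>, bool> edges;
  for (const Tet &t : tets) {
    if (!t.alive) continue;
    bool real = t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n;
    if (!real) continue;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        int u = std::min(t.v[a], t.v[b]), v = std::max(t.v[a], t.v[b]);
        edges[std::make_pair(u, v)] = true;
      }
  }
  IntegerMatrix out(edges.size(), 2);
  int k = 0;
  for (auto &e : edges) {
    out(k, 0) = e.first.first + 1;
    out(k, 1) = e.first.second + 1;
    ++k;
  }
  return out;
}
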