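#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Incremental quickhull in 3D. Returns triangular faces with outward
// orientation (counter-clockwise seen from outside). Used both for scalp
// meshing and, via the paraboloid lifting, for 2D Delaunay triangulation.

namespace {

struct QFace {
  int a, b, c;
  double n[3];   // unit outward normal
  double off;    // n . x = off for points x on the face plane
  std::vector<int> pts;  // outside point set
  bool alive;
};

inline void vsub(const double* u, const double* v, double* out) {
  out[0] = u[0] - v[0]; out[1] = u[1] - v[1]; out[2] = u[2] - v[2];
}
inline void vcross(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}
inline double vdot(const double* u, const double* v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}
inline double vnorm(const double* u) { return std::sqrt(vdot(u, u)); }

struct Hull {
  const double* X;  // n x 3, column major (R matrix)
  int n;
  double eps;
  std::vector<QFace> faces;
  double interior[3];

  void getp(int i, double* out) const {
    out[0] = X[i]; out[1] = X[i + n]; out[2] = X[i + 2 * n];
  }

  // Signed distance of point i above face f's plane.
  double dist(const QFace& f, int i) const {
    double p[3]; getp(i, p);
    return vdot(f.n, p) - f.off;
  }

  bool make_face(int a, int b, int c, QFace& f) const {
    double pa[3], pb[3], pc[3], e1[3], e2[3], nn[3];
    getp(a, pa); getp(b, pb); getp(c, pc);
    vsub(pb, pa, e1); vsub(pc, pa, e2);
    vcross(e1, e2, nn);
    double L = vnorm(nn);
    if (L < 1e-300) return false;
    nn[0] /= L; nn[1] /= L; nn[2] /= L;
    double off = vdot(nn, pa);
    // orient outward w.r.t. interior point
    if (vdot(nn, interior) - off > 0) {
      std::swap(b, c);
      nn[0] = -nn[0]; nn[1] = -nn[1]; nn[2] = -nn[2];
      off = -off;
    }
    f.a = a; f.b = b; f.c = c;
    f.n[0] = nn[0]; f.n[1] = nn[1]; f.n[2] = nn[2];
    f.off = off;
    f.alive = true;
    f.pts.clear();
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".qhull3d")]]
List qhull3d(NumericMatrix points) {
  int n = points.nrow();
  if (points.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("need at least 4 points for a 3D hull");

  Hull H;
  H.X = REAL(points);
  H.n = n;

  // bounding box scale for tolerances
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = H.X[i + d * n];
      if (!R_finite(v)) stop("non-finite coordinate in point set");
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) stop("degenerate point set: all points coincide");
  H.eps = 1e-10 * diag;
  double degtol = 1e-8 * diag;

  // --- initial simplex -------------------------------------------------
  // extreme points along each axis
  int ext[6];
  for (int d = 0; d < 3; ++d) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (H.X[i + d * n] < H.X[imin + d * n]) imin = i;
      if (H.X[i + d * n] > H.X[imax + d * n]) imax = i;
    }
    ext[2 * d] = imin; ext[2 * d + 1] = imax;
  }
  // farthest pair among extremes
  int i0 = ext[0], i1 = ext[1];
  double best = -1;
  for (int u = 0; u < 6; ++u) {
    for (int v = u + 1; v < 6; ++v) {
      double pu[3], pv[3], dif[3];
      H.getp(ext[u], pu); H.getp(ext[v], pv); vsub(pu, pv, dif);
      double d2 = vdot(dif, dif);
      if (d2 > best) { best = d2; i0 = ext[u]; i1 = ext[v]; }
    }
  }
  if (std::sqrt(best) < degtol) stop("degenerate point set: all points coincide");

  // farthest point from the line i0-i1
  double p0[3], p1[3], dirv[3];
  H.getp(i0, p0); H.getp(i1, p1); vsub(p1, p0, dirv);
  double dl = vnorm(dirv);
  dirv[0] /= dl; dirv[1] /= dl; dirv[2] /= dl;
  int i2 = -1; best = degtol;
  for (int i = 0; i < n; ++i) {
    double p[3], w[3], cr[3];
    H.getp(i, p); vsub(p, p0, w); vcross(w, dirv, cr);
    double d = vnorm(cr);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set: points are collinear");

  // farthest point from the plane i0-i1-i2
  double p2[3], e1[3], e2[3], nn[3];
  H.getp(i2, p2); vsub(p1, p0, e1); vsub(p2, p0, e2); vcross(e1, e2, nn);
  double L = vnorm(nn);
  nn[0] /= L; nn[1] /= L; nn[2] /= L;
  double off0 = vdot(nn, p0);
  int i3 = -1; best = degtol;
  for (int i = 0; i < n; ++i) {
    double p[3]; H.getp(i, p);
    double d = std::fabs(vdot(nn, p) - off0);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set: points are coplanar");

  // interior reference point = centroid of initial simplex
  {
    double p3[3]; H.getp(i3, p3);
    for (int d = 0; d < 3; ++d)
      H.interior[d] = (p0[d] + p1[d] + p2[d] + p3[d]) / 4.0;
  }

  int tet[4] = { i0, i1, i2, i3 };
  int tris[4][3] = { {0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3} };
  for (int k = 0; k < 4; ++k) {
    QFace f;
    if (!H.make_face(tet[tris[k][0]], tet[tris[k][1]], tet[tris[k][2]], f))
      stop("degenerate initial simplex");
    H.faces.push_back(f);
  }

  // assign points to outside sets
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t k = 0; k < H.faces.size(); ++k) {
      if (H.dist(H.faces[k], i) > H.eps) { H.faces[k].pts.push_back(i); break; }
    }
  }

  // --- main loop -------------------------------------------------------
  std::vector<int> stack;
  for (size_t k = 0; k < H.faces.size(); ++k)
    if (!H.faces[k].pts.empty()) stack.push_back((int)k);

  while (!stack.empty()) {
    int fi = stack.back(); stack.pop_back();
    QFace& f = H.faces[fi];
    if (!f.alive || f.pts.empty()) continue;

    // farthest outside point of this face
    int pbest = f.pts[0]; double dbest = H.dist(f, f.pts[0]);
    for (size_t j = 1; j < f.pts.size(); ++j) {
      double d = H.dist(f, f.pts[j]);
      if (d > dbest) { dbest = d; pbest = f.pts[j]; }
    }

    // visible faces (full scan; fine at the sizes used here)
    std::vector<int> visible;
    for (size_t k = 0; k < H.faces.size(); ++k) {
      if (H.faces[k].alive && H.dist(H.faces[k], pbest) > H.eps)
        visible.push_back((int)k);
    }
    if (visible.empty()) { f.pts.clear(); continue; }

    // horizon: directed edges of visible faces whose reverse edge is not
    // held by another visible face
    std::map<std::pair<int, int>, int> edges;
    std::vector<int> orphans;
    for (size_t v = 0; v < visible.size(); ++v) {
      QFace& g = H.faces[visible[v]];
      int ev[3][2] = { {g.a, g.b}, {g.b, g.c}, {g.c, g.a} };
      for (int e = 0; e < 3; ++e)
        edges[std::make_pair(ev[e][0], ev[e][1])] = 1;
      orphans.insert(orphans.end(), g.pts.begin(), g.pts.end());
      g.alive = false;
      g.pts.clear();
    }

    std::vector<int> newfaces;
    for (std::map<std::pair<int, int>, int>::iterator it = edges.begin();
         it != edges.end(); ++it) {
      int u = it->first.first, v = it->first.second;
      if (edges.count(std::make_pair(v, u))) continue;  // internal edge
      QFace nf;
      if (!H.make_face(u, v, pbest, nf)) continue;  // zero-area sliver
      H.faces.push_back(nf);
      newfaces.push_back((int)H.faces.size() - 1);
    }

    // redistribute orphaned outside points
    for (size_t j = 0; j < orphans.size(); ++j) {
      int i = orphans[j];
      if (i == pbest) continue;
      for (size_t k = 0; k < newfaces.size(); ++k) {
        QFace& g = H.faces[newfaces[k]];
        if (H.dist(g, i) > H.eps) { g.pts.push_back(i); break; }
      }
    }
    for (size_t k = 0; k < newfaces.size(); ++k)
      if (!H.faces[newfaces[k]].pts.empty()) stack.push_back(newfaces[k]);
  }

  // --- collect ---------------------------------------------------------
  int nf = 0;
  for (size_t k = 0; k < H.faces.size(); ++k) if (H.faces[k].alive) ++nf;
  IntegerMatrix faces(nf, 3);
  int r = 0;
  for (size_t k = 0; k < H.faces.size(); ++k) {
    if (!H.faces[k].alive) continue;
    faces(r, 0) = H.faces[k].a + 1;
    faces(r, 1) = H.faces[k].b + 1;
    faces(r, 2) = H.faces[k].c + 1;
    ++r;
  }
  return List::create(_["faces"] = faces);
}
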