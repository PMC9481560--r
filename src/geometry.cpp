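#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<double> dvec;
typedef std::vector<int> ivec;

// determinant by LU with partial pivoting; M is n*n row-major (copied)
static double det_lu(std::vector<double> M, int n) {
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(M[c * n + c]);
    for (int r = c + 1; r < n; ++r) {
      double a = std::fabs(M[r * n + c]);
      if (a > best) { best = a; piv = r; }
    }
    if (best == 0.0) return 0.0;
    if (piv != c) {
      for (int j = 0; j < n; ++j) std::swap(M[piv * n + j], M[c * n + j]);
      det = -det;
    }
    det *= M[c * n + c];
    for (int r = c + 1; r < n; ++r) {
      double f = M[r * n + c] / M[c * n + c];
      for (int j = c; j < n; ++j) M[r * n + j] -= f * M[c * n + j];
    }
  }
  return det;
}

// unit normal of the hyperplane through the d facet vertices (generalized
// cross product of the d-1 edge vectors); zero vector if degenerate
static dvec facet_normal(const NumericMatrix& P, const ivec& verts) {
  int d = P.ncol();
  std::vector<double> E((d - 1) * d);
  for (int i = 1; i < d; ++i)
    for (int j = 0; j < d; ++j)
      E[(i - 1) * d + j] = P(verts[i], j) - P(verts[0], j);
  dvec nrm(d);
  std::vector<double> sub((d - 1) * (d - 1));
  for (int j = 0; j < d; ++j) {
    int cc = 0;
    for (int c = 0; c < d; ++c) {
      if (c == j) continue;
      for (int r = 0; r < d - 1; ++r) sub[r * (d - 1) + cc] = E[r * d + c];
      ++cc;
    }
    double dj = det_lu(sub, d - 1);
    nrm[j] = ((j % 2) == 0 ? 1.0 : -1.0) * dj;
  }
  double nn = 0.0;
  for (double v : nrm) nn += v * v;
  nn = std::sqrt(nn);
  if (nn > 0.0) for (double& v : nrm) v /= nn;
  return nrm;
}

struct Facet {
  ivec v;
  dvec n;
  double off;
  bool alive;
};

// Exact convex hull of m points in d dimensions (m >= d+1) by the
// incremental beneath-beyond method. Returns the facet vertex indices
// (1-based, each row one (d-1)-simplex), outward unit normals and offsets,
// or degenerate = TRUE when the points do not span d dimensions.
// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts, double tol = 1e-9) {
  int m = pts.nrow(), d = pts.ncol();
  List degen = List::create(_["degenerate"] = true,
                            _["facets"] = IntegerMatrix(0, d),
                            _["normals"] = NumericMatrix(0, d),
                            _["offsets"] = NumericVector(0));
  if (d < 2) stop("dimension must be at least 2");
  if (m < d + 1) return degen;

  double scale = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < d; ++j) scale = std::max(scale, std::fabs(pts(i, j)));
  if (scale <= 0.0) scale = 1.0;
  double eps = tol * scale;

  // greedy affinely-independent seed simplex via Gram-Schmidt residuals
  ivec init;
  init.push_back(0);
  std::vector<dvec> basis;
  while ((int)init.size() < d + 1) {
    int best = -1;
    double bestres = eps;
    dvec bestdir;
    for (int i = 0; i < m; ++i) {
      if (std::find(init.begin(), init.end(), i) != init.end()) continue;
      dvec v(d);
      for (int j = 0; j < d; ++j) v[j] = pts(i, j) - pts(init[0], j);
      for (size_t b = 0; b < basis.size(); ++b) {
        double dp = 0.0;
        for (int j = 0; j < d; ++j) dp += v[j] * basis[b][j];
        for (int j = 0; j < d; ++j) v[j] -= dp * basis[b][j];
      }
      double res = 0.0;
      for (int j = 0; j < d; ++j) res += v[j] * v[j];
      res = std::sqrt(res);
      if (res > bestres) { bestres = res; best = i; bestdir = v; }
    }
    if (best < 0) return degen;
    for (double& x : bestdir) x /= bestres;
    basis.push_back(bestdir);
    init.push_back(best);
  }

  dvec interior(d, 0.0);
  for (size_t t = 0; t < init.size(); ++t)
    for (int j = 0; j < d; ++j) interior[j] += pts(init[t], j) / (d + 1.0);

  std::vector<Facet> facets;
  bool broken = false;
  auto make_facet = [&](ivec verts) {
    Facet f;
    f.v = verts;
    f.alive = true;
    f.n = facet_normal(pts, verts);
    double nn = 0.0;
    for (double x : f.n) nn += x * x;
    if (nn < 0.5) { broken = true; return; }  // degenerate new facet
    f.off = 0.0;
    for (int j = 0; j < d; ++j) f.off += f.n[j] * pts(verts[0], j);
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += f.n[j] * interior[j];
    if (s > f.off) {
      for (double& x : f.n) x = -x;
      f.off = -f.off;
    }
    facets.push_back(f);
  };

  for (int drop = 0; drop <= d; ++drop) {
    ivec verts;
    for (int t = 0; t <= d; ++t)
      if (t != drop) verts.push_back(init[t]);
    make_facet(verts);
  }
  if (broken) return degen;

  for (int p = 0; p < m; ++p) {
    if (std::find(init.begin(), init.end(), p) != init.end()) continue;
    ivec vis;
    for (int fi = 0; fi < (int)facets.size(); ++fi) {
      if (!facets[fi].alive) continue;
      double s = -facets[fi].off;
      for (int j = 0; j < d; ++j) s += facets[fi].n[j] * pts(p, j);
      if (s > eps) vis.push_back(fi);
    }
    if (vis.empty()) continue;  // inside current hull (within tolerance)
    std::map<ivec, int> ridgecount;
    for (size_t vv = 0; vv < vis.size(); ++vv) {
      const ivec& fv = facets[vis[vv]].v;
      for (int dropi = 0; dropi < d; ++dropi) {
        ivec r;
        for (int t = 0; t < d; ++t)
          if (t != dropi) r.push_back(fv[t]);
        std::sort(r.begin(), r.end());
        ridgecount[r]++;
      }
    }
    for (size_t vv = 0; vv < vis.size(); ++vv) facets[vis[vv]].alive = false;
    for (std::map<ivec, int>::iterator it = ridgecount.begin();
         it != ridgecount.end(); ++it) {
      if (it->second != 1) continue;  // internal ridge of the visible region
      ivec verts = it->first;
      verts.push_back(p);
      make_facet(verts);
      if (broken) return degen;
    }
  }

  std::vector<int> keep;
  for (int fi = 0; fi < (int)facets.size(); ++fi)
    if (facets[fi].alive) keep.push_back(fi);
  int f = keep.size();
  IntegerMatrix Fm(f, d);
  NumericMatrix Nm(f, d);
  NumericVector Off(f);
  for (int i = 0; i < f; ++i) {
    ivec v = facets[keep[i]].v;
    std::sort(v.begin(), v.end());
    for (int j = 0; j < d; ++j) {
      Fm(i, j) = v[j] + 1;
      Nm(i, j) = facets[keep[i]].n[j];
    }
    Off[i] = facets[keep[i]].off;
  }
  return List::create(_["degenerate"] = false, _["facets"] = Fm,
                      _["normals"] = Nm, _["offsets"] = Off);
}

// Delaunay triangulation of 2D points as the lower convex hull of the
// paraboloid lift (x, y) -> (x, y, x^2 + y^2).
// [[Rcpp::export]]
List cpp_delaunay(NumericMatrix xy) {
  int n = xy.nrow();
  if (xy.ncol() != 2) stop("a two-column coordinate matrix is required");
  if (n < 3) stop("at least 3 points are required for triangulation");
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += xy(i, 0) / n; my += xy(i, 1) / n; }
  NumericMatrix L(n, 3);
  for (int i = 0; i < n; ++i) {
    double x = xy(i, 0) - mx, y = xy(i, 1) - my;
    L(i, 0) = x;
    L(i, 1) = y;
    L(i, 2) = x * x + y * y;
  }
  List h = cpp_convex_hull(L, 1e-12);
  if (as<bool>(h["degenerate"]))
    return List::create(_["degenerate"] = true,
                        _["triangles"] = IntegerMatrix(0, 3));
  IntegerMatrix fac = h["facets"];
  NumericMatrix nrm = h["normals"];
  std::vector<int> low;
  for (int i = 0; i < fac.nrow(); ++i)
    if (nrm(i, 2) < -1e-12) low.push_back(i);
  IntegerMatrix tri(low.size(), 3);
  for (int i = 0; i < (int)low.size(); ++i)
    for (int j = 0; j < 3; ++j) tri(i, j) = fac(low[i], j);
  return List::create(_["degenerate"] = false, _["triangles"] = tri);
}

// Gram-determinant volume of each (d-1)-simplex facet:
// sqrt(det(A A^T)) / (d-1)! with A rows p_i - p_d.
// [[Rcpp::export]]
NumericVector cpp_simplex_volumes(NumericMatrix pts, IntegerMatrix facets) {
  int f = facets.nrow(), d = pts.ncol();
  if (facets.ncol() != d) stop("facet rows must have d vertex indices");
  double fact = 1.0;
  for (int i = 2; i <= d - 1; ++i) fact *= i;
  NumericVector out(f);
  std::vector<double> A((d - 1) * d), G((d - 1) * (d - 1));
  for (int s = 0; s < f; ++s) {
    int last = facets(s, d - 1) - 1;
    for (int i = 0; i < d - 1; ++i) {
      int vi = facets(s, i) - 1;
      for (int j = 0; j < d; ++j) A[i * d + j] = pts(vi, j) - pts(last, j);
    }
    for (int i = 0; i < d - 1; ++i)
      for (int j = 0; j < d - 1; ++j) {
        double g = 0.0;
        for (int t = 0; t < d; ++t) g += A[i * d + t] * A[j * d + t];
        G[i * (d - 1) + j] = g;
      }
    double det = det_lu(G, d - 1);
    out[s] = det > 0.0 ? std::sqrt(det) / fact : 0.0;
  }
  return out;
}
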