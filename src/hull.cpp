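#include <RcppArmadillo.h>
#include <map>
#include <utility>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Incremental 3-D convex hull.
//
// Points are expected to be in "general position enough" for a tetrahedral
// start; for SCHull they lie on the unit sphere so every distinct direction
// is a hull vertex.  Returns the hull as a face matrix (1-based vertex
// indices, consistently outward-oriented), or throws for degenerate input
// (all points coplanar / coincident).

namespace {

struct Face {
  int a, b, c;
  arma::vec3 n;   // outward normal (not normalised)
  double off;     // n . x for x on the face plane
  bool alive;
};

inline arma::vec3 row3(const arma::mat& P, int i) {
  return arma::vec3{P(i, 0), P(i, 1), P(i, 2)};
}

Face make_face(const arma::mat& P, int a, int b, int c,
               const arma::vec3& inside) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  arma::vec3 pa = row3(P, a), pb = row3(P, b), pc = row3(P, c);
  f.n = arma::cross(pb - pa, pc - pa);
  f.off = arma::dot(f.n, pa);
  // flip so the interior reference point is on the negative side
  if (arma::dot(f.n, inside) - f.off > 0) {
    std::swap(f.b, f.c);
    f.n = -f.n;
    f.off = arma::dot(f.n, pa);
  }
  f.alive = true;
  return f;
}

} // namespace

// [[Rcpp::export(name = ".convex_hull_faces")]]
IntegerMatrix convex_hull_faces(const arma::mat& P, double eps = 1e-10) {
  const int n = P.n_rows;
  if (n < 4) stop("convex hull needs at least 4 points");

  // --- initial simplex: spread-out, non-degenerate tetrahedron -------------
  int i0 = 0;
  int i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = arma::norm(P.row(i) - P.row(i0));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps) stop("degenerate input: all points coincident");
  arma::vec3 p0 = row3(P, i0), p1 = row3(P, i1);

  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double a = arma::norm(arma::cross(p1 - p0, row3(P, i) - p0));
    if (a > best) { best = a; i2 = i; }
  }
  if (i2 < 0 || best <= eps) stop("degenerate input: all points collinear");
  arma::vec3 p2 = row3(P, i2);
  arma::vec3 nrm = arma::cross(p1 - p0, p2 - p0);

  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::abs(arma::dot(nrm, row3(P, i) - p0));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best <= eps)
    stop("degenerate input: all points coplanar");

  arma::vec3 inside = (p0 + p1 + p2 + row3(P, i3)) / 4.0;

  std::vector<Face> faces;
  faces.reserve(4 * n);
  faces.push_back(make_face(P, i0, i1, i2, inside));
  faces.push_back(make_face(P, i0, i1, i3, inside));
  faces.push_back(make_face(P, i0, i2, i3, inside));
  faces.push_back(make_face(P, i1, i2, i3, inside));

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  // --- insert remaining points in index order (deterministic) -------------
  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    arma::vec3 pt = row3(P, p);

    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = arma::dot(faces[f].n, pt) - faces[f].off;
      if (d > eps * std::max(1.0, std::abs(faces[f].off))) visible.push_back((int)f);
    }
    if (visible.empty()) continue; // inside current hull

    // horizon = directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int, int>, int> edge_cnt;
    for (int fi : visible) {
      const Face& f = faces[fi];
      edge_cnt[{f.a, f.b}]++;
      edge_cnt[{f.b, f.c}]++;
      edge_cnt[{f.c, f.a}]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& kv : edge_cnt) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_cnt.find(rev) == edge_cnt.end()) horizon.push_back(kv.first);
    }
    for (int fi : visible) faces[fi].alive = false;
    for (auto& e : horizon) {
      // keep orientation (a, b, p): outward by construction, but re-check
      // against the fixed interior point for numerical safety
      faces.push_back(make_face(P, e.first, e.second, p, inside));
    }
  }

  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1;
    out(r, 1) = f.b + 1;
    out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}

// Greedy Poisson-disk thinning: keep a point iff no previously kept point
// lies within `spacing`.  Order of the input rows decides priority, so the
// result is fully deterministic.  Grid hashing keeps it O(n).
// [[Rcpp::export(name = ".poisson_subsample")]]
IntegerVector poisson_subsample(const arma::mat& P, double spacing) {
  const int n = P.n_rows;
  const double cell = spacing;
  const double sp2 = spacing * spacing;
  std::map<std::tuple<long, long, long>, std::vector<int>> grid;
  std::vector<int> keep;
  keep.reserve(n);
  for (int i = 0; i < n; ++i) {
    long cx = (long)std::floor(P(i, 0) / cell);
    long cy = (long)std::floor(P(i, 1) / cell);
    long cz = (long)std::floor(P(i, 2) / cell);
    bool ok = true;
    for (long dx = -1; dx <= 1 && ok; ++dx)
      for (long dy = -1; dy <= 1 && ok; ++dy)
        for (long dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(std::make_tuple(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double d2 = 0;
            for (int k = 0; k < 3; ++k) {
              double d = P(i, k) - P(j, k);
              d2 += d * d;
            }
            if (d2 < sp2) { ok = false; break; }
          }
        }
    if (ok) {
      grid[std::make_tuple(cx, cy, cz)].push_back(i);
      keep.push_back(i + 1);
    }
  }
  return wrap(keep);
}
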