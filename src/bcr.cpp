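#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Wrap an angle to (-pi, pi].  (floor-based: avoids fmod, whose symbol is
// versioned too recently in some toolchains to load portably)
static inline double wrap_ang(double a) {
  a -= 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  if (a <= -M_PI) a += 2.0 * M_PI;
  else if (a > M_PI) a -= 2.0 * M_PI;
  return a;
}

static inline double ang_diff(double a, double b) {
  return wrap_ang(a - b);
}

// Even-odd ray casting; polygon rows are (x, y) vertices, implicitly closed.
static bool point_in_poly(double x, double y, const NumericMatrix &poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// BCR state labels for the pair (prev, cur): 0 = H, 1 = H_IF, 2 = H_Is.
static inline int state_label(bool has_prev, double px, double py,
                              double cx, double cy, double xF, double yF,
                              double dmin, double halfw) {
  if (!has_prev) return 2; // origin: no defined heading, treat as immobile state
  double dx = cx - px, dy = cy - py;
  double d = std::sqrt(dx * dx + dy * dy);
  if (d <= dmin) return 2;
  double a2 = std::atan2(dy, dx);
  double a3 = std::atan2(yF - cy, xF - cx);
  if (std::fabs(ang_diff(a2, a3)) <= halfw) return 1;
  return 0;
}

// Simulate a BCR path. Draw order per step: x ~ U[0, chi); for moving
// branches d ~ lnN(mu, sigma); for the diffusion branch alpha1 ~ U[0, 2pi).
// The immobile branch consumes no further draws. An optional exclusion
// polygon triggers redraws of the whole step (x, d, alpha).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_bcr(int n_steps, double x0, double y0,
                               double pI, double ps, double pF,
                               double mu, double sigma,
                               double xF, double yF,
                               double dmin, double halfw,
                               NumericMatrix exclusion, int max_tries) {
  NumericMatrix out(n_steps + 1, 2);
  out(0, 0) = x0;
  out(0, 1) = y0;
  const double chi = 8.0 + pI + ps + pF;
  const bool has_excl = exclusion.nrow() >= 3;
  long rejected = 0;
  double px = 0.0, py = 0.0, cx = x0, cy = y0;
  bool has_prev = false;

  for (int i = 0; i < n_steps; ++i) {
    int st = state_label(has_prev, px, py, cx, cy, xF, yF, dmin, halfw);
    double nx = cx, ny = cy;
    int tries = 0;
    while (true) {
      double x = unif_rand() * chi;
      int branch; // 0 diffusion, 1 inertia, 2 immobile, 3 attraction
      if (st == 0) {          // H
        if (x < 8.0) branch = 0;
        else if (x < 8.0 + pI) branch = 1;
        else if (x < 8.0 + pI + ps) branch = 2;
        else branch = 3;
      } else if (st == 2) {   // H_Is: inertia mass merges into immobility
        if (x < 8.0) branch = 0;
        else if (x < 8.0 + pI + ps) branch = 2;
        else branch = 3;
      } else {                // H_IF: attraction mass merges into inertia
        if (x < 8.0) branch = 0;
        else if (x < 8.0 + ps) branch = 2;
        else branch = 1;
      }
      if (branch == 2) {
        nx = cx; ny = cy;
        break; // current location is outside any exclusion by construction
      }
      double d = std::exp(mu + sigma * norm_rand());
      double alpha;
      if (branch == 0) alpha = unif_rand() * 2.0 * M_PI;
      else if (branch == 1) alpha = std::atan2(cy - py, cx - px);
      else alpha = std::atan2(yF - cy, xF - cx);
      nx = cx + d * std::cos(alpha);
      ny = cy + d * std::sin(alpha);
      if (!has_excl || !point_in_poly(nx, ny, exclusion)) break;
      ++rejected;
      if (++tries >= max_tries) { nx = cx; ny = cy; break; }
    }
    out(i + 1, 0) = nx;
    out(i + 1, 1) = ny;
    px = cx; py = cy; cx = nx; cy = ny;
    has_prev = true;
  }
  out.attr("rejected") = (double)rejected;
  return out;
}

// ---- Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(std::vector<double> &f, int n,
                 std::vector<int> &v, std::vector<double> &z,
                 std::vector<double> &d) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in pixels) from every cell to the nearest TRUE cell of `mask`.
// A large finite sentinel stands in for "no seed" so the lower-envelope
// recursion never manipulates infinities; unreachable cells come out at
// ~1e10 pixels, far beyond any radius of interest.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  const double BIG = 1e20;
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = mask(i, j) ? 0.0 : BIG;

  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int j = 0; j < nc; ++j) { // along columns
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    dt1d(f, nr, v, z, d);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {  // along rows
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, nc, v, z, d);
    for (int j = 0; j < nc; ++j) g(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = std::sqrt(g(i, j));
  return g;
}

// 4-connected component labelling; returns 0 outside the mask, 1..k inside.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(i0 + j0 * nr);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int i = idx % nr, j = idx / nr;
        const int di[4] = {1, -1, 0, 0};
        const int dj[4] = {0, 0, 1, -1};
        for (int q = 0; q < 4; ++q) {
          int ii = i + di[q], jj = j + dj[q];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Mark every cell whose centre lies within half a cell of the polyline
// (x, y); sampling at res/2 along each segment. Origin (x0, y0) is the
// coordinate of the centre of cell [0, 0].
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_path(NumericVector x, NumericVector y,
                                 int nr, int nc,
                                 double x0, double y0, double res) {
  LogicalMatrix m(nr, nc);
  int n = x.size();
  auto mark = [&](double px, double py) {
    int j = (int)std::lround((px - x0) / res);
    int i = (int)std::lround((py - y0) / res);
    if (i >= 0 && i < nr && j >= 0 && j < nc) m(i, j) = true;
  };
  if (n == 1) { mark(x[0], y[0]); return m; }
  for (int s = 0; s + 1 < n; ++s) {
    double ax = x[s], ay = y[s], bx = x[s + 1], by = y[s + 1];
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay));
    int k = std::max(1, (int)std::ceil(len / (res * 0.5)));
    for (int t = 0; t <= k; ++t) {
      double u = (double)t / k;
      mark(ax + u * (bx - ax), ay + u * (by - ay));
    }
  }
  return m;
}

// Mark the cells containing each point of a point set.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_points(NumericVector x, NumericVector y,
                                   int nr, int nc,
                                   double x0, double y0, double res) {
  LogicalMatrix m(nr, nc);
  int n = x.size();
  for (int p = 0; p < n; ++p) {
    int j = (int)std::lround((x[p] - x0) / res);
    int i = (int)std::lround((y[p] - y0) / res);
    if (i >= 0 && i < nr && j >= 0 && j < nc) m(i, j) = true;
  }
  return m;
}

// Number of entries of the polyline (px, py) into the sight disk of each
// transect: starting inside counts one entry, and each outside->inside
// crossing (exact segment/circle intersection) counts another.
// [[Rcpp::export]]
IntegerVector cpp_crossing_counts(NumericVector px, NumericVector py,
                                  NumericVector tx, NumericVector ty,
                                  double sight) {
  int n = px.size(), m = tx.size();
  IntegerVector counts(m);
  double r2 = sight * sight;
  for (int t = 0; t < m; ++t) {
    double cx = tx[t], cy = ty[t];
    double d0x = px[0] - cx, d0y = py[0] - cy;
    bool inside = (d0x * d0x + d0y * d0y) <= r2;
    int cnt = inside ? 1 : 0;
    for (int s = 0; s + 1 < n; ++s) {
      double ax = px[s] - cx, ay = py[s] - cy;
      double dx = px[s + 1] - px[s], dy = py[s + 1] - py[s];
      double a = dx * dx + dy * dy;
      double bx2 = px[s + 1] - cx, by2 = py[s + 1] - cy;
      bool end_in = (bx2 * bx2 + by2 * by2) <= r2;
      if (a > 0.0) {
        double b = ax * dx + ay * dy;
        double c = ax * ax + ay * ay - r2;
        double disc = b * b - a * c;
        if (disc > 0.0) {
          double sq = std::sqrt(disc);
          double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
          bool st = inside;
          if (t1 > 0.0 && t1 < 1.0) { st = !st; if (st) ++cnt; }
          if (t2 > 0.0 && t2 < 1.0) { st = !st; if (st) ++cnt; }
        }
      }
      inside = end_in;
    }
    counts[t] = cnt;
  }
  return counts;
}

// Mobile transect census on a shared discrete clock. `animal` holds the
// animal position at every tick. Linear transects spawn at the two anchors
// in the 8 cardinal directions at tick 0 and every `respawn` ticks, moving
// at v (metres per tick); old transects keep moving. Two rotational
// transects orbit the anchors clockwise at `rot_radius`, angular speed
// v / rot_radius, starting due east. A count is an outside->inside
// transition of the animal w.r.t. a transect's sight disk (start-inside at
// spawn counts). Returns a sights x 2 matrix: columns linear, rotational.
// [[Rcpp::export]]
IntegerMatrix cpp_mobile_transect_counts(NumericMatrix animal,
                                         double a1x, double a1y,
                                         double aFx, double aFy,
                                         double v, int respawn,
                                         double rot_radius,
                                         NumericVector sights) {
  int T = animal.nrow();
  int ns = sights.size();
  IntegerMatrix counts(ns, 2);
  std::vector<double> r2(ns);
  for (int s = 0; s < ns; ++s) r2[s] = sights[s] * sights[s];

  const double sq = M_SQRT1_2;
  const double dirx[8] = {1, sq, 0, -sq, -1, -sq, 0, sq};
  const double diry[8] = {0, sq, 1, sq, 0, -sq, -1, -sq};

  int nsp = (respawn > 0) ? (T - 1) / respawn + 1 : 1;
  int nlin = nsp * 16;
  std::vector<int> spawn(nlin);
  std::vector<double> ox(nlin), oy(nlin), dx(nlin), dy(nlin);
  int q = 0;
  for (int sp = 0; sp < nsp; ++sp) {
    for (int k = 0; k < 8; ++k) {
      for (int anc = 0; anc < 2; ++anc) {
        spawn[q] = sp * respawn;
        ox[q] = anc == 0 ? a1x : aFx;
        oy[q] = anc == 0 ? a1y : aFy;
        dx[q] = dirx[k];
        dy[q] = diry[k];
        ++q;
      }
    }
  }
  std::vector<uint8_t> lin_in((size_t)nlin * ns, 0), rot_in(2 * ns, 0);
  double omega = (rot_radius > 0) ? v / rot_radius : 0.0;

  for (int t = 0; t < T; ++t) {
    double axp = animal(t, 0), ayp = animal(t, 1);
    for (int j = 0; j < nlin; ++j) {
      if (spawn[j] > t) break; // spawns are ordered by tick
      double trav = v * (t - spawn[j]);
      double ddx = axp - (ox[j] + dx[j] * trav);
      double ddy = ayp - (oy[j] + dy[j] * trav);
      double d2 = ddx * ddx + ddy * ddy;
      for (int s = 0; s < ns; ++s) {
        uint8_t in = d2 <= r2[s];
        uint8_t &prev = lin_in[(size_t)j * ns + s];
        if (in && !prev) ++counts(s, 0);
        prev = in;
      }
    }
    double th = -omega * t; // clockwise
    for (int rj = 0; rj < 2; ++rj) {
      double cxx = (rj == 0 ? a1x : aFx) + rot_radius * std::cos(th);
      double cyy = (rj == 0 ? a1y : aFy) + rot_radius * std::sin(th);
      double ddx = axp - cxx, ddy = ayp - cyy;
      double d2 = ddx * ddx + ddy * ddy;
      for (int s = 0; s < ns; ++s) {
        uint8_t in = d2 <= r2[s];
        uint8_t &prev = rot_in[(size_t)rj * ns + s];
        if (in && !prev) ++counts(s, 1);
        prev = in;
      }
    }
  }
  return counts;
}
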