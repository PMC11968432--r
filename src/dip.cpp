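// Hartigan dip statistic, implemented from the definition:
//   D(F_n) = inf over unimodal CDFs G of sup_x |F_n(x) - G(x)|.
//
// Two independent routes are provided.
//
// cpp_dip():  exact computation by enumerating modal placements.  A unimodal
//   G is convex left of its mode and concave right of it; for each placement
//   (mode inside a gap between adjacent order statistics, or at a data point
//   with a jump) the smallest feasible band half-width d decomposes into
//   (i) a convex-side term: half the max deviation of the upper ECDF corners
//       above the greatest convex minorant of the lower corners,
//   (ii) the mirrored concave-side term, and
//   (iii) a coupling term across the modal gap, evaluated through tangent
//        envelopes: any convex f through the boxes satisfies, for i < j,
//        f(m) >= a_j + (a_j - b_i)/(x_j - x_i) * (m - x_j), and the envelope
//        of these bounds is tight; the concave side is mirrored.
//   The dip is the minimum over placements of the per-placement threshold;
//   candidates are visited in order of their side terms so that most are
//   pruned without touching the coupling.
//
// cpp_dip_oracle(): brute-force check for small n used only by the test
//   suite.  Bisection on d; for each modal placement feasibility is decided
//   by propagating the exact reachable set of (value, arrival slope) pairs
//   of a convex nondecreasing function through the ECDF boxes as a 2-D
//   convex polygon (clip / shear / upward closure), mirrored for the
//   concave side, then intersecting achievable junction values.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TOL = 1e-11;

struct Side {
  std::vector<double> x, lc, uc;  // collapsed positions, lower/upper ECDF corners
  int P() const { return (int)x.size(); }
};

// Collapse sorted, normalized data into distinct points; build mirrored side.
static void build_sides(const std::vector<double>& xs, Side& L, Side& R) {
  const int n = (int)xs.size();
  std::vector<double> xv;
  std::vector<int> cnt;
  for (int i = 0; i < n; ++i) {
    if (!xv.empty() && xs[i] == xv.back()) {
      ++cnt.back();
    } else {
      xv.push_back(xs[i]);
      cnt.push_back(1);
    }
  }
  const int P = (int)xv.size();
  L.x.resize(P); L.lc.resize(P); L.uc.resize(P);
  int c = 0;
  for (int i = 0; i < P; ++i) {
    L.x[i] = xv[i];
    L.lc[i] = (double)c / n;
    c += cnt[i];
    L.uc[i] = (double)c / n;
  }
  R.x.resize(P); R.lc.resize(P); R.uc.resize(P);
  for (int i = 0; i < P; ++i) {
    const int j = P - 1 - i;
    R.x[i] = -L.x[j];
    R.lc[i] = 1.0 - L.uc[j];
    R.uc[i] = 1.0 - L.lc[j];
  }
}

// dev[g] = max_{i < g} (uc_i - gcm(x_i)) where gcm is the greatest convex
// minorant of the lower corners of the first g collapsed points.
// Incremental Andrew scan; on each push only the new final segment needs
// rescanning, prefix maxima are kept per hull vertex.
static std::vector<double> dev_prefix(const Side& S) {
  const int P = S.P();
  std::vector<double> dev(P + 1, 0.0);
  std::vector<int> hull;
  std::vector<double> hmax;
  for (int g = 0; g < P; ++g) {
    while (hull.size() >= 2) {
      const int a = hull[hull.size() - 2], b = hull.back();
      const double cr = (S.x[b] - S.x[a]) * (S.lc[g] - S.lc[a]) -
                        (S.lc[b] - S.lc[a]) * (S.x[g] - S.x[a]);
      if (cr <= 0) { hull.pop_back(); hmax.pop_back(); } else break;
    }
    double dcur;
    if (hull.empty()) {
      dcur = S.uc[g] - S.lc[g];
    } else {
      const int a = hull.back();
      const double x0 = S.x[a], y0 = S.lc[a];
      const double sl = (S.lc[g] - y0) / (S.x[g] - x0);
      double segmax = 0.0;
      for (int i = a + 1; i <= g; ++i) {
        const double dv = S.uc[i] - (y0 + sl * (S.x[i] - x0));
        if (dv > segmax) segmax = dv;
      }
      dcur = std::max(hmax.back(), segmax);
    }
    dev[g + 1] = std::max(dcur, dev[g]);
    hull.push_back(g);
    hmax.push_back(dev[g + 1]);
  }
  return dev;
}

// Tangent slopes for the coupling envelope.  bs[j] = max_{i<j} of the slope
// of the line through (x_i, lc_i + d) and (x_j, uc_j - d); the maximizing i
// lies on the incrementally built lower hull of the (x, lc) prefix.
static void tangent_slopes(const Side& S, double d, int lim, std::vector<double>& bs) {
  bs.assign(std::max(lim, 0), -1e300);
  std::vector<int> hull;
  for (int j = 0; j < lim; ++j) {
    if (j > 0) {
      const double C = S.uc[j] - 2.0 * d;
      double best = -1e300;
      for (size_t t = 0; t < hull.size(); ++t) {
        const int i = hull[t];
        const double s = (C - S.lc[i]) / (S.x[j] - S.x[i]);
        if (s > best) best = s;
      }
      bs[j] = best;
    }
    while (hull.size() >= 2) {
      const int a = hull[hull.size() - 2], b = hull.back();
      const double cr = (S.x[b] - S.x[a]) * (S.lc[j] - S.lc[a]) -
                        (S.lc[b] - S.lc[a]) * (S.x[j] - S.x[a]);
      if (cr <= 0) hull.pop_back(); else break;
    }
    hull.push_back(j);
  }
}

// Minimal achievable value at position m of a convex nondecreasing CDF piece
// through the first g boxes (band half-width d).
static double fmin_eval(const Side& S, double d, int g, double m,
                        const std::vector<double>& bs) {
  if (g <= 0) return 0.0;
  double v = S.uc[g - 1] - d;
  for (int j = 1; j < g; ++j) {
    if (bs[j] > 0) {
      const double val = (S.uc[j] - d) + bs[j] * (m - S.x[j]);
      if (val > v) v = val;
    }
  }
  return v;
}

struct CouplingCtx {
  const Side* L;
  const Side* R;
  int P;
};

// Is a mode placeable inside gap g (between collapsed points g-1 and g,
// 1 <= g <= P-1) with band half-width d?
static bool gap_feasible(const CouplingCtx& cx, int g, double d) {
  const Side& L = *cx.L;
  const Side& R = *cx.R;
  const int P = cx.P;
  std::vector<double> bsL, bsR;
  tangent_slopes(L, d, g, bsL);
  tangent_slopes(R, d, P - g, bsR);
  double lo = L.x[g - 1], hi = L.x[g];
  auto delta = [&](double m) {
    const double fl = fmin_eval(L, d, g, m, bsL);
    const double gr = 1.0 - fmin_eval(R, d, P - g, -m, bsR);
    return fl - gr;
  };
  double best = std::min(delta(lo), delta(hi));
  if (best <= TOL) return true;
  // ternary search: the envelope difference is convex in m
  for (int it = 0; it < 80 && hi - lo > 1e-14; ++it) {
    const double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
    const double d1 = delta(m1), d2 = delta(m2);
    best = std::min(best, std::min(d1, d2));
    if (best <= TOL) return true;
    if (d1 <= d2) hi = m2; else lo = m1;
  }
  return best <= TOL;
}

// Mode exactly at collapsed point r (a jump of G at the mode is allowed).
static bool point_feasible(const CouplingCtx& cx, int r, double d) {
  const Side& L = *cx.L;
  const Side& R = *cx.R;
  const int P = cx.P;
  std::vector<double> bsL, bsR;
  tangent_slopes(L, d, r, bsL);
  tangent_slopes(R, d, P - 1 - r, bsR);
  const double fl = (r == 0) ? 0.0 : fmin_eval(L, d, r, L.x[r], bsL);
  const double gr = (r == P - 1) ? 1.0 : 1.0 - fmin_eval(R, d, P - 1 - r, -L.x[r], bsR);
  return fl <= L.lc[r] + d + TOL && gr >= L.uc[r] - d - TOL && gr >= fl - TOL;
}

struct Cand {
  int type;  // 0 = gap, 1 = point
  int pos;
  double base;
};

static double dip_from_sorted(std::vector<double>& xs) {
  const int n = (int)xs.size();
  if (n < 1) Rcpp::stop("empty sample");
  const double x0 = xs[0], rng = xs[n - 1] - xs[0];
  if (rng > 0) {
    for (int i = 0; i < n; ++i) xs[i] = (xs[i] - x0) / rng;
    xs[n - 1] = 1.0;
  }
  Side L, R;
  build_sides(xs, L, R);
  const int P = L.P();
  if (P == 1) return 0.0;  // point mass is unimodal

  const std::vector<double> devL = dev_prefix(L);
  const std::vector<double> devRm = dev_prefix(R);
  // devRs[k] = side term of the suffix starting at collapsed index k
  std::vector<double> devRs(P + 1, 0.0);
  for (int k = 0; k <= P; ++k) devRs[k] = devRm[P - k];

  std::vector<Cand> cands;
  cands.reserve(2 * P + 1);
  for (int g = 0; g <= P; ++g)
    cands.push_back({0, g, std::max(devL[g], devRs[g]) / 2.0});
  for (int r = 0; r < P; ++r)
    cands.push_back({1, r, std::max(devL[r], devRs[r + 1]) / 2.0});
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.base < b.base; });

  CouplingCtx cx{&L, &R, P};
  double best = 0.2600001;  // the dip never exceeds 1/4
  for (const Cand& c : cands) {
    if (c.base >= best) break;
    auto feas = [&](double d) {
      if (c.type == 0) {
        if (c.pos == 0 || c.pos == P) return true;
        return gap_feasible(cx, c.pos, d);
      }
      return point_feasible(cx, c.pos, d);
    };
    double thr;
    if (feas(c.base)) {
      thr = c.base;
    } else if (!feas(best)) {
      continue;  // coupling threshold at or above current best
    } else {
      double lo = c.base, hi = best;
      for (int it = 0; it < 50 && hi - lo > 1e-13; ++it) {
        const double mid = 0.5 * (lo + hi);
        if (feas(mid)) hi = mid; else lo = mid;
      }
      thr = hi;
    }
    if (thr < best) best = thr;
  }
  return best;
}

// Deterministic random subsample (without replacement) of a sorted sample.
// A subsample of iid draws is itself iid, so the capped statistic keeps the
// plain uniform null; evenly spaced order statistics would instead produce
// an artificially regular ECDF with its own null law.
static std::vector<double> thin_sorted(const std::vector<double>& xs, int max_points) {
  const int n = (int)xs.size();
  if (max_points <= 0 || n <= max_points) return xs;
  std::vector<int> idx((size_t)n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long state = 0x5eedULL + (unsigned long long)n;
  auto next = [&]() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return (state >> 33);
  };
  for (int i = 0; i < max_points; ++i) {
    const int j = i + (int)(next() % (unsigned long long)(n - i));
    std::swap(idx[i], idx[j]);
  }
  std::vector<int> keep(idx.begin(), idx.begin() + max_points);
  std::sort(keep.begin(), keep.end());
  std::vector<double> out((size_t)max_points);
  for (int i = 0; i < max_points; ++i) out[i] = xs[keep[i]];
  return out;
}

// [[Rcpp::export]]
List cpp_dip(NumericVector x, int max_points = 0) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  xs = thin_sorted(xs, max_points);
  const double d = dip_from_sorted(xs);
  return List::create(_["dip"] = d, _["n_used"] = (int)xs.size());
}

// [[Rcpp::export]]
NumericVector cpp_dip_null(int n, int n_boot, int max_points = 0) {
  // a random subsample of iid uniforms is iid, so draw the capped size
  const int m = (max_points > 0 && n > max_points) ? max_points : n;
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    std::vector<double> xs((size_t)m);
    for (int i = 0; i < m; ++i) xs[i] = R::unif_rand();
    std::sort(xs.begin(), xs.end());
    out[b] = dip_from_sorted(xs);
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force oracle (small n): reachable-set propagation.
// ---------------------------------------------------------------------------

struct Poly {
  std::vector<double> vx, vy;  // convex polygon vertices (value, slope)
  bool empty() const { return vx.empty(); }
};

static Poly poly_hull(std::vector<double> px, std::vector<double> py) {
  const size_t n = px.size();
  Poly out;
  if (n == 0) return out;
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    return px[a] < px[b] || (px[a] == px[b] && py[a] < py[b]);
  });
  std::vector<size_t> h(2 * n);
  size_t k = 0;
  auto cross = [&](size_t o, size_t a, size_t b) {
    return (px[a] - px[o]) * (py[b] - py[o]) - (py[a] - py[o]) * (px[b] - px[o]);
  };
  for (size_t ii = 0; ii < n; ++ii) {
    const size_t i = idx[ii];
    while (k >= 2 && cross(h[k - 2], h[k - 1], i) <= 0) --k;
    h[k++] = i;
  }
  const size_t lower = k + 1;
  for (size_t ii = n; ii-- > 0;) {
    const size_t i = idx[ii];
    while (k >= lower && cross(h[k - 2], h[k - 1], i) <= 0) --k;
    h[k++] = i;
  }
  if (k > 1) --k;
  for (size_t t = 0; t < k; ++t) {
    out.vx.push_back(px[h[t]]);
    out.vy.push_back(py[h[t]]);
  }
  return out;
}

// clip polygon to halfplane a*x + b*y <= c
static Poly poly_clip(const Poly& p, double a, double b, double c) {
  Poly out;
  const size_t n = p.vx.size();
  if (n == 0) return out;
  const double eps = 1e-12;
  for (size_t i = 0; i < n; ++i) {
    const size_t j = (i + 1) % n;
    const double fi = a * p.vx[i] + b * p.vy[i] - c;
    const double fj = a * p.vx[j] + b * p.vy[j] - c;
    if (fi <= eps) {
      out.vx.push_back(p.vx[i]);
      out.vy.push_back(p.vy[i]);
    }
    if ((fi < -eps && fj > eps) || (fi > eps && fj < -eps)) {
      const double t = fi / (fi - fj);
      out.vx.push_back(p.vx[i] + t * (p.vx[j] - p.vx[i]));
      out.vy.push_back(p.vy[i] + t * (p.vy[j] - p.vy[i]));
    }
  }
  if (n == 1 || (n == 2 && out.vx.size() >= 1)) return out;  // degenerate fine
  return out;
}

// reachable (value, arrival-slope) set after the prefix of g boxes
static Poly propagate(const Side& S, double d, int g, double smax) {
  Poly P;
  if (g <= 0) return P;
  double vlo = std::max(S.uc[0] - d, 0.0), vhi = std::min(S.lc[0] + d, 1.0);
  if (vlo > vhi + 1e-12) return P;
  vhi = std::max(vhi, vlo);
  P.vx = {vlo, vhi, vhi, vlo};
  P.vy = {0.0, 0.0, smax, smax};
  for (int i = 1; i < g; ++i) {
    // upward closure in slope, capped at smax
    std::vector<double> px = P.vx, py = P.vy;
    for (size_t t = 0; t < P.vx.size(); ++t) {
      px.push_back(P.vx[t]);
      py.push_back(smax);
    }
    P = poly_hull(px, py);
    if (P.empty()) return P;
    // depart with slope = arrival slope (larger handled by closure), shear
    const double dx = S.x[i] - S.x[i - 1];
    for (size_t t = 0; t < P.vx.size(); ++t) P.vx[t] += P.vy[t] * dx;
    // recompute arrival slope = (v' - v)/dx is the departure slope: state y
    // already holds it; clip to the new box
    P = poly_clip(P, -1.0, 0.0, -(S.uc[i] - d));  // v >= a_i
    if (P.empty()) return P;
    P = poly_clip(P, 1.0, 0.0, std::min(S.lc[i] + d, 1.0));  // v <= b_i
    if (P.empty()) return P;
  }
  return P;
}

static double poly_min_continuation(const Poly& P, double dm) {
  double best = 1e300;
  for (size_t t = 0; t < P.vx.size(); ++t)
    best = std::min(best, P.vx[t] + P.vy[t] * dm);
  return best;
}

// [[Rcpp::export]]
double cpp_dip_oracle(NumericVector x, int m_grid = 33) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  const int n = (int)xs.size();
  if (n > 40) Rcpp::stop("oracle is for small samples only");
  const double x0 = xs[0], rng = xs[n - 1] - xs[0];
  if (rng > 0) {
    for (int i = 0; i < n; ++i) xs[i] = (xs[i] - x0) / rng;
    xs[n - 1] = 1.0;
  }
  Side L, R;
  build_sides(xs, L, R);
  const int P = L.P();
  if (P == 1) return 0.0;
  double mingap = 1e300;
  for (int i = 1; i < P; ++i) mingap = std::min(mingap, L.x[i] - L.x[i - 1]);
  const double smax = 4.0 / mingap + 4.0;

  auto feasible = [&](double d) {
    // mode inside gap g (or beyond either end: g = 0 / g = P)
    for (int g = 0; g <= P; ++g) {
      Poly Lp = propagate(L, d, g, smax);
      if (g > 0 && Lp.empty()) continue;
      Poly Rp = propagate(R, d, P - g, smax);
      if (g < P && Rp.empty()) continue;
      if (g == 0 || g == P) return true;
      const double xl = L.x[g - 1], xr = L.x[g];
      bool ok = false;
      for (int t = 0; t <= m_grid && !ok; ++t) {
        const double m = xl + (xr - xl) * t / m_grid;
        const double vl = poly_min_continuation(Lp, m - xl);
        const double vr = 1.0 - poly_min_continuation(Rp, -m + xr);
        if (vl <= vr + 1e-10) ok = true;
      }
      if (ok) return true;
    }
    // mode at a collapsed point with a jump
    for (int r = 0; r < P; ++r) {
      double vl = 0.0, vr = 1.0;
      if (r > 0) {
        Poly Lp = propagate(L, d, r, smax);
        if (Lp.empty()) continue;
        vl = poly_min_continuation(Lp, L.x[r] - L.x[r - 1]);
      }
      if (r < P - 1) {
        Poly Rp = propagate(R, d, P - 1 - r, smax);
        if (Rp.empty()) continue;
        vr = 1.0 - poly_min_continuation(Rp, L.x[r + 1] - L.x[r]);
      }
      if (vl <= L.lc[r] + d + 1e-10 && vr >= L.uc[r] - d - 1e-10 && vl <= vr + 1e-10)
        return true;
    }
    return false;
  };

  double lo = 0.0, hi = 0.26;
  for (int it = 0; it < 40 && hi - lo > 1e-10; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (feasible(mid)) hi = mid; else lo = mid;
  }
  return hi;
}
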