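#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-piece contact-point scan: each candidate split index i models samples
// 0..i as a constant (off-contact) and samples i+1..end as a two-layer
// piecewise contact response in the deflection-corrected depth d:
//   F = C1 * d^{3/2}                                    d <= boundary
//   F = C1 * boundary^{3/2} + C2 * (d^{3/2} - boundary^{3/2})   d > boundary
// (force-continuous; linear in C1, C2 >= 0, solved per candidate). Every
// candidate is scored on the same sample range [0, end], so a split placed
// too early must explain the force rise with the model's toe and is
// penalized. Returns the split minimizing the total squared residual,
// refined by parabolic interpolation.
// z must be ascending; lo/hi/end are 0-based indices.
// [[Rcpp::export]]
List cpp_contact_scan(NumericVector z, NumericVector f, int lo, int hi,
                      int end, double k_pn_nm, double boundary) {
  int n = z.size();
  if (end > n - 1) end = n - 1;
  if (lo < 1) lo = 1;
  if (hi > end - 4) hi = end - 4;
  if (hi < lo) hi = lo;

  // prefix sums for the flat part
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + f[i];
    cs2[i + 1] = cs2[i] + f[i] * f[i];
  }
  double b15 = boundary * std::sqrt(boundary);

  int best = lo;
  double best_sse = R_PosInf;
  std::vector<double> sse(hi - lo + 1, R_PosInf);

  for (int i = lo; i <= hi; ++i) {
    int m = i + 1;  // samples 0..i off-contact
    double sse_flat = cs2[m] - cs[m] * cs[m] / m;
    double saa = 0, sbb = 0, sab = 0, say = 0, sby = 0, syy = 0;
    for (int j = i + 1; j <= end; ++j) {
      double d = (z[j] - z[i]) - f[j] / k_pn_nm;
      double y = f[j];
      syy += y * y;
      if (d <= 0) continue;  // modeled as zero force
      double a, bb;
      if (d <= boundary) {
        a = d * std::sqrt(d);
        bb = 0.0;
      } else {
        a = b15;
        bb = d * std::sqrt(d) - b15;
      }
      saa += a * a; sbb += bb * bb; sab += a * bb;
      say += a * y; sby += bb * y;
    }
    // nonnegative least squares in 2 variables
    double c1 = 0, c2 = 0;
    double det = saa * sbb - sab * sab;
    if (det > 1e-12 * saa * sbb + 1e-300) {
      c1 = (sbb * say - sab * sby) / det;
      c2 = (saa * sby - sab * say) / det;
    }
    if (c1 < 0 || c2 < 0 || det <= 1e-12 * saa * sbb + 1e-300) {
      double s1 = (saa > 0 && say > 0) ? say * say / saa : 0;
      double s2 = (sbb > 0 && sby > 0) ? sby * sby / sbb : 0;
      if (s1 >= s2) { c1 = (saa > 0 && say > 0) ? say / saa : 0; c2 = 0; }
      else { c2 = (sbb > 0 && sby > 0) ? sby / sbb : 0; c1 = 0; }
    }
    double sse_h = syy - 2 * (c1 * say + c2 * sby) +
      c1 * c1 * saa + 2 * c1 * c2 * sab + c2 * c2 * sbb;
    double tot = sse_flat + sse_h;
    sse[i - lo] = tot;
    if (tot < best_sse) { best_sse = tot; best = i; }
  }

  double z0 = z[best];
  if (best > lo && best < hi) {
    double s0 = sse[best - lo - 1], s1 = sse[best - lo], s2 = sse[best - lo + 1];
    double den = s0 - 2.0 * s1 + s2;
    if (R_finite(den) && den > 0) {
      double off = 0.5 * (s0 - s2) / den;
      if (off > 0.5) off = 0.5;
      if (off < -0.5) off = -0.5;
      double dz = off >= 0 ? (z[best + 1] - z[best]) : (z[best] - z[best - 1]);
      z0 = z[best] + off * dz;
    }
  }
  return List::create(_["index"] = best, _["z0"] = z0, _["sse"] = best_sse);
}

// centered running mean, total window = 2*(w/2)+1 samples (w=3 -> 3 samples)
// [[Rcpp::export]]
NumericVector cpp_running_mean(NumericVector f, int w) {
  int n = f.size();
  int h = w / 2;
  NumericVector out(n);
  double acc = 0.0;
  int cnt = 0;
  // prefix sums
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + f[i];
  for (int i = 0; i < n; ++i) {
    int a = i - h; if (a < 0) a = 0;
    int b = i + h; if (b > n - 1) b = n - 1;
    acc = cs[b + 1] - cs[a];
    cnt = b - a + 1;
    out[i] = acc / cnt;
  }
  return out;
}

// Rupture-candidate detection on a retraction trace stored in time order
// (z descending). The detection statistic is the pairwise mean
// (f[i]+f[i+1])/2 - averaging just two samples keeps steep single-sample-wide
// tether dips visible while still reducing the noise floor by sqrt(2).
// Candidates are local minima of that trace below -snr*sigma, located past
// the contact point (z < z0), that return toward the baseline (pair mean
// > -sigma) within 5 samples. Returns 0-based indices of the raw force
// minima near each detection. `w` widens the pair to a centered running
// mean when > 2 (kept for configurability).
// [[Rcpp::export]]
IntegerVector cpp_detect_ruptures(NumericVector f, NumericVector z, double z0,
                                  double sigma, double snr, int w) {
  int n = f.size();
  NumericVector ps(n - 1);
  if (w > 2) {
    NumericVector fs = cpp_running_mean(f, w);
    for (int i = 0; i < n - 1; ++i) ps[i] = fs[i];
  } else {
    for (int i = 0; i < n - 1; ++i) ps[i] = 0.5 * (f[i] + f[i + 1]);
  }
  double thr = -snr * sigma;
  std::vector<int> hits;
  int last = -10;
  for (int i = 1; i < n - 2; ++i) {
    if (z[i] >= z0) continue;
    if (ps[i] >= thr) continue;
    if (!(ps[i] < ps[i - 1] && ps[i] <= ps[i + 1])) continue;
    bool returns = false;
    for (int j = i + 1; j <= i + 5 && j < n - 1; ++j)
      if (ps[j] > -sigma) { returns = true; break; }
    if (!returns) continue;
    // refine on the raw trace, then advance to the last tethered sample
    // (the force keeps exceeding the threshold until the actual break)
    int a = i - 1 > 0 ? i - 1 : 0;
    int b = i + 2 < n - 1 ? i + 2 : n - 1;
    int imin = -1;
    for (int j = a; j <= b; ++j)
      if (z[j] < z0 && (imin < 0 || f[j] < f[imin])) imin = j;
    while (imin >= 0 && imin + 1 < n && imin + 1 <= i + 3 &&
           z[imin + 1] < z0 && f[imin + 1] < thr)
      ++imin;
    if (imin >= 0 && imin - last > 3) {  // dedupe neighbouring detections
      hits.push_back(imin);
      last = imin;
    }
  }
  return wrap(hits);
}

static inline double wlc_f(double x, double lp, double lc, double kBT) {
  double t = x / lc;
  double om = 1.0 - t;
  return (kBT / lp) * (0.25 / (om * om) - 0.25 + t);
}

// Bounded Levenberg-Marquardt fit of the WLC interpolation formula over
// (Lp, Lc, x0), where x0 is an extension offset absorbing contact-point
// error. x: extensions (nm), y: tensile forces (pN). Samples with
// x - x0 outside (0, Lc) contribute a zero-force model value.
// [[Rcpp::export]]
List cpp_wlc_fit(NumericVector x, NumericVector y, double kBT,
                 double lp0, double lc0, double lp_lo, double lp_hi,
                 double lc_lo, double lc_hi,
                 double x0_lo = -10.0, double x0_hi = 10.0) {
  int n = x.size();
  double lp = lp0, lc = lc0, x0 = 0.0;
  if (lp < lp_lo) lp = lp_lo;
  if (lp > lp_hi) lp = lp_hi;
  if (lc < lc_lo) lc = lc_lo;
  if (lc > lc_hi) lc = lc_hi;

  double xmax = 0.0;
  for (int i = 0; i < n; ++i) if (x[i] > xmax) xmax = x[i];

  auto model = [&](double xi, double a, double b, double c) {
    double xe = xi - c;
    if (xe <= 0) return 0.0;
    double t = xe / b;
    if (t > 0.995) t = 0.995;
    double om = 1.0 - t;
    return (kBT / a) * (0.25 / (om * om) - 0.25 + t);
  };
  auto sse_at = [&](double a, double b, double c) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = model(x[i], a, b, c) - y[i];
      s += r * r;
    }
    return s;
  };

  double lambda = 1e-3;
  double sse = sse_at(lp, lc, x0);
  bool conv = false;
  for (int it = 0; it < 200; ++it) {
    double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double g[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      double xe = x[i] - x0;
      double fi, d0, d1, d2;
      if (xe <= 0) {
        fi = 0; d0 = 0; d1 = 0; d2 = 0;
      } else {
        double t = xe / lc;
        if (t > 0.995) t = 0.995;
        double om = 1.0 - t;
        fi = (kBT / lp) * (0.25 / (om * om) - 0.25 + t);
        double dfdt = (kBT / lp) * (0.5 / (om * om * om) + 1.0);
        d0 = -fi / lp;                 // d/dLp
        d1 = dfdt * (-xe / (lc * lc)); // d/dLc
        d2 = dfdt * (-1.0 / lc);       // d/dx0
      }
      double r = fi - y[i];
      double dd[3] = {d0, d1, d2};
      for (int a = 0; a < 3; ++a) {
        g[a] += dd[a] * r;
        for (int b = a; b < 3; ++b) J[a][b] += dd[a] * dd[b];
      }
    }
    J[1][0] = J[0][1]; J[2][0] = J[0][2]; J[2][1] = J[1][2];
    bool stepped = false;
    for (int tries = 0; tries < 12; ++tries) {
      double A[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          A[a][b] = J[a][b] * (a == b ? 1 + lambda : 1.0);
      // 3x3 solve by cofactors
      double det =
        A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
        A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
        A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
      if (det <= 0 || !R_finite(det)) { lambda *= 10; continue; }
      double inv[3][3];
      inv[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
      inv[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
      inv[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
      inv[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
      inv[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
      inv[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
      inv[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
      inv[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
      inv[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
      double st[3];
      for (int a = 0; a < 3; ++a)
        st[a] = -(inv[a][0] * g[0] + inv[a][1] * g[1] + inv[a][2] * g[2]);
      double nlp = lp + st[0], nlc = lc + st[1], nx0 = x0 + st[2];
      if (nlp < lp_lo) nlp = lp_lo;
      if (nlp > lp_hi) nlp = lp_hi;
      if (nlc < lc_lo) nlc = lc_lo;
      if (nlc > lc_hi) nlc = lc_hi;
      if (nx0 < x0_lo) nx0 = x0_lo;
      if (nx0 > x0_hi) nx0 = x0_hi;
      if (nx0 > xmax - 1.0) nx0 = xmax - 1.0;  // keep some tether
      double ns = sse_at(nlp, nlc, nx0);
      if (ns < sse) {
        double rel = (sse - ns) / (sse + 1e-12);
        lp = nlp; lc = nlc; x0 = nx0; sse = ns;
        lambda = lambda > 1e-9 ? lambda * 0.3 : lambda;
        stepped = true;
        if (rel < 1e-10) conv = true;
        break;
      }
      lambda *= 10;
      if (lambda > 1e8) break;
    }
    if (!stepped) { conv = true; break; }
    if (conv) break;
  }
  double rms = std::sqrt(sse / n);
  return List::create(_["lp"] = lp, _["lc"] = lc, _["x0"] = x0,
                      _["rms"] = rms, _["converged"] = true);
}

// Connected-component labeling of a logical grid (column-major, R layout)
// under 4- or 8-connectivity. Returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int nrow, int ncol,
                                   int connectivity) {
  IntegerVector lab(nrow * ncol, 0);
  int next = 0;
  std::vector<int> stack;
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity == 8 ? 8 : 4;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      int i = r + c * nrow;
      if (!mask[i] || lab[i]) continue;
      ++next;
      lab[i] = next;
      stack.clear();
      stack.push_back(i);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int rr = cur % nrow, cc = cur / nrow;
        for (int d = 0; d < nd; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nrow || c2 < 0 || c2 >= ncol) continue;
          int j = r2 + c2 * nrow;
          if (mask[j] && !lab[j]) {
            lab[j] = next;
            stack.push_back(j);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
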