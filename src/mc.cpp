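// Monte-Carlo kernel: simulates replicates of the three-stage hierarchical
// model and computes per-replicate p-values for the dosage, truth, EM-LRT
// and simplex-mixture tests entirely in compiled code. Used by the
// benchmark drivers, where 1e5+ replicates of n = 2000 are routine.
//
// Self-contained RNG (splitmix64-seeded xoshiro256++) and double-precision
// polynomial exp/log (|rel err| ~ 1e-11, far below the 1e-6 EM tolerance)
// keep the per-iteration cost at a few ns per sample-component.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- RNG -----------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0, 1), never exactly 0
    return ((next() >> 11) | 1ULL) * 0x1.0p-53;
  }
};

// ---- fast exp / log ------------------------------------------------------

static inline double fast_exp(double x) {
  if (x < -745.0) return 0.0;
  if (x > 709.0) return HUGE_VAL;
  const double log2e = 1.4426950408889634074;
  const double ln2_hi = 6.93147180369123816490e-01;
  const double ln2_lo = 1.90821492927058770002e-10;
  double kd = std::nearbyint(x * log2e);
  int k = (int)kd;
  double r = (x - kd * ln2_hi) - kd * ln2_lo;
  // degree-11 Taylor on |r| <= 0.3466 (tail term ~2e-13)
  double p = 1.0 / 39916800.0;
  p = p * r + 1.0 / 3628800.0;
  p = p * r + 1.0 / 362880.0;
  p = p * r + 1.0 / 40320.0;
  p = p * r + 1.0 / 5040.0;
  p = p * r + 1.0 / 720.0;
  p = p * r + 1.0 / 120.0;
  p = p * r + 1.0 / 24.0;
  p = p * r + 1.0 / 6.0;
  p = p * r + 0.5;
  p = p * r + 1.0;
  p = p * r + 1.0;
  union { uint64_t i; double d; } two_k;
  if (k < -1021) {  // subnormal range: build 2^(k+64) and rescale
    two_k.i = (uint64_t)(1023 + k + 64) << 52;
    return p * two_k.d * 0x1.0p-64;
  }
  two_k.i = (uint64_t)(1023 + k) << 52;
  return p * two_k.d;
}

static inline double fast_log(double x) {
  // x = 2^k m with m in [sqrt(2)/2, sqrt(2)); atanh series in s=(m-1)/(m+1)
  union { double d; uint64_t i; } u; u.d = x;
  int k = (int)((u.i >> 52) & 0x7ff) - 1023;
  u.i = (u.i & 0x000fffffffffffffULL) | 0x3ff0000000000000ULL;
  double m = u.d;
  if (m > 1.4142135623730951) { m *= 0.5; ++k; }
  double s = (m - 1.0) / (m + 1.0), s2 = s * s;
  double p = 2.0 / 15.0;
  p = p * s2 + 2.0 / 13.0;
  p = p * s2 + 2.0 / 11.0;
  p = p * s2 + 2.0 / 9.0;
  p = p * s2 + 2.0 / 7.0;
  p = p * s2 + 2.0 / 5.0;
  p = p * s2 + 2.0 / 3.0;
  p = p * s2 + 2.0;
  return p * s + k * 0.6931471805599453094;
}

// ---- samplers ------------------------------------------------------------

struct Sampler {
  Xoshiro rng;
  double cached_norm;
  bool has_cached;
  explicit Sampler(uint64_t seed) : rng(seed), cached_norm(0),
                                    has_cached(false) {}
  inline double unif() { return rng.unif(); }
  double norm() {  // Marsaglia polar
    if (has_cached) { has_cached = false; return cached_norm; }
    double x, y, s2;
    do {
      x = 2.0 * unif() - 1.0;
      y = 2.0 * unif() - 1.0;
      s2 = x * x + y * y;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * fast_log(s2) / s2);
    cached_norm = y * f;
    has_cached = true;
    return x * f;
  }
  double gamma_ge1(double a) {  // Marsaglia-Tsang, a >= 1
    double d = a - 1.0 / 3.0, c = 1.0 / (3.0 * std::sqrt(d));
    for (;;) {
      double x = norm(), v = 1.0 + c * x;
      if (v <= 0) continue;
      v = v * v * v;
      double u = unif(), x2 = x * x;
      if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
      if (fast_log(u) < 0.5 * x2 + d * (1.0 - v + fast_log(v))) return d * v;
    }
  }
  double gamma(double a) {
    if (a >= 1.0) return gamma_ge1(a);
    // boost: X = Gamma(a+1) * U^(1/a); when U^(1/a) is below ~e-17 the
    // draw is zero to double precision relative to any Dirichlet row sum,
    // so the Gamma(a+1) factor need not be drawn at all
    double lu = fast_log(unif()) / a;
    if (lu < -40.0) return 0.0;
    return gamma_ge1(a + 1.0) * fast_exp(lu);
  }
};

// ---- per-replicate data and tests ---------------------------------------

static const double LOG2PI = 1.8378770664093454836;

// Sparse component layout for one replicate: per sample, the active
// genotype components (f > 1e-14) with their g values and log f.
// Per-sample mixture data in base-component form: the component with the
// largest prior probability is the base b; the other two components A, B
// carry log prior offsets dA = log(f_A/f_b), dB = log(f_B/f_b)
// (-1e308 when inactive, which fast_exp maps to weight 0). With
// e = y - beta0, the posterior log-weight offsets are
//   t_X = d_X + [2 b1 e (g_X - g_b) - b1^2 (g_X^2 - g_b^2)] / (2 s2),
// so one pass needs only two fast_exp and one fast_log per sample.
struct RepData {
  int n;
  std::vector<double> y, gb, gA, gB, dA, dB, lfb;
  std::vector<double> d;    // dosage implied by the component probs
  double Sy, Syy;
  void resize(int n_) {
    n = n_;
    y.resize(n); gb.resize(n); gA.resize(n); gB.resize(n);
    dA.resize(n); dB.resize(n); lfb.resize(n); d.resize(n);
  }
  void set_probs_row(int i, double f0, double f1, double f2) {
    const double tiny = 1e-14, off = -1e308;
    double f[3] = {f0, f1, f2};
    int b = 0;
    if (f[1] > f[b]) b = 1;
    if (f[2] > f[b]) b = 2;
    int a = (b == 0) ? 1 : 0, c = (b == 2) ? 1 : 2;
    gb[i] = b; gA[i] = a; gB[i] = c;
    lfb[i] = fast_log(f[b]);
    dA[i] = f[a] > tiny ? fast_log(f[a]) - lfb[i] : off;
    dB[i] = f[c] > tiny ? fast_log(f[c]) - lfb[i] : off;
    d[i] = f1 + 2.0 * f2;
  }
  void finish_y() {
    Sy = 0; Syy = 0;
    for (int i = 0; i < n; ++i) { Sy += y[i]; Syy += y[i] * y[i]; }
  }
  double null_loglik() const {
    double s2 = (Syy - Sy * Sy / n) / n;
    if (s2 < 1e-12) s2 = 1e-12;
    return -0.5 * n * (LOG2PI + fast_log(s2) + 1.0);
  }
};

// Observed-data log-likelihood, and optionally the E-step sufficient
// statistics (Seg, Seg2, Syeg), in one fused pass.
static double mix_pass(const RepData& rd, double b0, double b1, double s2,
                       bool want_moments, double* Seg, double* Seg2,
                       double* Syeg) {
  const double c0 = -0.5 * (LOG2PI + fast_log(s2));
  const double inv = 0.5 / s2;
  const double b1sq = b1 * b1;
  double ll = 0, seg = 0, seg2 = 0, syeg = 0;
  const int n = rd.n;
  for (int i = 0; i < n; ++i) {
    const double yi = rd.y[i], e = yi - b0;
    const double gb = rd.gb[i], ga = rd.gA[i], gc = rd.gB[i];
    double tA = rd.dA[i] +
      (2.0 * b1 * e * (ga - gb) - b1sq * (ga * ga - gb * gb)) * inv;
    double tB = rd.dB[i] +
      (2.0 * b1 * e * (gc - gb) - b1sq * (gc * gc - gb * gb)) * inv;
    if (tA > 690.0) tA = 690.0;
    if (tB > 690.0) tB = 690.0;
    const double wA = fast_exp(tA), wB = fast_exp(tB);
    const double s = 1.0 + wA + wB;
    const double rb = e - gb * b1;
    ll += rd.lfb[i] + c0 - rb * rb * inv + fast_log(s);
    if (want_moments) {
      const double m1 = (gb + ga * wA + gc * wB) / s;
      const double m2 = (gb * gb + ga * ga * wA + gc * gc * wB) / s;
      seg += m1; seg2 += m2; syeg += yi * m1;
    }
  }
  if (want_moments) { *Seg = seg; *Seg2 = seg2; *Syeg = syeg; }
  return ll;
}

// Dosage-regression start (OLS of y on (1, x)); returns false when x is
// constant.
static bool ols_start(const RepData& rd, const double* x, double* b0,
                      double* b1, double* s2) {
  const int n = rd.n;
  double Sx = 0, Sxx = 0, Sxy = 0;
  for (int i = 0; i < n; ++i) {
    Sx += x[i]; Sxx += x[i] * x[i]; Sxy += x[i] * rd.y[i];
  }
  double det = n * Sxx - Sx * Sx;
  if (det <= 1e-12 * n * (Sxx + 1e-300)) return false;
  *b1 = (n * Sxy - Sx * rd.Sy) / det;
  *b0 = (rd.Sy - *b1 * Sx) / n;
  double rss = rd.Syy - 2 * (*b0) * rd.Sy - 2 * (*b1) * Sxy +
    n * (*b0) * (*b0) + 2 * (*b0) * (*b1) * Sx + (*b1) * (*b1) * Sxx;
  *s2 = rss / n;
  if (*s2 < 1e-12) *s2 = 1e-12;
  return true;
}

// 1-df Gaussian-regression LRT p-value of y on x.
static double lrt_pvalue(const RepData& rd, const double* x) {
  double b0, b1, s2;
  if (!ols_start(rd, x, &b0, &b1, &s2)) return 1.0;
  double s20 = (rd.Syy - rd.Sy * rd.Sy / rd.n) / rd.n;
  if (s20 < 1e-12) s20 = 1e-12;
  double lrs = rd.n * (std::log(s20) - std::log(s2));
  if (lrs < 0) lrs = 0;
  return R::pchisq(lrs, 1.0, 0, 0);
}

struct EMResult { double loglik, b0, b1, s2; int iter; bool converged; };

// One pass computing the observed log-likelihood, the EM sufficient
// statistics, and the score/Hessian of the observed log-likelihood in
// (b0, b1, tau = log sigma^2) -- used for the safeguarded Newton polish.
struct FullPass {
  double ll, Seg, Seg2, Syeg;
  double g0, g1, g2;                    // score
  double h00, h01, h02, h11, h12, h22;  // Hessian (symmetric)
};

// With g in {0,1,2}, every score/Hessian ingredient is a polynomial in
// e = y - b0 and the posterior genotype moments m1..m4, so the pass needs
// no extra transcendentals beyond mix_pass's two exp and one log.
static FullPass full_pass(const RepData& rd, double b0, double b1,
                          double s2) {
  FullPass o{};
  const double c0 = -0.5 * (LOG2PI + fast_log(s2));
  const double inv = 0.5 / s2;        // 1 / (2 s2)
  const double is2 = 1.0 / s2;
  const double b1sq = b1 * b1;
  const int n = rd.n;
  for (int i = 0; i < n; ++i) {
    const double yi = rd.y[i], e = yi - b0;
    const double gb = rd.gb[i], ga = rd.gA[i], gc = rd.gB[i];
    double tA = rd.dA[i] +
      (2.0 * b1 * e * (ga - gb) - b1sq * (ga * ga - gb * gb)) * inv;
    double tB = rd.dB[i] +
      (2.0 * b1 * e * (gc - gb) - b1sq * (gc * gc - gb * gb)) * inv;
    if (tA > 690.0) tA = 690.0;
    if (tB > 690.0) tB = 690.0;
    const double wA = fast_exp(tA), wB = fast_exp(tB);
    const double s = 1.0 + wA + wB;
    const double rb = e - gb * b1;
    o.ll += rd.lfb[i] + c0 - rb * rb * inv + fast_log(s);
    const double ga2 = ga * ga, gc2 = gc * gc, gb2 = gb * gb;
    const double m1 = (gb + ga * wA + gc * wB) / s;
    const double m2 = (gb2 + ga2 * wA + gc2 * wB) / s;
    const double m3 = (gb2 * gb + ga2 * ga * wA + gc2 * gc * wB) / s;
    const double m4 = (gb2 * gb2 + ga2 * ga2 * wA + gc2 * gc2 * wB) / s;
    o.Seg += m1; o.Seg2 += m2; o.Syeg += yi * m1;
    // posterior moments of the per-component residual r_g = e - g b1
    const double e2 = e * e, e3 = e2 * e, e4 = e2 * e2;
    const double Er = e - b1 * m1;
    const double Egr = e * m1 - b1 * m2;
    const double Er2 = e2 - 2 * b1 * e * m1 + b1sq * m2;
    const double Egr2 = e2 * m1 - 2 * b1 * e * m2 + b1sq * m3;
    const double Eg2r2 = e2 * m2 - 2 * b1 * e * m3 + b1sq * m4;
    const double Er3 = e3 - 3 * e2 * b1 * m1 + 3 * e * b1sq * m2 -
      b1sq * b1 * m3;
    const double Egr3 = e3 * m1 - 3 * e2 * b1 * m2 + 3 * e * b1sq * m3 -
      b1sq * b1 * m4;
    const double Er4 = e4 - 4 * e3 * b1 * m1 + 6 * e2 * b1sq * m2 -
      4 * e * b1sq * b1 * m3 + b1sq * b1sq * m4;
    // score of the observed log-likelihood in (b0, b1, tau = log s2)
    const double Ea = Er * is2, Eb = Egr * is2, Ec = Er2 * inv - 0.5;
    o.g0 += Ea; o.g1 += Eb; o.g2 += Ec;
    // Hessian = E[d score] + Cov of the complete-data score
    o.h00 += -is2 + Er2 * is2 * is2 - Ea * Ea;
    o.h01 += -m1 * is2 + Egr2 * is2 * is2 - Ea * Eb;
    o.h02 += -Er * is2 + Er3 * inv * is2 - Er * inv - Ea * Ec;
    o.h11 += -m2 * is2 + Eg2r2 * is2 * is2 - Eb * Eb;
    o.h12 += -Egr * is2 + Egr3 * inv * is2 - Egr * inv - Eb * Ec;
    o.h22 += -Er2 * inv + Er4 * inv * inv - Er2 * inv + 0.25 - Ec * Ec;
  }
  return o;
}

// Maximize the mixture log-likelihood: EM iterations with a safeguarded
// Newton polish on the observed log-likelihood (same fixed point; a
// Newton candidate is accepted only when it does not decrease the
// log-likelihood, so the iterate sequence is monotone like plain EM).
static EMResult em_fit_fast(const RepData& rd, double tol, int maxit) {
  EMResult res{-HUGE_VAL, 0, 0, 1, 0, false};
  double b0, b1, s2;
  if (!ols_start(rd, rd.d.data(), &b0, &b1, &s2)) {
    // constant dosage: the mixture collapses to the null fit
    double s20 = (rd.Syy - rd.Sy * rd.Sy / rd.n) / rd.n;
    res.b0 = rd.Sy / rd.n; res.b1 = 0;
    res.s2 = s20 < 1e-12 ? 1e-12 : s20;
    res.loglik = rd.null_loglik();
    res.converged = true;
    return res;
  }
  const int n = rd.n;
  FullPass cur = full_pass(rd, b0, b1, s2);
  int pass = 1;
  double prev = -HUGE_VAL;
  for (;;) {
    if (pass > 1 && std::fabs(cur.ll - prev) < tol) {
      res.converged = true;
      break;
    }
    if (pass >= maxit) break;
    prev = cur.ll;
    bool stepped = false;
    if (pass >= 2) {
      // Newton candidate in (b0, b1, tau); require negative definite H
      double A = -cur.h00, B = -cur.h01, C = -cur.h02,
             D = -cur.h11, E = -cur.h12, F = -cur.h22;  // -H, pos def
      double d1 = A, d2 = A * D - B * B,
             d3 = A * (D * F - E * E) - B * (B * F - C * E) +
                  C * (B * E - C * D);
      if (d1 > 0 && d2 > 0 && d3 > 0) {
        // solve (-H) delta = grad  => theta_new = theta + delta
        double g0 = cur.g0, g1 = cur.g1, g2 = cur.g2;
        double x0 = (g0 * (D * F - E * E) - g1 * (B * F - C * E) +
                     g2 * (B * E - C * D)) / d3;
        double x1 = (A * (g1 * F - g2 * E) - B * (g0 * F - g2 * C) +
                     C * (g0 * E - g1 * C)) / d3;
        double x2 = (A * (D * g2 - E * g1) - B * (B * g2 - E * g0) +
                     C * (B * g1 - D * g0)) / d3;
        double mx = std::fabs(x0);
        if (std::fabs(x1) > mx) mx = std::fabs(x1);
        if (std::fabs(x2) > mx) mx = std::fabs(x2);
        if (mx > 2.0) { x0 *= 2.0 / mx; x1 *= 2.0 / mx; x2 *= 2.0 / mx; }
        double nb0 = b0 + x0, nb1 = b1 + x1,
               ns2 = s2 * fast_exp(x2);
        if (std::isfinite(nb0) && std::isfinite(nb1) &&
            std::isfinite(ns2) && ns2 > 1e-12) {
          FullPass cand = full_pass(rd, nb0, nb1, ns2);
          ++pass;
          if (cand.ll >= cur.ll) {
            b0 = nb0; b1 = nb1; s2 = ns2; cur = cand; stepped = true;
          }
        }
      }
    }
    if (!stepped) {  // plain EM update from the current pass's moments
      double det = n * cur.Seg2 - cur.Seg * cur.Seg;
      if (std::fabs(det) <= 1e-10 * n * (cur.Seg2 + 1e-300)) break;
      b1 = (n * cur.Syeg - cur.Seg * rd.Sy) / det;
      b0 = (rd.Sy - b1 * cur.Seg) / n;
      double rss = rd.Syy - 2 * b0 * rd.Sy - 2 * b1 * cur.Syeg +
        n * b0 * b0 + 2 * b0 * b1 * cur.Seg + b1 * b1 * cur.Seg2;
      s2 = rss / n;
      if (s2 < 1e-12) s2 = 1e-12;
      cur = full_pass(rd, b0, b1, s2);
      ++pass;
    }
  }
  res.loglik = cur.ll; res.b0 = b0; res.b1 = b1; res.s2 = s2;
  res.iter = pass;
  return res;
}

static double em_lrt_p(const RepData& rd, double tol, int maxit,
                       double* beta1 = nullptr, int* niter = nullptr) {
  EMResult f = em_fit_fast(rd, tol, maxit);
  double lrs = 2.0 * (f.loglik - rd.null_loglik());
  if (lrs < 0) lrs = 0;
  if (beta1) *beta1 = f.b1;
  if (niter) *niter = f.iter;
  return R::pchisq(lrs, 1.0, 0, 0);
}

// Nelder-Mead maximization of the mixture log-likelihood over
// (b0, b1, log sigma), started at the dosage estimates; stopping rule as
// in stats::optim (relative spread of simplex values).
static double nm_mixture_p(const RepData& rd, double reltol, int maxit) {
  double b0, b1, s2;
  if (!ols_start(rd, rd.d.data(), &b0, &b1, &s2)) return 1.0;
  auto fn = [&](const double* p) {
    return -mix_pass(rd, p[0], p[1], fast_exp(2.0 * p[2]), false,
                     nullptr, nullptr, nullptr);
  };
  double pt[4][3], fv[4];
  pt[0][0] = b0; pt[0][1] = b1; pt[0][2] = 0.5 * std::log(s2);
  for (int j = 1; j < 4; ++j) {
    for (int k = 0; k < 3; ++k) pt[j][k] = pt[0][k];
    double step = 0.1 * std::fabs(pt[0][j - 1]);
    if (step < 0.1) step = 0.1;
    pt[j][j - 1] += step;
  }
  for (int j = 0; j < 4; ++j) fv[j] = fn(pt[j]);
  int evals = 4;
  while (evals < maxit) {
    int lo = 0, hi = 0, nh = 0;
    for (int j = 1; j < 4; ++j) {
      if (fv[j] < fv[lo]) lo = j;
      if (fv[j] > fv[hi]) hi = j;
    }
    for (int j = 0; j < 4; ++j) if (j != hi && fv[j] > fv[nh]) nh = j;
    if (std::fabs(fv[hi] - fv[lo]) <=
        reltol * (std::fabs(fv[lo]) + reltol)) break;
    double cen[3] = {0, 0, 0};
    for (int j = 0; j < 4; ++j)
      if (j != hi) for (int k = 0; k < 3; ++k) cen[k] += pt[j][k] / 3.0;
    double refl[3], tryp[3];
    for (int k = 0; k < 3; ++k) refl[k] = 2.0 * cen[k] - pt[hi][k];
    double fr = fn(refl); ++evals;
    if (fr < fv[lo]) {  // try expansion
      for (int k = 0; k < 3; ++k) tryp[k] = cen[k] + 2.0 * (refl[k] - cen[k]);
      double fe = fn(tryp); ++evals;
      if (fe < fr) { std::copy(tryp, tryp + 3, pt[hi]); fv[hi] = fe; }
      else { std::copy(refl, refl + 3, pt[hi]); fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      std::copy(refl, refl + 3, pt[hi]); fv[hi] = fr;
    } else {  // contraction
      bool outside = fr < fv[hi];
      if (outside) { std::copy(refl, refl + 3, pt[hi]); fv[hi] = fr; }
      for (int k = 0; k < 3; ++k)
        tryp[k] = cen[k] + 0.5 * (pt[hi][k] - cen[k]);
      double fc = fn(tryp); ++evals;
      if (fc < fv[hi]) { std::copy(tryp, tryp + 3, pt[hi]); fv[hi] = fc; }
      else {  // shrink toward best
        for (int j = 0; j < 4; ++j) {
          if (j == lo) continue;
          for (int k = 0; k < 3; ++k)
            pt[j][k] = pt[lo][k] + 0.5 * (pt[j][k] - pt[lo][k]);
          fv[j] = fn(pt[j]); ++evals;
        }
      }
    }
  }
  int lo = 0;
  for (int j = 1; j < 4; ++j) if (fv[j] < fv[lo]) lo = j;
  double lrs = 2.0 * (-fv[lo] - rd.null_loglik());
  if (lrs < 0) lrs = 0;
  return R::pchisq(lrs, 1.0, 0, 0);
}

// ---- exported batch interfaces ------------------------------------------

// EM-LRT p-values for `reps` stacked replicates of length n (no
// covariates); y has length n*reps, F is (n*reps) x 3.
// [[Rcpp::export]]
NumericMatrix em_lrt_batch_cpp(NumericVector y, NumericMatrix F, int n,
                               double tol, int maxit) {
  int reps = y.size() / n;
  NumericMatrix out(reps, 3);
  RepData rd; rd.resize(n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) {
      int k = r * n + i;
      rd.y[i] = y[k];
      rd.set_probs_row(i, F(k, 0), F(k, 1), F(k, 2));
    }
    rd.finish_y();
    double b1; int it;
    out(r, 0) = em_lrt_p(rd, tol, maxit, &b1, &it);
    out(r, 1) = b1; out(r, 2) = it;
  }
  colnames(out) = CharacterVector::create("pvalue", "beta1", "n_iter");
  return out;
}

// Simplex-mixture p-values for stacked replicates (see em_lrt_batch_cpp).
// [[Rcpp::export]]
NumericVector nm_mixture_batch_cpp(NumericVector y, NumericMatrix F, int n,
                                   double reltol, int maxit) {
  int reps = y.size() / n;
  NumericVector out(reps);
  RepData rd; rd.resize(n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) {
      int k = r * n + i;
      rd.y[i] = y[k];
      rd.set_probs_row(i, F(k, 0), F(k, 1), F(k, 2));
    }
    rd.finish_y();
    out[r] = nm_mixture_p(rd, reltol, maxit);
  }
  return out;
}

// Full simulate-and-test kernel for one (MAF, R^2) cell: returns a
// reps x |methods| matrix of p-values. methods_mask order:
// dosage, truth, emlrt_prob, emlrt_dose, mixture. The EM-LRT-Dose column
// uses the dosage-approximation reconstruction (the policy choice for
// every cell this kernel is used on); mixture runs for the first
// mixture_reps replicates.
// [[Rcpp::export]]
NumericMatrix mc_kernel_cpp(int n, int reps, NumericVector alpha,
                            NumericVector hwe, bool degenerate,
                            double beta0, double beta1, double sigma2,
                            double seed, LogicalVector methods_mask,
                            double tol, int maxit, int mixture_reps,
                            double nm_reltol, int nm_maxit) {
  const bool do_dosage = methods_mask[0], do_truth = methods_mask[1],
             do_prob = methods_mask[2], do_dose = methods_mask[3],
             do_mix = methods_mask[4];
  int ncol = do_dosage + do_truth + do_prob + do_dose + do_mix;
  NumericMatrix out(reps, ncol);
  Sampler smp((uint64_t)seed);
  RepData rd, rd_dose;
  rd.resize(n);
  if (do_dose) rd_dose.resize(n);
  std::vector<double> G(n);
  const double sd = std::sqrt(sigma2);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) {
      double f0, f1, f2;
      if (degenerate) {
        double u = smp.unif();
        f0 = f1 = f2 = 0.0;
        if (u < hwe[0]) f0 = 1.0;
        else if (u < hwe[0] + hwe[1]) f1 = 1.0;
        else f2 = 1.0;
      } else {
        double g0 = smp.gamma(alpha[0]), g1 = smp.gamma(alpha[1]),
               g2 = smp.gamma(alpha[2]);
        double s = g0 + g1 + g2;
        if (s <= 0) { g0 = 1; g1 = g2 = 0; s = 1; }
        f0 = g0 / s; f1 = g1 / s; f2 = g2 / s;
      }
      rd.set_probs_row(i, f0, f1, f2);
      double u = smp.unif();
      double g = (u > f0) + (u > f0 + f1);
      G[i] = g;
      rd.y[i] = beta0 + beta1 * g + sd * smp.norm();
      if (do_dose) {
        double d = rd.d[i];
        rd_dose.y[i] = rd.y[i];
        if (d <= 1.0) rd_dose.set_probs_row(i, 1.0 - d, d, 0.0);
        else rd_dose.set_probs_row(i, 0.0, 2.0 - d, d - 1.0);
      }
    }
    rd.finish_y();
    if (do_dose) rd_dose.finish_y();
    int col = 0;
    if (do_dosage) out(r, col++) = lrt_pvalue(rd, rd.d.data());
    if (do_truth) out(r, col++) = lrt_pvalue(rd, G.data());
    if (do_prob) out(r, col++) = em_lrt_p(rd, tol, maxit);
    if (do_dose) out(r, col++) = em_lrt_p(rd_dose, tol, maxit);
    if (do_mix)
      out(r, col++) = r < mixture_reps ?
        nm_mixture_p(rd, nm_reltol, nm_maxit) : NA_REAL;
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
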