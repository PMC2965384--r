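#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Emission model internals shared by the E-step and the M-step moment
// accumulator.  A "cell" is one (tumor state, genotype pair, heterogeneity
// level) combination; each cell spawns K Student-t mixture components whose
// means differ only by the component offset delta_k^(l).  Cells are sorted
// by expanded-state index `es` (state x heterogeneity level).
//
// The Student-t kernel (1 + q/nu)^{-(nu+2)/2} is evaluated in linear space:
// for (half-)integer exponents (any even-or-odd integer nu) this needs only
// multiplications and at most one sqrt, so the per-(probe, pair, component)
// work is transcendental-free; one log per (probe, expanded state) remains.
// The linear-space sum is exact to double precision: normalized kernels are
// <= 1 and cannot underflow for finite data (t^{-m/2} underflows only for
// astronomically large Mahalanobis distances).

// t^{-m2/2} for integer m2 >= 0 via binary exponentiation
static inline double neg_half_pow(double t, int m2) {
  double s = (m2 & 1) ? 1.0 / std::sqrt(t) : 1.0;
  double u = 1.0 / t;
  int e = m2 >> 1;
  while (e) {
    if (e & 1) s *= u;
    u *= u;
    e >>= 1;
  }
  return s;
}

struct EmisTables {
  int C, K, S, nCK;
  std::vector<double> mr;      // LRR mean incl. beta0 and delta (no GC term)
  std::vector<double> mb;      // BAF mean incl. delta
  std::vector<double> p11, p12, p22, s00inv;
  std::vector<double> w_hw, w_m0, w_m1, w_m2;  // exp(log prior + log w + const)
  std::vector<char> degen;     // zero total copy number at this omega
  double nu;
  int m2_biv, m2_uni;          // 2 * exponent, or -1 when not half-integer
  double h_biv, h_uni;
};

static EmisTables build_tables(const IntegerVector &pil,
    const NumericVector &zn, const NumericVector &xn,
    const NumericVector &zt, const NumericVector &xt,
    const IntegerVector &cls, const NumericVector &lgp_hw,
    const NumericMatrix &lgp_m, const NumericVector &pi_grid, double pi0,
    const NumericVector &rbar, double beta0,
    const NumericMatrix &delta, const NumericMatrix &prec,
    const NumericVector &sig00, const NumericVector &lw,
    double nu, int S, int K) {
  EmisTables T;
  T.C = pil.size();
  T.K = K;
  T.S = S;
  T.nCK = T.C * K;
  T.nu = nu;
  T.h_biv = 0.5 * (nu + 2.0);
  T.h_uni = 0.5 * (nu + 1.0);
  double m2b = nu + 2.0, m2u = nu + 1.0;
  T.m2_biv = (std::fabs(m2b - std::lround(m2b)) < 1e-9) ?
    (int)std::lround(m2b) : -1;
  T.m2_uni = (std::fabs(m2u - std::lround(m2u)) < 1e-9) ?
    (int)std::lround(m2u) : -1;
  T.mr.resize(T.nCK); T.mb.resize(T.nCK);
  T.p11.resize(T.nCK); T.p12.resize(T.nCK); T.p22.resize(T.nCK);
  T.s00inv.resize(T.nCK);
  T.w_hw.resize(T.nCK); T.w_m0.resize(T.nCK); T.w_m1.resize(T.nCK);
  T.w_m2.resize(T.nCK);
  T.degen.resize(T.nCK);
  const int KL = delta.ncol();
  std::vector<double> t2c(KL), t1c(KL);
  for (int kl = 0; kl < KL; ++kl) {
    t2c[kl] = lgamma(0.5 * (nu + 2.0)) - lgamma(0.5 * nu) -
      std::log(nu * M_PI) - 0.5 * prec(3, kl);
    t1c[kl] = lgamma(0.5 * (nu + 1.0)) - lgamma(0.5 * nu) -
      0.5 * std::log(nu * M_PI * sig00[kl]);
  }
  for (int c = 0; c < T.C; ++c) {
    double om = pi_grid[pil[c]] * (1.0 - pi0) + pi0;
    double den = om * xn[c] + (1.0 - om) * xt[c];
    double A = om * rbar[(int)xn[c]] + (1.0 - om) * rbar[(int)xt[c]];
    bool dg = !(den > 1e-12);
    double B = dg ? zn[c] / 2.0 : (om * zn[c] + (1.0 - om) * zt[c]) / den;
    for (int k = 0; k < K; ++k) {
      int kl = k + K * cls[c];
      int ck = c * K + k;
      T.mr[ck] = A + beta0 + delta(0, kl);
      T.mb[ck] = B + delta(1, kl);
      T.p11[ck] = prec(0, kl);
      T.p12[ck] = prec(1, kl);
      T.p22[ck] = prec(2, kl);
      T.s00inv[ck] = 1.0 / sig00[kl];
      T.degen[ck] = dg;
      double cst = dg ? t1c[kl] : t2c[kl];
      T.w_hw[ck] = R_finite(lgp_hw[c]) ? std::exp(lgp_hw[c] + lw[kl] + cst)
                                       : 0.0;
      T.w_m0[ck] = R_finite(lgp_m(c, 0)) ?
        std::exp(lgp_m(c, 0) + lw[kl] + cst) : 0.0;
      T.w_m1[ck] = R_finite(lgp_m(c, 1)) ?
        std::exp(lgp_m(c, 1) + lw[kl] + cst) : 0.0;
      T.w_m2[ck] = R_finite(lgp_m(c, 2)) ?
        std::exp(lgp_m(c, 2) + lw[kl] + cst) : 0.0;
    }
  }
  return T;
}

static inline const double *weight_vec(const EmisTables &T, int gm) {
  switch (gm) {
    case 0: return T.w_m0.data();
    case 1: return T.w_m1.data();
    case 2: return T.w_m2.data();
    default: return T.w_hw.data();
  }
}

// normalized t kernel value and (optionally) the Mahalanobis form
static inline double t_kernel(const EmisTables &T, int ck,
                              double e1, double e2, double *q_out) {
  double q, p;
  if (!T.degen[ck]) {
    q = T.p11[ck] * e1 * e1 + 2.0 * T.p12[ck] * e1 * e2 +
        T.p22[ck] * e2 * e2;
    double t = 1.0 + q / T.nu;
    p = (T.m2_biv > 0) ? neg_half_pow(t, T.m2_biv)
                       : std::pow(t, -T.h_biv);
  } else {
    q = e1 * e1 * T.s00inv[ck];
    double t = 1.0 + q / T.nu;
    p = (T.m2_uni > 0) ? neg_half_pow(t, T.m2_uni)
                       : std::pow(t, -T.h_uni);
  }
  if (q_out) *q_out = q;
  return p;
}

// [[Rcpp::export]]
NumericMatrix emission_core(NumericVector r, NumericVector b, NumericVector g,
                            IntegerVector matched,
                            IntegerVector es, IntegerVector pil,
                            NumericVector zn, NumericVector xn,
                            NumericVector zt, NumericVector xt,
                            IntegerVector cls,
                            NumericVector lgp_hw, NumericMatrix lgp_m,
                            NumericVector pi_grid, double pi0,
                            NumericVector rbar, double beta0, double beta1,
                            NumericMatrix delta, NumericMatrix prec,
                            NumericVector sig00, NumericVector lw,
                            double nu, double eta, double rmin, double rmax,
                            int S, int K) {
  const int n = r.size(), C = es.size();
  NumericMatrix out(n, S);
  EmisTables T = build_tables(pil, zn, xn, zt, xt, cls, lgp_hw, lgp_m,
                              pi_grid, pi0, rbar, beta0, delta, prec,
                              sig00, lw, nu, S, K);
  const double u_out = 1.0 / (rmax - rmin);
  std::vector<double> acc(S);
  std::vector<int> es_of(T.nCK);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k) es_of[c * K + k] = es[c];
  for (int i = 0; i < n; ++i) {
    const double ri = r[i], bi = b[i], bg = beta1 * g[i];
    const double *w = weight_vec(T, matched[i]);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int ck = 0; ck < T.nCK; ++ck) {
      if (w[ck] == 0.0) continue;
      double e1 = ri - T.mr[ck] - bg;
      double e2 = bi - T.mb[ck];
      acc[es_of[ck]] += w[ck] * t_kernel(T, ck, e1, e2, nullptr);
    }
    double outl = (ri >= rmin && ri <= rmax) ? eta * u_out : 0.0;
    for (int s = 0; s < S; ++s) {
      double v = outl + (1.0 - eta) * acc[s];
      out(i, s) = (v > 0.0) ? std::log(v) : R_NegInf;
    }
  }
  return out;
}

// Accumulates, per (cell, component), the latent-scale-weighted raw moments
// needed for the conjugate MAP updates:
// columns: m0 (resp), mu (resp*u), mug, mugg, mur, mub, mugr, mugb,
//          murr, murb, mubb   (g = GC, r = LRR, b = BAF)
// Degenerate (zero total copy) cells are excluded from the moments.  Also
// returns the total outlier responsibility.

// [[Rcpp::export]]
List moments_core(NumericVector r, NumericVector b, NumericVector g,
                  IntegerVector matched,
                  IntegerVector es, IntegerVector pil,
                  NumericVector zn, NumericVector xn,
                  NumericVector zt, NumericVector xt,
                  IntegerVector cls,
                  NumericVector lgp_hw, NumericMatrix lgp_m,
                  NumericVector pi_grid, double pi0,
                  NumericVector rbar, double beta0, double beta1,
                  NumericMatrix delta, NumericMatrix prec,
                  NumericVector sig00, NumericVector lw,
                  double nu, double eta, double rmin, double rmax,
                  int S, int K,
                  NumericMatrix gamma, NumericMatrix logemis, double thresh) {
  const int n = r.size(), C = es.size();
  EmisTables T = build_tables(pil, zn, xn, zt, xt, cls, lgp_hw, lgp_m,
                              pi_grid, pi0, rbar, beta0, delta, prec,
                              sig00, lw, nu, S, K);
  const double u_out = 1.0 / (rmax - rmin);
  NumericMatrix mom(T.nCK, 11);
  double s_out = 0.0;
  // per-probe scale factors gamma / emission, computed per expanded state
  std::vector<double> sc(S);
  for (int i = 0; i < n; ++i) {
    const double ri = r[i], bi = b[i], gi = g[i], bg = beta1 * gi;
    const double *w = weight_vec(T, matched[i]);
    bool any = false;
    for (int s = 0; s < S; ++s) {
      double ga = gamma(i, s);
      if (ga > thresh && R_finite(logemis(i, s))) {
        sc[s] = ga * std::exp(-logemis(i, s));
        any = true;
        if (eta > 0.0 && ri >= rmin && ri <= rmax)
          s_out += sc[s] * eta * u_out;
      } else sc[s] = 0.0;
    }
    if (!any) continue;
    const double one_m_eta = 1.0 - eta;
    for (int c = 0; c < C; ++c) {
      double f = sc[es[c]];
      if (f == 0.0) continue;
      for (int k = 0; k < K; ++k) {
        int ck = c * K + k;
        if (w[ck] == 0.0 || T.degen[ck]) continue;
        double e1 = ri - T.mr[ck] - bg;
        double e2 = bi - T.mb[ck];
        double q;
        double p = t_kernel(T, ck, e1, e2, &q);
        double resp = f * one_m_eta * w[ck] * p;
        if (!(resp > 1e-300)) continue;
        double ru = resp * (nu + 2.0) / (nu + q);
        double *m = &mom(ck, 0);
        const int L = T.nCK;
        m[0] += resp;
        m[L] += ru;
        m[2 * L] += ru * gi;
        m[3 * L] += ru * gi * gi;
        m[4 * L] += ru * ri;
        m[5 * L] += ru * bi;
        m[6 * L] += ru * gi * ri;
        m[7 * L] += ru * gi * bi;
        m[8 * L] += ru * ri * ri;
        m[9 * L] += ru * ri * bi;
        m[10 * L] += ru * bi * bi;
      }
    }
  }
  return List::create(_["mom"] = mom, _["s_out"] = s_out);
}

// Inhomogeneous chain with the distance-dependent switch probability rho_i
// (into probe i) and uniform split of the switch mass over the other S-1
// expanded states; rows flagged in `newchrom` restart from `init`.

// [[Rcpp::export]]
List fb_core(NumericMatrix logemis, NumericVector rho, LogicalVector newchrom,
             NumericVector init, bool want_gamma) {
  const int n = logemis.nrow(), S = logemis.ncol();
  NumericMatrix alpha(n, S), beta(want_gamma ? n : 1, S);
  double loglik = 0.0;
  std::vector<double> e(S);
  for (int i = 0; i < n; ++i) {
    double m = R_NegInf;
    for (int s = 0; s < S; ++s) if (logemis(i, s) > m) m = logemis(i, s);
    if (!R_finite(m)) stop("all-state zero emission probability at probe %d", i + 1);
    for (int s = 0; s < S; ++s) e[s] = std::exp(logemis(i, s) - m);
    double tot = 0.0;
    if (i == 0 || newchrom[i]) {
      for (int s = 0; s < S; ++s) { alpha(i, s) = init[s] * e[s]; tot += alpha(i, s); }
    } else {
      double stay = 1.0 - rho[i];
      double sw = (S > 1) ? rho[i] / (S - 1) : 0.0;
      for (int s = 0; s < S; ++s) {
        alpha(i, s) = e[s] * ((stay - sw) * alpha(i - 1, s) + sw);
        tot += alpha(i, s);
      }
    }
    if (!(tot > 0.0)) stop("forward pass underflow at probe %d", i + 1);
    for (int s = 0; s < S; ++s) alpha(i, s) /= tot;
    loglik += std::log(tot) + m;
  }
  if (!want_gamma)
    return List::create(_["loglik"] = loglik);
  for (int i = n - 1; i >= 0; --i) {
    if (i == n - 1 || newchrom[i + 1]) {
      for (int s = 0; s < S; ++s) beta(i, s) = 1.0 / S;
    } else {
      double m = R_NegInf;
      for (int s = 0; s < S; ++s) if (logemis(i + 1, s) > m) m = logemis(i + 1, s);
      double stay = 1.0 - rho[i + 1];
      double sw = (S > 1) ? rho[i + 1] / (S - 1) : 0.0;
      double dot = 0.0, tot = 0.0;
      for (int s = 0; s < S; ++s) {
        e[s] = std::exp(logemis(i + 1, s) - m) * beta(i + 1, s);
        dot += e[s];
      }
      for (int s = 0; s < S; ++s) {
        beta(i, s) = (stay - sw) * e[s] + sw * dot;
        tot += beta(i, s);
      }
      if (!(tot > 0.0)) stop("backward pass underflow at probe %d", i + 1);
      for (int s = 0; s < S; ++s) beta(i, s) /= tot;
    }
  }
  NumericMatrix gamma(n, S);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) { gamma(i, s) = alpha(i, s) * beta(i, s); tot += gamma(i, s); }
    for (int s = 0; s < S; ++s) gamma(i, s) /= tot;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma);
}

// [[Rcpp::export]]
IntegerVector viterbi_core(NumericMatrix logemis, NumericVector rho,
                           LogicalVector newchrom, NumericVector init) {
  const int n = logemis.nrow(), S = logemis.ncol();
  IntegerMatrix ptr(n, S);
  IntegerVector path(n);
  std::vector<double> v(S), vnew(S);
  std::vector<double> linit(S);
  for (int s = 0; s < S; ++s)
    linit[s] = (init[s] > 0) ? std::log(init[s]) : R_NegInf;
  int seg_start = 0;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || newchrom[i]) {
      if (i > 0) {  // close previous chromosome
        int best = 0;
        for (int s = 1; s < S; ++s) if (v[s] > v[best]) best = s;
        for (int j = i - 1; j >= seg_start; --j) { path[j] = best; best = ptr(j, best); }
      }
      seg_start = i;
      for (int s = 0; s < S; ++s) { v[s] = linit[s] + logemis(i, s); ptr(i, s) = s; }
      continue;
    }
    double lstay = (rho[i] < 1.0) ? std::log1p(-rho[i]) : R_NegInf;
    double lsw = (rho[i] > 0.0 && S > 1) ? std::log(rho[i] / (S - 1)) : R_NegInf;
    // top-2 of v (lowest index wins ties)
    int i1 = 0;
    for (int s = 1; s < S; ++s) if (v[s] > v[i1]) i1 = s;
    int i2 = -1;
    for (int s = 0; s < S; ++s) {
      if (s == i1) continue;
      if (i2 < 0 || v[s] > v[i2]) i2 = s;
    }
    for (int s = 0; s < S; ++s) {
      int bo = (s == i1) ? i2 : i1;
      double cstay = lstay + v[s];
      double csw = (bo >= 0) ? lsw + v[bo] : R_NegInf;
      if (csw > cstay || (csw == cstay && bo >= 0 && bo < s)) {
        vnew[s] = logemis(i, s) + csw;
        ptr(i, s) = bo;
      } else {
        vnew[s] = logemis(i, s) + cstay;
        ptr(i, s) = s;
      }
    }
    v = vnew;
  }
  int best = 0;
  for (int s = 1; s < S; ++s) if (v[s] > v[best]) best = s;
  for (int j = n - 1; j >= seg_start; --j) { path[j] = best; best = ptr(j, best); }
  return path;
}
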