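#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

// exp(A) for a 2x2 complex matrix via the closed form
// exp(A) = e^{tr/2} [ cosh(q) I + sinh(q)/q (A - tr/2 I) ],
// q^2 = ((a-d)/2)^2 + b c.  Equivalent to eigendecomposition but branch-free.
static void expm2(const cplx A[4], cplx E[4]) {
  cplx half_tr = 0.5 * (A[0] + A[3]);
  cplx delta = 0.5 * (A[0] - A[3]);
  cplx q = std::sqrt(delta * delta + A[1] * A[2]);
  cplx ch = std::cosh(q);
  cplx shq; // sinh(q)/q with series fallback near q = 0
  if (std::abs(q) < 1e-8) {
    cplx q2 = q * q;
    shq = 1.0 + q2 / 6.0 + q2 * q2 / 120.0;
  } else {
    shq = std::sinh(q) / q;
  }
  cplx s = std::exp(half_tr);
  E[0] = s * (ch + shq * (A[0] - half_tr));
  E[1] = s * (shq * A[1]);
  E[2] = s * (shq * A[2]);
  E[3] = s * (ch + shq * (A[3] - half_tr));
}

static inline void matvec2(const cplx M[4], const cplx v[2], cplx out[2]) {
  out[0] = M[0] * v[0] + M[1] * v[1];
  out[1] = M[2] * v[0] + M[3] * v[1];
}

// Exchange contribution to R2eff (intrinsic R2 = 0; it is additive) for a
// relaxation-compensated CPMG train: delta/2 - 180 - delta - ... - 180 - delta/2
// with n_pulses ideal 180s modeled as complex conjugation of the transverse
// magnetization. nu must already be snapped to admissible values
// (n = 2 * t_relax * nu an integer divisible by 4).
static double rex_one(double p_b, double k_ex, double dw_rad,
                      double nu, double t_relax);

// [[Rcpp::export]]
NumericVector bm_rex_curve_cpp(double p_b, double k_ex, double dw_rad,
                               NumericVector nu, double t_relax) {
  int m = nu.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j)
    out[j] = rex_one(p_b, k_ex, dw_rad, nu[j], t_relax);
  return out;
}

static double rex_one(double p_b, double k_ex, double dw_rad,
                      double nu_j, double t_relax) {
  double p_a = 1.0 - p_b;
  double k_ab = p_b * k_ex;
  double k_ba = p_a * k_ex;
  {
    int n = (int)std::lround(2.0 * t_relax * nu_j);
    double delta = t_relax / n;
    // generator of free evolution, rotating frame on state A
    cplx L[4] = { cplx(-k_ab, 0.0), cplx(k_ba, 0.0),
                  cplx(k_ab, 0.0), cplx(-k_ba, dw_rad) };
    cplx Uh[4], Uf[4];
    cplx Ah[4], Af[4];
    for (int i = 0; i < 4; ++i) { Ah[i] = L[i] * (delta / 2.0); Af[i] = L[i] * delta; }
    expm2(Ah, Uh);
    expm2(Af, Uf);
    cplx mvec[2] = { cplx(p_a, 0.0), cplx(p_b, 0.0) };
    cplx tmp[2];
    matvec2(Uh, mvec, tmp);
    mvec[0] = tmp[0]; mvec[1] = tmp[1];
    for (int k = 0; k < n - 1; ++k) {
      mvec[0] = std::conj(mvec[0]);
      mvec[1] = std::conj(mvec[1]);
      matvec2(Uf, mvec, tmp);
      mvec[0] = tmp[0]; mvec[1] = tmp[1];
    }
    mvec[0] = std::conj(mvec[0]);
    mvec[1] = std::conj(mvec[1]);
    matvec2(Uh, mvec, tmp);
    double mag = std::abs(tmp[0] + tmp[1]); // |m(0)| = p_a + p_b = 1
    return -std::log(mag) / t_relax;
  }
}

// chi^2 with the per-series exchange-free rate profiled out in closed form.
// Series are concatenated: series i occupies [start[i], start[i]+len[i]).
// [[Rcpp::export]]
List profiled_chi2_cpp(NumericVector p_b, NumericVector k_ex,
                       NumericVector dw_rad, NumericVector nu,
                       NumericVector obs, NumericVector w,
                       NumericVector t_relax, IntegerVector start,
                       IntegerVector len) {
  int ns = p_b.size();
  double chi2 = 0.0;
  NumericVector r2inf(ns);
  for (int i = 0; i < ns; ++i) {
    double sw = 0.0, swr = 0.0;
    int s0 = start[i];
    std::vector<double> rex(len[i]);
    for (int j = 0; j < len[i]; ++j) {
      rex[j] = rex_one(p_b[i], k_ex[i], dw_rad[i], nu[s0 + j], t_relax[i]);
      sw += w[s0 + j];
      swr += w[s0 + j] * (obs[s0 + j] - rex[j]);
    }
    double ri = swr / sw;
    r2inf[i] = ri;
    for (int j = 0; j < len[i]; ++j) {
      double r0 = obs[s0 + j] - rex[j] - ri;
      chi2 += w[s0 + j] * r0 * r0;
    }
  }
  return List::create(Named("chi2") = chi2, Named("r2inf") = r2inf);
}
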