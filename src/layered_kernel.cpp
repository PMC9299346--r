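#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hankel-space Green's function of the correlation diffusion equation for
// an N-layer half space, evaluated at the surface (z = 0), integrated
// against caller-supplied quadrature weights.
//
// Per layer i (surface first):
//   K_i^2(tau) = 3 mua_i musp_i + 6 musp_i^2 k0^2 D_i tau
//   alpha_i    = sqrt(s^2 + K_i^2)
//   Dp_i       = 1 / (3 musp_i)            (photon diffusion coefficient)
// The stack below layer 1 is collapsed into an effective boundary
// admittance zeta at z = L1 by the downward recursion
//   zeta_N = Dp_N alpha_N
//   zeta_i = Dp_i alpha_i (zeta_{i+1} + Dp_i alpha_i tanh(alpha_i L_i)) /
//            (Dp_i alpha_i + zeta_{i+1} tanh(alpha_i L_i)).
// With an isotropic point source at depth z0 and the extrapolated-zero
// plane at z = -zb, the surface Green's function is (only decaying
// exponentials; stable for arbitrarily thick layers):
//   P  = Dp_1 alpha_1,  u = e^{-alpha_1 z0},  v = e^{-alpha_1 zb},
//   e1 = e^{-alpha_1 (L1 - z0)},  E1 = e1^2,  E2 = (e1 u v)^2
//   phi = (1 - v^2) u [(P + zeta) + (P - zeta) E1] /
//         (2 P [(P + zeta) + (P - zeta) E2]).
// The semi-infinite (zeta = P) part of phi inverts to real space in
// closed form, so this kernel integrates only the layered correction
//   phi_corr = (1 - v^2) u (P - zeta)(E1 - E2) /
//              (2 P [(P + zeta) + (P - zeta) E2]),
// whose envelope decays like e^{-s (2 L1 - z0)} - much faster than the
// e^{-s z0} of the full integrand, and free of the large-cancellation
// oscillatory tail. The caller adds the closed-form semi-infinite part.
// The weights already fold in w_j * J0(s_j rho) * s_j, so the return
// value is the correction to unnormalized G1(tau) up to 1/(2 pi).
//
// [[Rcpp::export]]
NumericVector g1_layered_kernel(NumericVector s, NumericVector w,
                                NumericVector tau,
                                NumericVector mua, NumericVector musp,
                                NumericVector L, NumericVector bfi,
                                double k0, double z0, double zb) {
  const int ns = s.size(), nt = tau.size(), nl = mua.size();
  if (nl < 2) stop("need at least two layers");
  std::vector<double> s2(ns);
  for (int j = 0; j < ns; ++j) s2[j] = s[j] * s[j];

  std::vector<double> Dp(nl), c3(nl), bt(nl);
  for (int i = 0; i < nl; ++i) {
    Dp[i] = 1.0 / (3.0 * musp[i]);
    c3[i] = 3.0 * mua[i] * musp[i];
    bt[i] = 6.0 * musp[i] * musp[i] * k0 * k0 * bfi[i];
  }

  // Per-s caches for layers whose alpha does not depend on tau (D_i = 0):
  // middle layers need Dp*alpha and tanh(alpha L); the terminal layer
  // needs its admittance Dp*alpha.
  std::vector< std::vector<double> > cDa(nl), cTh(nl);
  for (int i = 1; i < nl; ++i) {
    if (bt[i] == 0.0) {
      cDa[i].resize(ns);
      if (i < nl - 1) cTh[i].resize(ns);
      for (int j = 0; j < ns; ++j) {
        double al = std::sqrt(s2[j] + c3[i]);
        cDa[i][j] = Dp[i] * al;
        if (i < nl - 1) cTh[i][j] = std::tanh(al * L[i]);
      }
    }
  }

  const double L1 = L[0];
  if (z0 >= L1) stop("source depth 1/musp exceeds the first layer thickness");
  NumericVector out(nt);

  for (int k = 0; k < nt; ++k) {
    const double t = tau[k];
    double acc = 0.0;
    std::vector<double> K2(nl);
    for (int i = 0; i < nl; ++i) K2[i] = c3[i] + bt[i] * t;
    for (int j = 0; j < ns; ++j) {
      // terminal layer admittance
      double zeta;
      if (bt[nl - 1] == 0.0) zeta = cDa[nl - 1][j];
      else zeta = Dp[nl - 1] * std::sqrt(s2[j] + K2[nl - 1]);
      // fold middle layers upward into zeta
      for (int i = nl - 2; i >= 1; --i) {
        double Da, th;
        if (bt[i] == 0.0) { Da = cDa[i][j]; th = cTh[i][j]; }
        else {
          double al = std::sqrt(s2[j] + K2[i]);
          Da = Dp[i] * al;
          th = std::tanh(al * L[i]);
        }
        zeta = Da * (zeta + Da * th) / (Da + zeta * th);
      }
      // surface layer
      const double a = std::sqrt(s2[j] + K2[0]);
      const double P = Dp[0] * a;
      const double u = std::exp(-a * z0);
      const double v = std::exp(-a * zb);
      const double e1 = std::exp(-a * (L1 - z0));
      const double E1 = e1 * e1;
      const double uv = u * v;
      const double E2 = E1 * uv * uv;
      const double num = (1.0 - v * v) * u * (P - zeta) * (E1 - E2);
      const double den = 2.0 * P * ((P + zeta) + (P - zeta) * E2);
      acc += w[j] * num / den;
    }
    out[k] = acc;
  }
  return out;
}

// Field autocorrelation from Monte Carlo photon records:
//   G1(tau_k) = (1/Np) sum_n  wabs_n * exp(-2 k0^2 tau_k * A_n)
// where A_n = sum_i Y_{n,i} D_i (momentum transfer weighted by layer flow)
// and wabs_n = exp(-sum_i mua_i L_{n,i}) are precomputed by the caller.
// Returned unnormalized (caller divides by G1(0) = mean(wabs)).
//
// [[Rcpp::export]]
NumericVector g1_records_kernel(NumericVector A, NumericVector wabs,
                                NumericVector tau, double k0) {
  const R_xlen_t np = A.size();
  const int nt = tau.size();
  if (wabs.size() != np) stop("A and wabs must have equal length");
  NumericVector out(nt);
  const double c = 2.0 * k0 * k0;
  for (int k = 0; k < nt; ++k) {
    const double ct = c * tau[k];
    double acc = 0.0;
    for (R_xlen_t n = 0; n < np; ++n) {
      acc += wabs[n] * std::exp(-ct * A[n]);
    }
    out[k] = acc / (double)np;
  }
  return out;
}
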