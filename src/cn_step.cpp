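// Crank-Nicolson step for the 1D clothing/air-gap conduction-radiation
// problem. Nonlinear terms (temperature-dependent conductivities, T^4
// radiation at the outer surface and across the gap, in-depth Beer sources)
// are lagged and the tridiagonal system is solved exactly (Thomas algorithm)
// inside a point-iteration loop that sweeps until the max temperature change
// falls below tol. The last node is the skin surface (Dirichlet).

#include <Rcpp.h>
using namespace Rcpp;

static const double SIG = 5.670374e-8;

static inline double k_air_T(double T) { return 0.026 + 0.000068 * (T - 300.0); }
static inline double k_mix_T(double T) {
  return 0.8 * k_air_T(T) + 0.2 * (0.13 + 0.0018 * (T - 300.0));
}

// [[Rcpp::export(name = ".cn_clothing_step")]]
List cn_clothing_step(NumericVector Tn_in, NumericVector dx, IntegerVector mat,
                      NumericVector k_scale, NumericVector cv,
                      NumericVector frac_src, double frac_src_skin,
                      NumericVector frac_gap, double frac_gap_skin,
                      int idx_liner, bool has_gap, double T_skin, double dt,
                      bool exposure, double h_conv, double T_amb,
                      double eps_shell, double F_sa, double eps_g,
                      double F_hs, double eps_hs, double T_hs, double A_ratio,
                      double sigma_eff_gap, double Nu_gap,
                      double tol, int maxit) {
  const int N = Tn_in.size();
  const int M = N - 1;            // unknowns: nodes 0..N-2 (0-based)
  const int il = idx_liner - 1;   // liner inner-surface node, 0-based
  std::vector<double> Tn(Tn_in.begin(), Tn_in.end());
  Tn[N - 1] = T_skin; // Dirichlet held at the supplied value over the step
  std::vector<double> Tit(Tn), Tnew(Tn);
  std::vector<double> w(N - 1), a(M), b(M), c(M), d(M), cp(M), dp(M);

  const double rad_att = exposure ? F_sa * (1.0 - eps_g) : 1.0;
  const double Ths4 = T_hs * T_hs * T_hs * T_hs;
  const double Tamb4 = T_amb * T_amb * T_amb * T_amb;

  double q_rad = 0.0, q_gap = 0.0, rad_loss = 0.0, max_ch = 0.0;
  int it = 0;
  bool converged = false;

  for (it = 1; it <= maxit; ++it) {
    // interval conductances at the CN mid-temperature of the current iterate
    for (int i = 0; i < N - 1; ++i) {
      double Tf = 0.25 * (Tn[i] + Tn[i + 1] + Tit[i] + Tit[i + 1]);
      double k = (mat[i] > 0) ? k_scale[i] * k_mix_T(Tf) : Nu_gap * k_air_T(Tf);
      w[i] = k / dx[i];
    }
    // nonlinear fluxes at the CN mid-temperature
    double T0m = 0.5 * (Tn[0] + Tit[0]);
    double T0m4 = T0m * T0m * T0m * T0m;
    q_rad = 0.0;
    if (exposure) {
      q_rad = F_hs * SIG * (eps_hs * Ths4 - eps_shell * T0m4) * A_ratio -
              SIG * eps_shell * F_sa * (1.0 - eps_g) * (T0m4 - Tamb4);
    }
    rad_loss = SIG * eps_shell * rad_att * (T0m4 - Tamb4);
    q_gap = 0.0;
    if (has_gap && sigma_eff_gap > 0.0) {
      double Tlm = 0.5 * (Tn[il] + Tit[il]);
      double Ts4 = T_skin * T_skin * T_skin * T_skin;
      q_gap = sigma_eff_gap * (Tlm * Tlm * Tlm * Tlm - Ts4);
    }
    // assemble the tridiagonal CN system
    for (int i = 0; i < M; ++i) {
      double wim = (i > 0) ? w[i - 1] : 0.0;
      double wip = w[i];
      double m = cv[i] / dt;
      a[i] = (i > 0) ? -0.5 * wim : 0.0;
      b[i] = m + 0.5 * (wim + wip);
      c[i] = (i < M - 1) ? -0.5 * wip : 0.0;
      double expl = wip * (Tn[i + 1] - Tn[i]);
      if (i > 0) expl -= wim * (Tn[i] - Tn[i - 1]);
      double S = 0.0;
      if (exposure) S += frac_src[i] * q_rad;
      S += frac_gap[i] * q_gap;
      if (i == il) S -= q_gap;
      d[i] = m * Tn[i] + 0.5 * expl + S;
      if (i == 0) {
        // conv loss h*(T0mid - Tamb): 0.5*h*T0^{n+1} implicit on the
        // diagonal, the rest explicit on the RHS; radiative loss lagged
        b[i] += 0.5 * h_conv;
        d[i] += -0.5 * h_conv * Tn[0] + h_conv * T_amb - rad_loss;
      }
      if (i == M - 1) d[i] += 0.5 * w[N - 2] * T_skin; // Dirichlet neighbour
    }
    // Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int i = 1; i < M; ++i) {
      double den = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / den;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / den;
    }
    Tnew[M - 1] = dp[M - 1];
    for (int i = M - 2; i >= 0; --i) Tnew[i] = dp[i] - cp[i] * Tnew[i + 1];
    Tnew[N - 1] = T_skin;
    max_ch = 0.0;
    for (int i = 0; i < M; ++i) {
      double ch = std::fabs(Tnew[i] - Tit[i]);
      if (ch > max_ch) max_ch = ch;
      Tit[i] = Tnew[i];
    }
    if (max_ch < tol) { converged = true; break; }
  }

  bool diverged = false;
  for (int i = 0; i < N; ++i) {
    if (!std::isfinite(Tnew[i]) || Tnew[i] <= 200.0 || Tnew[i] >= 1500.0) diverged = true;
  }

  // CN-mid diagnostics for the energy audit and the skin coupling
  double Tm_last = 0.5 * (Tn[N - 2] + Tnew[N - 2]);
  double q_cond_skin = w[N - 2] * (Tm_last - T_skin);
  double q_skin = q_cond_skin + q_gap * frac_gap_skin;
  if (exposure) q_skin += q_rad * frac_src_skin;
  double T0m = 0.5 * (Tn[0] + Tnew[0]);
  double conv_loss = h_conv * (T0m - T_amb);
  double sum_src = 0.0, sum_gap = 0.0;
  for (int i = 0; i < M; ++i) { sum_src += frac_src[i]; sum_gap += frac_gap[i]; }

  return List::create(
    _["T"] = NumericVector(Tnew.begin(), Tnew.end()),
    _["iters"] = it, _["max_change"] = max_ch, _["converged"] = converged,
    _["diverged"] = diverged,
    _["q_skin"] = q_skin, _["q_cond_skin"] = q_cond_skin,
    _["q_rad"] = q_rad, _["q_gap"] = q_gap,
    _["surf_loss"] = conv_loss + rad_loss, _["conv_loss"] = conv_loss,
    _["rad_loss"] = rad_loss,
    _["absorbed_src"] = q_rad * sum_src, _["absorbed_gap"] = q_gap * sum_gap);
}
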