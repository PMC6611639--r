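#include <Rcpp.h>
using namespace Rcpp;

static inline double hill(double c, double theta, double m) {
  if (c <= 0.0) return 0.0;
  double num = std::pow(c, m);
  return num / (num + std::pow(theta, m));
}

// Forward-Euler integration of the reporter equation for a tester exposed to a
// set of constant effective signal concentrations. All runs share the same
// logistic growth trajectory and a common no-signal baseline, so the whole
// batch is integrated in one pass; returns the LacZ fold change (final LacZ of
// each run over the final LacZ of the no-signal baseline).
// [[Rcpp::export]]
NumericVector cpp_fold_const(double f, double theta, double m,
                             double rho_L, double gamma_L, double mu_min,
                             double n0, double s, double dt, int nsteps,
                             NumericVector ceff) {
  int K = ceff.size();
  std::vector<double> act(K);
  for (int k = 0; k < K; ++k) {
    double ce = ceff[k] > 0.0 ? ceff[k] : 0.0;
    act[k] = f * hill(ce, theta, m) + 1.0;
  }
  double n = n0, L0 = 0.0;
  std::vector<double> L(K, 0.0);
  for (int t = 0; t < nsteps; ++t) {
    double base = dt * rho_L * n;
    for (int k = 0; k < K; ++k) {
      L[k] += base * act[k] - dt * gamma_L * L[k];
      if (L[k] < 0.0) L[k] = 0.0;
    }
    L0 += base - dt * gamma_L * L0;
    if (L0 < 0.0) L0 = 0.0;
    n += dt * mu_min * n * (1.0 - n / s);
    if (n < 0.0) n = 0.0;
  }
  if (L0 <= 0.0) stop("degenerate baseline: no-signal LacZ is zero (rho_L = 0?)");
  NumericVector out(K);
  for (int k = 0; k < K; ++k) out[k] = L[k] / L0;
  return out;
}

// Full coupled forward-Euler simulation of cell densities, signal
// concentrations and (optionally) the LacZ reporter of one tester strain.
//
// Strains flagged as producers synthesise signal at a QS-regulated rate; for
// non-producers the signal is an exogenous bolus which is either held constant
// or allowed to decay at gamma_c. Perturbations are instantaneous
// concentration increments applied at a given step.
// [[Rcpp::export]]
List cpp_simulate(NumericVector f, NumericVector theta, NumericVector m,
                  NumericVector rho_L, NumericVector gamma_L,
                  NumericVector rho_c, NumericVector gamma_c,
                  NumericVector mu_min,
                  NumericMatrix W, double s, double dt, int nsteps,
                  NumericVector n0, NumericVector c0,
                  LogicalVector producer, int tester, bool tester_decay,
                  IntegerVector pert_step, IntegerVector pert_strain,
                  NumericVector pert_dc) {
  int k = f.size();
  if (W.nrow() != k || W.ncol() != k)
    stop("weight matrix dimensions do not match the number of strains");
  NumericMatrix n(nsteps + 1, k), c(nsteps + 1, k);
  NumericVector L(nsteps + 1), times(nsteps + 1);
  std::vector<double> ncur(k), ccur(k), ceff(k), H(k);
  for (int i = 0; i < k; ++i) { ncur[i] = n0[i]; ccur[i] = c0[i]; }
  double Lcur = 0.0;
  int npert = pert_step.size();

  for (int p = 0; p < npert; ++p)
    if (pert_step[p] == 0) ccur[pert_strain[p]] += pert_dc[p];
  for (int i = 0; i < k; ++i) { n(0, i) = ncur[i]; c(0, i) = ccur[i]; }
  L[0] = 0.0; times[0] = 0.0;

  for (int t = 0; t < nsteps; ++t) {
    double ntot = 0.0;
    for (int i = 0; i < k; ++i) ntot += ncur[i];
    for (int i = 0; i < k; ++i) {
      double ce = 0.0;
      for (int j = 0; j < k; ++j) ce += W(i, j) * ccur[j];
      ceff[i] = ce > 0.0 ? ce : 0.0;
      H[i] = hill(ceff[i], theta[i], m[i]);
    }
    if (tester >= 0) {
      int i = tester;
      Lcur += dt * (rho_L[i] * ncur[i] * (f[i] * H[i] + 1.0) - gamma_L[i] * Lcur);
      if (Lcur < 0.0) Lcur = 0.0;
    }
    for (int i = 0; i < k; ++i) {
      if (producer[i]) {
        ccur[i] += dt * (rho_c[i] * ncur[i] * (f[i] * H[i] + 1.0) -
                         gamma_c[i] * ccur[i]);
      } else if (tester_decay) {
        ccur[i] += dt * (-gamma_c[i] * ccur[i]);
      }
      if (ccur[i] < 0.0) ccur[i] = 0.0;
    }
    for (int i = 0; i < k; ++i) {
      ncur[i] += dt * mu_min[i] * ncur[i] * (1.0 - ntot / s);
      if (ncur[i] < 0.0) ncur[i] = 0.0;
    }
    double tnext = (t + 1) * dt;
    for (int p = 0; p < npert; ++p)
      if (pert_step[p] == t + 1) ccur[pert_strain[p]] += pert_dc[p];
    for (int i = 0; i < k; ++i) {
      if (!std::isfinite(ncur[i]))
        stop("non-finite cell density for strain %d at t = %f min", i + 1, tnext);
      if (!std::isfinite(ccur[i]))
        stop("non-finite signal concentration for strain %d at t = %f min",
             i + 1, tnext);
      n(t + 1, i) = ncur[i];
      c(t + 1, i) = ccur[i];
    }
    if (tester >= 0 && !std::isfinite(Lcur))
      stop("non-finite LacZ for the tester at t = %f min", tnext);
    L[t + 1] = Lcur;
    times[t + 1] = tnext;
  }
  return List::create(_["times"] = times, _["n"] = n, _["c"] = c,
                      _["L"] = (tester >= 0) ? L : NumericVector(0));
}
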