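// Dormand-Prince 4(5) adaptive explicit integrator for the SEIV/SEIVD
// pairwise and community models. The R-level rhs functions in R/models.R are
// the readable reference; these compiled kernels exist because Bayesian
// fitting needs ~1e5 trajectory solves per chain set.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- model right-hand sides -------------------------------------------

struct PairwisePars {
  double r, phi, tau, beta, dc, hill, K;
  int n_e;
  bool adsorb_inf;
};

static inline double hill_theta(double D, double dc, double n) {
  if (!R_FINITE(dc)) return 1.0;
  if (D < 0) D = 0;
  return 1.0 / (1.0 + std::pow(D / dc, n));
}

// densities are physically non-negative; tiny negative excursions from the
// embedded error estimate are treated as zero when forming fluxes, so they
// decay instead of feeding mass into the chain
static inline double nn(double x) { return x > 0 ? x : 0.0; }

// state: S, E1..En, I, V, D
static void pairwise_rhs(const double* y, double* dy, const PairwisePars& p) {
  const int n_e = p.n_e;
  const double S = nn(y[0]);
  const double I = nn(y[n_e + 1]);
  const double V = nn(y[n_e + 2]);
  const double D = y[n_e + 3];
  const double k = (n_e + 1) / p.tau;
  const double theta = hill_theta(D, p.dc, p.hill);
  const double infection = theta * p.phi * S * V;
  double chain_sum = I;
  for (int m = 0; m < n_e; ++m) chain_sum += nn(y[1 + m]);
  double growth = p.r * S;
  if (R_FINITE(p.K)) growth *= 1.0 - (S + chain_sum) / p.K;
  dy[0] = growth - infection;
  if (n_e > 0) {
    dy[1] = infection - k * nn(y[1]);
    for (int m = 1; m < n_e; ++m) dy[1 + m] = k * (nn(y[m]) - nn(y[1 + m]));
    dy[n_e + 1] = k * (nn(y[n_e]) - I);
  } else {
    dy[1] = infection - k * I;
  }
  double sink = theta * p.phi * V * (S + (p.adsorb_inf ? chain_sum : 0.0));
  dy[n_e + 2] = p.beta * k * I - sink;
  dy[n_e + 3] = k * I;
}

struct CommunityPars {
  int nh, np, npair, n_state, v_off;
  std::vector<int> host, phage, n_e, pair_off;
  std::vector<double> r, phi, beta, k, dc;
  double hill;
  bool adsorb_inf;
};

// state: S_1..S_nh | per pair E1..En,I | V_1..V_np | D
static void community_rhs_c(const double* y, double* dy,
                            const CommunityPars& p) {
  const double D = y[p.n_state - 1];
  for (int i = 0; i < p.nh; ++i) dy[i] = p.r[i] * nn(y[i]);
  for (int j = 0; j < p.np; ++j) dy[p.v_off + j] = 0.0;
  double dD = 0.0;
  for (int q = 0; q < p.npair; ++q) {
    const int i = p.host[q], j = p.phage[q];
    const int n_e = p.n_e[q], off = p.pair_off[q];
    const double k = p.k[q];
    const double theta = hill_theta(D, p.dc[i], p.hill);
    const double S = nn(y[i]), V = nn(y[p.v_off + j]);
    const double I = nn(y[off + n_e]);
    const double infection = theta * p.phi[q] * S * V;
    dy[i] -= infection;
    double chain_sum = I;
    for (int m = 0; m < n_e; ++m) chain_sum += nn(y[off + m]);
    if (n_e > 0) {
      dy[off] = infection - k * nn(y[off]);
      for (int m = 1; m < n_e; ++m) {
        dy[off + m] = k * (nn(y[off + m - 1]) - nn(y[off + m]));
      }
      dy[off + n_e] = k * (nn(y[off + n_e - 1]) - I);
    } else {
      dy[off] = infection - k * I;
    }
    double sink = p.adsorb_inf ? theta * p.phi[q] * V * chain_sum : 0.0;
    dy[p.v_off + j] += p.beta[q] * k * I - infection - sink;
    dD += k * I;
  }
  dy[p.n_state - 1] = dD;
}

// ---- DP45 driver -------------------------------------------------------

// Dormand-Prince RK5(4)7M coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

template <class RHS>
static NumericMatrix dp45_solve(NumericVector y0, NumericVector times,
                                double rtol, double atol, const RHS& rhs,
                                double max_step) {
  const int n = y0.size(), nt = times.size();
  NumericMatrix out(nt, n);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), y5(n);
  double t = times[0];
  for (int j = 0; j < n; ++j) out(0, j) = y[j];
  rhs(y.data(), k1.data());
  double h = (times[nt - 1] - t) * 1e-4;
  if (max_step > 0 && h > max_step) h = max_step;
  for (int it = 1; it < nt; ++it) {
    const double t_target = times[it];
    while (t < t_target) {
      if (h > t_target - t) h = t_target - t;
      if (max_step > 0 && h > max_step) h = max_step;
      if (h < 1e-13 * std::max(1.0, std::fabs(t))) {
        stop("integration failure: step size underflow at t = %f", t);
      }
      // stages
      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      rhs(ytmp.data(), k2.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      rhs(ytmp.data(), k3.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      rhs(ytmp.data(), k4.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      rhs(ytmp.data(), k5.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      rhs(ytmp.data(), k6.data());
      for (int j = 0; j < n; ++j)
        y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
      rhs(y5.data(), k7.data());
      // error estimate (5th - 4th)
      double err = 0.0;
      bool bad = false;
      for (int j = 0; j < n; ++j) {
        const double y4 = y[j] + h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                      e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        if (!R_FINITE(y5[j])) { bad = true; break; }
        const double sc =
            atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
        const double d = (y5[j] - y4) / sc;
        err += d * d;
      }
      err = bad ? 1e10 : std::sqrt(err / n);
      if (err <= 1.0) {
        // non-negativity constraint: project small negative excursions
        // (within solver tolerance) back onto the positive orthant
        bool refresh = false;
        for (int j = 0; j < n; ++j) {
          if (y5[j] < 0) {
            const double tol_neg =
                100.0 * (atol + rtol * std::fabs(y[j]));
            if (y5[j] < -tol_neg) {
              stop("integration failure: negative excursion %g at t = %f",
                   y5[j], t + h);
            }
            y5[j] = 0.0;
            refresh = true;
          }
        }
        t += h;
        y.swap(y5);
        if (refresh) {
          rhs(y.data(), k7.data());
        }
        k1.swap(k7); // FSAL
      }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    }
    for (int j = 0; j < n; ++j) out(it, j) = y[j];
    t = t_target;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dp45_pairwise(NumericVector y0, NumericVector times,
                            List pars, double rtol, double atol,
                            double max_step = -1.0) {
  PairwisePars p;
  p.r = pars["r"]; p.phi = pars["phi"]; p.tau = pars["tau"];
  p.beta = pars["beta"]; p.dc = pars["d_c"]; p.hill = pars["hill"];
  p.K = pars["carrying_capacity"];
  p.n_e = pars["n_e"];
  p.adsorb_inf = pars["adsorb_to_infected"];
  if (y0.size() != p.n_e + 4) stop("state length does not match n_e");
  auto rhs = [&p](const double* y, double* dy) { pairwise_rhs(y, dy, p); };
  return dp45_solve(y0, times, rtol, atol, rhs, max_step);
}

// [[Rcpp::export]]
NumericMatrix dp45_community(NumericVector y0, NumericVector times,
                             List pars, double rtol, double atol,
                             double max_step = -1.0) {
  CommunityPars p;
  p.nh = pars["nh"]; p.np = pars["np"]; p.npair = pars["npair"];
  p.n_state = pars["n_state"]; p.v_off = pars["v_off"];
  p.host = as<std::vector<int>>(pars["host_idx0"]);
  p.phage = as<std::vector<int>>(pars["phage_idx0"]);
  p.n_e = as<std::vector<int>>(pars["n_e"]);
  p.pair_off = as<std::vector<int>>(pars["pair_off0"]);
  p.r = as<std::vector<double>>(pars["r_host"]);
  p.phi = as<std::vector<double>>(pars["phi"]);
  p.beta = as<std::vector<double>>(pars["beta"]);
  p.k = as<std::vector<double>>(pars["k"]);
  p.dc = as<std::vector<double>>(pars["d_c"]);
  p.hill = pars["hill"];
  p.adsorb_inf = pars["adsorb_to_infected"];
  if (y0.size() != p.n_state) stop("state length does not match layout");
  auto rhs = [&p](const double* y, double* dy) { community_rhs_c(y, dy, p); };
  return dp45_solve(y0, times, rtol, atol, rhs, max_step);
}
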