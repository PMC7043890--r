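// Inner loops of the voltage-clamp and dynamic-clamp simulators.
//
// Occupancies are row vectors advanced by right-multiplication with
// precomputed row-stochastic transition matrices (matrix-method stepping).
// The hybrid loop looks the transition matrix up on a voltage grid with
// linear interpolation between neighbouring grid matrices; a convex
// combination of row-stochastic matrices is row-stochastic, so the
// conservation contract is preserved exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_chain(const arma::rowvec& P0, const arma::mat& M, int n) {
  const int k = P0.n_elem;
  arma::mat out(n, k);
  arma::rowvec P = P0;
  for (int i = 0; i < n; ++i) {
    P = P * M;
    out.row(i) = P;
  }
  return out;
}

static inline double sum_at(const arma::rowvec& P, const arma::uvec& idx) {
  double s = 0.0;
  for (arma::uword i = 0; i < idx.n_elem; ++i) s += P(idx(i));
  return s;
}

static inline void advance_grid(arma::rowvec& P, const arma::cube& tm,
                                double vpos) {
  const int nv = tm.n_slices;
  int i0 = (int)std::floor(vpos);
  if (i0 < 0) i0 = 0;
  if (i0 > nv - 2) i0 = nv - 2;
  double w = vpos - i0;
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  P = (1.0 - w) * (P * tm.slice(i0)) + w * (P * tm.slice(i0 + 1));
}

// [[Rcpp::export]]
List cpp_hybrid(const arma::cube& tm1, const arma::cube& tm2, bool has2,
                arma::rowvec P1, arma::rowvec P2,
                const arma::uvec& open1, const arma::uvec& open2,
                const arma::uvec& slow1, const arma::uvec& slow2,
                double v0, double dv,
                double dt, int n_steps,
                List host,
                const arma::vec& iinj, const arma::ivec& inject,
                double gna_tot,
                double v_init, double n_init, double z_init,
                int out_every) {
  const double cm      = host["cm"];
  const double g_leak  = host["g_leak"];
  const double e_leak  = host["e_leak"];
  const double g_k     = host["g_k"];
  const double e_k     = host["e_k"];
  const double n_vh    = host["n_vhalf"];
  const double n_sl    = host["n_slope"];
  const double tau_n   = host["tau_n"];
  const double tau_n_slow = host["tau_n_slow"];
  const double tau_n_vh   = host["tau_n_vhalf"];
  const double tau_n_sl   = host["tau_n_kslope"];
  const double n_pow   = host["n_pow"];
  const double g_ad    = host["g_adapt"];
  const double e_ad    = host["e_adapt"];
  const double z_vh    = host["z_vhalf"];
  const double z_sl    = host["z_slope"];
  const double tau_z   = host["tau_z"];
  const double g_sh    = host["g_shoulder"];
  const double e_sh    = host["e_shoulder"];
  const double s_vh    = host["s_vhalf"];
  const double s_sl    = host["s_slope"];
  const double tau_s   = host["tau_s"];
  const double i_bias  = host["i_bias"];
  const double e_na    = host["e_na"];

  const int nv = tm1.n_slices;
  const double v_max = v0 + dv * (nv - 1);
  const double ez_dt = std::exp(-dt / tau_z);
  const double es_dt = std::exp(-dt / tau_s);
  const bool tau_n_fixed = tau_n_slow == tau_n;
  const double en_dt_fast = std::exp(-dt / tau_n);

  const bool iinj_vec = iinj.n_elem > 1;
  const bool inj_vec = inject.n_elem > 1;

  const int n_out = n_steps / out_every + 1;
  arma::vec t_out(n_out), v_out(n_out), ina_out(n_out), n_out_v(n_out);
  arma::vec po1_out(n_out), ps1_out(n_out), po2_out(n_out), ps2_out(n_out);

  double V = v_init, n = n_init, z = z_init;
  double s = 1.0 / (1.0 + std::exp(-(v_init - s_vh) / s_sl));
  int status = 0;
  double t_fail = NA_REAL;
  double cons_err = 0.0;
  int written = 0;

  auto record = [&](int step) {
    t_out(written) = step * dt;
    v_out(written) = V;
    n_out_v(written) = n;
    double po1 = sum_at(P1, open1);
    double po2 = has2 ? sum_at(P2, open2) : NA_REAL;
    int m = inj_vec ? inject(step < (int)inject.n_elem ? step : inject.n_elem - 1)
                    : inject(0);
    double po_inj = (m == 2 && has2) ? po2 : po1;
    ina_out(written) = gna_tot * po_inj * (V - e_na);
    po1_out(written) = po1;
    ps1_out(written) = slow1.n_elem ? sum_at(P1, slow1) : 0.0;
    po2_out(written) = po2;
    ps2_out(written) = (has2 && slow2.n_elem) ? sum_at(P2, slow2) : NA_REAL;
    ++written;
  };
  record(0);

  for (int step = 0; step < n_steps; ++step) {
    // matrix-method advance of the channel occupancies at the present V
    double vpos = (V - v0) / dv;
    advance_grid(P1, tm1, vpos);
    if (has2) advance_grid(P2, tm2, vpos);

    // injected sodium current from the active model's open probability
    int m = inj_vec ? inject(step) : inject(0);
    double po = (m == 2 && has2) ? sum_at(P2, open2) : sum_at(P1, open1);
    double i_na = gna_tot * po * (V - e_na);

    // host gates (exact exponential relaxation), then Euler membrane step
    double ninf = 1.0 / (1.0 + std::exp(-(V - n_vh) / n_sl));
    double en_dt = en_dt_fast;
    if (!tau_n_fixed) {
      // K kinetics slow down at hyperpolarised potentials (slow
      // deactivation paces the interspike release)
      double tn = tau_n + (tau_n_slow - tau_n) /
        (1.0 + std::exp((V - tau_n_vh) / tau_n_sl));
      en_dt = std::exp(-dt / tn);
    }
    n = ninf + (n - ninf) * en_dt;
    if (g_ad > 0) {
      double zinf = 1.0 / (1.0 + std::exp(-(V - z_vh) / z_sl));
      z = zinf + (z - zinf) * ez_dt;
    }
    double i_sh = 0.0;
    if (g_sh > 0) {
      double sinf = 1.0 / (1.0 + std::exp(-(V - s_vh) / s_sl));
      s = sinf + (s - sinf) * es_dt;
      i_sh = g_sh * s * (V - e_sh);
    }
    double i_k = g_k * std::pow(n, n_pow) * (V - e_k);
    double i_l = g_leak * (V - e_leak);
    double i_ad = g_ad * z * (V - e_ad);
    double i_in = iinj_vec ? iinj(step) : iinj(0);
    V += dt * (-(i_l + i_k + i_ad + i_sh + i_na) + i_bias + i_in) / cm;

    if (!(V >= v0 && V <= v_max)) {
      status = 1;
      t_fail = (step + 1) * dt;
      break;
    }
    if ((step + 1) % out_every == 0 && written < n_out) record(step + 1);
    if ((step + 1) % 5000 == 0) {
      double e1 = std::abs(arma::accu(P1) - 1.0);
      double e2 = has2 ? std::abs(arma::accu(P2) - 1.0) : 0.0;
      cons_err = std::max(cons_err, std::max(e1, e2));
    }
  }
  double e1 = std::abs(arma::accu(P1) - 1.0);
  double e2 = has2 ? std::abs(arma::accu(P2) - 1.0) : 0.0;
  cons_err = std::max(cons_err, std::max(e1, e2));

  return List::create(
    _["times"] = t_out.head(written),
    _["V"] = v_out.head(written),
    _["n_gate"] = n_out_v.head(written),
    _["I_Na"] = ina_out.head(written),
    _["Po1"] = po1_out.head(written),
    _["Ps1"] = ps1_out.head(written),
    _["Po2"] = po2_out.head(written),
    _["Ps2"] = ps2_out.head(written),
    _["P1_final"] = P1,
    _["P2_final"] = P2,
    _["conservation_err"] = cons_err,
    _["status"] = status,
    _["t_fail"] = t_fail);
}
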