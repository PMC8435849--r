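#include <Rcpp.h>
#include "models.h"
using namespace Rcpp;

static GtACR1Pars unpack_gtacr1(const NumericVector& p) {
  GtACR1Pars g;
  g.g_max = p["g_max"]; g.E_rev = p["E_rev"]; g.tau_on = p["tau_on"];
  g.tau_off = p["tau_off"]; g.c_num = p["c_num"]; g.c_den0 = p["c_den0"];
  g.c_den1 = p["c_den1"]; g.e_offset = p["e_offset"];
  return g;
}

static ChR2Pars unpack_chr2(const NumericVector& p) {
  ChR2Pars c;
  c.g_max = p["g_max"]; c.E_rev = p["E_rev"]; c.gamma = p["gamma"];
  c.eps1 = p["eps1"]; c.eps2 = p["eps2"]; c.Gd1_base = p["Gd1_base"];
  c.Gd1_amp = p["Gd1_amp"]; c.Gd2 = p["Gd2"]; c.Gr0 = p["Gr0"];
  c.Gr_vdep = p["Gr_vdep"]; c.e12_dark = p["e12_dark"]; c.e12_c = p["e12_c"];
  c.e12_scale = p["e12_scale"]; c.e21_dark = p["e21_dark"];
  c.e21_c = p["e21_c"]; c.e21_scale = p["e21_scale"]; c.tau_p = p["tau_p"];
  c.theta_half = p["theta_half"]; c.flux_factor = p["flux_factor"];
  return c;
}

// Single-myocyte simulation with electrical stimuli and an optional
// light-gated opsin current.  model: 0 = ventricular (TT06 epi),
// 1 = atrial (CRN).  opsin: 0 = none, 1 = GtACR1, 2 = ChR2 family.
// stim: matrix with columns (start_ms, dur_ms, amp_pA_pF);
// light: matrix with columns (start_ms, dur_ms, Ee_mW_mm2).
template <class Model>
static List cell_run_t(NumericVector y0, double dt, int n_steps,
                       int record_every, NumericMatrix stim,
                       NumericMatrix light, int opsin,
                       NumericVector opsin_pars, NumericVector opsin0,
                       NumericVector scales) {
  Model M(dt);
  if (y0.size() != Model::NSTATE) stop("bad state length");
  std::vector<double> y(y0.begin(), y0.end());
  RegionScale rs;
  for (int k = 0; k < 4; ++k) rs.s[k] = scales[k];

  GtACR1Pars gp{}; ChR2Pars cp{};
  double ops_state[5] = {0, 0, 0, 0, 0};
  if (opsin == 1) {
    gp = unpack_gtacr1(opsin_pars);
    ops_state[0] = opsin0[0];
  } else if (opsin == 2) {
    cp = unpack_chr2(opsin_pars);
    for (int k = 0; k < 5; ++k) ops_state[k] = opsin0[k];
  }

  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  const int n_stim = stim.nrow(), n_light = light.nrow();
  NumericVector t_out(n_rec), v_out(n_rec), iops_out(n_rec), ee_out(n_rec);
  int ir = 0;

  // light state caches
  double cur_ee = -1.0, g_pss = 0.0, g_dec = 1.0;
  double c_k1f = 0, c_k2f = 0, c_e12 = 0, c_e21 = 0, c_S0 = 0, c_pdec = 1.0;

  for (int s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    double istim = 0.0;
    for (int k = 0; k < n_stim; ++k)
      if (t >= stim(k, 0) && t < stim(k, 0) + stim(k, 1)) istim += stim(k, 2);
    double ee = 0.0;
    for (int k = 0; k < n_light; ++k)
      if (t >= light(k, 0) && t < light(k, 0) + light(k, 1)) ee += light(k, 2);

    if (ee != cur_ee) {
      cur_ee = ee;
      if (opsin == 1) {
        double kco = gp.opening_rate(ee);
        double koc = 1.0 / gp.tau_off;
        g_pss = kco / (kco + koc);
        g_dec = std::exp(-(kco + koc) * dt);
      } else if (opsin == 2) {
        double F = cp.flux_factor * ee;
        c_k1f = cp.eps1 * F; c_k2f = cp.eps2 * F;
        c_e12 = cp.e12_dark + cp.e12_c * std::log(1.0 + ee / cp.e12_scale);
        c_e21 = cp.e21_dark + cp.e21_c * std::log(1.0 + ee / cp.e21_scale);
        c_S0 = 0.5 * (1.0 + std::tanh(120.0 * (ee - cp.theta_half)));
        c_pdec = std::exp(-dt / cp.tau_p);
      }
    }

    double iops = 0.0;
    if (opsin == 1)
      iops = ops_state[0] * gp.g_max * (y[0] - gp.E_rev);
    else if (opsin == 2)
      iops = cp.g_max * ChR2Pars::rect(y[0]) *
             (ops_state[1] + cp.gamma * ops_state[2]) * (y[0] - cp.E_rev);

    if (record_every > 0 && s % record_every == 0 && ir < n_rec) {
      t_out[ir] = t; v_out[ir] = y[0]; iops_out[ir] = iops; ee_out[ir] = ee;
      ++ir;
    }
    if (s == n_steps) break;

    // advance opsin then membrane
    if (opsin == 1)
      ops_state[0] = g_pss + (ops_state[0] - g_pss) * g_dec;
    else if (opsin == 2)
      chr2_node_step(ops_state, y[0], dt, c_k1f, c_k2f, c_e12, c_e21, c_S0,
                     c_pdec, cp);
    Nernst E;
    Model::nernst(y.data(), E);
    y[0] += M.step(y.data(), iops, istim, rs, E);
    if (!std::isfinite(y[0]))
      stop("non-finite membrane voltage at t = %f ms", t);
  }

  NumericVector yout(y.begin(), y.end());
  NumericVector opsout(ops_state, ops_state + 5);
  return List::create(_["time_ms"] = t_out, _["V_mV"] = v_out,
                      _["I_opsin"] = iops_out, _["Ee"] = ee_out,
                      _["state"] = yout, _["opsin_state"] = opsout);
}

// [[Rcpp::export]]
List cell_run_cpp(int model, NumericVector y0, double dt, int n_steps,
                  int record_every, NumericMatrix stim, NumericMatrix light,
                  int opsin, NumericVector opsin_pars, NumericVector opsin0,
                  NumericVector scales) {
  if (model == 0)
    return cell_run_t<TT06>(y0, dt, n_steps, record_every, stim, light,
                            opsin, opsin_pars, opsin0, scales);
  return cell_run_t<CRN>(y0, dt, n_steps, record_every, stim, light, opsin,
                         opsin_pars, opsin0, scales);
}

// [[Rcpp::export]]
NumericVector cell_initial_state_cpp(int model) {
  if (model == 0) {
    NumericVector y(TT06::NSTATE);
    TT06::init_state(REAL(y));
    return y;
  }
  NumericVector y(CRN::NSTATE);
  CRN::init_state(REAL(y));
  return y;
}
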