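#include <Rcpp.h>
#include "models.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sparse symmetric operator in CSC (= CSR) layout taken from a dgCMatrix.
// ---------------------------------------------------------------------------
struct SpMat {
  int n;
  const int* p;
  const int* i;
  const double* x;
  void matvec(const double* v, double* out) const {
    for (int c = 0; c < n; ++c) out[c] = 0.0;
    for (int c = 0; c < n; ++c) {
      double vc = v[c];
      for (int k = p[c]; k < p[c + 1]; ++k) out[i[k]] += x[k] * vc;
    }
  }
};

// Conjugate gradient for (I - c A) u = b with Jacobi preconditioning.
// u holds the initial guess on entry.  Returns iteration count.
static int cg_solve(const SpMat& A, double c, const std::vector<double>& diagM,
                    const double* b, double* u, int n, double tol, int maxit,
                    std::vector<double>& r, std::vector<double>& z,
                    std::vector<double>& pv, std::vector<double>& Ap) {
  // r = b - M u
  A.matvec(u, Ap.data());
  double bnorm = 0.0;
  for (int k = 0; k < n; ++k) {
    r[k] = b[k] - (u[k] - c * Ap[k]);
    bnorm += b[k] * b[k];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rz = 0.0;
  for (int k = 0; k < n; ++k) {
    z[k] = r[k] / diagM[k];
    pv[k] = z[k];
    rz += r[k] * z[k];
  }
  int it = 0;
  for (; it < maxit; ++it) {
    double rn = 0.0;
    for (int k = 0; k < n; ++k) rn += r[k] * r[k];
    if (std::sqrt(rn) <= tol * bnorm) break;
    A.matvec(pv.data(), Ap.data());
    double pAp = 0.0;
    for (int k = 0; k < n; ++k) {
      Ap[k] = pv[k] - c * Ap[k];
      pAp += pv[k] * Ap[k];
    }
    double alpha = rz / pAp;
    for (int k = 0; k < n; ++k) {
      u[k] += alpha * pv[k];
      r[k] -= alpha * Ap[k];
    }
    double rz_new = 0.0;
    for (int k = 0; k < n; ++k) {
      z[k] = r[k] / diagM[k];
      rz_new += r[k] * z[k];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int k = 0; k < n; ++k) pv[k] = z[k] + beta * pv[k];
  }
  return it;
}

struct ChR2Tab {
  VTable tab;
  int r_gvv, r_gd1, r_gr;
  ChR2Tab(const ChR2Pars& cp) : tab() {
    r_gvv = tab.add_row([&cp](double v) {
      return ChR2Pars::rect(v) * (v - cp.E_rev);
    });
    r_gd1 = tab.add_row([&cp](double v) {
      return cp.Gd1_base + cp.Gd1_amp * std::tanh(-(v + 20.0) / 20.0);
    });
    r_gr = tab.add_row([&cp](double v) {
      return cp.Gr0 * std::exp(-cp.Gr_vdep * v);
    });
    tab.finalize();
  }
};

template <class Model>
static List tissue_run_t(NumericMatrix state0, IntegerVector region,
                         NumericMatrix scales, double dt, int n_steps,
                         int diff_every, S4 Amat, NumericMatrix stim_times,
                         List stim_nodes, NumericMatrix light_times,
                         NumericVector atten, int opsin,
                         NumericVector opsin_pars, LogicalVector express,
                         NumericMatrix opsin0, IntegerVector probes,
                         List groups, double sample_ms, double snap_ms,
                         double act_thresh, double act_lockout,
                         bool record_act, double quiesc_thresh,
                         bool early_exit, double early_after,
                         double early_vmax, double early_quiet_ms,
                         double cg_tol, int cg_maxit) {
  const int NS = Model::NSTATE;
  const int n = state0.ncol();
  if (state0.nrow() != NS) stop("state matrix has wrong number of rows");
  Model M(dt);

  // region scales
  int nreg = scales.ncol();
  std::vector<RegionScale> rsc(static_cast<size_t>(nreg));
  for (int r = 0; r < nreg; ++r)
    for (int k = 0; k < 4; ++k) rsc[static_cast<size_t>(r)].s[k] = scales(k, r);

  // sparse operator
  IntegerVector Ap_ = Amat.slot("p"), Ai_ = Amat.slot("i");
  NumericVector Ax_ = Amat.slot("x");
  SpMat A{n, INTEGER(Ap_), INTEGER(Ai_), REAL(Ax_)};
  double ccn = 0.5 * diff_every * dt;
  std::vector<double> diagM(static_cast<size_t>(n), 1.0);
  for (int c = 0; c < n; ++c)
    for (int k = A.p[c]; k < A.p[c + 1]; ++k)
      if (A.i[k] == c) diagM[static_cast<size_t>(c)] = 1.0 - ccn * A.x[k];

  // working copies
  std::vector<double> Y(static_cast<size_t>(NS) * n);
  std::copy(state0.begin(), state0.end(), Y.begin());
  std::vector<double> ops;
  GtACR1Pars gp{}; ChR2Pars cp{};
  ChR2Tab* ctab = nullptr;
  if (opsin == 1) {
    gp.g_max = opsin_pars["g_max"]; gp.E_rev = opsin_pars["E_rev"];
    gp.tau_on = opsin_pars["tau_on"]; gp.tau_off = opsin_pars["tau_off"];
    gp.c_num = opsin_pars["c_num"]; gp.c_den0 = opsin_pars["c_den0"];
    gp.c_den1 = opsin_pars["c_den1"]; gp.e_offset = opsin_pars["e_offset"];
    ops.assign(static_cast<size_t>(n), 0.0);
    for (int k = 0; k < n; ++k) ops[static_cast<size_t>(k)] = opsin0(0, k);
  } else if (opsin == 2) {
    cp.g_max = opsin_pars["g_max"]; cp.E_rev = opsin_pars["E_rev"];
    cp.gamma = opsin_pars["gamma"]; cp.eps1 = opsin_pars["eps1"];
    cp.eps2 = opsin_pars["eps2"]; cp.Gd1_base = opsin_pars["Gd1_base"];
    cp.Gd1_amp = opsin_pars["Gd1_amp"]; cp.Gd2 = opsin_pars["Gd2"];
    cp.Gr0 = opsin_pars["Gr0"]; cp.Gr_vdep = opsin_pars["Gr_vdep"];
    cp.e12_dark = opsin_pars["e12_dark"]; cp.e12_c = opsin_pars["e12_c"];
    cp.e12_scale = opsin_pars["e12_scale"];
    cp.e21_dark = opsin_pars["e21_dark"]; cp.e21_c = opsin_pars["e21_c"];
    cp.e21_scale = opsin_pars["e21_scale"]; cp.tau_p = opsin_pars["tau_p"];
    cp.theta_half = opsin_pars["theta_half"];
    cp.flux_factor = opsin_pars["flux_factor"];
    ops.assign(static_cast<size_t>(5) * n, 0.0);
    for (int k = 0; k < n; ++k)
      for (int s = 0; s < 5; ++s)
        ops[static_cast<size_t>(5) * k + s] = opsin0(s, k);
    ctab = new ChR2Tab(cp);
  }

  // opsin light caches
  std::vector<double> g_pss(opsin == 1 ? n : 0),
      g_dec(opsin == 1 ? n : 0);
  std::vector<double> c_k1f(opsin == 2 ? n : 0), c_k2f(opsin == 2 ? n : 0),
      c_e12(opsin == 2 ? n : 0), c_e21(opsin == 2 ? n : 0),
      c_S0(opsin == 2 ? n : 0);
  double c_pdec = (opsin == 2) ? std::exp(-dt / cp.tau_p) : 1.0;
  double cur_ee = -1.0;
  auto set_light = [&](double ee) {
    if (ee == cur_ee) return;
    cur_ee = ee;
    if (opsin == 1) {
      double koc = 1.0 / gp.tau_off;
      for (int k = 0; k < n; ++k) {
        double kco = gp.opening_rate(ee * atten[k]);
        g_pss[static_cast<size_t>(k)] = kco / (kco + koc);
        g_dec[static_cast<size_t>(k)] = std::exp(-(kco + koc) * dt);
      }
    } else if (opsin == 2) {
      for (int k = 0; k < n; ++k) {
        double el = ee * atten[k];
        double F = cp.flux_factor * el;
        c_k1f[static_cast<size_t>(k)] = cp.eps1 * F;
        c_k2f[static_cast<size_t>(k)] = cp.eps2 * F;
        c_e12[static_cast<size_t>(k)] =
            cp.e12_dark + cp.e12_c * std::log(1.0 + el / cp.e12_scale);
        c_e21[static_cast<size_t>(k)] =
            cp.e21_dark + cp.e21_c * std::log(1.0 + el / cp.e21_scale);
        c_S0[static_cast<size_t>(k)] =
            0.5 * (1.0 + std::tanh(120.0 * (el - cp.theta_half)));
      }
    }
  };
  set_light(0.0);

  // stimulus bookkeeping
  int nstim = stim_times.nrow();
  const int nlight = light_times.nrow();
  std::vector<double> stim_cur(static_cast<size_t>(n), 0.0);
  std::vector<char> stim_on(static_cast<size_t>(std::max(nstim, 1)), 0);
  std::vector<std::vector<int>> stim_idx(static_cast<size_t>(nstim));
  for (int k = 0; k < nstim; ++k) {
    IntegerVector v = stim_nodes[k];
    stim_idx[static_cast<size_t>(k)].assign(v.begin(), v.end());
  }

  // sampling setup
  int sample_every = std::max(1, static_cast<int>(std::lround(sample_ms / dt)));
  int n_samp_max = n_steps / sample_every + 1;
  int nprobe = probes.size();
  int ngroup = groups.size();
  std::vector<std::vector<int>> group_idx(static_cast<size_t>(ngroup));
  for (int g = 0; g < ngroup; ++g) {
    IntegerVector v = groups[g];
    group_idx[static_cast<size_t>(g)].assign(v.begin(), v.end());
  }
  NumericVector t_out(n_samp_max), activity(n_samp_max);
  NumericMatrix probe_out(std::max(nprobe, 1), nprobe ? n_samp_max : 1);
  NumericMatrix group_out(std::max(ngroup, 1), ngroup ? n_samp_max : 1);
  int snap_every = (snap_ms > 0)
                       ? std::max(1, static_cast<int>(std::lround(snap_ms / dt)))
                       : 0;
  int n_snap_max = snap_every ? (n_steps / snap_every + 1) : 0;
  NumericMatrix snaps(snap_every ? n : 1, std::max(n_snap_max, 1));
  NumericVector snap_t(std::max(n_snap_max, 1));
  int isnap = 0;

  // activation detection state
  std::vector<double> last_act(static_cast<size_t>(n), -1e9);
  std::vector<double> prevV(static_cast<size_t>(n));
  for (int k = 0; k < n; ++k) prevV[static_cast<size_t>(k)] = Y[static_cast<size_t>(NS) * k];
  std::vector<std::vector<double>> acts;
  if (record_act) acts.resize(static_cast<size_t>(n));

  // Nernst potential cache, refreshed every few ionic steps
  const int nernst_every = 8;
  std::vector<Nernst> Ecache(static_cast<size_t>(n));
  for (int k = 0; k < n; ++k)
    Model::nernst(&Y[static_cast<size_t>(NS) * k], Ecache[static_cast<size_t>(k)]);

  // CG work arrays
  std::vector<double> V(static_cast<size_t>(n)), b(static_cast<size_t>(n)),
      r(static_cast<size_t>(n)), z(static_cast<size_t>(n)),
      pv(static_cast<size_t>(n)), Apw(static_cast<size_t>(n));
  long cg_total = 0;

  int isamp = 0;
  double quiet_ms = 0.0;
  double end_ms = n_steps * dt;
  bool stopped_early = false;

  for (int s = 0; s <= n_steps; ++s) {
    double t = s * dt;

    // stimuli on/off transitions
    for (int k = 0; k < nstim; ++k) {
      bool on = (t >= stim_times(k, 0) && t < stim_times(k, 0) + stim_times(k, 1));
      if (on != static_cast<bool>(stim_on[static_cast<size_t>(k)])) {
        double amp = stim_times(k, 2) * (on ? 1.0 : -1.0);
        for (int idx : stim_idx[static_cast<size_t>(k)])
          stim_cur[static_cast<size_t>(idx)] += amp;
        stim_on[static_cast<size_t>(k)] = on;
      }
    }
    // light transitions
    double ee = 0.0;
    for (int k = 0; k < nlight; ++k)
      if (t >= light_times(k, 0) && t < light_times(k, 0) + light_times(k, 1))
        ee += light_times(k, 2);
    set_light(ee);

    // sampling
    if (s % sample_every == 0 && isamp < n_samp_max) {
      t_out[isamp] = t;
      int nact = 0;
      double vmax = -1e9;
      for (int k = 0; k < n; ++k) {
        double v = Y[static_cast<size_t>(NS) * k];
        if (v > act_thresh) ++nact;
        if (v > vmax) vmax = v;
        // activation: upward crossing of -20 mV since last sample
        if (v >= -20.0 && prevV[static_cast<size_t>(k)] < -20.0 &&
            t - last_act[static_cast<size_t>(k)] >= act_lockout) {
          last_act[static_cast<size_t>(k)] = t;
          if (record_act) acts[static_cast<size_t>(k)].push_back(t);
        }
        prevV[static_cast<size_t>(k)] = v;
      }
      activity[isamp] = static_cast<double>(nact) / n;
      for (int k = 0; k < nprobe; ++k)
        probe_out(k, isamp) = Y[static_cast<size_t>(NS) * probes[k]];
      for (int g = 0; g < ngroup; ++g) {
        double acc = 0.0;
        for (int idx : group_idx[static_cast<size_t>(g)])
          acc += Y[static_cast<size_t>(NS) * idx];
        group_out(g, isamp) =
            acc / std::max(1, static_cast<int>(group_idx[static_cast<size_t>(g)].size()));
      }
      ++isamp;
      if (early_exit && t >= early_after) {
        if (vmax < early_vmax) quiet_ms += sample_ms; else quiet_ms = 0.0;
        if (quiet_ms >= early_quiet_ms) {
          end_ms = t;
          stopped_early = true;
          break;
        }
      }
      if (s % (sample_every * 256) == 0) Rcpp::checkUserInterrupt();
    }
    if (snap_every && s % snap_every == 0 && isnap < n_snap_max) {
      for (int k = 0; k < n; ++k) snaps(k, isnap) = Y[static_cast<size_t>(NS) * k];
      snap_t[isnap] = t;
      ++isnap;
    }
    if (s == n_steps) break;

    // reaction (ionics + opsin) step
    bool refresh_E = (s % nernst_every == 0);
    for (int k = 0; k < n; ++k) {
      double* y = &Y[static_cast<size_t>(NS) * k];
      if (refresh_E) Model::nernst(y, Ecache[static_cast<size_t>(k)]);
      double iops = 0.0;
      if (express[k]) {
        if (opsin == 1) {
          size_t kk = static_cast<size_t>(k);
          ops[kk] = g_pss[kk] + (ops[kk] - g_pss[kk]) * g_dec[kk];
          iops = ops[kk] * gp.g_max * (y[0] - gp.E_rev);
        } else if (opsin == 2) {
          size_t kk = static_cast<size_t>(5) * k;
          double* sp = &ops[kk];
          size_t ki = static_cast<size_t>(k);
          int ti; double tw;
          ctab->tab.locate(y[0], ti, tw);
          double Gd1 = ctab->tab.get(ctab->r_gd1, ti, tw);
          double Gr = ctab->tab.get(ctab->r_gr, ti, tw);
          double p = sp[4];
          double k1 = c_k1f[ki] * p, k2 = c_k2f[ki] * p;
          double C1 = sp[0], O1 = sp[1], O2 = sp[2], C2 = sp[3];
          double dO1 = k1 * C1 - (Gd1 + c_e12[ki]) * O1 + c_e21[ki] * O2;
          double dO2 = k2 * C2 + c_e12[ki] * O1 - (cp.Gd2 + c_e21[ki]) * O2;
          double dC2 = cp.Gd2 * O2 - (k2 + Gr) * C2;
          double dC1 = Gr * C2 + Gd1 * O1 - k1 * C1;
          C1 += dt * dC1; O1 += dt * dO1; O2 += dt * dO2; C2 += dt * dC2;
          if (C1 < 0) C1 = 0; if (O1 < 0) O1 = 0;
          if (O2 < 0) O2 = 0; if (C2 < 0) C2 = 0;
          double tot = C1 + O1 + O2 + C2;
          sp[0] = C1 / tot; sp[1] = O1 / tot; sp[2] = O2 / tot;
          sp[3] = C2 / tot;
          sp[4] = c_S0[ki] + (p - c_S0[ki]) * c_pdec;
          iops = cp.g_max * ctab->tab.get(ctab->r_gvv, ti, tw) *
                 (sp[1] + cp.gamma * sp[2]);
        }
      }
      y[0] += M.step(y, iops, stim_cur[static_cast<size_t>(k)],
                     rsc[static_cast<size_t>(region[k])],
                     Ecache[static_cast<size_t>(k)]);
    }

    // diffusion (Crank-Nicolson) step
    if ((s + 1) % diff_every == 0) {
      for (int k = 0; k < n; ++k) V[static_cast<size_t>(k)] = Y[static_cast<size_t>(NS) * k];
      A.matvec(V.data(), Apw.data());
      for (int k = 0; k < n; ++k)
        b[static_cast<size_t>(k)] = V[static_cast<size_t>(k)] + ccn * Apw[static_cast<size_t>(k)];
      int it = cg_solve(A, ccn, diagM, b.data(), V.data(), n, cg_tol,
                        cg_maxit, r, z, pv, Apw);
      if (it >= cg_maxit)
        stop("Crank-Nicolson linear solve failed to converge at t = %f ms", t);
      cg_total += it;
      for (int k = 0; k < n; ++k) {
        double v = V[static_cast<size_t>(k)];
        if (!std::isfinite(v)) stop("non-finite voltage at node %d, t = %f", k + 1, t);
        Y[static_cast<size_t>(NS) * k] = v;
      }
    }
  }

  // outputs (trim to actual sample count)
  int ns = isamp;
  NumericVector t_o(ns), act_o(ns);
  for (int k = 0; k < ns; ++k) { t_o[k] = t_out[k]; act_o[k] = activity[k]; }
  NumericMatrix probe_o(nprobe, ns);
  for (int k = 0; k < nprobe; ++k)
    for (int j = 0; j < ns; ++j) probe_o(k, j) = probe_out(k, j);
  NumericMatrix group_o(ngroup, ns);
  for (int g = 0; g < ngroup; ++g)
    for (int j = 0; j < ns; ++j) group_o(g, j) = group_out(g, j);
  NumericMatrix state_f(NS, n);
  std::copy(Y.begin(), Y.end(), state_f.begin());
  NumericMatrix ops_f(5, n);
  if (opsin == 1)
    for (int k = 0; k < n; ++k) ops_f(0, k) = ops[static_cast<size_t>(k)];
  else if (opsin == 2)
    for (int k = 0; k < n; ++k)
      for (int s2 = 0; s2 < 5; ++s2)
        ops_f(s2, k) = ops[static_cast<size_t>(5) * k + s2];
  List acts_o;
  if (record_act) {
    acts_o = List(n);
    for (int k = 0; k < n; ++k)
      acts_o[k] = NumericVector(acts[static_cast<size_t>(k)].begin(),
                                acts[static_cast<size_t>(k)].end());
  }
  NumericMatrix snaps_o(snap_every ? n : 0, isnap);
  NumericVector snap_t_o(isnap);
  if (snap_every) {
    for (int k = 0; k < n; ++k)
      for (int j = 0; j < isnap; ++j) snaps_o(k, j) = snaps(k, j);
    for (int j = 0; j < isnap; ++j) snap_t_o[j] = snap_t[j];
  }
  delete ctab;
  return List::create(
      _["t_ms"] = t_o, _["activity"] = act_o, _["probe_V"] = probe_o,
      _["group_V"] = group_o, _["activations"] = acts_o,
      _["snap_t"] = snap_t_o, _["snapshots"] = snaps_o,
      _["state"] = state_f, _["opsin_state"] = ops_f,
      _["end_ms"] = end_ms, _["stopped_early"] = stopped_early,
      _["cg_iterations"] = static_cast<double>(cg_total));
}

// [[Rcpp::export]]
List tissue_run_cpp(int model, NumericMatrix state0, IntegerVector region,
                    NumericMatrix scales, double dt, int n_steps,
                    int diff_every, S4 Amat, NumericMatrix stim_times,
                    List stim_nodes, NumericMatrix light_times,
                    NumericVector atten, int opsin, NumericVector opsin_pars,
                    LogicalVector express, NumericMatrix opsin0,
                    IntegerVector probes, List groups, double sample_ms,
                    double snap_ms, double act_thresh, double act_lockout,
                    bool record_act, double quiesc_thresh, bool early_exit,
                    double early_after, double early_vmax,
                    double early_quiet_ms, double cg_tol, int cg_maxit) {
  if (model == 0)
    return tissue_run_t<TT06>(state0, region, scales, dt, n_steps, diff_every,
                              Amat, stim_times, stim_nodes, light_times,
                              atten, opsin, opsin_pars, express, opsin0,
                              probes, groups, sample_ms, snap_ms, act_thresh,
                              act_lockout, record_act, quiesc_thresh,
                              early_exit, early_after, early_vmax,
                              early_quiet_ms, cg_tol, cg_maxit);
  return tissue_run_t<CRN>(state0, region, scales, dt, n_steps, diff_every,
                           Amat, stim_times, stim_nodes, light_times, atten,
                           opsin, opsin_pars, express, opsin0, probes, groups,
                           sample_ms, snap_ms, act_thresh, act_lockout,
                           record_act, quiesc_thresh, early_exit, early_after,
                           early_vmax, early_quiet_ms, cg_tol, cg_maxit);
}
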