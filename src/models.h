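#ifndef OPTODEFIB_MODELS_H
#define OPTODEFIB_MODELS_H

#include <vector>
#include <cmath>
#include <functional>
#include <stdexcept>

// ---------------------------------------------------------------------------
// Voltage lookup tables.  Gate rate expressions and voltage-dependent current
// coefficients are tabulated once per (model, dt) on a uniform grid and read
// back with linear interpolation; this removes essentially all exp()/log()
// calls from the per-node inner loop.
// ---------------------------------------------------------------------------
struct VTable {
  double vmin, vmax, dv, inv_dv;
  int n;
  int nrows;
  std::vector<std::vector<double>> rows;   // build-time storage
  std::vector<double> packed;              // interleaved [index][row]

  VTable(double vmin_ = -150.0, double vmax_ = 100.0, double dv_ = 0.05)
      : vmin(vmin_), vmax(vmax_), dv(dv_), inv_dv(1.0 / dv_),
        n(static_cast<int>((vmax_ - vmin_) / dv_) + 2), nrows(0) {}

  int add_row(const std::function<double(double)>& f) {
    std::vector<double> r(static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) r[static_cast<size_t>(i)] = f(vmin + i * dv);
    rows.push_back(std::move(r));
    return static_cast<int>(rows.size()) - 1;
  }

  // interleave rows so that all values for one voltage index are adjacent
  // (the per-node inner loop touches ~2 cache blocks instead of one line
  // per row)
  void finalize() {
    nrows = static_cast<int>(rows.size());
    packed.assign(static_cast<size_t>(n) * nrows, 0.0);
    for (int i = 0; i < n; ++i)
      for (int r = 0; r < nrows; ++r)
        packed[static_cast<size_t>(i) * nrows + r] =
            rows[static_cast<size_t>(r)][static_cast<size_t>(i)];
    rows.clear();
    rows.shrink_to_fit();
  }

  // index + weight for a voltage; callers reuse for many rows
  inline void locate(double v, int& i, double& w) const {
    double x = (v - vmin) * inv_dv;
    if (x < 0.0) x = 0.0;
    double xmax = static_cast<double>(n - 2);
    if (x > xmax) x = xmax;
    i = static_cast<int>(x);
    w = x - i;
  }
  inline double get(int row, int i, double w) const {
    const double* p0 = &packed[static_cast<size_t>(i) * nrows + row];
    const double* p1 = p0 + nrows;
    return *p0 + w * (*p1 - *p0);
  }
};

// Rush-Larsen factors: y <- inf + (y - inf) * exp(-dt/tau)
inline double rl_update(double y, double inf, double e) {
  return inf + (y - inf) * e;
}

// exp(-x) for small x >= 0 (used for Ca-dependent gate time constants where
// dt/tau <= ~0.05; cubic Taylor error < 3e-7)
inline double exp_neg_small(double x) {
  return 1.0 - x + 0.5 * x * x - x * x * x / 6.0;
}

// Cached Nernst potentials; intracellular concentrations drift slowly, so
// tissue runs refresh these every few steps rather than every step.
struct Nernst {
  double ENa, EK, EKs, ECa;
};

// ---------------------------------------------------------------------------
// Region-dependent conductance multipliers (identity for normal tissue).
// Slot meaning depends on the ionic model:
//   TT06: {g_Na, g_CaL, g_Kr, g_Ks}
//   CRN:  {g_Na, g_CaL, g_K1, unused}
// ---------------------------------------------------------------------------
struct RegionScale {
  double s[4];
};

// ---------------------------------------------------------------------------
// ten Tusscher-Panfilov 2006, epicardial parameterization.
// State layout (per node), 19 doubles:
//  0 V, 1 m, 2 h, 3 j, 4 xr1, 5 xr2, 6 xs, 7 r, 8 s, 9 d, 10 f, 11 f2,
//  12 fcass, 13 RR, 14 Cai, 15 CaSR, 16 CaSS, 17 Nai, 18 Ki
// ---------------------------------------------------------------------------
struct TT06 {
  static constexpr int NSTATE = 19;
  // physical constants
  static constexpr double Rgas = 8314.472, Temp = 310.0, Fara = 96485.3415;
  static constexpr double Cm = 0.185, Vc = 0.016404, Vsr = 0.001094,
                          Vss = 0.00005468;
  static constexpr double Ko = 5.4, Nao = 140.0, Cao = 2.0;
  static constexpr double GNa = 14.838, GK1 = 5.405, Gto = 0.294,
                          GKr = 0.153, GKs = 0.392, pKNa = 0.03,
                          GCaL = 3.98e-5, knaca = 1000.0, KmNai = 87.5,
                          KmCa = 1.38, ksat = 0.1, ncxgamma = 0.35,
                          ncxalpha = 2.5, PNaK = 2.724, KmK = 1.0,
                          KmNa = 40.0, GpCa = 0.1238, KpCa = 0.0005,
                          GpK = 0.0146, GbNa = 0.00029, GbCa = 0.000592;
  static constexpr double Vmaxup = 0.006375, Kup = 0.00025,
                          Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.06,
                          k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0,
                          Vleak = 0.00036, Vxfer = 0.0038;
  static constexpr double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0,
                          Kbufsr = 0.3, Bufss = 0.4, Kbufss = 0.00025;

  // table row ids
  int m_i, m_e, h_i, h_e, j_i, j_e, xr1_i, xr1_e, xr2_i, xr2_e, xs_i, xs_e,
      r_i, r_e, s_i, s_e, d_i, d_e, f_i, f_e, f2_i, f2_e;
  int cal1, cal2, ncxA, ncxB, nakC, ipkC;
  VTable tab;
  VTable k1tab;  // indexed by V - E_K
  int k1row;
  double dt;

  static double rtof() { return Rgas * Temp / Fara; }

  explicit TT06(double dt_) : tab(), k1tab(-150.0, 250.0, 0.05), dt(dt_) {
    const double rtf = rtof();
    // gates: inf and exp(-dt/tau)
    m_i = tab.add_row([](double v) {
      double x = 1.0 / (1.0 + std::exp((-56.86 - v) / 9.03));
      return x * x;
    });
    m_e = tab.add_row([&](double v) {
      double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
      double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
                  0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
      return std::exp(-dt / (am * bm));
    });
    auto hinf = [](double v) {
      double x = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
      return x * x;
    };
    h_i = tab.add_row(hinf);
    h_e = tab.add_row([&](double v) {
      double ah, bh;
      if (v >= -40.0) {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
      } else {
        ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
        bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
      }
      return std::exp(-dt * (ah + bh));
    });
    j_i = tab.add_row(hinf);
    j_e = tab.add_row([&](double v) {
      double aj, bj;
      if (v >= -40.0) {
        aj = 0.0;
        bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
      } else {
        aj = (-2.5428e4 * std::exp(0.2444 * v) -
              6.948e-6 * std::exp(-0.04391 * v)) * (v + 37.78) /
             (1.0 + std::exp(0.311 * (v + 79.23)));
        bj = 0.02424 * std::exp(-0.01052 * v) /
             (1.0 + std::exp(-0.1378 * (v + 40.14)));
      }
      return std::exp(-dt * (aj + bj));
    });
    xr1_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((-26.0 - v) / 7.0));
    });
    xr1_e = tab.add_row([&](double v) {
      double a = 450.0 / (1.0 + std::exp((-45.0 - v) / 10.0));
      double b = 6.0 / (1.0 + std::exp((v + 30.0) / 11.5));
      return std::exp(-dt / (a * b));
    });
    xr2_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((v + 88.0) / 24.0));
    });
    xr2_e = tab.add_row([&](double v) {
      double a = 3.0 / (1.0 + std::exp((-60.0 - v) / 20.0));
      double b = 1.12 / (1.0 + std::exp((v - 60.0) / 20.0));
      return std::exp(-dt / (a * b));
    });
    xs_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((-5.0 - v) / 14.0));
    });
    xs_e = tab.add_row([&](double v) {
      double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - v) / 6.0));
      double b = 1.0 / (1.0 + std::exp((v - 35.0) / 15.0));
      return std::exp(-dt / (a * b + 80.0));
    });
    r_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((20.0 - v) / 6.0));
    });
    r_e = tab.add_row([&](double v) {
      double tau = 9.5 * std::exp(-(v + 40.0) * (v + 40.0) / 1800.0) + 0.8;
      return std::exp(-dt / tau);
    });
    s_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((v + 20.0) / 5.0));
    });
    s_e = tab.add_row([&](double v) {
      double tau = 85.0 * std::exp(-(v + 45.0) * (v + 45.0) / 320.0) +
                   5.0 / (1.0 + std::exp((v - 20.0) / 5.0)) + 3.0;
      return std::exp(-dt / tau);
    });
    d_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((-8.0 - v) / 7.5));
    });
    d_e = tab.add_row([&](double v) {
      double ad = 1.4 / (1.0 + std::exp((-35.0 - v) / 13.0)) + 0.25;
      double bd = 1.4 / (1.0 + std::exp((v + 5.0) / 5.0));
      double cd = 1.0 / (1.0 + std::exp((50.0 - v) / 20.0));
      return std::exp(-dt / (ad * bd + cd));
    });
    f_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((v + 20.0) / 7.0));
    });
    f_e = tab.add_row([&](double v) {
      double af = 1102.5 * std::exp(-(v + 27.0) * (v + 27.0) / 225.0);
      double bf = 200.0 / (1.0 + std::exp((13.0 - v) / 10.0));
      double cf = 180.0 / (1.0 + std::exp((v + 30.0) / 10.0)) + 20.0;
      return std::exp(-dt / (af + bf + cf));
    });
    f2_i = tab.add_row([](double v) {
      return 0.67 / (1.0 + std::exp((v + 35.0) / 7.0)) + 0.33;
    });
    f2_e = tab.add_row([&](double v) {
      double a = 562.0 * std::exp(-(v + 27.0) * (v + 27.0) / 240.0);
      double b = 31.0 / (1.0 + std::exp((25.0 - v) / 10.0));
      double c = 80.0 / (1.0 + std::exp((v + 30.0) / 10.0));
      return std::exp(-dt / (a + b + c));
    });
    // I_CaL voltage factors: I = d f f2 fcass * (cal2(V)*Cass - cal1(V))
    // with P(z) = GCaL * 2F * z / (e^z - 1), z = 2(V-15)F/RT
    cal1 = tab.add_row([&](double v) {
      double z = 2.0 * (v - 15.0) / rtf;
      double P = (std::fabs(z) < 1e-6)
                     ? GCaL * 2.0 * Fara
                     : GCaL * 2.0 * Fara * z / (std::exp(z) - 1.0);
      return P * Cao;
    });
    cal2 = tab.add_row([&](double v) {
      double z = 2.0 * (v - 15.0) / rtf;
      double Pez = (std::fabs(z) < 1e-6)
                       ? GCaL * 2.0 * Fara
                       : GCaL * 2.0 * Fara * z * std::exp(z) /
                             (std::exp(z) - 1.0);
      return 0.25 * Pez;
    });
    // I_NaCa = ncxA(V)*Nai^3 - ncxB(V)*Cai
    ncxA = tab.add_row([&](double v) {
      double e1 = std::exp(ncxgamma * v / rtf);
      double e2 = std::exp((ncxgamma - 1.0) * v / rtf);
      double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
                   (1.0 + ksat * e2);
      return knaca * e1 * Cao / den;
    });
    ncxB = tab.add_row([&](double v) {
      double e2 = std::exp((ncxgamma - 1.0) * v / rtf);
      double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
                   (1.0 + ksat * e2);
      return knaca * e2 * Nao * Nao * Nao * ncxalpha / den;
    });
    // I_NaK = nakC(V) * Nai/(Nai+KmNa)
    nakC = tab.add_row([&](double v) {
      double f = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf) +
                        0.0353 * std::exp(-v / rtf));
      return PNaK * Ko / (Ko + KmK) * f;
    });
    // I_pK = ipkC(V) * (V - E_K)
    ipkC = tab.add_row([](double v) {
      return GpK / (1.0 + std::exp((25.0 - v) / 5.98));
    });
    // inward rectifier gate as function of w = V - E_K
    k1row = k1tab.add_row([](double w) {
      double a = 0.1 / (1.0 + std::exp(0.06 * (w - 200.0)));
      double b = (3.0 * std::exp(0.0002 * (w + 100.0)) +
                  std::exp(0.1 * (w - 10.0))) /
                 (1.0 + std::exp(-0.5 * w));
      return a / (a + b);
    });
    tab.finalize();
    k1tab.finalize();
  }

  // published epicardial resting initial conditions
  static void init_state(double* y) {
    y[0] = -85.23;  y[1] = 0.00172; y[2] = 0.7444; y[3] = 0.7045;
    y[4] = 0.00621; y[5] = 0.4712;  y[6] = 0.0095; y[7] = 2.42e-8;
    y[8] = 0.999998; y[9] = 3.373e-5; y[10] = 0.7888; y[11] = 0.9755;
    y[12] = 0.9953; y[13] = 0.9073; y[14] = 0.000126; y[15] = 3.64;
    y[16] = 0.00036; y[17] = 8.604; y[18] = 136.89;
  }

  static void nernst(const double* y, Nernst& E) {
    const double rtf = rtof();
    E.EK = rtf * std::log(Ko / y[18]);
    E.ENa = rtf * std::log(Nao / y[17]);
    E.EKs = rtf * std::log((Ko + pKNa * Nao) / (y[18] + pKNa * y[17]));
    E.ECa = 0.5 * rtf * std::log(Cao / y[14]);
  }

  // One forward step.  i_ext (pA/pF): additional current already in the
  // inward-negative convention (opsin current); i_stim: depolarizing
  // stimulus magnitude.  Returns dV (change in voltage, caller applies).
  inline double step(double* y, double i_ext, double i_stim,
                     const RegionScale& rs, const Nernst& E) const {
    double V = y[0];
    int ti; double tw;
    tab.locate(V, ti, tw);
    // gates (Rush-Larsen)
    y[1] = rl_update(y[1], tab.get(m_i, ti, tw), tab.get(m_e, ti, tw));
    y[2] = rl_update(y[2], tab.get(h_i, ti, tw), tab.get(h_e, ti, tw));
    y[3] = rl_update(y[3], tab.get(j_i, ti, tw), tab.get(j_e, ti, tw));
    y[4] = rl_update(y[4], tab.get(xr1_i, ti, tw), tab.get(xr1_e, ti, tw));
    y[5] = rl_update(y[5], tab.get(xr2_i, ti, tw), tab.get(xr2_e, ti, tw));
    y[6] = rl_update(y[6], tab.get(xs_i, ti, tw), tab.get(xs_e, ti, tw));
    y[7] = rl_update(y[7], tab.get(r_i, ti, tw), tab.get(r_e, ti, tw));
    y[8] = rl_update(y[8], tab.get(s_i, ti, tw), tab.get(s_e, ti, tw));
    y[9] = rl_update(y[9], tab.get(d_i, ti, tw), tab.get(d_e, ti, tw));
    y[10] = rl_update(y[10], tab.get(f_i, ti, tw), tab.get(f_e, ti, tw));
    y[11] = rl_update(y[11], tab.get(f2_i, ti, tw), tab.get(f2_e, ti, tw));
    // fcass: Ca_ss-dependent
    {
      double cass = y[16];
      double q = cass / 0.05; q = q * q;
      double inf = 0.6 / (1.0 + q) + 0.4;
      double tau = 80.0 / (1.0 + q) + 2.0;
      y[12] = rl_update(y[12], inf, exp_neg_small(dt / tau));
    }
    double Cai = y[14], CaSR = y[15], CaSS = y[16], Nai = y[17];
    const double EK = E.EK, ENa = E.ENa, EKs = E.EKs, ECa = E.ECa;

    double INa = rs.s[0] * GNa * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
    int ki_; double kw_;
    k1tab.locate(V - EK, ki_, kw_);
    double IK1 = GK1 * k1tab.get(k1row, ki_, kw_) * (V - EK);
    double Ito = Gto * y[7] * y[8] * (V - EK);
    double IKr = rs.s[2] * GKr * y[4] * y[5] * (V - EK);
    double IKs = rs.s[3] * GKs * y[6] * y[6] * (V - EKs);
    double ICaL = rs.s[1] * y[9] * y[10] * y[11] * y[12] *
                  (tab.get(cal2, ti, tw) * CaSS - tab.get(cal1, ti, tw));
    double INaCa = tab.get(ncxA, ti, tw) * Nai * Nai * Nai -
                   tab.get(ncxB, ti, tw) * Cai;
    double INaK = tab.get(nakC, ti, tw) * Nai / (Nai + KmNa);
    double IpCa = GpCa * Cai / (Cai + KpCa);
    double IpK = tab.get(ipkC, ti, tw) * (V - EK);
    double IbNa = GbNa * (V - ENa);
    double IbCa = GbCa * (V - ECa);

    // calcium subsystem (algebraic rapid-buffer updates as in the original
    // published code)
    double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
    double kk1 = k1p / kCaSR;
    double kk2 = k2p * kCaSR;
    y[13] += dt * (k4 * (1.0 - y[13]) - kk2 * CaSS * y[13]);
    double OO = kk1 * CaSS * CaSS * y[13] / (k3 + kk1 * CaSS * CaSS);
    double Irel = Vrel * OO * (CaSR - CaSS);
    double Ileak = Vleak * (CaSR - Cai);
    double Iup = Vmaxup / (1.0 + Kup * Kup / (Cai * Cai));
    double Ixfer = Vxfer * (CaSS - Cai);

    double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
    double dCaSR = dt * (Iup - Irel - Ileak);
    double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
    double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
    y[15] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

    double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
    double dCaSS = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                         ICaL / (2.0 * Vss * Fara) * Cm);
    double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
    double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
    y[16] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

    double CaBuf = Bufc * Cai / (Cai + Kbufc);
    double dCai = dt * (-(IbCa + IpCa - 2.0 * INaCa) / (2.0 * Vc * Fara) * Cm -
                        (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
    double cc = Kbufc * (CaBuf + dCai + Cai);
    y[14] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

    y[17] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm /
                   (Vc * Fara));
    y[18] += dt * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK - i_stim) * Cm /
                   (Vc * Fara));

    double Iion = INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa +
                  IpK + IbNa + IbCa;
    return dt * (-(Iion + i_ext) + i_stim);
  }
};

// ---------------------------------------------------------------------------
// Courtemanche-Ramirez-Nattel 1998 human atrial model.
// State layout, 21 doubles:
//  0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs, 10 d, 11 f,
//  12 fca, 13 u, 14 vv, 15 w, 16 Cai, 17 Caup, 18 Carel, 19 Nai, 20 Ki
// ---------------------------------------------------------------------------
struct CRN {
  static constexpr int NSTATE = 21;
  static constexpr double Rgas = 8.3143, Temp = 310.0, Fara = 96.4867;
  static constexpr double Cm = 100.0;  // pF
  static constexpr double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48;
  static constexpr double Ko = 5.4, Nao = 140.0, Cao = 1.8;
  static constexpr double gNa = 7.8, gK1 = 0.09, gto = 0.1652,
                          gKr = 0.029411765, gKs = 0.12941176,
                          gCaL = 0.12375, gbCa = 0.001131, gbNa = 0.0006744375;
  static constexpr double INaKmax = 0.59933874, KmNai = 10.0, KmKo = 1.5;
  static constexpr double kNaCa = 1600.0, KmNa = 87.5, KmCa = 1.38,
                          ksat = 0.1, ncxgamma = 0.35;
  static constexpr double IpCamax = 0.275, Iupmax = 0.005, Kup = 0.00092,
                          Caupmax = 15.0, krel = 30.0, tautr = 180.0;
  static constexpr double KQ10 = 3.0;
  static constexpr double TRPNmax = 0.07, KmTRPN = 0.0005, CMDNmax = 0.05,
                          KmCMDN = 0.00238, CSQNmax = 10.0, KmCSQN = 0.8;

  int m_i, m_e, h_i, h_e, j_i, j_e, oa_i, oa_e, oi_i, oi_e, ua_i, ua_e,
      ui_i, ui_e, xr_i, xr_e, xs_i, xs_e, d_i, d_e, f_i, f_e, w_i, w_e;
  int gkur, ncxA, ncxB, nakC, k1den;
  VTable tab;
  double dt;
  double fca_dec, u_dec;

  static double rtof() { return Rgas * Temp / Fara; }

  explicit CRN(double dt_) : tab(), dt(dt_) {
    fca_dec = std::exp(-dt / 2.0);
    u_dec = std::exp(-dt / 8.0);
    // gates
    m_i = tab.add_row([](double v) {
      double am = (std::fabs(v + 47.13) < 1e-10)
                      ? 3.2
                      : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
      double bm = 0.08 * std::exp(-v / 11.0);
      return am / (am + bm);
    });
    m_e = tab.add_row([&](double v) {
      double am = (std::fabs(v + 47.13) < 1e-10)
                      ? 3.2
                      : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
      double bm = 0.08 * std::exp(-v / 11.0);
      return std::exp(-dt * (am + bm));
    });
    auto hab = [](double v, double& ah, double& bh) {
      if (v >= -40.0) {
        ah = 0.0;
        bh = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
      } else {
        ah = 0.135 * std::exp(-(v + 80.0) / 6.8);
        bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
      }
    };
    h_i = tab.add_row([&](double v) {
      double a, b; hab(v, a, b); return a / (a + b);
    });
    h_e = tab.add_row([&](double v) {
      double a, b; hab(v, a, b); return std::exp(-dt * (a + b));
    });
    auto jab = [](double v, double& aj, double& bj) {
      if (v >= -40.0) {
        aj = 0.0;
        bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
      } else {
        aj = (-1.2714e5 * std::exp(0.2444 * v) -
              3.474e-5 * std::exp(-0.04391 * v)) * (v + 37.78) /
             (1.0 + std::exp(0.311 * (v + 79.23)));
        bj = 0.1212 * std::exp(-0.01052 * v) /
             (1.0 + std::exp(-0.1378 * (v + 40.14)));
      }
    };
    j_i = tab.add_row([&](double v) {
      double a, b; jab(v, a, b); return a / (a + b);
    });
    j_e = tab.add_row([&](double v) {
      double a, b; jab(v, a, b); return std::exp(-dt * (a + b));
    });
    auto oaab = [](double v, double& a, double& b) {
      a = 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
      b = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
    };
    oa_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp(-(v + 20.47) / 17.54));
    });
    oa_e = tab.add_row([&](double v) {
      double a, b; oaab(v, a, b);
      return std::exp(-dt * (a + b) * KQ10);
    });
    oi_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((v + 43.1) / 5.3));
    });
    oi_e = tab.add_row([&](double v) {
      double a = 1.0 / (18.53 + std::exp((v + 113.7) / 10.95));
      double b = 1.0 / (35.56 + std::exp(-(v + 1.26) / 7.44));
      return std::exp(-dt * (a + b) * KQ10);
    });
    ua_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp(-(v + 30.3) / 9.6));
    });
    ua_e = tab.add_row([&](double v) {
      double a, b; oaab(v, a, b);
      return std::exp(-dt * (a + b) * KQ10);
    });
    ui_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((v - 99.45) / 27.48));
    });
    ui_e = tab.add_row([&](double v) {
      double a = 1.0 / (21.0 + std::exp(-(v - 185.0) / 28.0));
      double b = std::exp((v - 158.0) / 16.0);
      return std::exp(-dt * (a + b) * KQ10);
    });
    xr_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp(-(v + 14.1) / 6.5));
    });
    xr_e = tab.add_row([&](double v) {
      double a = (std::fabs(v + 14.1) < 1e-10)
                     ? 0.0015
                     : 0.0003 * (v + 14.1) / (1.0 - std::exp(-(v + 14.1) / 5.0));
      double b = (std::fabs(v - 3.3328) < 1e-10)
                     ? 3.7836118e-4
                     : 7.3898e-5 * (v - 3.3328) /
                           (std::exp((v - 3.3328) / 5.1237) - 1.0);
      return std::exp(-dt * (a + b));
    });
    xs_i = tab.add_row([](double v) {
      return 1.0 / std::sqrt(1.0 + std::exp(-(v - 19.9) / 12.7));
    });
    xs_e = tab.add_row([&](double v) {
      double a = (std::fabs(v - 19.9) < 1e-10)
                     ? 0.00068
                     : 4e-5 * (v - 19.9) / (1.0 - std::exp(-(v - 19.9) / 17.0));
      double b = (std::fabs(v - 19.9) < 1e-10)
                     ? 0.000315
                     : 3.5e-5 * (v - 19.9) / (std::exp((v - 19.9) / 9.0) - 1.0);
      return std::exp(-dt * 2.0 * (a + b));
    });
    d_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp(-(v + 10.0) / 8.0));
    });
    d_e = tab.add_row([&](double v) {
      double tau;
      if (std::fabs(v + 10.0) < 1e-10) tau = 4.579 / 2.0;
      else
        tau = (1.0 - std::exp(-(v + 10.0) / 6.24)) /
              (0.035 * (v + 10.0) * (1.0 + std::exp(-(v + 10.0) / 6.24)));
      return std::exp(-dt / tau);
    });
    f_i = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp((v + 28.0) / 6.9));
    });
    f_e = tab.add_row([&](double v) {
      double tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (v + 10.0) *
                                            (v + 10.0)) + 0.02);
      return std::exp(-dt / tau);
    });
    w_i = tab.add_row([](double v) {
      return 1.0 - 1.0 / (1.0 + std::exp(-(v - 40.0) / 17.0));
    });
    w_e = tab.add_row([&](double v) {
      double tau;
      if (std::fabs(v - 7.9) < 1e-10) tau = 6.0 * 0.2 / 1.3;
      else
        tau = 6.0 * (1.0 - std::exp(-(v - 7.9) / 5.0)) /
              ((1.0 + 0.3 * std::exp(-(v - 7.9) / 5.0)) * (v - 7.9));
      return std::exp(-dt / tau);
    });
    gkur = tab.add_row([](double v) {
      return 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
    });
    const double rtf = rtof();
    ncxA = tab.add_row([&](double v) {
      double e1 = std::exp(ncxgamma * v / rtf);
      double e2 = std::exp((ncxgamma - 1.0) * v / rtf);
      double den = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
                   (1.0 + ksat * e2);
      return kNaCa * e1 * Cao / den;
    });
    ncxB = tab.add_row([&](double v) {
      double e2 = std::exp((ncxgamma - 1.0) * v / rtf);
      double den = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
                   (1.0 + ksat * e2);
      return kNaCa * e2 * Nao * Nao * Nao / den;
    });
    nakC = tab.add_row([&](double v) {
      double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
      double f = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf) +
                        0.0365 * sigma * std::exp(-v / rtf));
      return INaKmax * f * Ko / (Ko + KmKo);
    });
    k1den = tab.add_row([](double v) {
      return 1.0 / (1.0 + std::exp(0.07 * (v + 80.0)));
    });
    tab.finalize();
  }

  static void init_state(double* y) {
    y[0] = -81.18; y[1] = 2.908e-3; y[2] = 0.9649; y[3] = 0.9775;
    y[4] = 3.043e-2; y[5] = 0.9992; y[6] = 4.966e-3; y[7] = 0.9986;
    y[8] = 3.296e-5; y[9] = 1.869e-2; y[10] = 1.367e-4; y[11] = 0.9996;
    y[12] = 0.7755; y[13] = 0.0; y[14] = 1.0; y[15] = 0.9992;
    y[16] = 1.013e-4; y[17] = 1.488; y[18] = 1.488; y[19] = 11.17;
    y[20] = 139.0;
  }

  static void nernst(const double* y, Nernst& E) {
    const double rtf = rtof();
    E.EK = rtf * std::log(Ko / y[20]);
    E.ENa = rtf * std::log(Nao / y[19]);
    E.EKs = E.EK;
    E.ECa = 0.5 * rtf * std::log(Cao / y[16]);
  }

  inline double step(double* y, double i_ext, double i_stim,
                     const RegionScale& rs, const Nernst& E) const {
    double V = y[0];
    int ti; double tw;
    tab.locate(V, ti, tw);
    y[1] = rl_update(y[1], tab.get(m_i, ti, tw), tab.get(m_e, ti, tw));
    y[2] = rl_update(y[2], tab.get(h_i, ti, tw), tab.get(h_e, ti, tw));
    y[3] = rl_update(y[3], tab.get(j_i, ti, tw), tab.get(j_e, ti, tw));
    y[4] = rl_update(y[4], tab.get(oa_i, ti, tw), tab.get(oa_e, ti, tw));
    y[5] = rl_update(y[5], tab.get(oi_i, ti, tw), tab.get(oi_e, ti, tw));
    y[6] = rl_update(y[6], tab.get(ua_i, ti, tw), tab.get(ua_e, ti, tw));
    y[7] = rl_update(y[7], tab.get(ui_i, ti, tw), tab.get(ui_e, ti, tw));
    y[8] = rl_update(y[8], tab.get(xr_i, ti, tw), tab.get(xr_e, ti, tw));
    y[9] = rl_update(y[9], tab.get(xs_i, ti, tw), tab.get(xs_e, ti, tw));
    y[10] = rl_update(y[10], tab.get(d_i, ti, tw), tab.get(d_e, ti, tw));
    y[11] = rl_update(y[11], tab.get(f_i, ti, tw), tab.get(f_e, ti, tw));
    y[15] = rl_update(y[15], tab.get(w_i, ti, tw), tab.get(w_e, ti, tw));

    double Cai = y[16], Caup = y[17], Carel = y[18], Nai = y[19];
    const double EK = E.EK, ENa = E.ENa, ECa = E.ECa;

    // fca gate (Ca-dependent, tau = 2 ms)
    {
      double inf = 1.0 / (1.0 + Cai / 0.00035);
      y[12] = rl_update(y[12], inf, fca_dec);
    }

    double INa = rs.s[0] * gNa * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
    double IK1 = rs.s[2] * gK1 * (V - EK) * tab.get(k1den, ti, tw);
    double Ito = gto * y[4] * y[4] * y[4] * y[5] * (V - EK);
    double IKur = tab.get(gkur, ti, tw) * y[6] * y[6] * y[6] * y[7] * (V - EK);
    double IKr = gKr * y[8] * (V - EK) /
                 (1.0 + std::exp((V + 15.0) / 22.4));
    double IKs = gKs * y[9] * y[9] * (V - EK);
    double ICaL = rs.s[1] * gCaL * y[10] * y[11] * y[12] * (V - 65.0);
    double xkm = KmNai / Nai;
    double INaK = tab.get(nakC, ti, tw) / (1.0 + xkm * std::sqrt(xkm));
    double INaCa = tab.get(ncxA, ti, tw) * Nai * Nai * Nai -
                   tab.get(ncxB, ti, tw) * Cai;
    double IpCa = IpCamax * Cai / (0.0005 + Cai);
    double IbNa = gbNa * (V - ENa);
    double IbCa = gbCa * (V - ECa);

    // SR fluxes and release gating
    double Irel = krel * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
    double Itr = (Caup - Carel) / tautr;
    double Iup = Iupmax / (1.0 + Kup / Cai);
    double Iupleak = Iupmax * Caup / Caupmax;

    double Fn = 1e-12 * Vrel * Irel -
                (5e-13 / Fara) * (0.5 * ICaL - 0.2 * INaCa);
    double uinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
    y[13] = rl_update(y[13], uinf, u_dec);
    double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
    double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
    y[14] = rl_update(y[14], vinf, exp_neg_small(dt / tauv));

    // concentrations
    double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * Fara * Vi) +
                (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
    double B2 = 1.0 + TRPNmax * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
                CMDNmax * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));
    y[16] += dt * B1 / B2;
    y[17] += dt * (Iup - Iupleak - Itr * Vrel / Vup);
    y[18] += dt * (Itr - Irel) /
             (1.0 + CSQNmax * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));
    y[19] += dt * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (Fara * Vi);
    y[20] += dt * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs + i_stim) * Cm /
             (Fara * Vi);

    double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
                  INaCa + IbNa + IbCa;
    return dt * (-(Iion + i_ext) + i_stim);
  }
};

// ---------------------------------------------------------------------------
// Opsin kernels (parameters passed from R; single source of truth there).
// ---------------------------------------------------------------------------
struct GtACR1Pars {
  double g_max, E_rev, tau_on, tau_off, c_num, c_den0, c_den1, e_offset;
  double opening_rate(double ee) const {
    double lg = std::log(ee + e_offset);
    double r = (1.0 / tau_on) * (c_num + lg) / (c_den0 - c_den1 * lg);
    return r > 0.0 ? r : 0.0;
  }
};

struct ChR2Pars {
  double g_max, E_rev, gamma, eps1, eps2, Gd1_base, Gd1_amp, Gd2, Gr0,
      Gr_vdep, e12_dark, e12_c, e12_scale, e21_dark, e21_c, e21_scale,
      tau_p, theta_half, flux_factor;
  static double rect(double v) {
    if (std::fabs(v) < 1e-6) return 14.6408 / 42.7671;
    return (10.6408 - 14.6408 * std::exp(-v / 42.7671)) / v;
  }
};

// per-node ChR2 state: C1, O1, O2, C2, p (5 doubles)
inline void chr2_node_step(double* s, double v, double dt, double k1f,
                           double k2f, double e12, double e21, double S0,
                           double p_decay, const ChR2Pars& cp) {
  double p = s[4];
  double k1 = k1f * p, k2 = k2f * p;
  double Gd1 = cp.Gd1_base + cp.Gd1_amp * std::tanh(-(v + 20.0) / 20.0);
  double Gr = cp.Gr0 * std::exp(-cp.Gr_vdep * v);
  double C1 = s[0], O1 = s[1], O2 = s[2], C2 = s[3];
  double dO1 = k1 * C1 - (Gd1 + e12) * O1 + e21 * O2;
  double dO2 = k2 * C2 + e12 * O1 - (cp.Gd2 + e21) * O2;
  double dC2 = cp.Gd2 * O2 - (k2 + Gr) * C2;
  double dC1 = Gr * C2 + Gd1 * O1 - k1 * C1;
  C1 += dt * dC1; O1 += dt * dO1; O2 += dt * dO2; C2 += dt * dC2;
  if (C1 < 0) C1 = 0; if (O1 < 0) O1 = 0; if (O2 < 0) O2 = 0; if (C2 < 0) C2 = 0;
  double tot = C1 + O1 + O2 + C2;
  s[0] = C1 / tot; s[1] = O1 / tot; s[2] = O2 / tot; s[3] = C2 / tot;
  s[4] = S0 + (p - S0) * p_decay;
}

#endif  // OPTODEFIB_MODELS_H
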