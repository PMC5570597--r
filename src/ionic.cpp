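// Membrane kernels and inner time-stepping loops.
//
// Ionic models:
//   0  human ventricular cell (ten Tusscher & Panfilov 2006, epicardial
//      parameter set), optionally augmented with an electroporation current
//      (pore-density ODE of the DeBruin & Krassowska form) and a sigmoidal
//      outward K+ current that activates beyond large positive polarisations.
//   1  passive linear leak (for analytic cable / antisymmetry tests).
//   2  reduced two-variable cubic excitable model (solver smoke tests only).
//
// Units: mV, ms, uA/cm2, mS/cm2, mM.  Gates advanced by exponential
// (Rush-Larsen) updates, concentrations by forward Euler.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <utility>
using namespace Rcpp;

static const int NSTATE = 19; // rows of the state matrix (all models)

// state row indices for the human ventricular model
enum { iM, iH, iJ, iXR1, iXR2, iXS, iR, iS, iD, iF, iF2, iFCASS, iRQ,
       iCAI, iCASR, iCASS, iNAI, iKI, iPORE };

struct MembParams {
  int model;
  bool aug_on;
  // conductance multipliers (VT-variant scaling etc.)
  double s_gNa, s_gto, s_gKr, s_gKs, s_gCaL, s_gK1, s_tauf;
  // augmentation constants
  double ep_alpha, ep_q, ep_Vep, ep_g, ka_g, ka_Vth, ka_k;
  // passive
  double Gm, Vrest;
  // reduced
  double rd_k, rd_a, rd_eps, rd_amp;
};

static MembParams parse_params(const List& prm) {
  MembParams p;
  p.model   = as<int>(prm["model"]);
  p.aug_on  = as<bool>(prm["aug_on"]);
  p.s_gNa   = as<double>(prm["s_gNa"]);
  p.s_gto   = as<double>(prm["s_gto"]);
  p.s_gKr   = as<double>(prm["s_gKr"]);
  p.s_gKs   = as<double>(prm["s_gKs"]);
  p.s_gCaL  = as<double>(prm["s_gCaL"]);
  p.s_gK1   = as<double>(prm["s_gK1"]);
  p.s_tauf  = as<double>(prm["s_tauf"]);
  p.ep_alpha= as<double>(prm["ep_alpha"]);
  p.ep_q    = as<double>(prm["ep_q"]);
  p.ep_Vep  = as<double>(prm["ep_Vep"]);
  p.ep_g    = as<double>(prm["ep_g"]);
  p.ka_g    = as<double>(prm["ka_g"]);
  p.ka_Vth  = as<double>(prm["ka_Vth"]);
  p.ka_k    = as<double>(prm["ka_k"]);
  p.Gm      = as<double>(prm["Gm"]);
  p.Vrest   = as<double>(prm["Vrest"]);
  p.rd_k    = as<double>(prm["rd_k"]);
  p.rd_a    = as<double>(prm["rd_a"]);
  p.rd_eps  = as<double>(prm["rd_eps"]);
  p.rd_amp  = as<double>(prm["rd_amp"]);
  return p;
}

// ---- human ventricular model constants (epicardial variant) ----
static const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
static const double RTF  = Rgas * Temp / Frdy;      // 26.713 mV
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
static const double GNa = 14.838, GK1 = 5.405, Gto = 0.294, GKr = 0.153,
                    GKs = 0.392, GCaL = 0.0000398, GbNa = 0.00029,
                    GbCa = 0.000592, GpCa = 0.1238, KpCa = 0.0005,
                    GpK = 0.0146, PNaK = 2.724, KmK = 1.0, KmNa = 40.0,
                    kNaCa = 1000.0, ksat = 0.1, alphaNC = 2.5, gammaNC = 0.35,
                    KmCa = 1.38, KmNai = 87.5, pKNa = 0.03;
static const double Vmaxup = 0.006375, Kup = 0.00025, Vrel = 0.102,
                    k1p = 0.15, k2p = 0.045, k3r = 0.060, k4r = 0.005,
                    ECsr = 1.5, maxsr = 2.5, minsr = 1.0,
                    Vleak = 0.00036, Vxfer = 0.0038;
static const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
                    Bufss = 0.4, Kbufss = 0.00025;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468,
                    CAP = 0.185;

// 13 exponentially updated gates (incl. RyR availability) + pore density
struct TTPRates {
  double inf[14], tau[14];
  double dconc[5]; // Cai, CaSR, CaSS, Nai, Ki
  double Iion;     // total, incl. augmentation if enabled
};

static inline double sq(double x) { return x * x; }
static inline double cb(double x) { return x * x * x; }

static void ttp_rates(double Vin, const double* S, const MembParams& p,
                      double Istim, TTPRates& o) {
  const double V = std::min(std::max(Vin, -600.0), 600.0);
  const double m = S[iM], h = S[iH], j = S[iJ], xr1 = S[iXR1], xr2 = S[iXR2],
               xs = S[iXS], r = S[iR], s = S[iS], d = S[iD], f = S[iF],
               f2 = S[iF2], fcass = S[iFCASS], Rq = S[iRQ];
  const double Cai = S[iCAI], CaSR = S[iCASR], CaSS = S[iCASS],
               Nai = S[iNAI], Ki = S[iKI], pore = S[iPORE];

  const double ENa = RTF * std::log(Nao / Nai);
  const double EK  = RTF * std::log(Ko / Ki);
  const double EKs = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  const double INa  = p.s_gNa * GNa * cb(m) * h * j * (V - ENa);
  const double IbNa = GbNa * (V - ENa);

  double ICaL;
  {
    const double z = 2.0 * (V - 15.0) / RTF;
    double fac;
    if (std::fabs(z) < 1e-6) fac = (0.25 * CaSS - Cao) * (1.0 - z / 2.0);
    else fac = (0.25 * CaSS * std::exp(z) - Cao) * z / (std::exp(z) - 1.0);
    ICaL = p.s_gCaL * GCaL * d * f * f2 * fcass * 2.0 * Frdy * fac;
  }
  const double IbCa = GbCa * (V - ECa);
  const double Ito  = p.s_gto * Gto * r * s * (V - EK);
  const double IKr  = p.s_gKr * GKr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double IKs  = p.s_gKs * GKs * sq(xs) * (V - EKs);
  double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                std::exp(0.1 * (V - EK - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = p.s_gK1 * GK1 * std::sqrt(Ko / 5.4) * (aK1 / (aK1 + bK1)) * (V - EK);
  const double INaCa =
      kNaCa *
      (std::exp(gammaNC * V / RTF) * cb(Nai) * Cao -
       std::exp((gammaNC - 1.0) * V / RTF) * cb(Nao) * Cai * alphaNC) /
      ((cb(KmNai) + cb(Nao)) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gammaNC - 1.0) * V / RTF)));
  const double INaK = PNaK * Ko * Nai /
                      ((Ko + KmK) * (Nai + KmNa) *
                       (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                        0.0353 * std::exp(-V / RTF)));
  const double IpCa = GpCa * Cai / (Cai + KpCa);
  const double IpK  = GpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));

  double Iaug = 0.0, IKaug = 0.0;
  if (p.aug_on) {
    IKaug = p.ka_g * (V - EK) / (1.0 + std::exp((p.ka_Vth - V) / p.ka_k));
    Iaug  = p.ep_g * pore * V + IKaug;
  }

  o.Iion = INa + IbNa + ICaL + IbCa + Ito + IKr + IKs + IK1 + INaCa + INaK +
           IpCa + IpK + Iaug;

  // gate kinetics
  o.inf[iM] = 1.0 / sq(1.0 + std::exp((-56.86 - V) / 9.03));
  {
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    o.tau[iM] = am * bm;
  }
  o.inf[iH] = 1.0 / sq(1.0 + std::exp((V + 71.55) / 7.43));
  {
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    o.tau[iH] = 1.0 / (ah + bh);
  }
  o.inf[iJ] = o.inf[iH];
  {
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    o.tau[iJ] = 1.0 / (aj + bj);
  }
  o.inf[iXR1] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  o.tau[iXR1] = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
                (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));
  o.inf[iXR2] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  o.tau[iXR2] = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
                (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));
  o.inf[iXS] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  o.tau[iXS] = (1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0))) *
                   (1.0 / (1.0 + std::exp((V - 35.0) / 15.0))) + 80.0;
  o.inf[iR] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  o.tau[iR] = 9.5 * std::exp(-sq(V + 40.0) / 1800.0) + 0.8;
  o.inf[iS] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0)); // epicardial
  o.tau[iS] = 85.0 * std::exp(-sq(V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  o.inf[iD] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  {
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    o.tau[iD] = ad * bd + gd;
  }
  o.inf[iF] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  o.tau[iF] = p.s_tauf * (1102.5 * std::exp(-sq(V + 27.0) / 225.0) +
                          200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                          180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0);
  o.inf[iF2] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  o.tau[iF2] = p.s_tauf * (562.0 * std::exp(-sq(V + 27.0) / 240.0) +
                           31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                           80.0 / (1.0 + std::exp((V + 30.0) / 10.0)));
  o.inf[iFCASS] = 0.6 / (1.0 + sq(CaSS / 0.05)) + 0.4;
  o.tau[iFCASS] = 80.0 / (1.0 + sq(CaSS / 0.05)) + 2.0;

  // RyR availability: linear ODE -> exponential update form
  const double kCaSR = maxsr - (maxsr - minsr) / (1.0 + sq(ECsr / CaSR));
  const double k1 = k1p / kCaSR, k2 = k2p * kCaSR;
  {
    double rate = k2 * CaSS + k4r;
    o.tau[iRQ] = 1.0 / rate;
    o.inf[iRQ] = k4r / rate;
  }
  // electroporation pore density: dp/dt = a e^x (1 - p e^{-q x}), x=(V/Vep)^2
  {
    double x = std::min(sq(V / p.ep_Vep), 25.0);
    double rate = p.ep_alpha * std::exp((1.0 - p.ep_q) * x);
    o.tau[13] = 1.0 / rate;
    o.inf[13] = std::exp(p.ep_q * x);
    if (!p.aug_on) { o.inf[13] = pore; o.tau[13] = 1e30; } // frozen
  }

  // calcium fluxes and concentration derivatives
  const double O = k1 * sq(CaSS) * Rq / (k3r + k1 * sq(CaSS));
  const double Irel  = Vrel * O * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup   = Vmaxup / (1.0 + sq(Kup / Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  const double bufCai  = 1.0 / (1.0 + Bufc * Kbufc / sq(Cai + Kbufc));
  const double bufCasr = 1.0 / (1.0 + Bufsr * Kbufsr / sq(CaSR + Kbufsr));
  const double bufCass = 1.0 / (1.0 + Bufss * Kbufss / sq(CaSS + Kbufss));

  o.dconc[0] = bufCai * ((-(IbCa + IpCa - 2.0 * INaCa) / (2.0 * Vc * Frdy)) * CAP
                         - (Iup - Ileak) * Vsr / Vc + Ixfer);
  o.dconc[1] = bufCasr * (Iup - Irel - Ileak);
  o.dconc[2] = bufCass * ((-ICaL / (2.0 * Vss * Frdy)) * CAP +
                          Irel * Vsr / Vss - Ixfer * Vc / Vss);
  o.dconc[3] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) / (Vc * Frdy) * CAP;
  o.dconc[4] = -(IK1 + Ito + IKr + IKs + IpK + IKaug - 2.0 * INaK - Istim) /
               (Vc * Frdy) * CAP;
}

// advance one node by dt (Rush-Larsen gates, FE concentrations);
// returns Iion evaluated at the entry state.
static inline double ttp_step_node(double V, double* S, const MembParams& p,
                                   double dt, double Istim) {
  TTPRates o;
  ttp_rates(V, S, p, Istim, o);
  static const int conc_idx[5] = { iCAI, iCASR, iCASS, iNAI, iKI };
  for (int g = 0; g < 13; ++g)
    S[g] = o.inf[g] + (S[g] - o.inf[g]) * std::exp(-dt / o.tau[g]);
  S[iPORE] = o.inf[13] + (S[iPORE] - o.inf[13]) * std::exp(-dt / o.tau[13]);
  for (int c = 0; c < 5; ++c) S[conc_idx[c]] += dt * o.dconc[c];
  return o.Iion;
}

// ---- 2004 formulation of the human ventricular model (epicardial) ----
// Differences from the 2006 revision: Cai-driven L-type current with an fCa
// gate, voltage-independent SR release inactivation gate g (both with
// conditional freezing during depolarisation), simpler SR Ca handling,
// GKr/GKs/PNaK/GpCa parameter values.
// state mapping: f2 row <- fCa, fcass row <- g, CaSS/Rq rows unused.
static const double GKr04 = 0.096, GKs04 = 0.245, PNaK04 = 1.362,
                    GpCa04 = 0.825, GCaL04 = 1.75e-4;
static const double arel = 0.016464, brel = 0.25, crel = 0.008232,
                    Vleak04 = 8e-5, Vmaxup04 = 0.000425, Bufc04 = 0.15;

struct TTP04Rates {
  double inf[14], tau[14];
  bool freeze_fca, freeze_g;
  double dconc[4]; // Cai, CaSR, Nai, Ki
  double Iion;
};

// all purely voltage-dependent pieces of the 2004 formulation, used both
// directly and to fill the interpolation table for the tissue hot loop
static const int NV04 = 26;
static void tt04_vdep(double V, double* o) {
  // gate steady states / time constants (f tau unscaled)
  o[0] = 1.0 / sq(1.0 + std::exp((-56.86 - V) / 9.03));        // m inf
  {
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    o[1] = am * bm;                                            // m tau
  }
  o[2] = 1.0 / sq(1.0 + std::exp((V + 71.55) / 7.43));         // h inf
  {
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    o[3] = 1.0 / (ah + bh);                                    // h tau
  }
  o[4] = o[2];                                                 // j inf
  {
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    o[5] = 1.0 / (aj + bj);                                    // j tau
  }
  o[6] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));            // xr1 inf
  o[7] = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
         (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));          // xr1 tau
  o[8] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));            // xr2 inf
  o[9] = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
         (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));         // xr2 tau
  o[10] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));           // xs inf
  o[11] = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0)) /
          (1.0 + std::exp((V - 60.0) / 20.0));                 // xs tau
  o[12] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));            // r inf
  o[13] = 9.5 * std::exp(-sq(V + 40.0) / 1800.0) + 0.8;        // r tau
  o[14] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));            // s inf (epi)
  o[15] = 85.0 * std::exp(-sq(V + 45.0) / 320.0) +
          5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;      // s tau
  o[16] = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));            // d inf
  {
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    o[17] = ad * bd + gd;                                      // d tau
  }
  o[18] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));            // f inf
  o[19] = 1125.0 * std::exp(-sq(V + 27.0) / 240.0) + 80.0 +
          165.0 / (1.0 + std::exp((25.0 - V) / 10.0));         // f tau
  {
    const double z = 2.0 * V / RTF;
    if (std::fabs(z) < 1e-6) { o[20] = 1.0 + z / 2.0; o[21] = 1.0 - z / 2.0; }
    else {
      double ez = std::exp(z);
      o[20] = z * ez / (ez - 1.0);                             // L-type A
      o[21] = z / (ez - 1.0);                                  // L-type B
    }
  }
  o[22] = std::exp(gammaNC * V / RTF);                         // NaCa e1
  o[23] = std::exp((gammaNC - 1.0) * V / RTF);                 // NaCa e2
  o[24] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                 0.0353 * std::exp(-V / RTF));                 // NaK factor
  o[25] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));           // pK factor
}

// interpolation table over the full shock voltage range
static struct {
  bool ready = false;
  double v0 = -600.0, dv = 0.05;
  int n = 0;
  std::vector<double> t;
} tab04;

static void tt04_build_table() {
  tab04.n = (int)std::lround((600.0 - tab04.v0) / tab04.dv) + 1;
  tab04.t.resize((size_t)tab04.n * NV04);
  for (int i = 0; i < tab04.n; ++i)
    tt04_vdep(tab04.v0 + i * tab04.dv, &tab04.t[(size_t)i * NV04]);
  tab04.ready = true;
}

// dt-specific Rush-Larsen decay factors exp(-dt/tau) for the ten
// voltage-gated gates, cached per (dt, tauf-multiplier)
static const int NE04 = 10;
static std::map<std::pair<long, long>, std::vector<double> > etab04;
static const double* tt04_etab(double dt, double s_tauf) {
  std::pair<long, long> key((long)std::llround(dt * 1e7),
                            (long)std::llround(s_tauf * 1e6));
  std::map<std::pair<long, long>, std::vector<double> >::iterator it =
      etab04.find(key);
  if (it != etab04.end()) return it->second.data();
  if (!tab04.ready) tt04_build_table();
  std::vector<double> e((size_t)tab04.n * NE04);
  static const int tcol[NE04] = { 1, 3, 5, 7, 9, 11, 13, 15, 17, 19 };
  for (int i = 0; i < tab04.n; ++i)
    for (int gi = 0; gi < NE04; ++gi) {
      double tau = tab04.t[(size_t)i * NV04 + tcol[gi]];
      if (gi == 9) tau *= s_tauf;
      e[(size_t)i * NE04 + gi] = std::exp(-dt / tau);
    }
  return etab04.insert(std::make_pair(key, e)).first->second.data();
}

static inline void tt04_vdep_interp(double V, double* o) {
  if (!tab04.ready) tt04_build_table();
  double u = (V - tab04.v0) / tab04.dv;
  if (u < 0) u = 0;
  if (u > tab04.n - 1.001) u = tab04.n - 1.001;
  int i = (int)u;
  double w = u - i;
  const double* a = &tab04.t[(size_t)i * NV04];
  const double* b = a + NV04;
  for (int c = 0; c < NV04; ++c) o[c] = a[c] * (1.0 - w) + b[c] * w;
}

static void ttp04_rates(double Vin, const double* S, const MembParams& p,
                        double Istim, TTP04Rates& o, bool use_tab = false) {
  const double V = std::min(std::max(Vin, -600.0), 600.0);
  const double m = S[iM], h = S[iH], j = S[iJ], xr1 = S[iXR1], xr2 = S[iXR2],
               xs = S[iXS], r = S[iR], s = S[iS], d = S[iD], f = S[iF],
               fca = S[iF2], g = S[iFCASS];
  const double Cai = S[iCAI], CaSR = S[iCASR], Nai = S[iNAI], Ki = S[iKI],
               pore = S[iPORE];

  double vd[NV04];
  if (use_tab) tt04_vdep_interp(V, vd); else tt04_vdep(V, vd);

  const double ENa = RTF * std::log(Nao / Nai);
  const double EK  = RTF * std::log(Ko / Ki);
  const double EKs = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  const double INa  = p.s_gNa * GNa * cb(m) * h * j * (V - ENa);
  const double IbNa = GbNa * (V - ENa);
  const double ICaL = p.s_gCaL * GCaL04 * d * f * fca * 2.0 * Frdy *
                      (Cai * vd[20] - 0.341 * Cao * vd[21]);
  const double IbCa = GbCa * (V - ECa);
  const double Ito  = p.s_gto * Gto * r * s * (V - EK);
  const double IKr  = p.s_gKr * GKr04 * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double IKs  = p.s_gKs * GKs04 * sq(xs) * (V - EKs);
  double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                std::exp(0.1 * (V - EK - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = p.s_gK1 * GK1 * std::sqrt(Ko / 5.4) *
                     (aK1 / (aK1 + bK1)) * (V - EK);
  const double INaCa =
      kNaCa * (vd[22] * cb(Nai) * Cao - vd[23] * cb(Nao) * Cai * alphaNC) /
      ((cb(KmNai) + cb(Nao)) * (KmCa + Cao) * (1.0 + ksat * vd[23]));
  const double INaK = PNaK04 * Ko * Nai /
                      ((Ko + KmK) * (Nai + KmNa)) * vd[24];
  const double IpCa = GpCa04 * Cai / (Cai + KpCa);
  const double IpK  = GpK * (V - EK) * vd[25];

  double Iaug = 0.0, IKaug = 0.0;
  if (p.aug_on) {
    IKaug = p.ka_g * (V - EK) / (1.0 + std::exp((p.ka_Vth - V) / p.ka_k));
    Iaug  = p.ep_g * pore * V + IKaug;
  }
  o.Iion = INa + IbNa + ICaL + IbCa + Ito + IKr + IKs + IK1 + INaCa + INaK +
           IpCa + IpK + Iaug;

  o.inf[iM] = vd[0];   o.tau[iM] = vd[1];
  o.inf[iH] = vd[2];   o.tau[iH] = vd[3];
  o.inf[iJ] = vd[4];   o.tau[iJ] = vd[5];
  o.inf[iXR1] = vd[6]; o.tau[iXR1] = vd[7];
  o.inf[iXR2] = vd[8]; o.tau[iXR2] = vd[9];
  o.inf[iXS] = vd[10]; o.tau[iXS] = vd[11];
  o.inf[iR] = vd[12];  o.tau[iR] = vd[13];
  o.inf[iS] = vd[14];  o.tau[iS] = vd[15];
  o.inf[iD] = vd[16];  o.tau[iD] = vd[17];
  o.inf[iF] = vd[18];  o.tau[iF] = p.s_tauf * vd[19];

  // fCa gate (f2 row) -- calcium dependent, computed directly
  {
    double c8 = Cai / 0.000325; c8 = sq(sq(sq(c8)));
    double afca = 1.0 / (1.0 + c8);
    double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
    double gfca = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
    o.inf[iF2] = (afca + bfca + gfca + 0.23) / 1.46;
    o.tau[iF2] = 2.0;
    o.freeze_fca = (o.inf[iF2] > fca) && (V > -60.0);
  }
  // g gate (fcass row)
  {
    double cg = Cai / 0.00035;
    double gi;
    if (Cai < 0.00035) { double c6 = sq(cb(cg)); gi = 1.0 / (1.0 + c6); }
    else { double c16 = sq(sq(sq(sq(cg)))); gi = 1.0 / (1.0 + c16); }
    o.inf[iFCASS] = gi;
    o.tau[iFCASS] = 2.0;
    o.freeze_g = (gi > g) && (V > -60.0);
  }
  o.inf[iRQ] = 1.0; o.tau[iRQ] = 1e30; // unused row
  {
    double x = std::min(sq(V / p.ep_Vep), 25.0);
    double rate = p.ep_alpha * std::exp((1.0 - p.ep_q) * x);
    o.tau[13] = 1.0 / rate;
    o.inf[13] = std::exp(p.ep_q * x);
    if (!p.aug_on) { o.inf[13] = pore; o.tau[13] = 1e30; }
  }

  const double Irel = (arel * sq(CaSR) / (sq(brel) + sq(CaSR)) + crel) * d * g;
  const double Ileak = Vleak04 * (CaSR - Cai);
  const double Iup = Vmaxup04 / (1.0 + sq(Kup / Cai));
  const double bufCai = 1.0 / (1.0 + Bufc04 * Kbufc / sq(Cai + Kbufc));
  const double bufCasr = 1.0 / (1.0 + Bufsr * Kbufsr / sq(CaSR + Kbufsr));
  o.dconc[0] = bufCai * ((-(ICaL + IbCa + IpCa - 2.0 * INaCa) /
                          (2.0 * Vc * Frdy)) * CAP + Ileak - Iup + Irel);
  o.dconc[1] = bufCasr * (Vc / Vsr) * (Iup - Ileak - Irel);
  o.dconc[2] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) / (Vc * Frdy) * CAP;
  o.dconc[3] = -(IK1 + Ito + IKr + IKs + IpK + IKaug - 2.0 * INaK - Istim) /
               (Vc * Frdy) * CAP;
}


static inline double ttp04_step_node(double V, double* S, const MembParams& p,
                                     double dt, double Istim) {
  TTP04Rates o;
  ttp04_rates(V, S, p, Istim, o, true);
  static const int conc_idx[4] = { iCAI, iCASR, iNAI, iKI };
  // tabulated decay factors for the ten voltage-gated gates
  const double* E = tt04_etab(dt, p.s_tauf);
  const double Vc_ = std::min(std::max(V, -600.0), 600.0);
  double u = (Vc_ - tab04.v0) / tab04.dv;
  if (u < 0) u = 0;
  if (u > tab04.n - 1.001) u = tab04.n - 1.001;
  int i = (int)u;
  double w = u - i;
  const double* ea = &E[(size_t)i * NE04];
  const double* eb = ea + NE04;
  for (int g = 0; g < 10; ++g) {
    double eg = ea[g] * (1.0 - w) + eb[g] * w;
    S[g] = o.inf[g] + (S[g] - o.inf[g]) * eg;
  }
  const double e2 = std::exp(-dt / 2.0);   // fCa and g gates, tau = 2 ms
  if (!o.freeze_fca) S[iF2] = o.inf[iF2] + (S[iF2] - o.inf[iF2]) * e2;
  if (!o.freeze_g) S[iFCASS] = o.inf[iFCASS] + (S[iFCASS] - o.inf[iFCASS]) * e2;
  if (p.aug_on)
    S[iPORE] = o.inf[13] + (S[iPORE] - o.inf[13]) * std::exp(-dt / o.tau[13]);
  for (int c = 0; c < 4; ++c) S[conc_idx[c]] += dt * o.dconc[c];
  return o.Iion;
}

// reduced cubic model: u=(V-Vrest)/amp, w = S[0]
static inline double reduced_iion(double V, const double* S,
                                  const MembParams& p) {
  double u = (V - p.Vrest) / p.rd_amp;
  return -p.rd_amp * (p.rd_k * u * (u - p.rd_a) * (1.0 - u) - u * S[0]);
}
static inline double reduced_step_node(double V, double* S,
                                       const MembParams& p, double dt) {
  double Iion = reduced_iion(V, S, p);
  double u = (V - p.Vrest) / p.rd_amp;
  S[0] += dt * p.rd_eps * (p.rd_k * u - S[0]);
  return Iion;
}

static inline double step_node(double V, double* S, const MembParams& p,
                               double dt, double Istim) {
  switch (p.model) {
    case 0: return ttp_step_node(V, S, p, dt, Istim);
    case 1: return p.Gm * (V - p.Vrest);
    case 3: return ttp04_step_node(V, S, p, dt, Istim);
    default: return reduced_step_node(V, S, p, dt);
  }
}

// [[Rcpp::export]]
List cpp_ionic_eval(NumericVector Vm, NumericMatrix S, List prm,
                    double Istim = 0.0) {
  MembParams p = parse_params(prm);
  int n = Vm.size();
  if (S.nrow() != NSTATE || S.ncol() != n) stop("state dimension mismatch");
  NumericVector Iion(n);
  NumericMatrix dS(NSTATE, n);
  static const int conc_idx[5] = { iCAI, iCASR, iCASS, iNAI, iKI };
  for (int k = 0; k < n; ++k) {
    const double* s = &S(0, k);
    if (p.model == 0) {
      TTPRates o;
      ttp_rates(Vm[k], s, p, Istim, o);
      Iion[k] = o.Iion;
      for (int g = 0; g < 13; ++g) dS(g, k) = (o.inf[g] - s[g]) / o.tau[g];
      dS(iPORE, k) = (o.inf[13] - s[iPORE]) / o.tau[13];
      for (int c = 0; c < 5; ++c) dS(conc_idx[c], k) = o.dconc[c];
    } else if (p.model == 3) {
      TTP04Rates o;
      ttp04_rates(Vm[k], s, p, Istim, o);
      Iion[k] = o.Iion;
      static const int ci4[4] = { iCAI, iCASR, iNAI, iKI };
      for (int g = 0; g < 13; ++g) {
        double d = (o.inf[g] - s[g]) / o.tau[g];
        if (g == iF2 && o.freeze_fca) d = 0.0;
        if (g == iFCASS && o.freeze_g) d = 0.0;
        dS(g, k) = d;
      }
      dS(iPORE, k) = (o.inf[13] - s[iPORE]) / o.tau[13];
      for (int c = 0; c < 4; ++c) dS(ci4[c], k) = o.dconc[c];
    } else if (p.model == 1) {
      Iion[k] = p.Gm * (Vm[k] - p.Vrest);
    } else {
      Iion[k] = reduced_iion(Vm[k], s, p);
      double u = (Vm[k] - p.Vrest) / p.rd_amp;
      dS(0, k) = p.rd_eps * (p.rd_k * u - s[0]);
    }
  }
  return List::create(_["I_ion"] = Iion, _["dstate"] = dS);
}

// augmentation currents alone (zero-length sum when disabled)
// [[Rcpp::export]]
NumericVector cpp_aug_currents(NumericVector Vm, NumericMatrix S, List prm) {
  MembParams p = parse_params(prm);
  int n = Vm.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double V = Vm[k];
    double EK = RTF * std::log(Ko / S(iKI, k));
    double IKaug = p.ka_g * (V - EK) / (1.0 + std::exp((p.ka_Vth - V) / p.ka_k));
    out[k] = p.ep_g * S(iPORE, k) * V + IKaug;
  }
  return out;
}

// single uniform membrane patch driver (also the spatially uniform tissue
// fast path: a uniform state has zero diffusion current exactly).
// stim_times: onsets (ms) of square transmembrane pulses.
// snapshot_times: times (ms) at which full state copies are returned.
// [[Rcpp::export]]
List cpp_run_cell(double V0, NumericVector S0, List prm, double dt,
                  double t_end, double stim_amp, double stim_dur,
                  NumericVector stim_times, double record_dt,
                  NumericVector snapshot_times) {
  MembParams p = parse_params(prm);
  std::vector<double> S(S0.begin(), S0.end());
  double V = V0, Cm = 1.0; // uF/cm2
  long nsteps = (long)std::llround(t_end / dt);
  int nrec = (int)std::floor(t_end / record_dt) + 1;
  NumericVector tr_t(nrec), tr_v(nrec);
  int irec = 0;
  List snaps(snapshot_times.size());
  std::vector<bool> snapped(snapshot_times.size(), false);
  long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  for (long it = 0; it <= nsteps; ++it) {
    double t = it * dt;
    if (it % rec_every == 0 && irec < nrec) { tr_t[irec] = t; tr_v[irec] = V; ++irec; }
    for (int q = 0; q < snapshot_times.size(); ++q) {
      if (!snapped[q] && t >= snapshot_times[q] - 1e-9) {
        snaps[q] = List::create(_["t"] = t, _["Vm"] = V,
                                _["state"] = NumericVector(S.begin(), S.end()));
        snapped[q] = true;
      }
    }
    if (it == nsteps) break;
    double Is = 0.0;
    for (int q = 0; q < stim_times.size(); ++q)
      if (t >= stim_times[q] - 1e-9 && t < stim_times[q] + stim_dur - 1e-9)
        Is = stim_amp;
    double Iion = step_node(V, S.data(), p, dt, Is);
    V += dt * (-(Iion - Is) / Cm);
    if (!std::isfinite(V)) stop("membrane integration diverged (non-finite Vm)");
  }
  return List::create(_["t"] = tr_t[Range(0, irec - 1)],
                      _["Vm"] = tr_v[Range(0, irec - 1)],
                      _["Vm_end"] = V,
                      _["state_end"] = NumericVector(S.begin(), S.end()),
                      _["snapshots"] = snaps);
}

// interpolation-table fidelity: largest relative deviation between the
// tabulated and directly evaluated voltage-dependent terms over a V sweep
// [[Rcpp::export]]
double cpp_tt04_table_error(NumericVector V) {
  double worst = 0.0;
  double a[NV04], b[NV04];
  for (int k = 0; k < V.size(); ++k) {
    tt04_vdep(std::min(std::max(V[k], -600.0), 600.0), a);
    tt04_vdep_interp(V[k], b);
    for (int c = 0; c < NV04; ++c) {
      double rel = std::fabs(a[c] - b[c]) /
                   std::max(std::fabs(a[c]), 1e-12);
      if (rel > worst) worst = rel;
    }
  }
  return worst;
}

// sparse CSR matvec: y = A x  (A given by rowptr/colind/vals, 0-based)
static inline void csr_mv(const IntegerVector& rp, const IntegerVector& ci,
                          const NumericVector& vx, const double* x, double* y,
                          int n) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int q = rp[i]; q < rp[i + 1]; ++q) acc += vx[q] * x[ci[q]];
    y[i] = acc;
  }
}

// monodomain driver: explicit diffusion + membrane over n_steps.
// invM = 1/(beta*Cm*m_i) per node; stim = per-node transmembrane current
// density (uA/cm2) active on steps [stim_on, stim_off).
// Records Vm frames every `stride` steps (including step 0).
// [[Rcpp::export]]
List cpp_run_monodomain(NumericVector Vm0, NumericMatrix S0, List prm,
                        IntegerVector rp, IntegerVector ci, NumericVector vx,
                        NumericVector invM, double Cm, double dt, long n_steps,
                        NumericVector stim, long stim_on, long stim_off,
                        long stride) {
  MembParams p = parse_params(prm);
  int n = Vm0.size();
  std::vector<double> V(Vm0.begin(), Vm0.end());
  NumericMatrix S = clone(S0);
  std::vector<double> KV(n);
  int nframes = (int)(n_steps / stride) + 1;
  NumericMatrix frames(n, nframes);
  NumericVector ftimes(nframes);
  int fi = 0;
  for (long it = 0; it <= n_steps; ++it) {
    if (it % stride == 0 && fi < nframes) {
      for (int i = 0; i < n; ++i) frames(i, fi) = V[i];
      ftimes[fi] = it * dt;
      ++fi;
    }
    if (it == n_steps) break;
    csr_mv(rp, ci, vx, V.data(), KV.data(), n);
    bool stim_now = (it >= stim_on && it < stim_off);
    for (int i = 0; i < n; ++i) {
      double Is = stim_now ? stim[i] : 0.0;
      double Iion = step_node(V[i], &S(0, i), p, dt, Is);
      V[i] += dt * (-KV[i] * invM[i] - (Iion - Is) / Cm);
    }
    if (it % 200 == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 500.0)
          stop("instability: |Vm| exceeded 500 mV at t=%f ms", it * dt);
    }
  }
  return List::create(_["Vm"] = NumericVector(V.begin(), V.end()),
                      _["state"] = S,
                      _["frames"] = frames, _["n_frames"] = fi,
                      _["frame_times"] = ftimes[Range(0, fi - 1)]);
}

// parabolic substeps of the operator-split bidomain update with phi_e frozen:
//   beta Cm M dVm/dt = -Ki (Vm + phi_e) - M beta (Iion - Is)
// Vm and S are modified IN PLACE (caller owns fresh copies).
// [[Rcpp::export]]
double cpp_parabolic_substeps(NumericVector Vm, NumericMatrix S, List prm,
                              IntegerVector rp, IntegerVector ci,
                              NumericVector vx, NumericVector phie,
                              NumericVector invM, double Cm, double dt,
                              int n_sub, NumericVector stim, bool stim_now) {
  MembParams p = parse_params(prm);
  int n = Vm.size();
  std::vector<double> W(n), KV(n);
  double vmax = -1e30;
  for (int sub = 0; sub < n_sub; ++sub) {
    for (int i = 0; i < n; ++i) W[i] = Vm[i] + phie[i];
    csr_mv(rp, ci, vx, W.data(), KV.data(), n);
    for (int i = 0; i < n; ++i) {
      double Is = stim_now ? stim[i] : 0.0;
      double Iion = step_node(Vm[i], &S(0, i), p, dt, Is);
      Vm[i] += dt * (-KV[i] * invM[i] - (Iion - Is) / Cm);
      if (Vm[i] > vmax) vmax = Vm[i];
      if (!std::isfinite(Vm[i]) || std::fabs(Vm[i]) > 500.0)
        stop("instability: |Vm| exceeded 500 mV during shock substep");
    }
  }
  return vmax;
}

// connected components of a logical mask on a structured grid
// (4-adjacency in 2-D, 6-face adjacency in 3-D); returns component labels
// (0 = background) with attribute "count".
// [[Rcpp::export]]
IntegerVector cpp_connected_components(LogicalVector mask, IntegerVector dims) {
  int nd = dims.size();
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  long n = (long)nx * ny * nz;
  if ((long)mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  int comp = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++comp;
    stack.push_back(s);
    lab[s] = comp;
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int i = c % nx, j = (c / nx) % ny, k = c / ((long)nx * ny);
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      int nb = (nd == 3) ? 6 : 4;
      for (int q = 0; q < nb; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        long cc = ii + (long)nx * (jj + (long)ny * kk);
        if (mask[cc] && !lab[cc]) { lab[cc] = comp; stack.push_back(cc); }
      }
    }
  }
  lab.attr("count") = comp;
  return lab;
}
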