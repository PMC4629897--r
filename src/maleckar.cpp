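// Compiled kernels for the human atrial myocyte model (Maleckar-type,
// Nygren-lineage formulation with reformulated I_t / I_Kur) and for the
// per-node reaction step of the monodomain solver.
//
// Units: mV, ms, pA, pF, nS, mM, nL. Rate constants of the published
// formulation are per second; they are converted to per millisecond here.
// Gating variables advance by Rush-Larsen, everything else by forward Euler.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// state vector layout (must match R side maleckarStateNames())
enum StateIdx {
  iV = 0, iNac, iNai, iKc, iKi, iCac, iCai, iCad, iCaup, iCarel,
  im, ih1, ih2, idL, ifL1, ifL2, ir, is_, iaur, iiur, in_, ipa,
  iF1, iF2, iOC, iOTC, iOTMgC, iOTMgMg, iOCalse, N_STATE
};

struct MalConsts {
  double F, RTF, Cm;
  double PNa, gCaL, ECaapp, kCa, gt, gkur, gK1, gKs, gKr, gBNa, gBCa;
  double KNaKK, iNaKmax, KNaKNa, iCaPmax, kCaP, KNaCa, gammaNa, dNaCa, phiNaen;
  double Voli, Volc, Vold, Volrel, Volup;
  double tauNa, tauK, tauCa, Nab, Kb, Cab, Mgi;
  double Iupmax, kcyca, ksrca, kxcs, tautr, alpharel, rrecov, taudi;
  double ACh;
  double sgt, sgCaL, sgKr;  // regional conductance scalings
};

static MalConsts buildConsts(const NumericVector& cv, double sgt, double sgCaL,
                             double sgKr) {
  MalConsts c;
  double R = cv["R"], T = cv["T"];
  c.F = cv["F"];
  c.RTF = R * T / c.F;  // mV
  c.Cm = cv["Cm"];
  c.PNa = cv["P_Na"];
  c.gCaL = cv["g_CaL"];
  c.ECaapp = cv["E_Ca_app"];
  c.kCa = cv["k_Ca"];
  c.gt = cv["g_t"];
  c.gkur = cv["g_kur"];
  c.gK1 = cv["g_K1"];
  c.gKs = cv["g_Ks"];
  c.gKr = cv["g_Kr"];
  c.gBNa = cv["g_B_Na"];
  c.gBCa = cv["g_B_Ca"];
  c.KNaKK = cv["K_NaK_K"];
  c.iNaKmax = cv["i_NaK_max"];
  c.KNaKNa = cv["K_NaK_Na"];
  c.iCaPmax = cv["i_CaP_max"];
  c.kCaP = cv["k_CaP"];
  c.KNaCa = cv["K_NaCa"];
  c.gammaNa = cv["gamma_Na"];
  c.dNaCa = cv["d_NaCa"];
  c.phiNaen = cv["phi_Na_en"];
  c.Voli = cv["Vol_i"];
  c.Volc = cv["Vol_c"];
  c.Vold = cv["Vol_d"];
  c.Volrel = cv["Vol_rel"];
  c.Volup = cv["Vol_up"];
  c.tauNa = cv["tau_Na"];
  c.tauK = cv["tau_K"];
  c.tauCa = cv["tau_Ca"];
  c.Nab = cv["Na_b"];
  c.Kb = cv["K_b"];
  c.Cab = cv["Ca_b"];
  c.Mgi = cv["Mg_i"];
  c.Iupmax = cv["I_up_max"];
  c.kcyca = cv["k_cyca"];
  c.ksrca = cv["k_srca"];
  c.kxcs = cv["k_xcs"];
  c.tautr = cv["tau_tr"];
  c.alpharel = cv["alpha_rel"];
  c.rrecov = cv["r_recov"];
  c.taudi = cv["tau_di"];
  c.ACh = cv["ACh"];
  c.sgt = sgt;
  c.sgCaL = sgCaL;
  c.sgKr = sgKr;
  return c;
}

static inline double sq(double x) { return x * x; }

// advance one node by dt (ms); istim in pA/pF, positive = depolarizing
static inline void mal_step(double* y, double istim, double dt,
                            const MalConsts& c) {
  const double V = y[iV];
  const double Nac = y[iNac], Nai = y[iNai];
  const double Kc = y[iKc], Ki = y[iKi];
  const double Cac = y[iCac], Cai = y[iCai], Cad = y[iCad];
  const double Caup = y[iCaup], Carel = y[iCarel];

  const double ENa = c.RTF * std::log(Nac / Nai);
  const double EK = c.RTF * std::log(Kc / Ki);
  const double ECa = 0.5 * c.RTF * std::log(Cac / Cai);

  // I_Na (GHK-type)
  const double den = std::expm1(V / c.RTF);
  const double Vfac = (std::fabs(V) < 1e-6) ? c.RTF : V / den;
  const double m3 = y[im] * y[im] * y[im];
  const double iNa = c.PNa * m3 * (0.9 * y[ih1] + 0.1 * y[ih2]) * Nac *
                     (c.F / c.RTF) * Vfac * std::expm1((V - ENa) / c.RTF);

  // I_CaL
  const double fCa = Cad / (Cad + c.kCa);
  const double iCaL = c.sgCaL * c.gCaL * y[idL] *
                      (fCa * y[ifL1] + (1.0 - fCa) * y[ifL2]) * (V - c.ECaapp);

  // I_t, I_Kur
  const double it = c.sgt * c.gt * y[ir] * y[is_] * (V - EK);
  const double iKur = c.gkur * y[iaur] * y[iiur] * (V - EK);

  // I_K1, I_Kr, I_Ks
  const double iK1 = c.gK1 * std::pow(Kc, 0.4457) * (V - EK) /
                     (1.0 + std::exp(1.5 * (V - EK + 3.6) / c.RTF));
  const double pip = 1.0 / (1.0 + std::exp((V + 55.0) / 24.0));
  const double iKr = c.sgKr * c.gKr * y[ipa] * pip * (V - EK);
  const double iKs = c.gKs * y[in_] * (V - EK);

  // background, pumps, exchanger
  const double iBNa = c.gBNa * (V - ENa);
  const double iBCa = c.gBCa * (V - ECa);
  const double nai15 = std::pow(Nai, 1.5);
  const double iNaK = c.iNaKmax * Kc / (Kc + c.KNaKK) * nai15 /
                      (nai15 + std::pow(c.KNaKNa, 1.5)) * (V + 150.0) /
                      (V + 200.0);
  const double iCaP = c.iCaPmax * Cai / (Cai + c.kCaP);
  const double na3i = Nai * Nai * Nai, na3c = Nac * Nac * Nac;
  const double iNaCa =
      c.KNaCa *
      (na3i * Cac * std::exp(c.gammaNa * V / c.RTF) -
       na3c * Cai * std::exp((c.gammaNa - 1.0) * V / c.RTF)) /
      (1.0 + c.dNaCa * (na3c * Cai + na3i * Cac));

  // I_K,ACh (negligible at the default agonist level)
  const double iKACh = 10.0 / (1.0 + 9.13652 / std::pow(c.ACh, 0.477811)) *
                       (0.0517 + 0.4516 / (1.0 + std::exp((V + 59.53) / 17.18))) *
                       (V - EK) * c.Cm;

  const double iStimPA = -istim * c.Cm;  // applied depolarizing current, pA

  const double Itot = iNa + iCaL + it + iKur + iK1 + iKr + iKs + iBNa + iBCa +
                      iNaK + iCaP + iNaCa + iKACh + iStimPA;

  // SR and diadic fluxes (pA-equivalent)
  const double idi = (Cad - Cai) * 2.0 * c.F * c.Vold / c.taudi;
  const double iup = c.Iupmax *
                     (Cai / c.kcyca - c.kxcs * c.kxcs * Caup / c.ksrca) /
                     ((Cai + c.kcyca) / c.kcyca +
                      c.kxcs * (Caup + c.ksrca) / c.ksrca);
  const double itr = (Caup - Carel) * 2.0 * c.F * c.Volrel / c.tautr;
  const double rdi = Cad / (Cad + 0.003);
  const double rci = Cai / (Cai + 0.0003);
  const double ract = 203.8 * (rci * rci * rci * rci + rdi * rdi * rdi * rdi);
  const double rinact = 33.96 + 339.6 * rci * rci * rci * rci;
  const double f2frac = y[iF2] / (y[iF2] + 0.25);
  const double irel = c.alpharel * f2frac * f2frac * (Carel - Cai);

  // buffer rates (per s)
  const double dOC = 200000.0 * Cai * (1.0 - y[iOC]) - 476.0 * y[iOC];
  const double dOTC = 78400.0 * Cai * (1.0 - y[iOTC]) - 392.0 * y[iOTC];
  const double dOTMgC =
      200000.0 * Cai * (1.0 - y[iOTMgC] - y[iOTMgMg]) - 6.6 * y[iOTMgC];
  const double dOTMgMg =
      2000.0 * c.Mgi * (1.0 - y[iOTMgC] - y[iOTMgMg]) - 666.0 * y[iOTMgMg];
  const double dOCalse = 480.0 * Carel * (1.0 - y[iOCalse]) - 400.0 * y[iOCalse];

  // concentration rates (mM per s)
  const double dNai =
      -(iNa + iBNa + 3.0 * iNaCa + 3.0 * iNaK + c.phiNaen) / (c.Voli * c.F);
  const double dKi =
      -(it + iKur + iK1 + iKs + iKr - 2.0 * iNaK + iKACh + iStimPA) /
      (c.Voli * c.F);
  const double dCai =
      -(iBCa + iCaP + iup - (idi + irel + 2.0 * iNaCa)) / (2.0 * c.Voli * c.F) -
      (0.08 * dOTC + 0.16 * dOTMgC + 0.045 * dOC);
  const double dCad = -(iCaL + idi) / (2.0 * c.Vold * c.F);
  const double dNac = (c.Nab - Nac) / c.tauNa +
                      (iNa + iBNa + 3.0 * iNaCa + 3.0 * iNaK + c.phiNaen) /
                          (c.Volc * c.F);
  const double dKc = (c.Kb - Kc) / c.tauK +
                     (it + iKur + iK1 + iKs + iKr + iKACh - 2.0 * iNaK) /
                         (c.Volc * c.F);
  const double dCac = (c.Cab - Cac) / c.tauCa +
                      (iCaL + iBCa + iCaP - 2.0 * iNaCa) / (2.0 * c.Volc * c.F);
  const double dCaup = (iup - itr) / (2.0 * c.Volup * c.F);
  const double dCarel = (itr - irel) / (2.0 * c.Volrel * c.F) - 31.0 * dOCalse;

  const double dts = dt * 1e-3;  // s

  // gating: Rush-Larsen with tau in ms
  {
    const double minf = 1.0 / (1.0 + std::exp(-(V + 27.12) / 8.21));
    const double taum = (0.000042 * std::exp(-sq((V + 25.57) / 28.8)) + 0.000024) * 1e3;
    y[im] += (minf - y[im]) * (1.0 - std::exp(-dt / taum));

    const double hinf = 1.0 / (1.0 + std::exp((V + 63.6) / 5.3));
    const double hfac = 1.0 / (1.0 + std::exp((V + 35.1) / 3.2));
    const double tauh1 = (0.03 * hfac + 0.0003) * 1e3;
    const double tauh2 = (0.12 * hfac + 0.003) * 1e3;
    y[ih1] += (hinf - y[ih1]) * (1.0 - std::exp(-dt / tauh1));
    y[ih2] += (hinf - y[ih2]) * (1.0 - std::exp(-dt / tauh2));

    const double dinf = 1.0 / (1.0 + std::exp(-(V + 9.0) / 5.8));
    const double taud = (0.0027 * std::exp(-sq((V + 35.0) / 30.0)) + 0.002) * 1e3;
    y[idL] += (dinf - y[idL]) * (1.0 - std::exp(-dt / taud));

    const double finf = 1.0 / (1.0 + std::exp((V + 27.4) / 7.1));
    const double tauf1 = (0.161 * std::exp(-sq((V + 40.0) / 14.4)) + 0.01) * 1e3;
    const double tauf2 = (1.3323 * std::exp(-sq((V + 40.0) / 14.2)) + 0.0626) * 1e3;
    y[ifL1] += (finf - y[ifL1]) * (1.0 - std::exp(-dt / tauf1));
    y[ifL2] += (finf - y[ifL2]) * (1.0 - std::exp(-dt / tauf2));

    const double rinf = 1.0 / (1.0 + std::exp(-(V - 1.0) / 11.0));
    const double taur = (0.0035 * std::exp(-sq(V / 30.0)) + 0.0015) * 1e3;
    y[ir] += (rinf - y[ir]) * (1.0 - std::exp(-dt / taur));

    const double sinf = 1.0 / (1.0 + std::exp((V + 40.5) / 11.5));
    const double taus = (0.025635 * std::exp(-sq((V + 52.45) / 15.8827)) + 0.01414) * 1e3;
    y[is_] += (sinf - y[is_]) * (1.0 - std::exp(-dt / taus));

    const double aurinf = 1.0 / (1.0 + std::exp(-(V + 6.0) / 8.6));
    const double tauaur = (0.009 / (1.0 + std::exp((V + 5.0) / 12.0)) + 0.0005) * 1e3;
    y[iaur] += (aurinf - y[iaur]) * (1.0 - std::exp(-dt / tauaur));

    const double iurinf = 1.0 / (1.0 + std::exp((V + 7.5) / 10.0));
    const double tauiur = (0.59 / (1.0 + std::exp((V + 60.0) / 10.0)) + 3.05) * 1e3;
    y[iiur] += (iurinf - y[iiur]) * (1.0 - std::exp(-dt / tauiur));

    const double ninf = 1.0 / (1.0 + std::exp(-(V - 19.9) / 12.7));
    const double taun = (0.7 + 0.4 * std::exp(-sq((V - 20.0) / 20.0))) * 1e3;
    y[in_] += (ninf - y[in_]) * (1.0 - std::exp(-dt / taun));

    const double painf = 1.0 / (1.0 + std::exp(-(V + 15.0) / 6.0));
    const double taupa = (0.03118 + 0.21718 * std::exp(-sq((V + 20.1376) / 22.1996))) * 1e3;
    y[ipa] += (painf - y[ipa]) * (1.0 - std::exp(-dt / taupa));
  }

  // SR release gates and buffers: forward Euler (rates per s)
  y[iF1] += dts * (c.rrecov * (1.0 - y[iF1] - y[iF2]) - ract * y[iF1]);
  y[iF2] += dts * (ract * y[iF1] - rinact * y[iF2]);
  y[iOC] += dts * dOC;
  y[iOTC] += dts * dOTC;
  y[iOTMgC] += dts * dOTMgC;
  y[iOTMgMg] += dts * dOTMgMg;
  y[iOCalse] += dts * dOCalse;

  y[iNai] += dts * dNai;
  y[iKi] += dts * dKi;
  y[iCai] += dts * dCai;
  y[iCad] += dts * dCad;
  y[iNac] += dts * dNac;
  y[iKc] += dts * dKc;
  y[iCac] += dts * dCac;
  y[iCaup] += dts * dCaup;
  y[iCarel] += dts * dCarel;

  y[iV] += dt * (-(Itot) / c.Cm);
}

// APD at the given repolarization fraction from one beat's Vm samples.
// onset = time of max dV/dt; rest = pre-stimulus diastolic Vm (beat start).
// Returns NA if no crossing.
static double beat_apd(const std::vector<double>& vbuf, double dt,
                       double fraction) {
  const int n = (int)vbuf.size();
  if (n < 3) return NA_REAL;
  int onset = 1;
  double maxd = -1e300;
  for (int i = 1; i < n; ++i) {
    double d = vbuf[i] - vbuf[i - 1];
    if (d > maxd) { maxd = d; onset = i; }
  }
  const double rest = vbuf[0];
  double peak = -1e300;
  int peakIdx = onset;
  for (int i = onset; i < n; ++i)
    if (vbuf[i] > peak) { peak = vbuf[i]; peakIdx = i; }
  if (peak - rest < 10.0) return NA_REAL;  // no beat
  const double level = peak - fraction * (peak - rest);
  for (int i = peakIdx + 1; i < n; ++i) {
    if (vbuf[i] <= level && vbuf[i - 1] > level) {
      const double frac = (vbuf[i - 1] - level) / (vbuf[i - 1] - vbuf[i]);
      const double tcross = (i - 1 + frac) * dt;
      return tcross - onset * dt;
    }
  }
  return NA_REAL;
}

// [[Rcpp::export]]
List paceCellCpp(NumericVector constants, NumericVector scalings,
                 NumericVector init, int n_beats, double bcl, double stim_amp,
                 double stim_dur, double dt, double sample_dt, int record_beats,
                 bool stop_on_converged, int conv_window, double conv_tol,
                 int min_beats, double apd_fraction) {
  MalConsts c = buildConsts(constants, scalings[0], scalings[1], scalings[2]);
  double y[N_STATE];
  for (int i = 0; i < N_STATE; ++i) y[i] = init[i];

  const int spb = (int)std::lround(bcl / dt);          // steps per beat
  const int sstride = std::max(1, (int)std::lround(sample_dt / dt));
  const int cap = record_beats * (spb / sstride + 2) + 8;

  std::vector<double> rt(cap), rv(cap), rna(cap), rk(cap), rca(cap);
  int rn = 0, rpos = 0;
  bool wrapped = false;

  NumericMatrix prestim(n_beats, 3);
  NumericVector apd(n_beats, NA_REAL);
  std::vector<double> vbuf((size_t)spb + 1);

  double blowup_t = -1.0;
  int beats_run = 0;
  bool converged = false;

  for (int b = 0; b < n_beats && blowup_t < 0.0; ++b) {
    prestim(b, 0) = y[iNai];
    prestim(b, 1) = y[iKi];
    prestim(b, 2) = y[iCai];
    vbuf[0] = y[iV];
    for (int k = 0; k < spb; ++k) {
      const double tbeat = k * dt;
      const double tglob = b * bcl + tbeat;
      const double istim = (tbeat < stim_dur) ? stim_amp : 0.0;
      mal_step(y, istim, dt, c);
      vbuf[(size_t)k + 1] = y[iV];
      if (((k + 1) % sstride) == 0) {
        rt[rpos] = tglob + dt;
        rv[rpos] = y[iV];
        rna[rpos] = y[iNai];
        rk[rpos] = y[iKi];
        rca[rpos] = y[iCai];
        ++rpos;
        if (rpos == cap) { rpos = 0; wrapped = true; }
        if (rn < cap) ++rn;
      }
      if ((k & 255) == 0 && !std::isfinite(y[iV])) {
        blowup_t = tglob;
        break;
      }
    }
    if (blowup_t >= 0.0) break;
    apd[b] = beat_apd(vbuf, dt, apd_fraction);
    beats_run = b + 1;
    if (stop_on_converged && beats_run >= min_beats && b >= conv_window &&
        R_finite(apd[b]) && R_finite(apd[b - conv_window]) &&
        std::fabs(apd[b] - apd[b - conv_window]) < conv_tol) {
      converged = true;
      break;
    }
  }

  // unroll ring buffer chronologically
  NumericVector ot(rn), ov(rn), ona(rn), ok(rn), oca(rn);
  int start = wrapped ? rpos : 0;
  for (int i = 0; i < rn; ++i) {
    int j = (start + i) % cap;
    ot[i] = rt[j];
    ov[i] = rv[j];
    ona[i] = rna[j];
    ok[i] = rk[j];
    oca[i] = rca[j];
  }

  NumericVector fin(N_STATE);
  for (int i = 0; i < N_STATE; ++i) fin[i] = y[i];

  return List::create(
      _["time"] = ot, _["Vm"] = ov, _["Na_i"] = ona, _["K_i"] = ok,
      _["Ca_i"] = oca,
      _["prestim"] = prestim(Range(0, std::max(beats_run - 1, 0)), _),
      _["apd"] = apd[Range(0, std::max(beats_run - 1, 0))],
      _["beats_run"] = beats_run, _["converged"] = converged,
      _["final_state"] = fin, _["blowup_time"] = blowup_t);
}

// Advance all nodes of a tissue by one reaction step of length dt.
// state: N_STATE x nNodes, modified in place. scalings: 3 x nRegions,
// region: 1-based region index per node, istim: pA/pF per node.
// Returns -1 on success, else the 1-based index of the first node whose
// Vm became non-finite.
// [[Rcpp::export]]
int reactionStepCpp(NumericMatrix state, NumericVector constants,
                    NumericMatrix scalings, IntegerVector region,
                    NumericVector istim, double dt) {
  const int nn = state.ncol();
  const int nr = scalings.ncol();
  std::vector<MalConsts> cs;
  cs.reserve(nr);
  for (int r = 0; r < nr; ++r)
    cs.push_back(buildConsts(constants, scalings(0, r), scalings(1, r),
                             scalings(2, r)));
  double* p = REAL(state);
  for (int j = 0; j < nn; ++j) {
    mal_step(p + (size_t)j * N_STATE, istim[j], dt, cs[region[j] - 1]);
    if (!std::isfinite(p[(size_t)j * N_STATE + iV])) return j + 1;
  }
  return -1;
}
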