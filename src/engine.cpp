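// Compiled core of the LP-neuron simulator.
//
// Unit system (self-consistent): mV, ms, nA, uS, nF, MOhm, mM.
//   uS * mV = nA;  mV / MOhm = nA;  nF * mV / ms = nA.
// Sign convention: ionic/synaptic currents positive = outward.
//
// The voltage step is semi-implicit (backward Euler on the linear part of
// the membrane equation, with channel open fractions and the GHK current
// frozen at the beginning of the step), so the 4x4 compartment system is
// solved exactly each step; gates, calcium pools and the PD synaptic gate
// advance by exponential integrators. This mirrors the staggered
// Crank-Nicolson/implicit schemes used by compartmental simulators and is
// unconditionally stable for the coupled RC network.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- channel matrix column layout (kept in lock-step with R/cell.R) ----
enum {
  CH_COMP = 0, CH_KIND, CH_G, CH_EREV, CH_P, CH_Q,
  CH_AVH, CH_AK, CH_ATT, CH_AC0, CH_AAMP, CH_AVHT, CH_AK1, CH_AK2,
  CH_IVH, CH_IK, CH_ITT, CH_IC0, CH_IAMP, CH_IVHT, CH_IK1, CH_IK2,
  CH_CADEP, CH_KD, CH_CAO, CH_TEMP, CH_Z, CH_NCOL
};
enum { SY_DRIVE = 0, SY_COMP, SY_G, SY_EREV, SY_VTH, SY_VSC, SY_TAU, SY_NCOL };
enum { CA_COMP = 0, CA_REST, CA_TAU, CA_F, CA_NCOL };

static const double BOLTZ_OVER_QE = 8.617333262e-2; // k/qe in mV per Kelvin
static const double FARADAY = 96485.33212;          // NA*qe, C/mol
static const double XI_CUTOFF = 1e-4;
static const double CA_FLOOR = 1e-9;                // mM, keeps pool positive

static inline double sigm(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static inline double tau_eval(int type, double c0, double amp, double vh,
                              double k1, double k2, double v) {
  if (type == 0) return c0;
  if (type == 1) return c0 + amp / (1.0 + std::exp((v - vh) / k1));
  // bell: two-sided exponential well
  return c0 + amp / (std::exp((v - vh) / k1) + std::exp(-(v - vh) / k2));
}

// GHK concentration bracket: cai*(-xi)/(exp(-xi)-1) - cao*xi/(exp(xi)-1),
// with the second-order series below |xi| < 1e-4 (both Boltzmann factors -> 1).
static inline double ghk_bracket(double v, double cai, double cao, double temp,
                                 double z) {
  double xi = z * v / (BOLTZ_OVER_QE * temp);
  if (std::fabs(xi) < XI_CUTOFF) {
    return (cai - cao) + 0.5 * xi * (cai + cao) +
           (xi * xi / 12.0) * (cai - cao);
  }
  return cai * (-xi) / (std::exp(-xi) - 1.0) - cao * xi / (std::exp(xi) - 1.0);
}

// ---------------- elementary kernels (exported for the R wrappers) --------

// [[Rcpp::export]]
double cppOhmicCurrent(double gbar, double w, double v, double erev) {
  return gbar * w * (v - erev);
}

// [[Rcpp::export]]
double cppGhkCurrent(double pbar, double w, double cai, double cao, double v,
                     double temp, double z) {
  return pbar * w * z * FARADAY * ghk_bracket(v, cai, cao, temp, z);
}

// [[Rcpp::export]]
NumericVector cppGateInfTau(double v, double vhalf, double slope, int tauType,
                            double c0, double amp, double vhTau, double k1,
                            double k2) {
  NumericVector out(2);
  out[0] = sigm(v, vhalf, slope);
  out[1] = tau_eval(tauType, c0, amp, vhTau, k1, k2, v);
  return out;
}

// First-order calcium pool, exact exponential update over dt:
// dCa/dt = (ca_rest - ca)/tau - f*i_ca  (i_ca in nA, inward negative).
// [[Rcpp::export]]
double cppStepCalcium(double cai, double iCa, double dt, double caRest,
                      double tauCa, double f) {
  double target = caRest - f * tauCa * iCa;
  double out = target + (cai - target) * std::exp(-dt / tauCa);
  return out > CA_FLOOR ? out : CA_FLOOR;
}

// ---------------- integrator ---------------------------------------------

struct CellC {
  double caps[4];
  // dense symmetric coupling conductance matrix (1/R, in uS since R in MOhm)
  double gax[4][4];
  NumericMatrix chan;
  NumericMatrix syn;
  NumericMatrix ca;
  int nchan, nsyn, nca;
  int caIndexOfComp[4]; // -1 if compartment has no pool
};

static CellC unpack_cell(List cell) {
  CellC c;
  NumericVector caps = cell["capacitances"];
  for (int i = 0; i < 4; ++i) c.caps[i] = caps[i];
  NumericMatrix edges = cell["edges"]; // cols: i, j (0-based), R in Ohm
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) c.gax[i][j] = 0.0;
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = (int)edges(e, 0), j = (int)edges(e, 1);
    double g = 1.0 / (edges(e, 2) / 1e6); // Ohm -> MOhm -> uS
    c.gax[i][j] += g;
    c.gax[j][i] += g;
  }
  c.chan = as<NumericMatrix>(cell["chanMat"]);
  c.syn = as<NumericMatrix>(cell["synMat"]);
  c.ca = as<NumericMatrix>(cell["caMat"]);
  c.nchan = c.chan.nrow();
  c.nsyn = c.syn.nrow();
  c.nca = c.ca.nrow();
  for (int i = 0; i < 4; ++i) c.caIndexOfComp[i] = -1;
  for (int k = 0; k < c.nca; ++k) c.caIndexOfComp[(int)c.ca(k, CA_COMP)] = k;
  return c;
}

// State layout (documented, fixed): V[0..3]; per channel row in order: m (if
// p>0) then h (if q>0); then one [Ca]i per caMat row; then one s per synapse
// row with tau > 0.
static int state_length(const CellC &c) {
  int n = 4;
  for (int r = 0; r < c.nchan; ++r) {
    if (c.chan(r, CH_P) > 0) ++n;
    if (c.chan(r, CH_Q) > 0) ++n;
  }
  n += c.nca;
  for (int s = 0; s < c.nsyn; ++s)
    if (c.syn(s, SY_TAU) > 0) ++n;
  return n;
}

// Lookup tables for gate steady states and time constants on a voltage grid.
struct GateTab {
  std::vector<double> inf, tau;
};
static const double VMIN = -150.0, VMAX = 80.0, VSTEP = 0.05;
static const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 1;

// the tau slot holds exp(-dt/tau(V)) so the hot loop needs no exp() call
static void build_tab(GateTab &t, double vh, double k, int tt, double c0,
                      double amp, double vht, double k1, double k2,
                      double dt) {
  t.inf.resize(NTAB);
  t.tau.resize(NTAB);
  for (int i = 0; i < NTAB; ++i) {
    double v = VMIN + i * VSTEP;
    t.inf[i] = sigm(v, vh, k);
    t.tau[i] = std::exp(-dt / tau_eval(tt, c0, amp, vht, k1, k2, v));
  }
}

static inline void tab_lookup(const GateTab &t, double v, double &inf,
                              double &tau) {
  double x = (v - VMIN) / VSTEP;
  // NaN-safe: non-finite x falls into the first branch
  if (!(x > 0)) { inf = t.inf[0]; tau = t.tau[0]; return; }
  if (x >= NTAB - 1) { inf = t.inf[NTAB - 1]; tau = t.tau[NTAB - 1]; return; }
  int i = (int)x;
  double f = x - i;
  inf = t.inf[i] * (1 - f) + t.inf[i + 1] * f;
  tau = t.tau[i] * (1 - f) + t.tau[i + 1] * f;
}

struct Engine {
  CellC cell;
  std::vector<GateTab> actTab, inactTab;
  bool useTables;
  NumericMatrix drive; // nper x ndrive, presynaptic mV sampled on dt grid
  int nper;
  double dt;

  // flat per-channel copies of the channel matrix (hot-loop friendly)
  std::vector<int> cComp, cKind, cP, cQ, cCadep;
  std::vector<double> cG, cErev, cKd, cCao, cTemp, cZ;
  // flat synapse copies
  std::vector<int> sDrive, sComp;
  std::vector<double> sG, sErev, sVth, sVsc, sTau;
  // flat calcium-pool copies
  std::vector<int> pComp;
  std::vector<double> pRest, pTau, pF, pDec, synDec;

  // scratch per step
  double G[4], B[4], Ighk[4], Ica[4];
  std::vector<int> mIdx, hIdx;
  int caOff, sOff;

  Engine(List cellList, NumericMatrix driveMat, double dt_, bool tables)
      : cell(unpack_cell(cellList)), useTables(tables), drive(driveMat),
        nper(driveMat.nrow()), dt(dt_) {
    mIdx.assign(cell.nchan, -1);
    hIdx.assign(cell.nchan, -1);
    int gi = 4;
    for (int r = 0; r < cell.nchan; ++r) {
      if (cell.chan(r, CH_P) > 0) mIdx[r] = gi++;
      if (cell.chan(r, CH_Q) > 0) hIdx[r] = gi++;
    }
    caOff = gi;
    sOff = caOff + cell.nca;
    for (int r = 0; r < cell.nchan; ++r) {
      cComp.push_back((int)cell.chan(r, CH_COMP));
      cKind.push_back((int)cell.chan(r, CH_KIND));
      cP.push_back((int)cell.chan(r, CH_P));
      cQ.push_back((int)cell.chan(r, CH_Q));
      cCadep.push_back((int)cell.chan(r, CH_CADEP));
      cG.push_back(cell.chan(r, CH_G));
      cErev.push_back(cell.chan(r, CH_EREV));
      cKd.push_back(cell.chan(r, CH_KD));
      cCao.push_back(cell.chan(r, CH_CAO));
      cTemp.push_back(cell.chan(r, CH_TEMP));
      cZ.push_back(cell.chan(r, CH_Z));
    }
    for (int s = 0; s < cell.nsyn; ++s) {
      sDrive.push_back((int)cell.syn(s, SY_DRIVE));
      sComp.push_back((int)cell.syn(s, SY_COMP));
      sG.push_back(cell.syn(s, SY_G));
      sErev.push_back(cell.syn(s, SY_EREV));
      sVth.push_back(cell.syn(s, SY_VTH));
      sVsc.push_back(cell.syn(s, SY_VSC));
      sTau.push_back(cell.syn(s, SY_TAU));
    }
    for (int k = 0; k < cell.nca; ++k) {
      pComp.push_back((int)cell.ca(k, CA_COMP));
      pRest.push_back(cell.ca(k, CA_REST));
      pTau.push_back(cell.ca(k, CA_TAU));
      pF.push_back(cell.ca(k, CA_F));
      pDec.push_back(std::exp(-dt_ / cell.ca(k, CA_TAU)));
    }
    for (int s = 0; s < cell.nsyn; ++s)
      synDec.push_back(cell.syn(s, SY_TAU) > 0
                           ? std::exp(-dt_ / cell.syn(s, SY_TAU)) : 0.0);
    if (useTables) {
      actTab.resize(cell.nchan);
      inactTab.resize(cell.nchan);
      for (int r = 0; r < cell.nchan; ++r) {
        const NumericMatrix &ch = cell.chan;
        if (ch(r, CH_P) > 0)
          build_tab(actTab[r], ch(r, CH_AVH), ch(r, CH_AK), (int)ch(r, CH_ATT),
                    ch(r, CH_AC0), ch(r, CH_AAMP), ch(r, CH_AVHT),
                    ch(r, CH_AK1), ch(r, CH_AK2), dt);
        if (ch(r, CH_Q) > 0)
          build_tab(inactTab[r], ch(r, CH_IVH), ch(r, CH_IK), (int)ch(r, CH_ITT),
                    ch(r, CH_IC0), ch(r, CH_IAMP), ch(r, CH_IVHT),
                    ch(r, CH_IK1), ch(r, CH_IK2), dt);
      }
    }
  }

  // table mode: 'dec' receives exp(-dt/tau); exact mode: 'dec' receives tau
  void gate_of(int r, bool act, double v, double &inf, double &dec) {
    const NumericMatrix &ch = cell.chan;
    double &tau = dec;
    if (useTables) {
      tab_lookup(act ? actTab[r] : inactTab[r], v, inf, dec);
      return;
    }
    if (act) {
      inf = sigm(v, ch(r, CH_AVH), ch(r, CH_AK));
      tau = tau_eval((int)ch(r, CH_ATT), ch(r, CH_AC0), ch(r, CH_AAMP),
                     ch(r, CH_AVHT), ch(r, CH_AK1), ch(r, CH_AK2), v);
    } else {
      inf = sigm(v, ch(r, CH_IVH), ch(r, CH_IK));
      tau = tau_eval((int)ch(r, CH_ITT), ch(r, CH_IC0), ch(r, CH_IAMP),
                     ch(r, CH_IVHT), ch(r, CH_IK1), ch(r, CH_IK2), v);
    }
  }

  // advance state in place by one step; phaseStep = global step index
  // (drive is indexed modulo its period)
  void step(std::vector<double> &st, long phaseStep) {
    int idrive = (int)(phaseStep % nper);

    for (int i = 0; i < 4; ++i) { G[i] = 0; B[i] = 0; Ighk[i] = 0; Ica[i] = 0; }

    // ionic currents with gates frozen at step start
    for (int r = 0; r < cell.nchan; ++r) {
      int comp = cComp[r];
      double w = 1.0;
      if (mIdx[r] >= 0) {
        double m = st[mIdx[r]];
        for (int k = 0; k < cP[r]; ++k) w *= m;
      }
      if (hIdx[r] >= 0) {
        double h = st[hIdx[r]];
        for (int k = 0; k < cQ[r]; ++k) w *= h;
      }
      if (cKind[r] == 0) {
        double g = cG[r] * w;
        G[comp] += g;
        B[comp] += g * cErev[r];
      } else {
        int k = cell.caIndexOfComp[comp];
        double cai = k >= 0 ? st[caOff + k] : pRest[0];
        double I = cG[r] * w * cZ[r] * FARADAY *
                   ghk_bracket(st[comp], cai, cCao[r], cTemp[r], cZ[r]);
        Ighk[comp] += I;
        Ica[comp] += I;
      }
    }

    // synaptic currents (graded, driven by presynaptic waveform)
    int sk = 0;
    for (int s = 0; s < cell.nsyn; ++s) {
      int comp = sComp[s];
      double vpre = drive(idrive, sDrive[s]);
      double sval;
      if (sTau[s] > 0) {
        sval = st[sOff + sk];
        ++sk;
      } else {
        sval = sigm(vpre, sVth[s], sVsc[s]);
      }
      double g = sG[s] * sval;
      G[comp] += g;
      B[comp] += g * sErev[s];
    }

    // backward-Euler voltage solve: (C/dt + G + sum g_ax) V' - sum g_ax V'_j
    //   = C/dt V + B - Ighk
    double A[4][5];
    for (int i = 0; i < 4; ++i) {
      double diag = cell.caps[i] / dt + G[i];
      for (int j = 0; j < 4; ++j) {
        if (j == i) continue;
        diag += cell.gax[i][j];
        A[i][j] = -cell.gax[i][j];
      }
      A[i][i] = diag;
      A[i][4] = cell.caps[i] / dt * st[i] + B[i] - Ighk[i];
    }
    // Gaussian elimination with partial pivoting on the 4x4 system
    for (int col = 0; col < 4; ++col) {
      int piv = col;
      for (int rr = col + 1; rr < 4; ++rr)
        if (std::fabs(A[rr][col]) > std::fabs(A[piv][col])) piv = rr;
      if (piv != col)
        for (int cc = col; cc < 5; ++cc) std::swap(A[piv][cc], A[col][cc]);
      for (int rr = col + 1; rr < 4; ++rr) {
        double f = A[rr][col] / A[col][col];
        for (int cc = col; cc < 5; ++cc) A[rr][cc] -= f * A[col][cc];
      }
    }
    double Vn[4];
    for (int i = 3; i >= 0; --i) {
      double acc = A[i][4];
      for (int j = i + 1; j < 4; ++j) acc -= A[i][j] * Vn[j];
      Vn[i] = acc / A[i][i];
    }

    // exponential gate updates at the new voltage (staggered scheme)
    for (int r = 0; r < cell.nchan; ++r) {
      int comp = cComp[r];
      double v = Vn[comp];
      if (mIdx[r] >= 0) {
        double inf, dec;
        gate_of(r, true, v, inf, dec);
        if (!useTables) dec = std::exp(-dt / dec);
        if (cCadep[r] == 1) {
          int k = cell.caIndexOfComp[comp];
          double cai = k >= 0 ? st[caOff + k] : pRest[0];
          inf *= cai / (cai + cKd[r]);
        }
        double m = st[mIdx[r]];
        st[mIdx[r]] = inf + (m - inf) * dec;
      }
      if (hIdx[r] >= 0) {
        double inf, dec;
        gate_of(r, false, v, inf, dec);
        if (!useTables) dec = std::exp(-dt / dec);
        double h = st[hIdx[r]];
        st[hIdx[r]] = inf + (h - inf) * dec;
      }
    }

    // calcium pools (exact exponential update; Ica frozen over the step)
    for (int k = 0; k < cell.nca; ++k) {
      double target = pRest[k] - pF[k] * pTau[k] * Ica[pComp[k]];
      double out = target + (st[caOff + k] - target) * pDec[k];
      st[caOff + k] = out > CA_FLOOR ? out : CA_FLOOR;
    }

    // first-order synaptic gates (PD)
    sk = 0;
    int idriveNext = (int)((phaseStep + 1) % nper);
    for (int s = 0; s < cell.nsyn; ++s) {
      if (sTau[s] <= 0) continue;
      double vpre = drive(idriveNext, sDrive[s]);
      double sinf = sigm(vpre, sVth[s], sVsc[s]);
      double sv = st[sOff + sk];
      st[sOff + sk] = sinf + (sv - sinf) * synDec[s];
      ++sk;
    }

    for (int i = 0; i < 4; ++i) st[i] = Vn[i];
  }
};

static void check_finite(const std::vector<double> &st, long stepIdx) {
  for (size_t i = 0; i < st.size(); ++i)
    if (!std::isfinite(st[i]))
      stop("non-finite state at step %ld (state component %d)", stepIdx,
           (int)i + 1);
}

// [[Rcpp::export]]
int cppStateLength(List cell) {
  CellC c = unpack_cell(cell);
  return state_length(c);
}

// [[Rcpp::export]]
List cppSimulate(List cell, NumericMatrix driveMat, double dt, long nsteps,
                 NumericVector state0, int recordEvery, long phase0,
                 bool useTables) {
  Engine eng(cell, driveMat, dt, useTables);
  std::vector<double> st(state0.begin(), state0.end());
  if ((int)st.size() != state_length(eng.cell))
    stop("state vector length %d does not match cell layout (%d)",
         (int)st.size(), state_length(eng.cell));
  long nrec = nsteps / recordEvery + 1;
  NumericMatrix V(nrec, 4);
  NumericVector tt(nrec);
  NumericMatrix cai(nrec, eng.cell.nca);
  int caOff = 4;
  for (int r = 0; r < eng.cell.nchan; ++r) {
    if (eng.cell.chan(r, CH_P) > 0) ++caOff;
    if (eng.cell.chan(r, CH_Q) > 0) ++caOff;
  }
  long rec = 0;
  for (int i = 0; i < 4; ++i) V(0, i) = st[i];
  for (int k = 0; k < eng.cell.nca; ++k) cai(0, k) = st[caOff + k];
  tt[0] = 0.0;
  rec = 1;
  for (long n = 0; n < nsteps; ++n) {
    eng.step(st, phase0 + n);
    if ((n + 1) % 1000 == 0) check_finite(st, n + 1);
    if ((n + 1) % recordEvery == 0 && rec < nrec) {
      tt[rec] = (n + 1) * dt;
      for (int i = 0; i < 4; ++i) V(rec, i) = st[i];
      for (int k = 0; k < eng.cell.nca; ++k) cai(rec, k) = st[caOff + k];
      ++rec;
    }
  }
  check_finite(st, nsteps);
  return List::create(_["time"] = tt, _["V"] = V, _["cai"] = cai,
                      _["state"] = NumericVector(st.begin(), st.end()));
}

// threshold-crossing spike detector with linear interpolation and a
// refractory window; v sampled at dt starting at t0
static std::vector<double> detect_spikes_buf(const std::vector<double> &v,
                                             double dt, double t0,
                                             double threshold,
                                             double refractory) {
  std::vector<double> out;
  double last = -1e30;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i - 1] < threshold && v[i] >= threshold) {
      double f = (threshold - v[i - 1]) / (v[i] - v[i - 1]);
      double t = t0 + (i - 1 + f) * dt;
      if (t - last >= refractory) {
        out.push_back(t);
        last = t;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cppDetectSpikes(NumericVector v, double dt, double t0,
                              double threshold, double refractory) {
  std::vector<double> buf(v.begin(), v.end());
  std::vector<double> sp = detect_spikes_buf(buf, dt, t0, threshold, refractory);
  return NumericVector(sp.begin(), sp.end());
}

// Integrate whole drive cycles until the axonal spike pattern of consecutive
// cycles matches (same count, phase-aligned times within tolMs), then record
// an analysis window of analysisCycles further cycles.
// [[Rcpp::export]]
List cppRunToSteadyState(List cell, NumericMatrix driveMat, double dt,
                         int maxSettleCycles, int analysisCycles, double tolMs,
                         double threshold, double refractory,
                         NumericVector state0, int recordEvery,
                         bool useTables) {
  Engine eng(cell, driveMat, dt, useTables);
  std::vector<double> st(state0.begin(), state0.end());
  if ((int)st.size() != state_length(eng.cell))
    stop("state vector length %d does not match cell layout (%d)",
         (int)st.size(), state_length(eng.cell));
  long nper = eng.nper;
  double period = nper * dt;

  std::vector<double> vax(nper + 1);
  std::vector<double> prevSp, curSp;
  bool settled = false;
  int cyclesRun = 0;
  long stepIdx = 0;

  for (int cyc = 0; cyc < maxSettleCycles; ++cyc) {
    vax[0] = st[0];
    for (long n = 0; n < nper; ++n) {
      eng.step(st, stepIdx++);
      vax[n + 1] = st[0];
    }
    check_finite(st, stepIdx);
    ++cyclesRun;
    curSp = detect_spikes_buf(vax, dt, 0.0, threshold, refractory);
    if (cyc > 0) {
      bool match = curSp.size() == prevSp.size();
      if (match) {
        for (size_t k = 0; k < curSp.size(); ++k)
          if (std::fabs(curSp[k] - prevSp[k]) > tolMs) { match = false; break; }
      }
      if (match) { settled = true; break; }
    }
    prevSp = curSp;
  }

  // analysis window: analysisCycles further whole cycles, recorded
  long nsteps = (long)analysisCycles * nper;
  long nrec = nsteps / recordEvery + 1;
  NumericMatrix V(nrec, 4);
  NumericVector tt(nrec);
  for (int i = 0; i < 4; ++i) V(0, i) = st[i];
  tt[0] = 0.0;
  std::vector<double> vaxFull(nsteps + 1);
  vaxFull[0] = st[0];
  long rec = 1;
  for (long n = 0; n < nsteps; ++n) {
    eng.step(st, stepIdx++);
    vaxFull[n + 1] = st[0];
    if ((n + 1) % recordEvery == 0 && rec < nrec) {
      tt[rec] = (n + 1) * dt;
      for (int i = 0; i < 4; ++i) V(rec, i) = st[i];
      ++rec;
    }
  }
  check_finite(st, stepIdx);
  std::vector<double> spikes =
      detect_spikes_buf(vaxFull, dt, 0.0, threshold, refractory);

  // re-verify periodicity over the analysis window itself
  if (settled && analysisCycles >= 2) {
    std::vector<std::vector<double>> perCyc(analysisCycles);
    for (double t : spikes) {
      int c = (int)(t / period);
      if (c >= analysisCycles) c = analysisCycles - 1;
      perCyc[c].push_back(t - c * period);
    }
    for (int c = 1; c < analysisCycles && settled; ++c) {
      if (perCyc[c].size() != perCyc[0].size()) settled = false;
      else
        for (size_t k = 0; k < perCyc[c].size(); ++k)
          if (std::fabs(perCyc[c][k] - perCyc[0][k]) > tolMs) {
            settled = false;
            break;
          }
    }
  }

  return List::create(
      _["settled"] = settled, _["cycles_to_settle"] = cyclesRun,
      _["time"] = tt, _["V"] = V,
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["period"] = period, _["analysis_cycles"] = analysisCycles,
      _["state"] = NumericVector(st.begin(), st.end()));
}
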