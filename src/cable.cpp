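// Implicit (backward Euler) time integration of a double-cable fiber model
// driven by time-varying extracellular potentials.
//
// Unknowns per compartment k: Vm_k (potential across the axolemma, mV) and
// Vp_k (periaxonal-space potential, mV). The axolemma connects the
// intracellular node (Vi = Vm + Vp) to the periaxonal node; the myelin
// sheath (conductance xg, capacitance xc) connects the periaxonal node to
// the applied extracellular potential Ve. At nodes of Ranvier xg is set
// very large so Vp tracks Ve (no myelin). Intracellular axial conductances
// ga couple neighboring Vi; periaxonal conductances gp couple neighboring
// Vp. Ends are sealed (no axial flux past the terminal compartments).
//
// Units: mV, ms, nA, uS, nF (consistent: uS*mV = nA, nF*mV/ms = nA).
//
// Gating variables advance by exponential integration of the
// voltage-dependent rate equations evaluated at the previous step's Vm
// (staggered update); the voltage solve is then linear and unconditionally
// stable. The interleaved (Vm_0, Vp_0, Vm_1, Vp_1, ...) system is banded
// with bandwidth 3 and solved by LAPACK dgbsv each step.

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double vtrap(double num, double x, double scale) {
  // num * x / (1 - exp(-x/scale)) with the removable singularity handled
  if (std::fabs(x / scale) < 1e-6)
    return num * scale * (1.0 + x / (2.0 * scale));
  return num * x / (1.0 - std::exp(-x / scale));
}

struct MRGRates {
  double q10_1, q10_2, q10_3;
  MRGRates(double celsius) {
    q10_1 = std::pow(2.2, (celsius - 20.0) / 10.0);
    q10_2 = std::pow(2.9, (celsius - 20.0) / 10.0);
    q10_3 = std::pow(3.0, (celsius - 36.0) / 10.0);
  }
  void rates(double v, double &am, double &bm, double &ah, double &bh,
             double &ap, double &bp, double &as, double &bs) const {
    am = q10_1 * vtrap(1.86, v + 21.4, 10.3);
    bm = q10_1 * vtrap(0.086, -(v + 25.7), 9.16);
    ah = q10_2 * vtrap(0.062, -(v + 114.0), 11.0);
    bh = q10_2 * 2.3 / (1.0 + std::exp(-(v + 31.8) / 13.4));
    ap = q10_1 * vtrap(0.01, v + 27.0, 10.2);
    bp = q10_1 * vtrap(0.00025, -(v + 34.0), 10.0);
    double v2 = v + 80.0;  // relative to vtraub = -80
    as = q10_3 * 0.3 / (1.0 + std::exp((27.0 - v2) / 5.0));
    bs = q10_3 * 0.03 / (1.0 + std::exp(-(v2 + 10.0)));
  }
};

struct HHRates {
  // Rate constants are taken as already valid at the model's reference
  // temperature (default 37 C); Q10 = 3 scaling applies only to deviations
  // from it. Scaling the classical 6.3 C rates up to body temperature
  // blocks propagation (heat block), which is why the reference sits at
  // the operating temperature in this model family.
  double k;
  double vtraub;
  HHRates(double celsius, double vt, double tref) : vtraub(vt) {
    k = std::pow(3.0, (celsius - tref) / 10.0);
  }
  void rates(double v, double &am, double &bm, double &ah, double &bh,
             double &an, double &bn) const {
    double v2 = v - vtraub;
    am = k * ((std::fabs((25.0 - v2) / 10.0) < 1e-6)
                  ? 1.0
                  : 0.1 * (25.0 - v2) / (std::exp((25.0 - v2) / 10.0) - 1.0));
    bm = k * 4.0 * std::exp(-v2 / 18.0);
    ah = k * 0.07 * std::exp(-v2 / 20.0);
    bh = k * 1.0 / (std::exp((30.0 - v2) / 10.0) + 1.0);
    an = k * ((std::fabs((10.0 - v2) / 10.0) < 1e-6)
                  ? 0.1
                  : 0.01 * (10.0 - v2) / (std::exp((10.0 - v2) / 10.0) - 1.0));
    bn = k * 0.125 * std::exp(-v2 / 80.0);
  }
};

// gating update: x <- xinf + (x - xinf) * exp(-dt/tau)
static inline void gate_step(double &x, double a, double b, double dt) {
  double tau = 1.0 / (a + b);
  double xinf = a * tau;
  x = xinf + (x - xinf) * std::exp(-dt / tau);
}

// [[Rcpp::export(name = ".run_cable")]]
List run_cable(List fib, NumericVector unit_mV, NumericVector wave,
               double amp, double dt, IntegerVector rec_idx,
               NumericVector istim, int istim_idx, List state0,
               int record_stride) {
  const int model = as<int>(fib["model"]);  // 0 = MRG, 1 = HH
  NumericVector cm = fib["cm"], gpas = fib["gpas"], epas = fib["epas"];
  NumericVector gnaf = fib["gnaf"], gnap = fib["gnap"], gks = fib["gks"];
  NumericVector ga = fib["ga"], gp = fib["gp"];
  NumericVector xg = fib["xg"], xc = fib["xc"];
  IntegerVector active = fib["active"];
  const double ena = as<double>(fib["ena"]);
  const double ek = as<double>(fib["ek"]);
  const double celsius = as<double>(fib["celsius"]);
  const double hh_vtraub = fib.containsElementNamed("vtraub")
                               ? as<double>(fib["vtraub"]) : -70.0;
  const double hh_tref = fib.containsElementNamed("hh_tref")
                             ? as<double>(fib["hh_tref"]) : 37.0;

  const int n = cm.size();
  const int nt = wave.size();
  const int N = 2 * n;
  const int KL = 3, KU = 3, LDAB = 2 * KL + KU + 1;

  // state
  std::vector<double> vm(n), vp(n), g1(n), g2(n), g3(n), g4(n);
  {
    NumericVector v0 = state0["vm"], p0 = state0["vp"];
    NumericVector a1 = state0["g1"], a2 = state0["g2"], a3 = state0["g3"],
                  a4 = state0["g4"];
    for (int i = 0; i < n; ++i) {
      vm[i] = v0[i]; vp[i] = p0[i];
      g1[i] = a1[i]; g2[i] = a2[i]; g3[i] = a3[i]; g4[i] = a4[i];
    }
  }

  std::vector<double> ve_old(n), ve_new(n);
  for (int i = 0; i < n; ++i) ve_old[i] = amp * wave[0] * unit_mV[i];

  MRGRates mrg(celsius);
  HHRates hh(celsius, hh_vtraub, hh_tref);

  const int nrec = rec_idx.size();
  const int nrec_t = (nt - 1) / record_stride + 1;
  NumericMatrix vrec(nrec_t, nrec);
  NumericVector trec(nrec_t);
  int rrow = 0;
  for (int j = 0; j < nrec; ++j) vrec(0, j) = vm[rec_idx[j]];
  trec[0] = 0.0;
  rrow = 1;

  std::vector<double> AB(LDAB * N), rhs(N);
  std::vector<int> ipiv(N);
  std::vector<double> gion(n), gionE(n);

  bool has_istim = istim_idx >= 0 && istim.size() == nt;

  for (int t = 1; t < nt; ++t) {
    double wf = wave[t];
    for (int i = 0; i < n; ++i) ve_new[i] = amp * wf * unit_mV[i];

    // gating + ionic conductances at old Vm
    for (int i = 0; i < n; ++i) {
      if (active[i] == 1) {  // MRG node
        double am, bm, ah, bh, ap, bp, as_, bs;
        mrg.rates(vm[i], am, bm, ah, bh, ap, bp, as_, bs);
        gate_step(g1[i], am, bm, dt);
        gate_step(g2[i], ah, bh, dt);
        gate_step(g3[i], ap, bp, dt);
        gate_step(g4[i], as_, bs, dt);
        double gNa = gnaf[i] * g1[i] * g1[i] * g1[i] * g2[i];
        double gNaP = gnap[i] * g3[i] * g3[i] * g3[i];
        double gK = gks[i] * g4[i];
        gion[i] = gNa + gNaP + gK;
        gionE[i] = (gNa + gNaP) * ena + gK * ek;
      } else if (active[i] == 2) {  // HH membrane
        double am, bm, ah, bh, an, bn;
        hh.rates(vm[i], am, bm, ah, bh, an, bn);
        gate_step(g1[i], am, bm, dt);
        gate_step(g2[i], ah, bh, dt);
        gate_step(g4[i], an, bn, dt);
        double gNa = gnaf[i] * g1[i] * g1[i] * g1[i] * g2[i];
        double gK = gks[i] * g4[i] * g4[i] * g4[i] * g4[i];
        gion[i] = gNa + gK;
        gionE[i] = gNa * ena + gK * ek;
      } else {
        gion[i] = 0.0;
        gionE[i] = 0.0;
      }
    }

    // assemble banded system (LAPACK general band storage with room for
    // fill: row KL+KU+1+i-j holds A(i,j), 1-based)
    std::fill(AB.begin(), AB.end(), 0.0);
    auto at = [&](int i, int j) -> double & {
      // 0-based i, j
      return AB[(size_t)j * LDAB + (KL + KU + i - j)];
    };

    for (int k = 0; k < n; ++k) {
      int M = 2 * k, P = 2 * k + 1;
      double gaL = (k > 0) ? ga[k - 1] : 0.0;
      double gaR = (k < n - 1) ? ga[k] : 0.0;
      double gpL = (k > 0) ? gp[k - 1] : 0.0;
      double gpR = (k < n - 1) ? gp[k] : 0.0;
      double cdt = cm[k] / dt;
      double memb = cdt + gion[k] + gpas[k];

      // intracellular row
      at(M, M) = memb + gaL + gaR;
      at(M, P) = gaL + gaR;
      if (k > 0) { at(M, M - 2) = -gaL; at(M, M - 1) = -gaL; }
      if (k < n - 1) { at(M, M + 2) = -gaR; at(M, M + 3) = -gaR; }
      double rM = cdt * vm[k] + gionE[k] + gpas[k] * epas[k];
      if (has_istim && k == istim_idx) rM += istim[t];
      rhs[M] = rM;

      // periaxonal row (negated so the Vp diagonal is positive)
      at(P, M) = -memb;
      at(P, P) = gpL + gpR + xg[k] + xc[k] / dt;
      if (k > 0) at(P, P - 2) = -gpL;
      if (k < n - 1) at(P, P + 2) = -gpR;
      rhs[P] = -(cdt * vm[k] + gionE[k] + gpas[k] * epas[k]) +
               xg[k] * ve_new[k] +
               (xc[k] / dt) * (ve_new[k] + vp[k] - ve_old[k]);
    }

    int info = 0, nrhs = 1, nn = N, kl = KL, ku = KU, ldab = LDAB;
    F77_CALL(dgbsv)(&nn, &kl, &ku, &nrhs, AB.data(), &ldab, ipiv.data(),
                    rhs.data(), &nn, &info);
    if (info != 0)
      stop("cable solve failed (dgbsv info=%d) at step %d", info, t);

    for (int k = 0; k < n; ++k) {
      vm[k] = rhs[2 * k];
      vp[k] = rhs[2 * k + 1];
      if (!std::isfinite(vm[k]))
        stop("cable integration diverged at step %d", t);
    }
    std::swap(ve_old, ve_new);

    if (t % record_stride == 0 && rrow < nrec_t) {
      for (int j = 0; j < nrec; ++j) vrec(rrow, j) = vm[rec_idx[j]];
      trec[rrow] = t * dt;
      ++rrow;
    }
  }

  List state = List::create(
      _["vm"] = NumericVector(vm.begin(), vm.end()),
      _["vp"] = NumericVector(vp.begin(), vp.end()),
      _["g1"] = NumericVector(g1.begin(), g1.end()),
      _["g2"] = NumericVector(g2.begin(), g2.end()),
      _["g3"] = NumericVector(g3.begin(), g3.end()),
      _["g4"] = NumericVector(g4.begin(), g4.end()));

  return List::create(_["vm_rec"] = vrec, _["t_rec"] = trec,
                      _["state"] = state);
}

// steady-state gating values at a given Vm (used for initialization checks)
// [[Rcpp::export(name = ".gating_inf")]]
NumericVector gating_inf(double v, int model, double celsius,
                         double vtraub) {
  NumericVector out(4);
  if (model == 0) {
    MRGRates mrg(celsius);
    double am, bm, ah, bh, ap, bp, as_, bs;
    mrg.rates(v, am, bm, ah, bh, ap, bp, as_, bs);
    out[0] = am / (am + bm);
    out[1] = ah / (ah + bh);
    out[2] = ap / (ap + bp);
    out[3] = as_ / (as_ + bs);
  } else {
    HHRates hh(celsius, vtraub, 37.0);
    double am, bm, ah, bh, an, bn;
    hh.rates(v, am, bm, ah, bh, an, bn);
    out[0] = am / (am + bm);
    out[1] = ah / (ah + bh);
    out[2] = 0.0;
    out[3] = an / (an + bn);
  }
  return out;
}
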