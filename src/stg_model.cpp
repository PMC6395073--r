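// Single-compartment conductance-based model with eight ionic currents
// (Na, CaT, CaS, A, KCa, Kd, H, leak) and first-order intracellular calcium.
// Fixed-step RK4; gating rate functions either evaluated exactly or through
// a fine voltage lookup table with linear interpolation (the table is built
// once per kinetics configuration and reused across calls).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int N_GATED = 7;   // leak carries no gates
static const int N_CHAN = 8;
static const int TW = 4 * N_GATED; // table values per voltage grid point

// time-constant functional forms
enum TauForm { TAU_SIGMOID = 1, TAU_BIEXP = 2, TAU_PRODUCT = 3 };

struct TauFun {
  int form;
  double a, b, c1, d1, c2, d2;
  double eval(double V) const {
    switch (form) {
    case TAU_SIGMOID: // a + b / (1 + exp((V + c1)/d1))
      return a + b / (1.0 + std::exp((V + c1) / d1));
    case TAU_BIEXP:   // a + b / (exp((V + c1)/d1) + exp((V + c2)/d2))
      return a + b / (std::exp((V + c1) / d1) + std::exp((V + c2) / d2));
    case TAU_PRODUCT: // a/(1+exp((V+c1)/d1)) * (b + 1/(1+exp((V+c2)/d2)))
      return (a / (1.0 + std::exp((V + c1) / d1))) *
             (b + 1.0 / (1.0 + std::exp((V + c2) / d2)));
    }
    return NA_REAL;
  }
};

struct Channel {
  int p, q;
  double m_vh, m_k;       // m_inf = 1/(1 + exp((V - m_vh)/m_k))
  double h_vh, h_k;
  int ca_dep;             // KCa: m_inf *= Ca/(Ca + ca_half)
  double ca_half;
  TauFun tau_m, tau_h;
  double m_inf(double V) const { return 1.0 / (1.0 + std::exp((V - m_vh) / m_k)); }
  double h_inf(double V) const { return 1.0 / (1.0 + std::exp((V - h_vh) / h_k)); }
};

// kin matrix: one row per gated channel, columns
//  0 p, 1 q, 2 m_vh, 3 m_k, 4 ca_dep, 5 ca_half,
//  6 taum_form, 7..12 taum params, 13 h_vh, 14 h_k,
//  15 tauh_form, 16..21 tauh params
static std::vector<Channel> parse_kinetics(const NumericMatrix &kin) {
  if (kin.nrow() != N_GATED || kin.ncol() < 22)
    stop("kinetics matrix must be 7 x 22");
  std::vector<Channel> ch(N_GATED);
  for (int i = 0; i < N_GATED; ++i) {
    Channel &c = ch[i];
    c.p = (int)kin(i, 0); c.q = (int)kin(i, 1);
    c.m_vh = kin(i, 2); c.m_k = kin(i, 3);
    c.ca_dep = (int)kin(i, 4); c.ca_half = kin(i, 5);
    c.tau_m.form = (int)kin(i, 6);
    c.tau_m.a = kin(i, 7);  c.tau_m.b = kin(i, 8);
    c.tau_m.c1 = kin(i, 9); c.tau_m.d1 = kin(i, 10);
    c.tau_m.c2 = kin(i, 11); c.tau_m.d2 = kin(i, 12);
    c.h_vh = kin(i, 13); c.h_k = kin(i, 14);
    c.tau_h.form = (int)kin(i, 15);
    c.tau_h.a = kin(i, 16);  c.tau_h.b = kin(i, 17);
    c.tau_h.c1 = kin(i, 18); c.tau_h.d1 = kin(i, 19);
    c.tau_h.c2 = kin(i, 20); c.tau_h.d2 = kin(i, 21);
  }
  return ch;
}

// Build the voltage lookup table: per grid point, interleaved
// (m_inf, 1/tau_m, h_inf, 1/tau_h) for the 7 gated channels.
// [[Rcpp::export(name = ".stg_build_tables_cpp")]]
NumericVector stg_build_tables_cpp(NumericMatrix kin, double vmin,
                                   double vmax, double dv) {
  std::vector<Channel> ch = parse_kinetics(kin);
  int n = (int)std::floor((vmax - vmin) / dv) + 1;
  NumericVector tab((size_t)n * TW);
  std::fill(tab.begin(), tab.end(), 1.0);
  for (int j = 0; j < n; ++j) {
    double V = vmin + j * dv;
    double *row = &tab[0] + (size_t)j * TW;
    for (int i = 0; i < N_GATED; ++i) {
      row[4 * i] = ch[i].m_inf(V);
      row[4 * i + 1] = 1.0 / ch[i].tau_m.eval(V);
      if (ch[i].q > 0) {
        row[4 * i + 2] = ch[i].h_inf(V);
        row[4 * i + 3] = 1.0 / ch[i].tau_h.eval(V);
      }
    }
  }
  tab.attr("vmin") = vmin;
  tab.attr("dv") = dv;
  tab.attr("n") = n;
  return tab;
}

// state layout: [0] V, [1..11] gates (mNa hNa mCaT hCaT mCaS hCaS mA hA mKCa mKd mH), [12] Ca
static const int IDX_M[N_GATED] = {1, 3, 5, 7, 9, 10, 11};
static const int IDX_H[N_GATED] = {2, 4, 6, 8, -1, -1, -1};

struct FlatModel {
  // channel constants in flat arrays for the hot loop
  int p[N_GATED], q[N_GATED], ca_dep[N_GATED];
  double ca_half[N_GATED];
  double g[N_CHAN], Erev[N_CHAN];
  int is_ca[N_CHAN];
  double tau_ca, C, Ca0, CaF, Ca_out, nernst_pref;
};

// evaluate all gating rates at one (V); exact path
static inline void exact_rates(const std::vector<Channel> &ch, double V,
                               double *rates) {
  for (int i = 0; i < N_GATED; ++i) {
    const Channel &c = ch[i];
    rates[4 * i] = c.m_inf(V);
    rates[4 * i + 1] = 1.0 / c.tau_m.eval(V);
    if (c.q > 0) {
      rates[4 * i + 2] = c.h_inf(V);
      rates[4 * i + 3] = 1.0 / c.tau_h.eval(V);
    } else {
      rates[4 * i + 2] = 1.0;
      rates[4 * i + 3] = 1.0;
    }
  }
}

// [[Rcpp::export(name = ".stg_integrate_cpp")]]
List stg_integrate_cpp(NumericMatrix kin, NumericVector g, double tau_ca,
                       double C, double Ca0, double CaF, double Ca_out,
                       double nernst_pref, NumericVector Erev,
                       NumericVector Ie, double dt, double duration,
                       double transient, NumericVector init,
                       bool record_currents, Nullable<NumericVector> table) {
  std::vector<Channel> ch = parse_kinetics(kin);
  FlatModel fm;
  for (int i = 0; i < N_GATED; ++i) {
    fm.p[i] = ch[i].p; fm.q[i] = ch[i].q;
    fm.ca_dep[i] = ch[i].ca_dep; fm.ca_half[i] = ch[i].ca_half;
  }
  for (int i = 0; i < N_CHAN; ++i) {
    fm.g[i] = g[i];
    fm.Erev[i] = Erev[i];
    fm.is_ca[i] = (i == 1 || i == 2);
  }
  fm.tau_ca = tau_ca; fm.C = C; fm.Ca0 = Ca0; fm.CaF = CaF;
  fm.Ca_out = Ca_out; fm.nernst_pref = nernst_pref;

  const double *tab = nullptr;
  double tab_vmin = 0, tab_inv_dv = 0;
  int tab_n = 0;
  NumericVector tabv;
  if (table.isNotNull()) {
    tabv = table.get();
    tab = &tabv[0];
    tab_vmin = as<double>(tabv.attr("vmin"));
    tab_inv_dv = 1.0 / as<double>(tabv.attr("dv"));
    tab_n = as<int>(tabv.attr("n"));
  }

  long n_total = (long)std::llround(duration / dt);
  long n_skip = (long)std::llround(transient / dt);
  if (n_skip >= n_total) stop("transient must be shorter than duration");
  long n_rec = n_total - n_skip;
  bool ie_seq = Ie.size() > 1;
  if (ie_seq && (long)Ie.size() < n_total)
    stop("Ie schedule shorter than the number of steps");
  const double *iep = &Ie[0];

  NumericVector Vout(n_rec), Caout(n_rec);
  NumericMatrix Iout = record_currents ? NumericMatrix(n_rec, N_CHAN)
                                       : NumericMatrix(0, 0);
  double *voutp = &Vout[0], *caoutp = &Caout[0];
  double *ioutp = record_currents ? &Iout[0] : nullptr;

  // hoist model constants into plain locals for the hot loop
  int p_[N_GATED], q_[N_GATED], cadep_[N_GATED];
  double cahalf_[N_GATED], g_[N_CHAN], Erev_[N_CHAN];
  for (int i = 0; i < N_GATED; ++i) {
    p_[i] = fm.p[i]; q_[i] = fm.q[i];
    cadep_[i] = fm.ca_dep[i]; cahalf_[i] = fm.ca_half[i];
  }
  for (int i = 0; i < N_CHAN; ++i) { g_[i] = fm.g[i]; Erev_[i] = fm.Erev[i]; }
  const double inv_C = 1.0 / fm.C, inv_tauca = 1.0 / fm.tau_ca;
  const double CaF_ = fm.CaF, Ca0_ = fm.Ca0, Ca_out_ = fm.Ca_out,
               npref_ = fm.nernst_pref;

  double s[13], kk[4][13], tmp[13], Irec[N_CHAN], rates[TW];
  for (int i = 0; i < 13; ++i) s[i] = init[i];
  const double stage_w[3] = {0.5 * dt, 0.5 * dt, dt};

  for (long step = 0; step < n_total; ++step) {
    double ie = ie_seq ? iep[step] : iep[0];
    bool ok = true;
    for (int stage = 0; stage < 4 && ok; ++stage) {
      const double *src = stage == 0 ? s : tmp;
      double *ds = kk[stage];
      double V = src[0], Ca = src[12];
      if (!(Ca > 0.0)) { ok = false; break; }
      double ECa = npref_ * std::log(Ca_out_ / Ca);
      if (tab) {
        double x = (V - tab_vmin) * tab_inv_dv;
        if (x < 0.0) x = 0.0;
        if (x > tab_n - 1.000001) x = tab_n - 1.000001;
        int j = (int)x;
        double f = x - j;
        const double *a = tab + (size_t)j * TW;
        const double *b = a + TW;
        for (int k = 0; k < TW; ++k) rates[k] = a[k] + f * (b[k] - a[k]);
      } else {
        exact_rates(ch, V, rates);
      }
      double Isum = 0.0, ICaT = 0.0, ICaS = 0.0;
      for (int i = 0; i < N_GATED; ++i) {
        double mi = rates[4 * i], itm = rates[4 * i + 1];
        if (cadep_[i]) mi *= Ca / (Ca + cahalf_[i]);
        double m = src[IDX_M[i]];
        ds[IDX_M[i]] = (mi - m) * itm;
        double h = 1.0;
        if (q_[i]) {
          h = src[IDX_H[i]];
          ds[IDX_H[i]] = (rates[4 * i + 2] - h) * rates[4 * i + 3];
        }
        double mp;
        switch (p_[i]) { // p in {0,1,3,4}
        case 4: mp = m * m * m * m; break;
        case 3: mp = m * m * m; break;
        case 1: mp = m; break;
        default: mp = 1.0;
        }
        double E = (i == 1 || i == 2) ? ECa : Erev_[i];
        double I = g_[i] * mp * h * (V - E);
        if (i == 1) ICaT = I;
        else if (i == 2) ICaS = I;
        Isum += I;
      }
      Isum += g_[7] * (V - Erev_[7]);
      ds[0] = (ie - Isum) * inv_C;
      ds[12] = (-CaF_ * (ICaT + ICaS) - Ca + Ca0_) * inv_tauca;
      if (stage < 3) {
        double w = stage_w[stage];
        for (int i = 0; i < 13; ++i) tmp[i] = s[i] + w * ds[i];
      }
    }
    if (ok) {
      for (int i = 0; i < 13; ++i)
        s[i] += dt / 6.0 * (kk[0][i] + 2.0 * kk[1][i] + 2.0 * kk[2][i] + kk[3][i]);
    }
    if (!ok || !std::isfinite(s[0]) || std::fabs(s[0]) > 1e3 || !(s[12] > 0.0)) {
      return List::create(_["failed"] = true,
                          _["step"] = (double)(step + 1),
                          _["time_ms"] = (step + 1) * dt);
    }
    if (step >= n_skip) {
      long r = step - n_skip;
      voutp[r] = s[0];
      caoutp[r] = s[12];
      if (ioutp) {
        // per-channel currents at the retained state
        double V = s[0], Ca = s[12];
        double ECa = npref_ * std::log(Ca_out_ / Ca);
        for (int i = 0; i < N_GATED; ++i) {
          double m = s[IDX_M[i]];
          double h = (IDX_H[i] >= 0) ? s[IDX_H[i]] : 1.0;
          double mp;
          switch (p_[i]) {
          case 4: mp = m * m * m * m; break;
          case 3: mp = m * m * m; break;
          case 1: mp = m; break;
          default: mp = 1.0;
          }
          double E = (i == 1 || i == 2) ? ECa : Erev_[i];
          Irec[i] = g_[i] * mp * (q_[i] ? h : 1.0) * (V - E);
        }
        Irec[7] = g_[7] * (V - Erev_[7]);
        for (int c2 = 0; c2 < N_CHAN; ++c2) ioutp[(size_t)c2 * n_rec + r] = Irec[c2];
      }
    }
    if ((step & 0x1FFFFF) == 0x1FFFFF) Rcpp::checkUserInterrupt();
  }

  NumericVector fin(13);
  for (int i = 0; i < 13; ++i) fin[i] = s[i];
  return List::create(_["failed"] = false, _["V"] = Vout, _["Ca"] = Caout,
                      _["I"] = Iout, _["final_state"] = fin,
                      _["t0"] = n_skip * dt, _["n"] = (double)n_rec);
}

// Exact gating rates at one (V, Ca): 7 x 4 matrix (m_inf, tau_m, h_inf, tau_h)
// [[Rcpp::export(name = ".stg_rates_cpp")]]
NumericMatrix stg_rates_cpp(NumericMatrix kin, double V, double Ca) {
  std::vector<Channel> ch = parse_kinetics(kin);
  NumericMatrix out(N_GATED, 4);
  for (int i = 0; i < N_GATED; ++i) {
    double mi = ch[i].m_inf(V);
    if (ch[i].ca_dep) mi *= Ca / (Ca + ch[i].ca_half);
    out(i, 0) = mi;
    out(i, 1) = ch[i].tau_m.eval(V);
    out(i, 2) = ch[i].q > 0 ? ch[i].h_inf(V) : NA_REAL;
    out(i, 3) = ch[i].q > 0 ? ch[i].tau_h.eval(V) : NA_REAL;
  }
  return out;
}

// Instantaneous per-channel currents at one state (exact reversal handling)
// [[Rcpp::export(name = ".stg_currents_cpp")]]
NumericVector stg_currents_cpp(NumericMatrix kin, NumericVector state,
                               NumericVector g, double Ca_out,
                               double nernst_pref, NumericVector Erev) {
  std::vector<Channel> ch = parse_kinetics(kin);
  NumericVector I(N_CHAN);
  double V = state[0], Ca = state[12];
  double ECa = nernst_pref * std::log(Ca_out / Ca);
  for (int i = 0; i < N_GATED; ++i) {
    double m = state[IDX_M[i]];
    double h = (IDX_H[i] >= 0) ? state[IDX_H[i]] : 1.0;
    double E = (i == 1 || i == 2) ? ECa : Erev[i];
    double mp = 1.0;
    for (int e = 0; e < ch[i].p; ++e) mp *= m;
    I[i] = g[i] * mp * (ch[i].q > 0 ? h : 1.0) * (V - E);
  }
  I[7] = g[7] * (V - Erev[7]);
  return I;
}
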