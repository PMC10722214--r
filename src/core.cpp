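// Core integrator for the network-coupled atrial tissue model.
//
// State layout (columns of the state matrix):
//   0 V      membrane potential (mV)
//   1 m      INa activation
//   2 h      INa fast inactivation
//   3 j      INa slow inactivation
//   4 d      ICaL activation
//   5 f      ICaL inactivation
//   6 x      lumped repolarising K+ activation
//   7 a      RyR (CICR) activation
//   8 r      RyR (CICR) refractory/availability
//   9 Cai    cytosolic [Ca2+] (mM)
//  10 CaSR   sarcoplasmic-reticulum [Ca2+] (mM)
//
// Gates are advanced with the Rush-Larsen exponential update; V and the
// calcium concentrations with forward Euler.  All voltage-dependent terms
// are evaluated through lookup tables over [-95, 65] mV rebuilt per run
// (they depend on dt and on the kinetic scale parameters).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// ---- parameter vector indices (kept in step with R/cell-params.R) ----
enum {
  P_GNA = 0, P_ENA, P_GCAL, P_ECAL, P_GK, P_EK, P_GK1, P_KNCX,
  P_GUP, P_KUP, P_GLEAK, P_GREL, P_GATESCALE, P_EFB, P_TAUM, P_TAUH,
  P_TAUJ, P_TAUF, P_TAUX, P_BUF, P_CCONV, P_VRATIO, P_CASRFLOOR,
  P_GFB, P_MSHIFT, P_EK1, P_NPAR
};

static const int NVAR = 11;
static const double V_MIN = -95.0, V_MAX = 65.0, V_STEP = 0.05;
static const int NTAB = (int)((V_MAX - V_MIN) / V_STEP) + 2;

struct Tables {
  std::vector<double> m_inf, m_rlc, h_inf, h_rlc, j_inf, j_rlc;
  std::vector<double> d_inf, d_rlc, f_inf, f_rlc, x_inf, x_rlc;
  std::vector<double> a_inf, a_rlc, r_inf, r_rlc;
  std::vector<double> ik1, ncx1, ncx2;
};

static inline double sq(double x) { return x * x; }

// steady-state / time-constant formulations of the minimal model
static inline double f_m_inf(double v, double sh) { return 1.0 / (1.0 + exp(-(v + 61.0 + sh) / 5.0)); }
static inline double f_tau_m(double v, double s)  { return s * (0.033 + 0.11 * exp(-sq((v + 45.0) / 25.0))); }
static inline double f_h_inf(double v)            { return 1.0 / (1.0 + exp((v + 71.0) / 6.0)); }
static inline double f_tau_h(double v, double s)  { return s * (0.50 + 6.0 * exp(-sq((v + 75.0) / 20.0))); }
static inline double f_tau_j(double v, double s)  { return s * (8.0 + 70.0 * exp(-sq((v + 75.0) / 20.0))); }
static inline double f_d_inf(double v)            { return 1.0 / (1.0 + exp(-(v + 10.0) / 6.5)); }
static inline double f_tau_d(double v)            { return 0.6 + 1.2 * exp(-sq((v + 20.0) / 25.0)); }
static inline double f_f_inf(double v)            { return 1.0 / (1.0 + exp((v + 26.0) / 5.5)); }
static inline double f_tau_f(double v, double s)  { return s * (120.0 + 300.0 * exp(-sq((v + 30.0) / 30.0))); }
static inline double f_x_inf(double v)            { return 1.0 / (1.0 + exp(-(v + 12.0) / 9.0)); }
static inline double f_tau_x(double v, double s)  { return s * (80.0 + 350.0 * exp(-sq((v + 25.0) / 30.0))); }
static inline double f_a_inf(double v)            { return 1.0 / (1.0 + exp(-(v + 12.0) / 4.0)); }
static inline double f_tau_a(double v)            { (void)v; return 1.0; }
static inline double f_r_inf(double v)            { return 1.0 / (1.0 + exp((v + 40.0) / 4.0)); }
static inline double f_tau_r(double v)            { return 120.0 - 95.0 / (1.0 + exp(-(v + 40.0) / 5.0)); }

// NCX constants (fixed intra/extracellular Na, standard electrogenic form)
static const double NCX_GAMMA = 0.35, NCX_NAI = 11.0, NCX_NAO = 140.0;
static const double NCX_CAO = 1.8, NCX_KMNA = 87.5, NCX_KMCA = 1.38;
static const double NCX_KSAT = 0.1, FRT = 0.0374; // mV^-1

static void build_tables(Tables &tb, const NumericVector &p, double dt) {
  tb.m_inf.resize(NTAB); tb.m_rlc.resize(NTAB);
  tb.h_inf.resize(NTAB); tb.h_rlc.resize(NTAB);
  tb.j_inf.resize(NTAB); tb.j_rlc.resize(NTAB);
  tb.d_inf.resize(NTAB); tb.d_rlc.resize(NTAB);
  tb.f_inf.resize(NTAB); tb.f_rlc.resize(NTAB);
  tb.x_inf.resize(NTAB); tb.x_rlc.resize(NTAB);
  tb.a_inf.resize(NTAB); tb.a_rlc.resize(NTAB);
  tb.r_inf.resize(NTAB); tb.r_rlc.resize(NTAB);
  tb.ik1.resize(NTAB); tb.ncx1.resize(NTAB); tb.ncx2.resize(NTAB);
  const double denom_na = NCX_KMNA * NCX_KMNA * NCX_KMNA + NCX_NAO * NCX_NAO * NCX_NAO;
  const double denom_ca = NCX_KMCA + NCX_CAO;
  for (int i = 0; i < NTAB; ++i) {
    double v = V_MIN + i * V_STEP;
    tb.m_inf[i] = f_m_inf(v, p[P_MSHIFT]);
    tb.m_rlc[i] = 1.0 - exp(-dt / f_tau_m(v, p[P_TAUM]));
    tb.h_inf[i] = f_h_inf(v);
    tb.h_rlc[i] = 1.0 - exp(-dt / f_tau_h(v, p[P_TAUH]));
    tb.j_inf[i] = f_h_inf(v);
    tb.j_rlc[i] = 1.0 - exp(-dt / f_tau_j(v, p[P_TAUJ]));
    tb.d_inf[i] = f_d_inf(v);
    tb.d_rlc[i] = 1.0 - exp(-dt / f_tau_d(v));
    tb.f_inf[i] = f_f_inf(v);
    tb.f_rlc[i] = 1.0 - exp(-dt / f_tau_f(v, p[P_TAUF]));
    tb.x_inf[i] = f_x_inf(v);
    tb.x_rlc[i] = 1.0 - exp(-dt / f_tau_x(v, p[P_TAUX]));
    tb.a_inf[i] = f_a_inf(v);
    tb.a_rlc[i] = 1.0 - exp(-dt / f_tau_a(v));
    tb.r_inf[i] = f_r_inf(v);
    tb.r_rlc[i] = 1.0 - exp(-dt / f_tau_r(v));
    tb.ik1[i] = p[P_GK1] * (v - p[P_EK1]) / (1.0 + exp(0.05 * (v + 80.0)));
    double e1 = exp(NCX_GAMMA * v * FRT);
    double e2 = exp((NCX_GAMMA - 1.0) * v * FRT);
    double den = denom_na * denom_ca * (1.0 + NCX_KSAT * e2);
    tb.ncx1[i] = p[P_KNCX] * e1 * NCX_NAI * NCX_NAI * NCX_NAI * NCX_CAO / den;
    tb.ncx2[i] = p[P_KNCX] * e2 * NCX_NAO * NCX_NAO * NCX_NAO / den;
  }
}

// linear interpolation helper; caller supplies precomputed index and frac
static inline double lut(const std::vector<double> &t, int i, double w) {
  return t[i] + w * (t[i + 1] - t[i]);
}

// SRF waveform parameter columns (kept in step with R/srf.R srf_matrix()):
//  0 morph (0 none, 1 spike, 2 plateau), 1 ti, 2 tf, 3 tp,
//  4 npeak, 5 nplat, 6 t1, 7 t2, 8 k1, 9 k2
static inline double srf_eval(const double *w, double t) {
  int morph = (int)w[0];
  if (morph == 0) return 0.0;
  if (t < w[1] - 60.0 || t > w[2] + 60.0) return 0.0;
  if (morph == 1) {
    double s1 = 1.0 + exp(-(t - w[6]) / w[8]);
    double s2 = 1.0 + exp((t - w[7]) / w[9]);
    return w[4] / (s1 * s2);
  }
  // plateau form: plateau term plus peak term, fixed slope 5.946 and the
  // printed 17.5 / 25 ms offsets
  double ti = w[1], tf = w[2], tp = w[3], npk = w[4], npl = w[5];
  double p1 = npl / ((1.0 + exp(-(t - (ti + 17.5)) / 5.946)) *
                     (1.0 + exp((t - (tf - 17.5)) / 5.946)));
  double p2 = (npk - npl) / ((1.0 + exp(-(t - (tp - 25.0)) / 5.946)) *
                             (1.0 + exp((t - (tp + 17.5)) / 5.946)));
  return p1 + p2;
}

struct StepError {
  std::string what;
};

// advance one node by dt; returns ionic current sum used for dV
static inline void node_step(double *s, const Tables &tb, const NumericVector &p,
                             double istim, double icoup, double nsrf,
                             double gfb, double dt) {
  double v = s[0];
  double vi = (v - V_MIN) / V_STEP;
  int i0 = (int)vi;
  if (i0 < 0) i0 = 0;
  if (i0 > NTAB - 2) i0 = NTAB - 2;
  double w = vi - i0;
  if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;

  // Rush-Larsen gate updates
  s[1] += (lut(tb.m_inf, i0, w) - s[1]) * lut(tb.m_rlc, i0, w);
  s[2] += (lut(tb.h_inf, i0, w) - s[2]) * lut(tb.h_rlc, i0, w);
  s[3] += (lut(tb.j_inf, i0, w) - s[3]) * lut(tb.j_rlc, i0, w);
  s[4] += (lut(tb.d_inf, i0, w) - s[4]) * lut(tb.d_rlc, i0, w);
  s[5] += (lut(tb.f_inf, i0, w) - s[5]) * lut(tb.f_rlc, i0, w);
  s[6] += (lut(tb.x_inf, i0, w) - s[6]) * lut(tb.x_rlc, i0, w);
  s[7] += (lut(tb.a_inf, i0, w) - s[7]) * lut(tb.a_rlc, i0, w);
  s[8] += (lut(tb.r_inf, i0, w) - s[8]) * lut(tb.r_rlc, i0, w);

  double cai = s[9], casr = s[10];

  double ina  = p[P_GNA] * s[1] * s[1] * s[1] * s[2] * s[3] * (v - p[P_ENA]);
  double ical = p[P_GCAL] * s[4] * s[5] * (v - p[P_ECAL]);
  double ik   = p[P_GK] * s[6] * (v - p[P_EK]);
  double ik1  = lut(tb.ik1, i0, w);
  double incx = lut(tb.ncx1, i0, w) - lut(tb.ncx2, i0, w) * cai;
  double ifb  = gfb * (v - p[P_EFB]);

  // calcium subsystem
  double nryr = s[7] * s[8] * p[P_GATESCALE] + nsrf;
  if (nryr > 1.0) nryr = 1.0;
  double jrel  = p[P_GREL] * nryr * (casr - cai);
  double jup   = p[P_GUP] * cai * cai / (cai * cai + p[P_KUP] * p[P_KUP]);
  double jleak = p[P_GLEAK] * (casr - cai);

  s[9]  += dt * p[P_BUF] * (jrel + jleak - jup + p[P_CCONV] * (-ical + 2.0 * incx));
  s[10] += dt * p[P_VRATIO] * (jup - jrel - jleak);
  if (s[9] < 1e-6) s[9] = 1e-6;
  if (s[10] < p[P_CASRFLOOR]) s[10] = p[P_CASRFLOOR];

  s[0] += dt * (-(ina + ical + ik + ik1 + incx + ifb + istim) + icoup);
}

static void check_node(const double *s, int node, double t) {
  for (int k = 0; k < NVAR; ++k) {
    if (!std::isfinite(s[k])) {
      const char *names[NVAR] = {"V", "m", "h", "j", "d", "f", "x", "a", "r",
                                 "Cai", "CaSR"};
      StepError e;
      e.what = std::string("non-finite ") + names[k] + " at node " +
               std::to_string(node + 1) + ", t = " + std::to_string(t) + " ms";
      throw e;
    }
  }
  if (std::fabs(s[0]) > 100.0) {
    StepError e;
    e.what = std::string("voltage out of range (|V| > 100 mV) at node ") +
             std::to_string(node + 1) + ", t = " + std::to_string(t) + " ms";
    throw e;
  }
}

// [[Rcpp::export(name = ".tissue_run_cpp")]]
List tissue_run_cpp(NumericMatrix state, NumericMatrix conn, IntegerVector dims,
                    NumericVector params, NumericVector gfb_node,
                    NumericMatrix srf, double srf_gate,
                    NumericMatrix stim, IntegerVector stim_nodes,
                    double t0, double duration, double dt,
                    double v_thresh, double trace_dt, double snap_dt,
                    int srf_refresh) {
  const int nx = dims[0], ny = dims[1], n = nx * ny;
  if (state.nrow() != n || state.ncol() != NVAR)
    stop("state must be n x %d", NVAR);
  if (conn.nrow() != n || conn.ncol() != 4) stop("conn must be n x 4");
  const bool have_srf = srf.nrow() == n;
  const bool have_gfb = gfb_node.size() == n;

  Tables tb;
  build_tables(tb, params, dt);

  // working copies (column-major flat arrays)
  std::vector<double> S(n * NVAR);
  for (int k = 0; k < NVAR; ++k)
    for (int i = 0; i < n; ++i) S[i * NVAR + k] = state(i, k);

  std::vector<double> w0(n), w1(n), w2(n), w3(n);
  for (int i = 0; i < n; ++i) {
    w0[i] = conn(i, 0); w1[i] = conn(i, 1); w2[i] = conn(i, 2); w3[i] = conn(i, 3);
  }
  std::vector<double> srf_flat;
  if (have_srf) {
    srf_flat.resize(n * 10);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 10; ++k) srf_flat[i * 10 + k] = srf(i, k);
  }

  std::vector<double> vold(n), icoup(n), nsrf(n, 0.0), stim_now(n, 0.0);
  const int nsteps = (int)std::floor(duration / dt + 0.5);
  const int trace_stride = trace_dt > 0 ? std::max(1, (int)std::floor(trace_dt / dt + 0.5)) : 0;
  const int snap_stride = snap_dt > 0 ? std::max(1, (int)std::floor(snap_dt / dt + 0.5)) : 0;

  std::vector<int> ev_node;
  std::vector<double> ev_time;
  std::vector<double> tr_t, tr_v, tr_casr;
  int nsnap = snap_stride > 0 ? nsteps / snap_stride + 1 : 0;
  NumericMatrix snaps(snap_stride > 0 ? n : 0, nsnap);
  std::vector<double> snap_times;

  const int nstim = stim.nrow();
  std::string err_msg;
  bool failed = false;

  for (int step = 0; step < nsteps; ++step) {
    double t = t0 + step * dt;

    // stimulus currents (amplitude in pA/pF on the masked nodes)
    double amp = 0.0;
    for (int si = 0; si < nstim; ++si) {
      if (t >= stim(si, 0) && t < stim(si, 0) + stim(si, 1)) amp += stim(si, 2);
    }
    // refresh SRF drive every srf_refresh steps (the waveform varies on a
    // tens-of-ms scale; holding it for <=0.1 ms is far inside tolerance)
    if (have_srf && t >= srf_gate && (step % srf_refresh) == 0) {
      for (int i = 0; i < n; ++i) nsrf[i] = srf_eval(&srf_flat[i * 10], t);
    }

    for (int i = 0; i < n; ++i) { vold[i] = S[i * NVAR]; icoup[i] = 0.0; }

    // coupling pass: accumulate w*(Vj - Vi) symmetrically over the 4 bond
    // directions stored at the lower endpoint
    for (int y = 0; y < ny; ++y) {
      int row = y * nx;
      for (int x = 0; x < nx; ++x) {
        int i = row + x;
        double vi = vold[i];
        double wxy;
        if (x < nx - 1 && (wxy = w0[i]) != 0.0) {
          int j = i + 1; double d = wxy * (vold[j] - vi);
          icoup[i] += d; icoup[j] -= d;
        }
        if (y < ny - 1 && (wxy = w1[i]) != 0.0) {
          int j = i + nx; double d = wxy * (vold[j] - vi);
          icoup[i] += d; icoup[j] -= d;
        }
        if (x < nx - 1 && y < ny - 1 && (wxy = w2[i]) != 0.0) {
          int j = i + nx + 1; double d = wxy * (vold[j] - vi);
          icoup[i] += d; icoup[j] -= d;
        }
        if (x < nx - 1 && y > 0 && (wxy = w3[i]) != 0.0) {
          int j = i - nx + 1; double d = wxy * (vold[j] - vi);
          icoup[i] += d; icoup[j] -= d;
        }
      }
    }

    if (amp != 0.0) {
      for (R_xlen_t k = 0; k < stim_nodes.size(); ++k) stim_now[stim_nodes[k]] = amp;
    }

    try {
      for (int i = 0; i < n; ++i) {
        double *s = &S[i * NVAR];
        node_step(s, tb, params, stim_now[i], icoup[i],
                  have_srf ? nsrf[i] : 0.0, have_gfb ? gfb_node[i] : 0.0, dt);
        if (s[0] >= v_thresh && vold[i] < v_thresh) {
          ev_node.push_back(i + 1);
          ev_time.push_back(t + dt);
        }
        if (!std::isfinite(s[0]) || std::fabs(s[0]) > 100.0) check_node(s, i, t + dt);
      }
    } catch (StepError &e) {
      err_msg = e.what;
      failed = true;
    }
    if (failed) break;

    if (amp != 0.0) {
      for (R_xlen_t k = 0; k < stim_nodes.size(); ++k) stim_now[stim_nodes[k]] = 0.0;
    }

    if (trace_stride > 0 && (step % trace_stride) == 0) {
      double vs = 0.0, cs = 0.0;
      for (int i = 0; i < n; ++i) { vs += S[i * NVAR]; cs += S[i * NVAR + 10]; }
      tr_t.push_back(t + dt);
      tr_v.push_back(vs / n);
      tr_casr.push_back(cs / n);
    }
    if (snap_stride > 0 && (step % snap_stride) == 0) {
      int col = step / snap_stride;
      for (int i = 0; i < n; ++i) snaps(i, col) = S[i * NVAR];
      snap_times.push_back(t + dt);
    }
  }

  if (failed) stop("tissue integration failure: %s", err_msg.c_str());

  NumericMatrix out_state(n, NVAR);
  for (int k = 0; k < NVAR; ++k)
    for (int i = 0; i < n; ++i) out_state(i, k) = S[i * NVAR + k];

  List res = List::create(
    _["state"] = out_state,
    _["event_node"] = wrap(ev_node),
    _["event_time"] = wrap(ev_time),
    _["trace_t"] = wrap(tr_t),
    _["trace_vmean"] = wrap(tr_v),
    _["trace_casr_mean"] = wrap(tr_casr),
    _["t_end"] = t0 + nsteps * dt);
  if (snap_stride > 0) {
    res["snap_v"] = snaps;
    res["snap_t"] = wrap(snap_times);
  }
  return res;
}

// Single-cell runner: stimulus train plus one SRF waveform (or a constant
// imposed RyR open fraction), with full traces at the requested stride.
// [[Rcpp::export(name = ".cell_run_cpp")]]
List cell_run_cpp(NumericVector state, NumericVector params,
                  NumericVector srf_row, double nryr_const,
                  NumericMatrix stim, double t0, double duration, double dt,
                  double trace_dt, double gfb) {
  if (state.size() != NVAR) stop("state must have %d entries", NVAR);
  Tables tb;
  build_tables(tb, params, dt);
  double S[NVAR];
  for (int k = 0; k < NVAR; ++k) S[k] = state[k];
  const bool have_srf = srf_row.size() == 10;
  const int nsteps = (int)std::floor(duration / dt + 0.5);
  const int stride = trace_dt > 0 ? std::max(1, (int)std::floor(trace_dt / dt + 0.5)) : 0;
  std::vector<double> tr_t, tr_v, tr_cai, tr_casr, tr_nryr;
  const int nstim = stim.nrow();
  double nsrf = nryr_const;
  for (int step = 0; step < nsteps; ++step) {
    double t = t0 + step * dt;
    double amp = 0.0;
    for (int si = 0; si < nstim; ++si)
      if (t >= stim(si, 0) && t < stim(si, 0) + stim(si, 1)) amp += stim(si, 2);
    if (have_srf) nsrf = srf_eval(&srf_row[0], t) + nryr_const;
    try {
      node_step(S, tb, params, amp, 0.0, nsrf, gfb, dt);
      check_node(S, 0, t + dt);
    } catch (StepError &e) {
      stop("cell integration failure: %s", e.what.c_str());
    }
    if (stride > 0 && (step % stride) == 0) {
      tr_t.push_back(t + dt);
      tr_v.push_back(S[0]);
      tr_cai.push_back(S[9]);
      tr_casr.push_back(S[10]);
      tr_nryr.push_back(nsrf);
    }
  }
  NumericVector out(NVAR);
  for (int k = 0; k < NVAR; ++k) out[k] = S[k];
  return List::create(_["state"] = out, _["t"] = wrap(tr_t), _["V"] = wrap(tr_v),
                      _["Cai"] = wrap(tr_cai), _["CaSR"] = wrap(tr_casr),
                      _["Nryr"] = wrap(tr_nryr), _["t_end"] = t0 + nsteps * dt);
}

// one (or a few) explicit forward steps of a single cell; used by ionic_step()
// [[Rcpp::export(name = ".ionic_step_cpp")]]
NumericVector ionic_step_cpp(NumericVector state, NumericVector params,
                             double istim, double nryr, double dt, int nsteps,
                             double gfb) {
  if (state.size() != NVAR) stop("state must have %d entries", NVAR);
  Tables tb;
  build_tables(tb, params, dt);
  double S[NVAR];
  for (int k = 0; k < NVAR; ++k) S[k] = state[k];
  for (int step = 0; step < nsteps; ++step) {
    try {
      node_step(S, tb, params, istim, 0.0, nryr, gfb, dt);
      check_node(S, 0, (step + 1) * dt);
    } catch (StepError &e) {
      stop("cell integration failure: %s", e.what.c_str());
    }
  }
  NumericVector out(NVAR);
  for (int k = 0; k < NVAR; ++k) out[k] = S[k];
  out.attr("names") = CharacterVector::create("V", "m", "h", "j", "d", "f",
                                              "x", "a", "r", "Cai", "CaSR");
  return out;
}

// gate steady states at a voltage (used to build initial conditions)
// [[Rcpp::export(name = ".gate_inf_cpp")]]
NumericVector gate_inf_cpp(double v, NumericVector params) {
  NumericVector out = NumericVector::create(
    _["m"] = f_m_inf(v, params[P_MSHIFT]), _["h"] = f_h_inf(v),
    _["j"] = f_h_inf(v), _["d"] = f_d_inf(v), _["f"] = f_f_inf(v),
    _["x"] = f_x_inf(v), _["a"] = f_a_inf(v), _["r"] = f_r_inf(v));
  return out;
}

// 4-connectivity connected-component labelling of a logical grid
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      if (!mask(x, y) || lab(x, y) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(x + nx * y);
      lab(x, y) = next;
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        int cx = id % nx, cy = id / nx;
        const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int px = cx + dx[k], py = cy + dy[k];
          if (px < 0 || px >= nx || py < 0 || py >= ny) continue;
          if (mask(px, py) && lab(px, py) == 0) {
            lab(px, py) = next;
            stack.push_back(px + nx * py);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
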