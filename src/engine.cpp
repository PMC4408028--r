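// Core update loop of the hybrid discrete-continuous tumor-macrophage model.
//
// Layer codes (shared with R, see occupancy_codes()):
//   tumor layer:      0 empty, 1 live tumor, 2 dead tumor
//   macrophage layer: 0 empty, 1 naive, 2 M1, 3 M2,
//                     4 EMP naive, 5 EMP M1, 6 EMP M2, 7 dead macrophage
//
// Parameter vector p is 0-indexed here: p[0] = p1, ..., p[17] = p18.
// All randomness goes through R's RNG (unif_rand) so a set.seed() on the R
// side makes every entry point bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Cfg {
  int nx, ny;
  double dx, dt;
  int nsub;                // diffusion sub-steps per macro step
  double lam_tls, lam_m2s, lam_act, lam_blk;
  double vmax;
  double necro_window;     // dead tumor cells stay Activator sources this long
  int chemo_mode;          // 0 deterministic argmax, 1 stochastic
  double chemo_floor;      // uniform weight floor in stochastic mode [pg/LS]
  int chemo_classes;       // 0 all macrophage classes move, 1 naive+M1 only
  int neigh;               // 0 Moore (8), 1 von Neumann (4)
};

struct Ther {
  int strategy;            // 0 none, 1 ENHANCED_TLS, 2 NO_M2, 3 ACTIVE_CONVERSION
  double t_intro, frac, tls_mult, blk_rate, kb;
};

static Cfg parse_cfg(const List& cfgl) {
  Cfg c;
  c.nx = as<int>(cfgl["nx"]);
  c.ny = as<int>(cfgl["ny"]);
  c.dx = as<double>(cfgl["dx"]);
  c.dt = as<double>(cfgl["dt"]);
  c.nsub = as<int>(cfgl["n_substeps"]);
  c.lam_tls = as<double>(cfgl["lambda_tls"]);
  c.lam_m2s = as<double>(cfgl["lambda_m2s"]);
  c.lam_act = as<double>(cfgl["lambda_act"]);
  c.lam_blk = as<double>(cfgl["lambda_blocker"]);
  c.vmax = as<double>(cfgl["v_max"]);
  c.necro_window = as<double>(cfgl["necro_window"]);
  c.chemo_mode = as<int>(cfgl["chemo_mode_code"]);
  c.chemo_floor = as<double>(cfgl["chemotaxis_floor"]);
  c.chemo_classes = as<int>(cfgl["chemo_classes_code"]);
  c.neigh = as<int>(cfgl["neighborhood_code"]);
  return c;
}

static Ther parse_ther(SEXP therl) {
  Ther t;
  if (Rf_isNull(therl)) {
    t.strategy = 0; t.t_intro = 0.0; t.frac = 0.0;
    t.tls_mult = 1.0; t.blk_rate = 0.0; t.kb = 1.0;
    return t;
  }
  List tl(therl);
  t.strategy = as<int>(tl["strategy_code"]);
  t.t_intro = as<double>(tl["t_intro"]);
  t.frac = as<double>(tl["emp_fraction"]);
  t.tls_mult = as<double>(tl["tls_multiplier"]);
  t.blk_rate = as<double>(tl["blocker_rate"]);
  t.kb = as<double>(tl["k_blocker"]);
  return t;
}

// ---------------------------------------------------------------------------
// Stage 1-2 helpers: reaction and diffusion
// ---------------------------------------------------------------------------

// Explicit FTCS 5-point diffusion with zero-flux (mirror) boundaries.
static void diffuse_core(NumericMatrix f, double D, double dt, int nsub, double dx) {
  if (D <= 0.0 || dt <= 0.0) return;
  const int nx = f.nrow(), ny = f.ncol();
  const double sdt = dt / nsub;
  const double r = D * sdt / (dx * dx);
  NumericMatrix tmp(nx, ny);
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 0 : j - 1;
      const int jp = (j == ny - 1) ? ny - 1 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i == 0) ? 0 : i - 1;
        const int ip = (i == nx - 1) ? nx - 1 : i + 1;
        const double lap = f(im, j) + f(ip, j) + f(i, jm) + f(i, jp) - 4.0 * f(i, j);
        tmp(i, j) = f(i, j) + r * lap;
      }
    }
    std::copy(tmp.begin(), tmp.end(), f.begin());
  }
}

// Secretion, oxygen delivery/uptake (floored at 0), first-order decay.
static void react_core(NumericMatrix tls, NumericMatrix m2s, NumericMatrix act,
                       NumericMatrix oxy, NumericMatrix blk,
                       const NumericMatrix& vasc,
                       const IntegerMatrix& tum, const IntegerMatrix& mac,
                       const NumericMatrix& tdeath,
                       const NumericVector& p, const Cfg& cfg, const Ther& th,
                       double tnow, double dt) {
  const int n = tum.size();
  const double f_tls = std::exp(-cfg.lam_tls * dt);
  const double f_m2s = std::exp(-cfg.lam_m2s * dt);
  const double f_act = std::exp(-cfg.lam_act * dt);
  const double f_blk = std::exp(-cfg.lam_blk * dt);
  for (int k = 0; k < n; ++k) {
    const int tc = tum[k], mc = mac[k];
    if (mc == 2) {
      tls[k] += p[4] * dt;                                     // M1 secretes TLS (p5)
    } else if (mc == 5) {
      const double mult = (th.strategy == 1) ? th.tls_mult : 1.0;
      tls[k] += mult * p[4] * dt;                              // EMP-M1 (4x under ENHANCED_TLS)
    }
    if (tc == 1) {
      m2s[k] += p[1] * dt;                                     // tumor secretes M2S (p2)
      act[k] += p[2] * dt;                                     // and Activator (p3)
    } else if (tc == 2 && tdeath[k] >= 0.0 &&
               (tnow - tdeath[k]) <= cfg.necro_window) {
      act[k] += p[2] * dt;                                     // necrotic Activator release
    }
    if (mc == 3 || mc == 6) m2s[k] += p[3] * dt;               // M2 secretes M2S (p4)
    if (th.strategy == 3 && mc >= 4 && mc <= 6) blk[k] += th.blk_rate * dt;
    oxy[k] += p[7] * vasc[k] * dt;                             // delivery (p8)
    const int live = ((tc == 1) ? 1 : 0) + ((mc >= 1 && mc <= 6) ? 1 : 0);
    if (live > 0) {
      oxy[k] -= p[8] * dt * live;                              // uptake (p9), floored
      if (oxy[k] < 0.0) oxy[k] = 0.0;
    }
    tls[k] *= f_tls;
    m2s[k] *= f_m2s;
    act[k] *= f_act;
    if (th.strategy == 3) blk[k] *= f_blk;
  }
}

// ---------------------------------------------------------------------------
// Stage 3: M2S-driven vasculature growth (capped, never decreasing)
// ---------------------------------------------------------------------------

static void vasc_core(NumericMatrix vasc, const NumericMatrix& m2s,
                      double p14, double vmax, double dt) {
  const int n = vasc.size();
  for (int k = 0; k < n; ++k) {
    double v = vasc[k] + p14 * m2s[k] * dt;
    vasc[k] = (v > vmax) ? vmax : v;
  }
}

// ---------------------------------------------------------------------------
// Stage 4: vasculature-proportional recruitment (with optional EMP mix)
// ---------------------------------------------------------------------------

static void recruit_core(IntegerMatrix mac, const NumericMatrix& vasc,
                         double p15, const Ther& th, double tnow, double dt) {
  const int n = mac.size();
  for (int k = 0; k < n; ++k) {
    if (mac[k] != 0) continue;
    double pr = p15 * vasc[k] * dt;
    if (pr <= 0.0) continue;
    if (pr > 1.0) pr = 1.0;
    if (unif_rand() < pr) {
      int code = 1;
      if (th.strategy != 0 && tnow >= th.t_intro && th.frac > 0.0) {
        if (unif_rand() < th.frac) code = 4;
      }
      mac[k] = code;
    }
  }
}

// ---------------------------------------------------------------------------
// Stage 5: stochastic polarization of activated naive macrophages
// ---------------------------------------------------------------------------

static double logistic(double z) {
  if (z > 0) return 1.0 / (1.0 + std::exp(-z));
  const double e = std::exp(z);
  return e / (1.0 + e);
}

static void polarize_core(IntegerMatrix mac, const NumericMatrix& act,
                          const NumericMatrix& m2s, const NumericMatrix& blk,
                          const NumericVector& p, const Ther& th) {
  const int n = mac.size();
  for (int k = 0; k < n; ++k) {
    const int mc = mac[k];
    if (mc != 1 && mc != 4) continue;
    if (act[k] < p[6]) continue;                               // activation threshold p7 (inclusive >=)
    if (mc == 4 && (th.strategy == 2 || th.strategy == 3)) {
      mac[k] = 5;                                              // EMP forbidden from M2
      continue;
    }
    double m = m2s[k];
    if (mc == 1 && th.strategy == 3) m = m / (1.0 + blk[k] / th.kb);
    const double P = logistic((m - p[12]) / p[15]);            // p13 threshold, p16 width
    const double u = unif_rand();
    if (u < P) mac[k] = (mc == 1) ? 3 : 6;
    else       mac[k] = (mc == 1) ? 2 : 5;
  }
}

// ---------------------------------------------------------------------------
// Stage 6: chemotaxis along M2S gradients, random update order
// ---------------------------------------------------------------------------

static const int MOORE_DI[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
static const int MOORE_DJ[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
static const int VN_DI[4] = { -1, 1, 0, 0 };
static const int VN_DJ[4] = { 0, 0, -1, 1 };

static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

static void move_core(IntegerMatrix mac, const NumericMatrix& m2s, const Cfg& cfg) {
  const int nx = mac.nrow(), ny = mac.ncol();
  std::vector<int> cells;
  cells.reserve(256);
  for (int k = 0; k < nx * ny; ++k) {
    const int mc = mac[k];
    if (mc < 1 || mc > 6) continue;
    if (cfg.chemo_classes == 1 && (mc == 3 || mc == 6)) continue;  // naive+M1 variant
    cells.push_back(k);
  }
  shuffle_idx(cells);
  const int ndir = (cfg.neigh == 0) ? 8 : 4;
  const int* DI = (cfg.neigh == 0) ? MOORE_DI : VN_DI;
  const int* DJ = (cfg.neigh == 0) ? MOORE_DJ : VN_DJ;
  int cand[9];
  double w[9];
  int bests[9];
  for (size_t c = 0; c < cells.size(); ++c) {
    const int idx = cells[c];
    const int code = mac[idx];
    const int ci = idx % nx, cj = idx / nx;
    int nc = 0;
    cand[nc] = idx; w[nc] = m2s[idx]; ++nc;                    // staying is always a candidate
    for (int d = 0; d < ndir; ++d) {
      const int ni = ci + DI[d], nj = cj + DJ[d];
      if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
      const int nk = ni + nj * nx;
      if (mac[nk] != 0) continue;
      cand[nc] = nk; w[nc] = m2s[nk]; ++nc;
    }
    int dest = idx;
    if (cfg.chemo_mode == 0) {
      double best = w[0];
      int nbest = 0;
      bests[nbest++] = cand[0];
      for (int t = 1; t < nc; ++t) {
        if (w[t] > best) { best = w[t]; nbest = 0; bests[nbest++] = cand[t]; }
        else if (w[t] == best) bests[nbest++] = cand[t];
      }
      if (nbest == 1) dest = bests[0];
      else {
        int pick = (int)(unif_rand() * nbest);
        if (pick >= nbest) pick = nbest - 1;
        dest = bests[pick];
      }
    } else {
      double tot = 0.0;
      for (int t = 0; t < nc; ++t) tot += w[t] + cfg.chemo_floor;
      double u = unif_rand() * tot, acc = 0.0;
      for (int t = 0; t < nc; ++t) {
        acc += w[t] + cfg.chemo_floor;
        if (u <= acc) { dest = cand[t]; break; }
      }
    }
    if (dest != idx) {
      mac[dest] = code;
      mac[idx] = 0;
    }
  }
}

// ---------------------------------------------------------------------------
// Stage 7: tumor division into empty neighboring sites
// ---------------------------------------------------------------------------

static void divide_core(IntegerMatrix tum, double p12, const Cfg& cfg, double dt) {
  const int nx = tum.nrow(), ny = tum.ncol();
  double pr = p12 * dt;
  if (pr > 1.0) pr = 1.0;
  if (pr <= 0.0) return;
  std::vector<int> cells;
  cells.reserve(256);
  for (int k = 0; k < nx * ny; ++k)
    if (tum[k] == 1) cells.push_back(k);
  shuffle_idx(cells);
  const int ndir = (cfg.neigh == 0) ? 8 : 4;
  const int* DI = (cfg.neigh == 0) ? MOORE_DI : VN_DI;
  const int* DJ = (cfg.neigh == 0) ? MOORE_DJ : VN_DJ;
  int empt[8];
  for (size_t c = 0; c < cells.size(); ++c) {
    const int idx = cells[c];
    const int ci = idx % nx, cj = idx / nx;
    int ne = 0;
    for (int d = 0; d < ndir; ++d) {
      const int ni = ci + DI[d], nj = cj + DJ[d];
      if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
      const int nk = ni + nj * nx;
      if (tum[nk] == 0) empt[ne++] = nk;
    }
    if (ne == 0) continue;                                     // enclosed cells cannot divide
    if (unif_rand() < pr) {
      int pick = (int)(unif_rand() * ne);
      if (pick >= ne) pick = ne - 1;
      tum[empt[pick]] = 1;
    }
  }
}

// ---------------------------------------------------------------------------
// Stage 8: death by TLS (tumor) and by anoxia (all live cells)
// ---------------------------------------------------------------------------

static void death_core(IntegerMatrix tum, IntegerMatrix mac,
                       const NumericMatrix& tls, const NumericMatrix& oxy,
                       NumericMatrix tdeath, double p6, double p10, double tnow) {
  const int n = tum.size();
  for (int k = 0; k < n; ++k) {
    if (tum[k] == 1 && (tls[k] >= p6 || oxy[k] < p10)) {
      tum[k] = 2;
      tdeath[k] = tnow;
    }
    const int mc = mac[k];
    if (mc >= 1 && mc <= 6 && oxy[k] < p10) mac[k] = 7;
  }
}

// ---------------------------------------------------------------------------
// Full macro step (the canonical eight-stage order)
// ---------------------------------------------------------------------------

static double step_all(double tnow,
                       NumericMatrix tls, NumericMatrix m2s, NumericMatrix act,
                       NumericMatrix oxy, NumericMatrix blk, NumericMatrix vasc,
                       IntegerMatrix tum, IntegerMatrix mac, NumericMatrix tdeath,
                       const NumericVector& p, const Cfg& cfg, const Ther& th) {
  const double dt = cfg.dt;
  react_core(tls, m2s, act, oxy, blk, vasc, tum, mac, tdeath, p, cfg, th, tnow, dt);
  diffuse_core(tls, p[0], dt, cfg.nsub, cfg.dx);
  diffuse_core(m2s, p[0], dt, cfg.nsub, cfg.dx);
  diffuse_core(act, p[0], dt, cfg.nsub, cfg.dx);
  diffuse_core(oxy, p[0], dt, cfg.nsub, cfg.dx);
  if (th.strategy == 3) diffuse_core(blk, p[0], dt, cfg.nsub, cfg.dx);
  vasc_core(vasc, m2s, p[13], cfg.vmax, dt);
  recruit_core(mac, vasc, p[14], th, tnow, dt);
  polarize_core(mac, act, m2s, blk, p, th);
  move_core(mac, m2s, cfg);
  divide_core(tum, p[11], cfg, dt);
  death_core(tum, mac, tls, oxy, tdeath, p[5], p[9], tnow + dt);
  return tnow + dt;
}

// ---------------------------------------------------------------------------
// Exported entry points (all clone their inputs; R keeps copy semantics)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix field, double D, double dt, int nsub, double dx) {
  NumericMatrix f = clone(field);
  diffuse_core(f, D, dt, nsub, dx);
  return f;
}

// [[Rcpp::export]]
List cpp_react(List state, NumericVector p, List cfgl, SEXP therl) {
  Cfg cfg = parse_cfg(cfgl);
  Ther th = parse_ther(therl);
  NumericMatrix tls = clone(as<NumericMatrix>(state["tls"]));
  NumericMatrix m2s = clone(as<NumericMatrix>(state["m2s"]));
  NumericMatrix act = clone(as<NumericMatrix>(state["activator"]));
  NumericMatrix oxy = clone(as<NumericMatrix>(state["oxygen"]));
  NumericMatrix blk = clone(as<NumericMatrix>(state["blocker"]));
  NumericMatrix vasc = as<NumericMatrix>(state["vasculature"]);
  IntegerMatrix tum = as<IntegerMatrix>(state["tumor"]);
  IntegerMatrix mac = as<IntegerMatrix>(state["mac"]);
  NumericMatrix tdeath = as<NumericMatrix>(state["tdeath"]);
  double tnow = as<double>(state["time"]);
  react_core(tls, m2s, act, oxy, blk, vasc, tum, mac, tdeath, p, cfg, th, tnow, cfg.dt);
  return List::create(_["tls"] = tls, _["m2s"] = m2s, _["activator"] = act,
                      _["oxygen"] = oxy, _["blocker"] = blk);
}

// [[Rcpp::export]]
NumericMatrix cpp_grow_vasc(NumericMatrix vasc, NumericMatrix m2s,
                            double p14, double vmax, double dt) {
  NumericMatrix v = clone(vasc);
  vasc_core(v, m2s, p14, vmax, dt);
  return v;
}

// [[Rcpp::export]]
IntegerMatrix cpp_recruit(IntegerMatrix mac, NumericMatrix vasc, double p15,
                          SEXP therl, double tnow, double dt) {
  IntegerMatrix m = clone(mac);
  Ther th = parse_ther(therl);
  recruit_core(m, vasc, p15, th, tnow, dt);
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_polarize(IntegerMatrix mac, NumericMatrix act, NumericMatrix m2s,
                           NumericMatrix blk, NumericVector p, SEXP therl) {
  IntegerMatrix m = clone(mac);
  Ther th = parse_ther(therl);
  polarize_core(m, act, m2s, blk, p, th);
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_move(IntegerMatrix mac, NumericMatrix m2s, List cfgl) {
  IntegerMatrix m = clone(mac);
  Cfg cfg = parse_cfg(cfgl);
  move_core(m, m2s, cfg);
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_divide(IntegerMatrix tum, double p12, List cfgl, double dt) {
  IntegerMatrix t = clone(tum);
  Cfg cfg = parse_cfg(cfgl);
  divide_core(t, p12, cfg, dt);
  return t;
}

// [[Rcpp::export]]
List cpp_death(IntegerMatrix tum, IntegerMatrix mac, NumericMatrix tls,
               NumericMatrix oxy, NumericMatrix tdeath,
               double p6, double p10, double tnow) {
  IntegerMatrix t = clone(tum);
  IntegerMatrix m = clone(mac);
  NumericMatrix td = clone(tdeath);
  death_core(t, m, tls, oxy, td, p6, p10, tnow);
  return List::create(_["tumor"] = t, _["mac"] = m, _["tdeath"] = td);
}

static List clone_state(const List& state) {
  return List::create(
    _["time"] = as<double>(state["time"]),
    _["tls"] = clone(as<NumericMatrix>(state["tls"])),
    _["m2s"] = clone(as<NumericMatrix>(state["m2s"])),
    _["activator"] = clone(as<NumericMatrix>(state["activator"])),
    _["oxygen"] = clone(as<NumericMatrix>(state["oxygen"])),
    _["blocker"] = clone(as<NumericMatrix>(state["blocker"])),
    _["vasculature"] = clone(as<NumericMatrix>(state["vasculature"])),
    _["tumor"] = clone(as<IntegerMatrix>(state["tumor"])),
    _["mac"] = clone(as<IntegerMatrix>(state["mac"])),
    _["tdeath"] = clone(as<NumericMatrix>(state["tdeath"])));
}

// [[Rcpp::export]]
List cpp_step(List state, NumericVector p, List cfgl, SEXP therl) {
  Cfg cfg = parse_cfg(cfgl);
  Ther th = parse_ther(therl);
  List s = clone_state(state);
  NumericMatrix tls = s["tls"], m2s = s["m2s"], act = s["activator"],
                oxy = s["oxygen"], blk = s["blocker"], vasc = s["vasculature"],
                tdeath = s["tdeath"];
  IntegerMatrix tum = s["tumor"], mac = s["mac"];
  double tnow = as<double>(s["time"]);
  tnow = step_all(tnow, tls, m2s, act, oxy, blk, vasc, tum, mac, tdeath, p, cfg, th);
  s["time"] = tnow;
  return s;
}

// Row layout of the time-series matrix returned by cpp_run.
static const int TS_NCOL = 19;

static void record_row(NumericMatrix ts, int row, double tnow,
                       const IntegerMatrix& tum, const IntegerMatrix& mac,
                       const NumericMatrix& m2s, const NumericMatrix& oxy,
                       const NumericMatrix& tls, const NumericMatrix& act,
                       const NumericMatrix& vasc) {
  const int n = tum.size();
  int counts[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int tlive = 0, tdead = 0;
  double m2s_sum = 0, m2s_max = 0, oxy_sum = 0, oxy_min = R_PosInf;
  double tls_sum = 0, tls_max = 0, act_sum = 0, vasc_sum = 0, vasc_max = 0;
  for (int k = 0; k < n; ++k) {
    if (tum[k] == 1) ++tlive; else if (tum[k] == 2) ++tdead;
    const int mc = mac[k];
    if (mc >= 1 && mc <= 7) ++counts[mc];
    m2s_sum += m2s[k]; if (m2s[k] > m2s_max) m2s_max = m2s[k];
    oxy_sum += oxy[k]; if (oxy[k] < oxy_min) oxy_min = oxy[k];
    tls_sum += tls[k]; if (tls[k] > tls_max) tls_max = tls[k];
    act_sum += act[k];
    vasc_sum += vasc[k]; if (vasc[k] > vasc_max) vasc_max = vasc[k];
  }
  ts(row, 0) = tnow;
  ts(row, 1) = tlive;
  ts(row, 2) = tdead;
  ts(row, 3) = counts[1];     // naive
  ts(row, 4) = counts[2];     // m1
  ts(row, 5) = counts[3];     // m2
  ts(row, 6) = counts[4];     // emp_naive
  ts(row, 7) = counts[5];     // emp_m1
  ts(row, 8) = counts[6];     // emp_m2
  ts(row, 9) = counts[7];     // mac_dead
  ts(row, 10) = m2s_sum / n;
  ts(row, 11) = m2s_max;
  ts(row, 12) = oxy_sum / n;
  ts(row, 13) = oxy_min;
  ts(row, 14) = tls_sum / n;
  ts(row, 15) = tls_max;
  ts(row, 16) = act_sum / n;
  ts(row, 17) = vasc_sum / n;
  ts(row, 18) = vasc_max;
}

// [[Rcpp::export]]
List cpp_run(List state, NumericVector p, List cfgl, SEXP therl,
             double t_end, double out_dt, bool early_exit) {
  Cfg cfg = parse_cfg(cfgl);
  Ther th = parse_ther(therl);
  List s = clone_state(state);
  NumericMatrix tls = s["tls"], m2s = s["m2s"], act = s["activator"],
                oxy = s["oxygen"], blk = s["blocker"], vasc = s["vasculature"],
                tdeath = s["tdeath"];
  IntegerMatrix tum = s["tumor"], mac = s["mac"];
  double tnow = as<double>(s["time"]);

  const double t0 = tnow;
  const int nsteps = (int)std::lround((t_end - tnow) / cfg.dt);
  const int out_every = (int)std::lround(out_dt / cfg.dt);
  const int nrow = nsteps / out_every + 1;
  NumericMatrix ts(nrow, TS_NCOL);

  record_row(ts, 0, tnow, tum, mac, m2s, oxy, tls, act, vasc);
  double first_core_time = NA_REAL;
  if (ts(0, 2) > 0) first_core_time = tnow;
  int row = 1;
  bool extinct = (ts(0, 1) == 0);

  for (int step = 1; step <= nsteps && !extinct; ++step) {
    step_all(tnow, tls, m2s, act, oxy, blk, vasc, tum, mac, tdeath, p, cfg, th);
    tnow = t0 + step * cfg.dt;   // exact clock, no accumulated rounding
    if (step % out_every == 0) {
      record_row(ts, row, tnow, tum, mac, m2s, oxy, tls, act, vasc);
      if (!R_finite(ts(row, 10)) || !R_finite(ts(row, 12)) || !R_finite(ts(row, 15)))
        stop("non-finite field values at t = %g; simulation aborted", tnow);
      if (ISNA(first_core_time) && ts(row, 2) > 0) first_core_time = tnow;
      if (early_exit && ts(row, 1) == 0) extinct = true;
      ++row;
    } else if (ISNA(first_core_time)) {
      // cheap scan for the first dead tumor cell between output samples
      const int n = tum.size();
      for (int k = 0; k < n; ++k)
        if (tum[k] == 2) { first_core_time = tnow; break; }
    }
  }
  // pad remaining sample rows after early exit (series carry last values)
  for (; row < nrow; ++row) {
    for (int cidx = 0; cidx < TS_NCOL; ++cidx) ts(row, cidx) = ts(row - 1, cidx);
    ts(row, 0) = t0 + (double)row * out_every * cfg.dt;
  }

  s["time"] = tnow;
  return List::create(_["ts"] = ts, _["state"] = s,
                      _["first_core_time"] = first_core_time,
                      _["early_exit"] = extinct);
}
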