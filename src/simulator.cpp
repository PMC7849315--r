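// Fixed-step integrator for the two-file root model with division,
// elongation-transition and window-advection events, and an exactly
// accumulated auxin mass ledger. The R-level rhs primitives in
// R/core-model.R define the dynamics; this file reimplements them for the
// inner loop and is cross-checked against them in the test suite.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Params {
  double s1, s2, z, k_a, d_a, m_p, d_p, q_p;
  double l_n, tr_n, tr_wn, tr_a, tr_i;
  double k_v0, k_v1, k_v2, k_v3, k_v4, t_v, h1, h2;
  double k_l_mer, k_l_el, m_l_mer, m_l_el;
  double maxL, thr_amm, thr_nit, DIV_thr, min_div_len;
  int window;
  bool literal;
  bool maxA_dynamic;
  double maxA_fixed;
};

// One cell file as a structure of arrays.
struct FileState {
  std::vector<double> A, Pc, Pa, Pb, Po, DIV, L;
  std::vector<int> zone; // 0 meristem, 1 elongation
  size_t n() const { return A.size(); }
};

struct Deriv {
  std::vector<double> A, Pc, Pa, Pb, Po, DIV, L;
  void resize(size_t n) {
    A.assign(n, 0.0); Pc.assign(n, 0.0); Pa.assign(n, 0.0); Pb.assign(n, 0.0);
    Po.assign(n, 0.0); DIV.assign(n, 0.0); L.assign(n, 0.0);
  }
};

// Ledger flux rates (instantaneous, summed over all cells).
struct LedgerRate {
  double in = 0, deg = 0, out = 0;
};

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// rhs for both files; `src` is the positional epidermal source vector.
// Returns ledger rates; optionally records the maximum per-pool loss-rate
// coefficient for the stability check.
static LedgerRate rhs(const FileState st[2], const std::vector<double>& src,
                      int N, const Params& p, double maxA,
                      Deriv d[2], double* max_rate) {
  LedgerRate lr;
  double rate_sel = N * p.tr_n + (1 - N) * p.tr_wn;
  double alloc_o = p.l_n * N, alloc_a = 1.0 - alloc_o;
  double mrate = 0.0;

  for (int f = 0; f < 2; ++f) {
    const FileState& s = st[f];
    size_t n = s.n();
    d[f].resize(n);
    for (size_t c = 0; c < n; ++c) {
      double i = (double)(c + 1);
      double A = s.A[c];
      double gate = logistic(p.tr_a * A + p.tr_i * i);
      double T = s.Pc[c] * rate_sel * gate;
      double dp_eff = p.d_p * (1.0 + A / p.q_p);
      double mdecay = p.literal ? 0.0 : dp_eff;
      d[f].Pc[c] = p.m_p - dp_eff * s.Pc[c] - (p.literal ? 0.0 : T);
      d[f].Pa[c] = alloc_a * T - mdecay * s.Pa[c];
      d[f].Pb[c] = -mdecay * s.Pb[c];
      d[f].Po[c] = alloc_o * T - mdecay * s.Po[c];

      // division factor
      double relA = (maxA > 0.0) ? A / maxA : 0.0;
      double synth = p.k_v0 * p.k_v1 * (relA + s.L[c] / p.maxL) /
                     (1.0 + std::exp(i * p.t_v));
      double degr = s.DIV[c] * p.k_v2 *
                    (1.0 + std::pow(A / p.k_v3, p.h1)) /
                    (1.0 + std::pow(A / p.k_v4, p.h2));
      d[f].DIV[c] = synth - degr;

      // growth
      double k_l = s.zone[c] == 0 ? p.k_l_mer : p.k_l_el;
      double m_l = s.zone[c] == 0 ? p.m_l_mer : p.m_l_el;
      double g = k_l * (A / (A + 1.0)) * s.L[c] * (1.0 - s.L[c] / m_l);
      d[f].L[c] = g > 0.0 ? g : 0.0;

      // auxin: source and turnover
      double sc = (f == 0) ? src[c] : 0.0;
      d[f].A[c] = sc - p.d_a * A;
      lr.in += sc;
      lr.deg += p.d_a * A;

      double loss_coeff = p.d_a + p.k_a * (s.Pa[c] + s.Po[c]);
      double pc_coeff = dp_eff + rate_sel * gate;
      double m = std::max(loss_coeff, pc_coeff);
      if (m > mrate) mrate = m;
    }
    // shootward transport within the file (basal faces carry no PIN2, so
    // walls are crossed apically only); the last cell exports out of the
    // simulated window ("outer limit" of the tissue strip).
    for (size_t c = 0; c < n; ++c) {
      double flux = p.k_a * s.A[c] * s.Pa[c];
      d[f].A[c] -= flux;
      if (c + 1 < n) d[f].A[c + 1] += flux; else lr.out += flux;
    }
  }
  // lateral exchange across the shared epidermis<->cortex wall, one wall
  // per index pair; unpaired cells export through their lateral face.
  size_t npair = std::min(st[0].n(), st[1].n());
  for (int f = 0; f < 2; ++f) {
    const FileState& s = st[f];
    for (size_t c = 0; c < s.n(); ++c) {
      double flux = p.k_a * s.A[c] * s.Po[c];
      d[f].A[c] -= flux;
      if (c < npair) d[1 - f].A[c] += flux; else lr.out += flux;
    }
  }
  if (max_rate) *max_rate = mrate;
  return lr;
}

static double max_A(const FileState st[2]) {
  double m = 0.0;
  for (int f = 0; f < 2; ++f)
    for (size_t c = 0; c < st[f].n(); ++c)
      if (st[f].A[c] > m) m = st[f].A[c];
  return m;
}

static void axpy(FileState& out, const FileState& base, const Deriv& d,
                 double h) {
  size_t n = base.n();
  out = base;
  for (size_t c = 0; c < n; ++c) {
    out.A[c] = base.A[c] + h * d.A[c];
    out.Pc[c] = base.Pc[c] + h * d.Pc[c];
    out.Pa[c] = base.Pa[c] + h * d.Pa[c];
    out.Pb[c] = base.Pb[c] + h * d.Pb[c];
    out.Po[c] = base.Po[c] + h * d.Po[c];
    out.DIV[c] = base.DIV[c] + h * d.DIV[c];
    out.L[c] = base.L[c] + h * d.L[c];
  }
}

static FileState as_file(const List& fl) {
  FileState s;
  NumericVector A = fl["A"], Pc = fl["PINc"], Pa = fl["PINm_apical"],
                Pb = fl["PINm_basal"], Po = fl["PINm_outer"],
                DIV = fl["DIV"], L = fl["length"];
  IntegerVector z = fl["zone"];
  s.A = std::vector<double>(A.begin(), A.end());
  s.Pc = std::vector<double>(Pc.begin(), Pc.end());
  s.Pa = std::vector<double>(Pa.begin(), Pa.end());
  s.Pb = std::vector<double>(Pb.begin(), Pb.end());
  s.Po = std::vector<double>(Po.begin(), Po.end());
  s.DIV = std::vector<double>(DIV.begin(), DIV.end());
  s.L = std::vector<double>(L.begin(), L.end());
  s.zone = std::vector<int>(z.begin(), z.end());
  return s;
}

static List file_as_list(const FileState& s) {
  return List::create(
    _["A"] = NumericVector(s.A.begin(), s.A.end()),
    _["PINc"] = NumericVector(s.Pc.begin(), s.Pc.end()),
    _["PINm_apical"] = NumericVector(s.Pa.begin(), s.Pa.end()),
    _["PINm_basal"] = NumericVector(s.Pb.begin(), s.Pb.end()),
    _["PINm_outer"] = NumericVector(s.Po.begin(), s.Po.end()),
    _["DIV"] = NumericVector(s.DIV.begin(), s.DIV.end()),
    _["length"] = NumericVector(s.L.begin(), s.L.end()),
    _["zone"] = IntegerVector(s.zone.begin(), s.zone.end()));
}

static double total_A(const FileState st[2]) {
  double t = 0;
  for (int f = 0; f < 2; ++f)
    for (size_t c = 0; c < st[f].n(); ++c) t += st[f].A[c];
  return t;
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List state0, List par, NumericMatrix schedule,
                 NumericVector src_epi, double dt, double horizon,
                 std::string method, int snap_every, double ss_tol,
                 double ss_interval, bool events) {
  Params p;
  p.s1 = par["s1"]; p.s2 = par["s2"]; p.z = par["z"];
  p.k_a = par["k_a"]; p.d_a = par["d_a"];
  p.m_p = par["m_p"]; p.d_p = par["d_p"]; p.q_p = par["q_p"];
  p.l_n = par["l_n"]; p.tr_n = par["tr_n"]; p.tr_wn = par["tr_wn"];
  p.tr_a = par["tr_a"]; p.tr_i = par["tr_i"];
  p.k_v0 = par["k_v0"]; p.k_v1 = par["k_v1"]; p.k_v2 = par["k_v2"];
  p.k_v3 = par["k_v3"]; p.k_v4 = par["k_v4"]; p.t_v = par["t_v"];
  p.h1 = par["h1"]; p.h2 = par["h2"];
  p.k_l_mer = par["k_l_meristem"]; p.k_l_el = par["k_l_elongation"];
  p.m_l_mer = par["m_l_meristem"]; p.m_l_el = par["m_l_elongation"];
  p.maxL = par["maxL"];
  p.thr_amm = par["A_thr_ammonium"]; p.thr_nit = par["A_thr_nitrate"];
  p.DIV_thr = par["DIV_thr"]; p.min_div_len = par["min_div_length"];
  p.window = as<int>(par["window"]);
  p.literal = as<bool>(par["literal_equations"]);
  RObject mm = par["maxA_mode"];
  if (TYPEOF(mm) == STRSXP) {
    p.maxA_dynamic = true; p.maxA_fixed = -1.0;
  } else {
    p.maxA_dynamic = false; p.maxA_fixed = as<double>(mm);
  }

  FileState st[2];
  st[0] = as_file(state0["epidermis"]);
  st[1] = as_file(state0["cortex"]);
  std::vector<double> src(src_epi.begin(), src_epi.end());
  if ((int)src.size() < p.window)
    stop("positional source vector shorter than the cell window");

  bool rk4 = (method == "rk4");
  long nsteps = (long)std::ceil(horizon / dt - 1e-9);

  // ledger accumulators
  double led_in = 0, led_deg = 0, led_out = 0, led_adv = 0;
  double A0_total = total_A(st);

  std::vector<double> divlog[2];
  divlog[0].assign(p.window, 0.0);
  divlog[1].assign(p.window, 0.0);

  List snaps;
  double t = 0.0;
  bool converged = false;
  double worst_closure = 0.0;

  // steady-state checkpoints
  long check_steps = ss_interval > 0 ? std::max(1L, (long)(ss_interval / dt)) : 0;
  std::vector<double> prev_sum;

  Deriv k1[2], k2[2], k3[2], k4[2];
  FileState tmp[2];

  auto n_sched = schedule.nrow();
  auto N_at = [&](double tt) {
    int N = (int)schedule(0, 1);
    for (int r = 0; r < n_sched; ++r)
      if (schedule(r, 0) <= tt + 1e-12) N = (int)schedule(r, 1);
    return N;
  };

  auto take_snapshot = [&](double tt) {
    List s = List::create(_["time"] = tt,
                          _["epidermis"] = file_as_list(st[0]),
                          _["cortex"] = file_as_list(st[1]));
    snaps.push_back(s);
  };
  if (snap_every > 0) take_snapshot(0.0);

  for (long stp = 0; stp < nsteps; ++stp) {
    int N = N_at(t);
    double maxA = p.maxA_dynamic ? max_A(st) : p.maxA_fixed;

    double mrate = 0.0;
    LedgerRate r1 = rhs(st, src, N, p, maxA, k1, &mrate);
    if (dt * mrate >= 0.5) {
      stop("integration unstable: dt * max rate coefficient = %f >= 0.5 "
           "(max per-pool loss rate %f per time); reduce dt",
           dt * mrate, mrate);
    }

    LedgerRate lr;
    if (!rk4) {
      lr = r1;
      for (int f = 0; f < 2; ++f) axpy(st[f], st[f], k1[f], dt);
    } else {
      for (int f = 0; f < 2; ++f) axpy(tmp[f], st[f], k1[f], dt / 2);
      LedgerRate r2 = rhs(tmp, src, N, p, maxA, k2, nullptr);
      for (int f = 0; f < 2; ++f) axpy(tmp[f], st[f], k2[f], dt / 2);
      LedgerRate r3 = rhs(tmp, src, N, p, maxA, k3, nullptr);
      for (int f = 0; f < 2; ++f) axpy(tmp[f], st[f], k3[f], dt);
      LedgerRate r4 = rhs(tmp, src, N, p, maxA, k4, nullptr);
      for (int f = 0; f < 2; ++f) {
        size_t n = st[f].n();
        for (size_t c = 0; c < n; ++c) {
          st[f].A[c] += dt / 6.0 * (k1[f].A[c] + 2 * k2[f].A[c] + 2 * k3[f].A[c] + k4[f].A[c]);
          st[f].Pc[c] += dt / 6.0 * (k1[f].Pc[c] + 2 * k2[f].Pc[c] + 2 * k3[f].Pc[c] + k4[f].Pc[c]);
          st[f].Pa[c] += dt / 6.0 * (k1[f].Pa[c] + 2 * k2[f].Pa[c] + 2 * k3[f].Pa[c] + k4[f].Pa[c]);
          st[f].Pb[c] += dt / 6.0 * (k1[f].Pb[c] + 2 * k2[f].Pb[c] + 2 * k3[f].Pb[c] + k4[f].Pb[c]);
          st[f].Po[c] += dt / 6.0 * (k1[f].Po[c] + 2 * k2[f].Po[c] + 2 * k3[f].Po[c] + k4[f].Po[c]);
          st[f].DIV[c] += dt / 6.0 * (k1[f].DIV[c] + 2 * k2[f].DIV[c] + 2 * k3[f].DIV[c] + k4[f].DIV[c]);
          st[f].L[c] += dt / 6.0 * (k1[f].L[c] + 2 * k2[f].L[c] + 2 * k3[f].L[c] + k4[f].L[c]);
        }
      }
      lr.in = (r1.in + 2 * r2.in + 2 * r3.in + r4.in) / 6.0;
      lr.deg = (r1.deg + 2 * r2.deg + 2 * r3.deg + r4.deg) / 6.0;
      lr.out = (r1.out + 2 * r2.out + 2 * r3.out + r4.out) / 6.0;
    }
    led_in += dt * lr.in;
    led_deg += dt * lr.deg;
    led_out += dt * lr.out;
    t += dt;

    if (events) {
      // elongation transition (one-way, closed threshold)
      double mA = p.maxA_dynamic ? max_A(st) : p.maxA_fixed;
      double thr = (N_at(t) == 1) ? p.thr_nit : p.thr_amm;
      if (mA > 0) {
        for (int f = 0; f < 2; ++f)
          for (size_t c = 0; c < st[f].n(); ++c)
            if (st[f].zone[c] == 0 && st[f].A[c] / mA >= thr)
              st[f].zone[c] = 1;
      }
      // divisions, processed from the QC outward
      for (int f = 0; f < 2; ++f) {
        FileState& s = st[f];
        for (size_t c = 0; c < s.n(); ++c) {
          if (s.zone[c] == 0 && s.DIV[c] >= p.DIV_thr &&
              s.L[c] >= p.min_div_len) {
            if ((int)(c) < p.window) divlog[f][c] += 1.0;
            double Ld = s.L[c] / 2, Ad = s.A[c] / 2, Pcd = s.Pc[c] / 2,
                   Pad = s.Pa[c] / 2, Pbd = s.Pb[c] / 2, Pod = s.Po[c] / 2;
            s.L[c] = Ld; s.A[c] = Ad; s.Pc[c] = Pcd; s.Pa[c] = Pad;
            s.Pb[c] = Pbd; s.Po[c] = Pod; s.DIV[c] = 0.0;
            s.L.insert(s.L.begin() + c + 1, Ld);
            s.A.insert(s.A.begin() + c + 1, Ad);
            s.Pc.insert(s.Pc.begin() + c + 1, Pcd);
            s.Pa.insert(s.Pa.begin() + c + 1, Pad);
            s.Pb.insert(s.Pb.begin() + c + 1, Pbd);
            s.Po.insert(s.Po.begin() + c + 1, Pod);
            s.DIV.insert(s.DIV.begin() + c + 1, 0.0);
            s.zone.insert(s.zone.begin() + c + 1, 0);
            ++c; // skip the second daughter
          }
        }
        // window advection: drop shootward cells pushed past the window
        while ((int)s.n() > p.window) {
          led_adv += s.A.back();
          s.A.pop_back(); s.Pc.pop_back(); s.Pa.pop_back(); s.Pb.pop_back();
          s.Po.pop_back(); s.DIV.pop_back(); s.L.pop_back(); s.zone.pop_back();
        }
      }
    }

    // ledger closure (relative)
    double tot = total_A(st);
    double closure = std::fabs(tot - (A0_total + led_in - led_deg - led_out - led_adv));
    double scale = std::max(1.0, std::max(tot, led_in));
    double rel = closure / scale;
    if (rel > worst_closure) worst_closure = rel;

    if (snap_every > 0 && ((stp + 1) % snap_every == 0))
      take_snapshot(t);

    if (check_steps > 0 && ((stp + 1) % check_steps == 0)) {
      std::vector<double> cur;
      for (int f = 0; f < 2; ++f) {
        double sA = 0, sP = 0, sL = 0;
        int nel = 0;
        for (size_t c = 0; c < st[f].n(); ++c) {
          sA += st[f].A[c]; sP += st[f].Pa[c] + st[f].Po[c] + st[f].Pc[c];
          sL += st[f].L[c]; nel += st[f].zone[c];
        }
        cur.push_back(sA); cur.push_back(sP); cur.push_back(sL);
        cur.push_back((double)nel); cur.push_back((double)st[f].n());
      }
      if (!prev_sum.empty()) {
        double worst = 0;
        for (size_t j = 0; j < cur.size(); ++j) {
          double rel2 = std::fabs(cur[j] - prev_sum[j]) /
                        (std::fabs(prev_sum[j]) + 1e-8);
          if (rel2 > worst) worst = rel2;
        }
        if (worst < ss_tol) { converged = true; prev_sum = cur; break; }
      }
      prev_sum = cur;
    }
  }

  if (snap_every > 0) take_snapshot(t); // final state snapshot

  List ledger = List::create(
    _["input"] = led_in, _["degradation"] = led_deg,
    _["boundary_efflux"] = led_out, _["advection_loss"] = led_adv,
    _["initial_auxin"] = A0_total, _["final_auxin"] = total_A(st),
    _["max_rel_closure_error"] = worst_closure);

  return List::create(
    _["time"] = t,
    _["epidermis"] = file_as_list(st[0]),
    _["cortex"] = file_as_list(st[1]),
    _["ledger"] = ledger,
    _["division_log"] = List::create(
      _["epidermis"] = NumericVector(divlog[0].begin(), divlog[0].end()),
      _["cortex"] = NumericVector(divlog[1].begin(), divlog[1].end())),
    _["snapshots"] = snaps,
    _["converged"] = converged,
    _["maxA"] = p.maxA_dynamic ? max_A(st) : p.maxA_fixed);
}
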