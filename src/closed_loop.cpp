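// Closed-loop engine: fixed-step RK4 integration of the virtual patient
// and sensor current, 10-s raw sensor sampling with pre-drawn noise,
// 5-min averaged readings, the tanh PD controller with emergency rescue,
// and quantized pump actuation.  Mirrors the R-level model functions; the
// pure-R explicit-Euler reference engine serves as its cross-check.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  // patient
  double w, Sh, Sp, c, renal_thr, renal_cl, vg, vi;
  double ke, ka_build, ka_decay, ka_sat, u_ii, util_km, util_gref;
  double nhgb_gslope, nhgb_min, nhgb_max, nhgb_hypo_thr, nhgb_hypo_slope;
  double nhgb_hypo_ins_sup;
  double abs_vmax, abs_km;
  double bol_k12, bol_k21, bol_kel, bol_v1;
  // sensor
  double alpha, tau, sat_lo, sat_hi;
  // controller
  double M, S_slope, B, K1, K2, a0, a5, a10, IR_min, G_crit, K_G;
  // pumps
  double ins_min, ins_max, ins_step, ins_kvo, ins_conc;
  double glc_min, glc_max, glc_step, glc_kvo, glc_conc;
};

struct Event {
  int kind;  // 1 oral (trapezoid), 3 iv glucose rate, 4 iv insulin rate,
             // 5 impulse glucose (mg), 6 impulse insulin (mIU)
  double t_start, t_end, rate, slope, vmax, t_up, t_down;
  double amount;  // for impulses
};

double interp_clamped(const std::vector<double>& x,
                      const std::vector<double>& y, double xi) {
  const size_t n = x.size();
  if (xi <= x[0]) return y[0];
  if (xi >= x[n - 1]) return y[n - 1];
  size_t hi = 1;
  while (x[hi] < xi) ++hi;
  const double f = (xi - x[hi - 1]) / (x[hi] - x[hi - 1]);
  return y[hi - 1] + f * (y[hi] - y[hi - 1]);
}

double quantize(double req, double lo, double hi, double step) {
  double q = std::floor(req / step + 0.5 + 1e-9) * step;
  if (q < lo) q = lo;
  if (q > hi) q = hi;
  return q;
}

struct Inputs { double ge, ivg, bol, ins; };

std::vector<double> nhgb_x_g, nhgb_y_g;  // hepatic table, set per call

// y = (G, I, Ia, Ggut, S, B1, B2); g_delayed < 0 means "use stage G"
void deriv(const double* y, const Inputs& in, const Params& p,
           double g_delayed, double* dy) {
  const double G = y[0] > 0 ? y[0] : 0.0;
  const double I = y[1], Ia = y[2], Ggut = y[3] > 0 ? y[3] : 0.0;
  const double S = y[4], B1 = y[5], B2 = y[6];

  const double abs_flux = p.abs_vmax * Ggut / (p.abs_km + Ggut);
  const double Itot = I + B1 / p.bol_v1;
  const double ieff = p.Sh * Itot;

  double nhgb = interp_clamped(nhgb_x_g, nhgb_y_g, ieff) -
                p.nhgb_gslope * (G - p.util_gref);
  if (nhgb < p.nhgb_min) nhgb = p.nhgb_min;
  if (nhgb > p.nhgb_max) nhgb = p.nhgb_max;
  if (G < p.nhgb_hypo_thr) {
    const double hypo = p.nhgb_hypo_slope * (p.nhgb_hypo_thr - G) -
                        p.nhgb_hypo_ins_sup * ieff;
    if (hypo > nhgb) nhgb = hypo < p.nhgb_max ? hypo : p.nhgb_max;
  }

  const double mich = G * (p.util_km + p.util_gref) /
                      (p.util_gref * (p.util_km + G));
  const double gout = (p.u_ii + 60.0 * p.c * p.Sp * Ia) * mich;  // mg/kg/h
  const double gren = p.renal_cl * std::max(0.0, G - p.renal_thr);  // mg/min

  dy[0] = (abs_flux + in.ivg + nhgb * p.w / 60.0 - gout * p.w / 60.0 - gren) /
          p.vg;
  dy[1] = in.ins / p.vi - p.ke * I;
  dy[2] = p.ka_build * std::min(Itot, p.ka_sat) - p.ka_decay * Ia;
  dy[3] = in.ge - abs_flux;
  const double gd = g_delayed >= 0 ? g_delayed : G;
  dy[4] = (p.alpha * gd - S) / p.tau;
  dy[5] = in.bol - (p.bol_k12 + p.bol_kel) * B1 + p.bol_k21 * B2;
  dy[6] = p.bol_k12 * B1 - p.bol_k21 * B2;
}

double event_ge(const std::vector<Event>& ev, double t) {
  double f = 0.0;
  for (const Event& e : ev) {
    if (e.kind != 1) continue;
    const double u = t - e.t_start;
    if (u <= 0 || u >= e.t_end) continue;
    if (u < e.t_up) f += e.slope * u;
    else if (u < e.t_down) f += e.vmax;
    else f += e.vmax - e.slope * (u - e.t_down);
  }
  return f;
}

double event_rate(const std::vector<Event>& ev, int kind, double t) {
  double f = 0.0;
  for (const Event& e : ev)
    if (e.kind == kind && t >= e.t_start && t < e.t_end) f += e.rate;
  return f;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_closed_loop(NumericVector y0, List par, List events,
                         NumericVector nhgb_x, NumericVector nhgb_y,
                         NumericVector noise, double duration, double dt,
                         int steps_per_sample, int steps_per_reading,
                         double td_min, double ir_mlh0, double gr_mlh0) {
  Params p;
  p.w = par["w"]; p.Sh = par["Sh"]; p.Sp = par["Sp"]; p.c = par["c"];
  p.renal_thr = par["renal_thr"]; p.renal_cl = par["renal_cl"];
  p.vg = par["vg"]; p.vi = par["vi"]; p.ke = par["ke"];
  p.ka_build = par["ka_build"]; p.ka_decay = par["ka_decay"];
  p.ka_sat = par["ka_sat"];
  p.u_ii = par["u_ii"]; p.util_km = par["util_km"];
  p.util_gref = par["util_gref"]; p.nhgb_gslope = par["nhgb_gslope"];
  p.nhgb_min = par["nhgb_min"]; p.nhgb_max = par["nhgb_max"];
  p.nhgb_hypo_thr = par["nhgb_hypo_thr"]; p.nhgb_hypo_slope = par["nhgb_hypo_slope"];
  p.nhgb_hypo_ins_sup = par["nhgb_hypo_ins_sup"];
  p.abs_vmax = par["abs_vmax"]; p.abs_km = par["abs_km"];
  p.bol_k12 = par["bol_k12"]; p.bol_k21 = par["bol_k21"];
  p.bol_kel = par["bol_kel"]; p.bol_v1 = par["bol_v1"];
  p.alpha = par["alpha"]; p.tau = par["tau"];
  p.sat_lo = par["sat_lo"]; p.sat_hi = par["sat_hi"];
  p.M = par["M"]; p.S_slope = par["S_slope"]; p.B = par["B"];
  p.K1 = par["K1"]; p.K2 = par["K2"];
  p.a0 = par["a0"]; p.a5 = par["a5"]; p.a10 = par["a10"];
  p.IR_min = par["IR_min"]; p.G_crit = par["G_crit"]; p.K_G = par["K_G"];
  p.ins_min = par["ins_min"]; p.ins_max = par["ins_max"];
  p.ins_step = par["ins_step"]; p.ins_kvo = par["ins_kvo"];
  p.ins_conc = par["ins_conc"];
  p.glc_min = par["glc_min"]; p.glc_max = par["glc_max"];
  p.glc_step = par["glc_step"]; p.glc_kvo = par["glc_kvo"];
  p.glc_conc = par["glc_conc"];

  nhgb_x_g.assign(nhgb_x.begin(), nhgb_x.end());
  nhgb_y_g.assign(nhgb_y.begin(), nhgb_y.end());

  std::vector<Event> ev;
  for (int i = 0; i < events.size(); ++i) {
    List e = events[i];
    Event E;
    E.kind = as<int>(e["kind"]);
    E.t_start = as<double>(e["t_start"]);
    E.t_end = as<double>(e["t_end"]);
    E.rate = e.containsElementNamed("rate") ? as<double>(e["rate"]) : 0.0;
    E.slope = e.containsElementNamed("slope") ? as<double>(e["slope"]) : 0.0;
    E.vmax = e.containsElementNamed("vmax") ? as<double>(e["vmax"]) : 0.0;
    E.t_up = e.containsElementNamed("t_up") ? as<double>(e["t_up"]) : 0.0;
    E.t_down = e.containsElementNamed("t_down") ? as<double>(e["t_down"]) : 0.0;
    E.amount = e.containsElementNamed("amount") ? as<double>(e["amount"]) : 0.0;
    ev.push_back(E);
  }

  const int n_steps = (int)std::lround(duration / dt);
  const int n_read = n_steps / steps_per_reading;
  const int td_steps = (int)std::lround(td_min / dt);

  NumericMatrix series(n_steps + 1, 9);
  colnames(series) = CharacterVector::create(
      "t", "G", "I", "Ia", "Ggut", "S", "I_plasma", "IR_mLh", "GR_mLh");
  NumericMatrix trace(n_read, 10);
  colnames(trace) = CharacterVector::create(
      "t", "G_est", "A", "DF", "IR_prime_mIU", "IR_mIU", "GR_prime_mLh",
      "GR_mLh", "emergency", "IR_mLh");

  double y[7];
  for (int i = 0; i < 7; ++i) y[i] = y0[i];

  std::vector<double> gbuf;
  if (td_steps > 0) gbuf.assign(td_steps, y[0]);

  double ir_mlh = ir_mlh0, gr_mlh = gr_mlh0;
  double buf_sum = 0.0; int buf_n = 0, sample_idx = 0, read_idx = 0;
  double g0 = NA_REAL, g5 = NA_REAL, g10 = NA_REAL;
  int hist_n = 0, n_clip = 0;

  auto record = [&](int row, double t) {
    series(row, 0) = t; series(row, 1) = y[0];
    series(row, 2) = y[1]; series(row, 3) = y[2]; series(row, 4) = y[3];
    series(row, 5) = y[4]; series(row, 6) = y[1] + y[5] / p.bol_v1;
    series(row, 7) = ir_mlh; series(row, 8) = gr_mlh;
  };
  record(0, 0.0);

  double k1[7], k2[7], k3[7], k4[7], yt[7];

  for (int step = 1; step <= n_steps; ++step) {
    const double t0 = (step - 1) * dt;

    // impulse events applied at the first boundary at/after t_start
    for (const Event& e : ev) {
      if ((e.kind == 5 || e.kind == 6) &&
          e.t_start >= t0 - 1e-9 && e.t_start < t0 + dt - 1e-9) {
        if (e.kind == 5) y[0] += e.amount / p.vg;  // mg -> mg/dL
        else y[5] += e.amount;                     // mIU into B1
      }
    }

    Inputs in;
    in.ins = ir_mlh * p.ins_conc * 1000.0 / 60.0;              // mIU/min
    const double rescue = gr_mlh * p.glc_conc / 60.0;          // mg/min
    const double gd = td_steps > 0 ? gbuf[(step - 1) % td_steps] : -1.0;

    // RK4 with inputs evaluated at stage times
    in.ge = event_ge(ev, t0);
    in.ivg = event_rate(ev, 3, t0) + rescue;
    in.bol = event_rate(ev, 4, t0);
    deriv(y, in, p, gd, k1);

    const double th = t0 + dt / 2.0;
    in.ge = event_ge(ev, th);
    in.ivg = event_rate(ev, 3, th) + rescue;
    in.bol = event_rate(ev, 4, th);
    for (int i = 0; i < 7; ++i) yt[i] = y[i] + dt / 2.0 * k1[i];
    deriv(yt, in, p, gd, k2);
    for (int i = 0; i < 7; ++i) yt[i] = y[i] + dt / 2.0 * k2[i];
    deriv(yt, in, p, gd, k3);

    const double t1 = t0 + dt;
    in.ge = event_ge(ev, t1);
    in.ivg = event_rate(ev, 3, t1) + rescue;
    in.bol = event_rate(ev, 4, t1);
    for (int i = 0; i < 7; ++i) yt[i] = y[i] + dt * k3[i];
    deriv(yt, in, p, gd, k4);

    for (int i = 0; i < 7; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]))
        stop("integration failure: non-finite state at t = %f (index %d)",
             t1, i);
      if (y[i] < 0) { y[i] = 0.0; ++n_clip; }
    }
    if (td_steps > 0) gbuf[(step - 1) % td_steps] = y[0];

    if (step % steps_per_sample == 0) {
      const double s = y[4] + (sample_idx < noise.size()
                               ? noise[sample_idx] : 0.0);
      ++sample_idx;
      buf_sum += s; ++buf_n;
    }

    if (step % steps_per_reading == 0 && buf_n > 0) {
      double g_est = buf_sum / buf_n / p.alpha;
      if (g_est < p.sat_lo) g_est = p.sat_lo;
      if (g_est > p.sat_hi) g_est = p.sat_hi;
      buf_sum = 0.0; buf_n = 0;

      g10 = g5; g5 = g0; g0 = g_est;
      if (hist_n < 3) ++hist_n;
      const double A = (hist_n >= 3)
          ? p.a0 * g0 + p.a5 * g5 + p.a10 * g10 : 0.0;
      const double DF = p.K2 * A / (1.0 + p.K1 * A * A);
      const double IRp = (p.M / 2.0) *
          (1.0 + std::tanh(p.S_slope * (g0 + DF - p.B)));
      const double GRp = p.K_G * std::max(0.0, p.G_crit - g0);
      const bool emergency = g0 < p.G_crit;

      double ir_mIU, gr_cmd_mlh;
      if (emergency) {
        ir_mIU = p.IR_min;
        gr_cmd_mlh = GRp;
      } else {
        ir_mIU = std::max(IRp, p.IR_min);
        gr_cmd_mlh = 0.0;
      }
      const double ir_req_mlh = ir_mIU * 60.0 / 1000.0 / p.ins_conc;
      ir_mlh = quantize(ir_req_mlh, p.ins_min, p.ins_max, p.ins_step);
      if (ir_mlh < p.ins_kvo) ir_mlh = p.ins_kvo;
      gr_mlh = emergency
          ? quantize(gr_cmd_mlh, p.glc_min, p.glc_max, p.glc_step)
          : 0.0;

      trace(read_idx, 0) = t1; trace(read_idx, 1) = g_est;
      trace(read_idx, 2) = A; trace(read_idx, 3) = DF;
      trace(read_idx, 4) = IRp;
      trace(read_idx, 5) = ir_mlh * p.ins_conc * 1000.0 / 60.0;
      trace(read_idx, 6) = GRp; trace(read_idx, 7) = gr_mlh;
      trace(read_idx, 8) = emergency ? 1.0 : 0.0;
      trace(read_idx, 9) = ir_mlh;
      ++read_idx;
    }

    record(step, t1);
  }

  return List::create(_["series"] = series, _["trace"] = trace,
                      _["n_clipped"] = n_clip);
}
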