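#include <Rcpp.h>
using namespace Rcpp;

// Minimal two-current (Mitchell-Schaeffer form) ionic model with a smoothed
// recovery gate, advanced by forward Euler. Time in ms, voltage dimensionless.
//
//   dv/dt = h v^2 (1 - v) / tau_in - v / tau_out + J_stim(t)
//   dh/dt = sg * (1 - h) / tau_open - (1 - sg) * h / tau_close
//   sg    = 1 / (1 + exp((v - v_gate) / k_gate))
//
// The logistic blend sg replaces the hard v < v_gate switch so that the
// one-beat map is differentiable, which the finite-difference Jacobian
// relies on. Activation/repolarization times are located by linear
// interpolation between bracketing samples of v across v_up / v_down.

struct MsPars {
  double tau_in, tau_out, tau_open, tau_close, v_gate, k_gate;
  double dt, stim_dur, stim_amp, v_up, v_down;
};

static MsPars get_pars(const List& p) {
  MsPars q;
  q.tau_in = p["tau_in"]; q.tau_out = p["tau_out"];
  q.tau_open = p["tau_open"]; q.tau_close = p["tau_close"];
  q.v_gate = p["v_gate"]; q.k_gate = p["k_gate"];
  q.dt = p["dt"]; q.stim_dur = p["stim_dur"]; q.stim_amp = p["stim_amp"];
  q.v_up = p["v_up"]; q.v_down = p["v_down"];
  return q;
}

// one beat; returns apd (NA on capture failure), updates v, h in place
static double ms_one_beat(double& v, double& h, double cl, const MsPars& q) {
  int nst = (int) std::lround(cl / q.dt);
  double t_up = NA_REAL, t_dn = NA_REAL;
  for (int k = 0; k < nst; ++k) {
    double tk = k * q.dt;
    double stim = (tk < q.stim_dur) ? q.stim_amp : 0.0;
    double sg = 1.0 / (1.0 + std::exp((v - q.v_gate) / q.k_gate));
    double dv = h * v * v * (1.0 - v) / q.tau_in - v / q.tau_out + stim;
    double dh = sg * (1.0 - h) / q.tau_open - (1.0 - sg) * h / q.tau_close;
    double vn = v + q.dt * dv;
    double hn = h + q.dt * dh;
    if (ISNA(t_up) && v < q.v_up && vn >= q.v_up)
      t_up = tk + q.dt * (q.v_up - v) / (vn - v);
    if (!ISNA(t_up) && ISNA(t_dn) && v >= q.v_down && vn < q.v_down)
      t_dn = tk + q.dt * (v - q.v_down) / (v - vn);
    v = vn; h = hn;
  }
  if (ISNA(t_up) || ISNA(t_dn)) return NA_REAL;
  return t_dn - t_up;
}

// [[Rcpp::export(name = ".ms_run")]]
List ms_run(NumericVector state, NumericVector cl_series, List params) {
  MsPars q = get_pars(params);
  double v = state[0], h = state[1];
  int n = cl_series.size();
  NumericVector apd(n, NA_REAL);
  NumericMatrix states(n, 2);
  std::fill(states.begin(), states.end(), NA_REAL);
  int failed = NA_INTEGER, n_done = 0;
  for (int i = 0; i < n; ++i) {
    double a = ms_one_beat(v, h, cl_series[i], q);
    if (ISNA(a) || cl_series[i] - a <= 0.0) { failed = i + 1; break; }
    apd[i] = a;
    states(i, 0) = v; states(i, 1) = h;
    n_done = i + 1;
  }
  return List::create(_["states"] = states, _["apd"] = apd,
                      _["n_done"] = n_done, _["failed_beat"] = failed,
                      _["state"] = NumericVector::create(v, h));
}

// [[Rcpp::export(name = ".ms_trace")]]
NumericMatrix ms_trace(NumericVector state, double cl, List params) {
  MsPars q = get_pars(params);
  double v = state[0], h = state[1];
  int nst = (int) std::lround(cl / q.dt);
  NumericMatrix out(nst + 1, 3);
  out(0, 0) = 0.0; out(0, 1) = v; out(0, 2) = h;
  for (int k = 0; k < nst; ++k) {
    double tk = k * q.dt;
    double stim = (tk < q.stim_dur) ? q.stim_amp : 0.0;
    double sg = 1.0 / (1.0 + std::exp((v - q.v_gate) / q.k_gate));
    double dv = h * v * v * (1.0 - v) / q.tau_in - v / q.tau_out + stim;
    double dh = sg * (1.0 - h) / q.tau_open - (1.0 - sg) * h / q.tau_close;
    v += q.dt * dv; h += q.dt * dh;
    out(k + 1, 0) = tk + q.dt; out(k + 1, 1) = v; out(k + 1, 2) = h;
  }
  colnames(out) = CharacterVector::create("time_ms", "v", "h");
  return out;
}
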