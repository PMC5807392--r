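// Fixed-step classical RK4 integration of the two-cell M-cell circuit.
//
// The drive is piecewise constant (rectangular pulses), so pulse edges and
// all requested sample times are forced grid points: between consecutive
// anchor times the step count is ceil(dt/step) with an evenly divided step
// h <= step.  Within an anchor interval the drive is constant, so no RK4
// substage ever straddles a pulse edge.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Params {
  double g_Ca, g_K, g_KCa, g_L;
  double v_Ca, v_K, v_L;
  double v1, v2, v3, v4;
  double k1, k2, k_Ca, eps, mu, C, phi;
  double alpha, beta, theta_s, sigma_s;
  double g_syn, v_syn, I0, w_M, ag_max, rho;
};

static Params unpack_params(const List& p) {
  Params q;
  q.g_Ca = p["g_Ca"]; q.g_K = p["g_K"]; q.g_KCa = p["g_KCa"]; q.g_L = p["g_L"];
  q.v_Ca = p["v_Ca"]; q.v_K = p["v_K"]; q.v_L = p["v_L"];
  q.v1 = p["v1"]; q.v2 = p["v2"]; q.v3 = p["v3"]; q.v4 = p["v4"];
  q.k1 = p["k1"]; q.k2 = p["k2"]; q.k_Ca = p["k_Ca"]; q.eps = p["eps"];
  q.mu = p["mu"]; q.C = p["C"]; q.phi = p["phi"];
  q.alpha = p["alpha"]; q.beta = p["beta"];
  q.theta_s = p["theta_s"]; q.sigma_s = p["sigma_s"];
  q.g_syn = p["g_syn"]; q.v_syn = p["v_syn"];
  q.I0 = p["I0"]; q.w_M = p["w_M"]; q.ag_max = p["ag_max"]; q.rho = p["rho"];
  return q;
}

// Derivatives of one cell; other_s is the synaptic variable of the other
// cell.  Calcium slightly below 0 (round-off) is clamped before the
// saturating terms are evaluated; the caller counts clamping events.
static inline void cell_deriv(const double* y, double other_s, double drive,
                              const Params& p, double* dy) {
  const double v = y[0], n = y[1], s = y[3], E = y[4];
  const double Ca = y[2] > 0.0 ? y[2] : 0.0;

  // one exp per gating curve: tanh(x) = (e2x - 1) / (e2x + 1)
  const double em = std::exp(2.0 * (v - p.v1) / p.v2);
  const double m_inf = em / (em + 1.0);
  const double w = (v - p.v3) / (2.0 * p.v4);
  const double ew = std::exp(w);                    // exp((v - v3)/(2 v4))
  const double e4 = (ew * ew) * (ew * ew);          // exp(2 (v - v3)/v4)
  const double n_inf = e4 / (e4 + 1.0);             // 0.5 (1 + tanh((v-v3)/v4))
  const double cosh_w = 0.5 * (ew + 1.0 / ew);      // 1 / tau_n
  const double s_inf = 1.0 / (1.0 + std::exp(-(v - p.theta_s) / p.sigma_s));

  const double I_Ca = p.g_Ca * m_inf * (v - p.v_Ca);
  const double I_K = p.g_K * n * (v - p.v_K);
  const double I_KCa = p.g_KCa * (Ca / (Ca + p.k1)) * (v - p.v_K);
  const double I_L = p.g_L * (v - p.v_L);
  const double I_syn = p.g_syn * (v - p.v_syn) * other_s;
  const double I_app = p.I0 + drive + p.w_M * E;

  dy[0] = (-I_Ca - I_K - I_L - I_KCa - I_syn + I_app) / p.C;
  dy[1] = p.phi * (n_inf - n) * cosh_w;
  dy[2] = p.eps * (-p.mu * I_Ca - p.k_Ca * Ca);
  dy[3] = p.alpha * s_inf * (1.0 - s) - p.beta * s;
  dy[4] = (p.ag_max / (Ca + p.k2) - E) / p.rho;
}

static inline void circuit_deriv(const double* y, double d1, double d2,
                                 const Params& p, double* dy) {
  cell_deriv(y, y[8], d1, p, dy);          // cell 1, gated by s of cell 2
  cell_deriv(y + 5, y[3], d2, p, dy + 5);  // cell 2, gated by s of cell 1
}

static inline void rk4_step(double* y, double h, double d1, double d2,
                            const Params& p) {
  double k1[10], k2[10], k3[10], k4[10], yt[10];
  circuit_deriv(y, d1, d2, p, k1);
  for (int i = 0; i < 10; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  circuit_deriv(yt, d1, d2, p, k2);
  for (int i = 0; i < 10; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  circuit_deriv(yt, d1, d2, p, k3);
  for (int i = 0; i < 10; ++i) yt[i] = y[i] + h * k3[i];
  circuit_deriv(yt, d1, d2, p, k4);
  for (int i = 0; i < 10; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export(name = ".rk4_integrate")]]
List rk4_integrate(NumericVector y0, List params,
                   NumericVector pulse_onsets, double pulse_width,
                   double amplitude1, double amplitude2,
                   double t_end, double step,
                   NumericVector sample_times) {
  if (y0.size() != 10) stop("state vector must have 10 components");
  if (step <= 0) stop("step must be > 0");
  if (t_end < 0) stop("t_end must be >= 0");
  const Params p = unpack_params(params);

  // anchors: 0, t_end, pulse edges inside [0, t_end], sample times
  std::vector<double> anchors;
  anchors.reserve(sample_times.size() + 2 * pulse_onsets.size() + 2);
  anchors.push_back(0.0);
  anchors.push_back(t_end);
  for (double on : pulse_onsets) {
    if (on >= 0.0 && on <= t_end) anchors.push_back(on);
    double off = on + pulse_width;
    if (off >= 0.0 && off <= t_end) anchors.push_back(off);
  }
  for (double ts : sample_times) {
    if (ts < 0.0 || ts > t_end) stop("sample times must lie in [0, t_end]");
    anchors.push_back(ts);
  }
  std::sort(anchors.begin(), anchors.end());
  anchors.erase(std::unique(anchors.begin(), anchors.end(),
                            [](double a, double b) {
                              return std::fabs(a - b) < 1e-9;
                            }),
                anchors.end());

  // sample lookup: which anchors are requested sample times
  std::vector<double> st(sample_times.begin(), sample_times.end());
  std::sort(st.begin(), st.end());
  auto is_sample = [&st](double t) {
    auto it = std::lower_bound(st.begin(), st.end(), t - 1e-9);
    return it != st.end() && std::fabs(*it - t) < 1e-9;
  };

  std::vector<double> on(pulse_onsets.begin(), pulse_onsets.end());
  std::sort(on.begin(), on.end());
  auto drive_of = [&](double t) -> double {
    // pulse active on [onset, onset + width)
    auto it = std::upper_bound(on.begin(), on.end(), t);
    if (it == on.begin()) return 0.0;
    double o = *(it - 1);
    return (t - o < pulse_width) ? amplitude1 : 0.0;
  };

  const int n_out = static_cast<int>(
      std::count_if(anchors.begin(), anchors.end(), is_sample));
  NumericVector out_t(n_out);
  NumericMatrix out_y(n_out, 10);
  NumericVector out_drive(n_out);

  double y[10];
  for (int i = 0; i < 10; ++i) y[i] = y0[i];
  long clamped = 0;
  int row = 0;

  auto record = [&](double t, double drive) {
    out_t[row] = t;
    for (int i = 0; i < 10; ++i) out_y(row, i) = y[i];
    out_drive[row] = drive;
    ++row;
  };

  if (!anchors.empty() && is_sample(anchors.front()))
    record(anchors.front(), drive_of(anchors.front()));

  for (size_t a = 0; a + 1 < anchors.size(); ++a) {
    const double ta = anchors[a], tb = anchors[a + 1];
    const double dt = tb - ta;
    if (dt <= 0) continue;
    const double mid = 0.5 * (ta + tb);
    const double d1 = drive_of(mid);
    const double d2 = (amplitude2 != 0.0 && d1 != 0.0)
                          ? amplitude2 : 0.0;  // routing: cell 2 undriven
    const long nstep = std::max(1L, static_cast<long>(
        std::ceil(dt / step - 1e-9)));
    const double h = dt / static_cast<double>(nstep);
    for (long k = 0; k < nstep; ++k) {
      if (y[2] < 0.0) { y[2] = 0.0; ++clamped; }
      if (y[7] < 0.0) { y[7] = 0.0; ++clamped; }
      rk4_step(y, h, d1, d2, p);
    }
    if (!std::isfinite(y[0]) || !std::isfinite(y[5]))
      stop("non-finite state at t = %f ms", tb);
    if (is_sample(tb)) record(tb, drive_of(tb));
  }

  return List::create(_["time"] = out_t, _["state"] = out_y,
                      _["drive"] = out_drive,
                      _["ca_clamped"] = static_cast<double>(clamped));
}
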