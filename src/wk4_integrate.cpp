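#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Modified four-element Windkessel with pressure-dependent central compliance.
// State y = (q, p_c, p_p):
//   dq/dt   = (p_c - p_p) / L
//   dp_c/dt = (q_in(t) - q) / C1(p_c)
//   dp_p/dt = q / C2 - p_p / (R * C2)
// C1(p) = Am * l / (pi * P1 * (1 + ((p - P0)/P1)^2))   (Langewouters volume
// compliance of a unit-length segment).

struct BeatParams {
  double Am, P0, P1, l;      // compliance profile
  double C2, R, L;           // distal elements
  double q0, T, Ts, alpha;   // inflow
  double t0;                 // absolute beat start time
  // optional inflow modifier windows (absolute time, multiplicative factor)
  std::vector<double> m_t0, m_t1, m_fac;
};

static inline double c1_of(const BeatParams& p, double pc) {
  double z = (pc - p.P0) / p.P1;
  return p.Am * p.l / (M_PI * p.P1 * (1.0 + z * z));
}

static inline double qin_of(const BeatParams& p, double t_abs) {
  double t = t_abs - p.t0;
  double q;
  double aTs = p.alpha * p.Ts;
  if (t < 0.0 || t > p.T) {
    q = 0.0;
  } else if (t <= aTs) {
    q = p.q0 * std::sin(M_PI * t / (2.0 * aTs));
  } else if (t <= p.Ts) {
    q = p.q0 * std::cos(M_PI * (t - aTs) / (4.0 * aTs));
  } else {
    q = 0.0;
  }
  for (size_t i = 0; i < p.m_t0.size(); ++i) {
    if (t_abs >= p.m_t0[i] && t_abs < p.m_t1[i]) q *= p.m_fac[i];
  }
  return q;
}

static inline void rhs(const BeatParams& p, double t, const double y[3],
                       double dy[3]) {
  double c1 = c1_of(p, y[1]);
  dy[0] = (y[1] - y[2]) / p.L;
  dy[1] = (qin_of(p, t) - y[0]) / c1;
  dy[2] = y[0] / p.C2 - y[2] / (p.R * p.C2);
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate one segment [t, t_end] adaptively (no output inside).
static void integrate_to(const BeatParams& p, double& t, double t_end,
                         double y[3], double rtol, double atol, double& h,
                         int beat_index) {
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], y5[3];
  rhs(p, t, y, k1);
  while (t < t_end - 1e-12) {
    if (h > t_end - t) h = t_end - t;
    if (h < 1e-12) h = 1e-12;
    for (int i = 0; i < 3; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(p, t + c2 * h, yt, k2);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(p, t + c3 * h, yt, k3);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(p, t + c4 * h, yt, k4);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    rhs(p, t + c5 * h, yt, k5);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(p, t + h, yt, k6);
    for (int i = 0; i < 3; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    rhs(p, t + h, y5, k7);
    double err = 0.0;
    for (int i = 0; i < 3; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      err += (ei / sc) * (ei / sc);
    }
    err = std::sqrt(err / 3.0);
    if (!std::isfinite(err))
      stop("non-finite state during integration of beat %d", beat_index);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < 3; ++i) {
        y[i] = y5[i];
        k1[i] = k7[i];  // FSAL
      }
    }
    double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h > 0.05) h = 0.05;
  }
}

//' @noRd
// [[Rcpp::export]]
List wk4_integrate_beat(NumericVector state0, List pars, double t0,
                        double dt_out, double rtol, double atol,
                        int beat_index) {
  BeatParams p;
  p.Am = pars["Am"]; p.P0 = pars["P0"]; p.P1 = pars["P1"]; p.l = pars["l"];
  p.C2 = pars["C2"]; p.R = pars["R"]; p.L = pars["L"];
  p.q0 = pars["q0"]; p.T = pars["T"]; p.Ts = pars["Ts"];
  p.alpha = pars["alpha"];
  p.t0 = t0;
  NumericVector m0 = pars["mini_t0"], m1 = pars["mini_t1"],
                mf = pars["mini_factor"];
  for (int i = 0; i < m0.size(); ++i) {
    // keep only windows overlapping this beat
    if (m1[i] > t0 - 1e-12 && m0[i] < t0 + p.T + 1e-12) {
      p.m_t0.push_back(m0[i]);
      p.m_t1.push_back(m1[i]);
      p.m_fac.push_back(mf[i]);
    }
  }

  // output grid: multiples of dt_out in [t0, t0 + T)
  long k0 = (long)std::ceil(t0 / dt_out - 1e-9);
  long k1_ = (long)std::ceil((t0 + p.T) / dt_out - 1e-9);  // exclusive
  int n_out = (int)(k1_ - k0);

  // breakpoints: output times, modifier-window edges, beat end
  std::vector<double> brk;
  for (long k = k0; k < k1_; ++k) brk.push_back(k * dt_out);
  for (size_t i = 0; i < p.m_t0.size(); ++i) {
    brk.push_back(std::max(p.m_t0[i], t0));
    brk.push_back(std::min(p.m_t1[i], t0 + p.T));
  }
  brk.push_back(t0 + p.Ts * p.alpha);
  brk.push_back(t0 + p.Ts);
  brk.push_back(t0 + p.T);
  std::sort(brk.begin(), brk.end());

  NumericVector out_pp(n_out), out_pc(n_out), out_q(n_out), out_c1(n_out),
      out_qin(n_out), out_t(n_out);
  double y[3] = {state0[0], state0[1], state0[2]};
  double t = t0, h = dt_out / 4.0;
  int io = 0;
  for (size_t i = 0; i < brk.size(); ++i) {
    double te = brk[i];
    if (te <= t + 1e-12) {
      // still record if this breakpoint is an output time already reached
    } else {
      integrate_to(p, t, te, y, rtol, atol, h, beat_index);
    }
    if (io < n_out && std::fabs(te - (k0 + io) * dt_out) < 1e-9) {
      out_t[io] = te;
      out_q[io] = y[0];
      out_pc[io] = y[1];
      out_pp[io] = y[2];
      out_c1[io] = c1_of(p, y[1]);
      out_qin[io] = qin_of(p, te);
      ++io;
    }
  }
  for (int i = 0; i < 3; ++i)
    if (!std::isfinite(y[i]))
      stop("non-finite state at end of beat %d", beat_index);
  return List::create(_["time"] = out_t, _["q"] = out_q, _["p_c"] = out_pc,
                      _["p_p"] = out_pp, _["c1"] = out_c1,
                      _["q_in"] = out_qin,
                      _["state"] = NumericVector::create(y[0], y[1], y[2]));
}
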