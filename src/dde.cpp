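// Method-of-steps integrator for the three-species circadian clock DDE and
// for the scalar linear test DDE x'(t) = -a x(t - tau).
//
// Fixed-step classical RK4 with dense history: state and derivative are
// stored at every internal step and delayed arguments are evaluated by cubic
// Hermite interpolation. All delays (6-16 h) are far larger than the step
// size (default 0.02 h), so every delayed lookup falls in already-computed
// history and no implicit iteration is needed. Pre-history (t < 0) is
// constant at the initial condition.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct History {
  double h;                 // uniform internal step
  std::vector<double> val;  // dim * (n+1), column-major per step
  std::vector<double> der;
  int dim;
  int filled;               // last filled step index

  History(int dim_, int nsteps, double h_) : h(h_), dim(dim_), filled(0) {
    val.assign(static_cast<size_t>(dim_) * (nsteps + 1), 0.0);
    der.assign(static_cast<size_t>(dim_) * (nsteps + 1), 0.0);
  }
  // value of component k at time t (t <= filled*h); constant for t < 0
  double at(double t, int k) const {
    if (t <= 0.0) return val[k];
    double s = t / h;
    int j = static_cast<int>(std::floor(s));
    if (j >= filled) return val[static_cast<size_t>(filled) * dim + k];
    double u = s - j;
    const double y0 = val[static_cast<size_t>(j) * dim + k];
    const double y1 = val[static_cast<size_t>(j + 1) * dim + k];
    const double d0 = der[static_cast<size_t>(j) * dim + k];
    const double d1 = der[static_cast<size_t>(j + 1) * dim + k];
    const double u2 = u * u, u3 = u2 * u;
    return (2 * u3 - 3 * u2 + 1) * y0 + (u3 - 2 * u2 + u) * h * d0 +
           (-2 * u3 + 3 * u2) * y1 + (u3 - u2) * h * d1;
  }
};

inline double hill_act(double x, double k, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n);
  return xn / (std::pow(k, n) + xn);
}
inline double hill_inh(double x, double k, double n) {
  if (x <= 0.0) return 1.0;
  return 1.0 / (1.0 + std::pow(x / k, n));
}

struct ClockParams {
  double tau_b, tau_p, tau_r, kd_b, kd_p, kd_r;
  double keb0, kib, n_b, kep0, kab, kip, n_p, zeta;
  double keb2, kep2, ker2;  // condition-dependent coupling constants
};

// rhs of the clock; delayed arguments through the history object
inline void clock_rhs(double t, const double* y, const History& H,
                      const ClockParams& q, double* dy, double* kep1_out) {
  const double R_tb = H.at(t - q.tau_b, 2);
  const double B_tp = H.at(t - q.tau_p, 0);
  const double P_tp = H.at(t - q.tau_p, 1);
  const double B_tr = H.at(t - q.tau_r, 0);
  const double P_tr = H.at(t - q.tau_r, 1);

  const double keb1 = q.keb0 * hill_inh(R_tb, q.kib, q.n_b);
  const double kep1 = q.kep0 * hill_act(B_tp, q.kab, q.n_p) *
                      hill_inh(P_tp, q.kip, q.n_p);
  const double ker1 = q.zeta * q.kep0 * hill_act(B_tr, q.kab, q.n_p) *
                      hill_inh(P_tr, q.kip, q.n_p);

  dy[0] = keb1 + q.keb2 - q.kd_b * y[0];
  dy[1] = kep1 + q.kep2 - q.kd_p * y[1];
  dy[2] = ker1 + q.ker2 - q.kd_r * y[2];
  if (kep1_out) *kep1_out = kep1 + q.kep2;
}

}  // namespace

// [[Rcpp::export(name = ".clock_dde_cpp")]]
List clock_dde_cpp(NumericVector par, NumericVector y0, double duration,
                   double dt_out, double dt_step) {
  ClockParams q;
  q.tau_b = par["tau_b"]; q.tau_p = par["tau_p"]; q.tau_r = par["tau_r"];
  q.kd_b = par["kd_b"]; q.kd_p = par["kd_p"]; q.kd_r = par["kd_r"];
  q.keb0 = par["keb0"]; q.kib = par["kib"]; q.n_b = par["n_b"];
  q.kep0 = par["kep0"]; q.kab = par["kab"]; q.kip = par["kip"];
  q.n_p = par["n_p"]; q.zeta = par["zeta"];
  q.keb2 = par["keb2"]; q.kep2 = par["kep2"]; q.ker2 = par["ker2"];

  const double tau_min = std::min(q.tau_b, std::min(q.tau_p, q.tau_r));
  int sub = std::max(1, (int)std::ceil(dt_out / dt_step));
  double h = dt_out / sub;
  if (h >= tau_min)
    stop("internal step must be smaller than the shortest delay");
  const int nout = (int)std::round(duration / dt_out);
  const int nsteps = nout * sub;

  History H(3, nsteps, h);
  double y[3] = {y0[0], y0[1], y0[2]};
  double dy[3], k1[3], k2[3], k3[3], k4[3], ytmp[3];

  // t = 0 record
  clock_rhs(0.0, y, H, q, dy, nullptr);
  for (int k = 0; k < 3; ++k) { H.val[k] = y[k]; H.der[k] = dy[k]; }

  NumericVector t_out(nout + 1), B(nout + 1), P(nout + 1), R(nout + 1),
      keP(nout + 1);
  double kep_now;
  clock_rhs(0.0, y, H, q, dy, &kep_now);
  t_out[0] = 0.0; B[0] = y[0]; P[0] = y[1]; R[0] = y[2]; keP[0] = kep_now;

  for (int i = 0; i < nsteps; ++i) {
    const double t = i * h;
    clock_rhs(t, y, H, q, k1, nullptr);
    for (int k = 0; k < 3; ++k) ytmp[k] = y[k] + 0.5 * h * k1[k];
    clock_rhs(t + 0.5 * h, ytmp, H, q, k2, nullptr);
    for (int k = 0; k < 3; ++k) ytmp[k] = y[k] + 0.5 * h * k2[k];
    clock_rhs(t + 0.5 * h, ytmp, H, q, k3, nullptr);
    for (int k = 0; k < 3; ++k) ytmp[k] = y[k] + h * k3[k];
    clock_rhs(t + h, ytmp, H, q, k4, nullptr);
    for (int k = 0; k < 3; ++k)
      y[k] += h / 6.0 * (k1[k] + 2 * k2[k] + 2 * k3[k] + k4[k]);
    // record step i+1
    H.filled = i + 1;
    clock_rhs(t + h, y, H, q, dy, &kep_now);
    for (int k = 0; k < 3; ++k) {
      H.val[static_cast<size_t>(i + 1) * 3 + k] = y[k];
      H.der[static_cast<size_t>(i + 1) * 3 + k] = dy[k];
    }
    if ((i + 1) % sub == 0) {
      int j = (i + 1) / sub;
      t_out[j] = (t + h);
      B[j] = y[0]; P[j] = y[1]; R[j] = y[2]; keP[j] = kep_now;
    }
  }
  return List::create(_["t_h"] = t_out, _["B"] = B, _["P"] = P, _["R"] = R,
                      _["keP"] = keP);
}

// [[Rcpp::export(name = ".linear_dde_cpp")]]
NumericVector linear_dde_cpp(double a, double tau, double x0, double duration,
                             double dt) {
  int sub = 1;
  double h = dt;
  if (h >= tau) { sub = (int)std::ceil(4.0 * dt / tau); h = dt / sub; }
  const int nout = (int)std::round(duration / dt);
  const int nsteps = nout * sub;
  History H(1, nsteps, h);
  double x = x0;
  H.val[0] = x; H.der[0] = -a * x0;  // constant pre-history

  NumericVector out(nout + 1);
  out[0] = x;
  for (int i = 0; i < nsteps; ++i) {
    const double t = i * h;
    const double k1 = -a * H.at(t - tau, 0);
    const double k2 = -a * H.at(t + 0.5 * h - tau, 0);
    const double k3 = k2;
    const double k4 = -a * H.at(t + h - tau, 0);
    x += h / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
    H.filled = i + 1;
    H.val[i + 1] = x;
    H.der[i + 1] = -a * H.at(t + h - tau, 0);
    if ((i + 1) % sub == 0) out[(i + 1) / sub] = x;
  }
  return out;
}
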