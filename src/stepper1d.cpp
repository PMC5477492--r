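#include <Rcpp.h>
using namespace Rcpp;

// Semi-implicit stepper for the 1D active Maxwell cell.
//
// Continuum system (x in [0,L]):
//   passive Maxwell stress   d(sp)/dt = E dv/dx - (E/eta) sp
//   total stress             sigma    = sp + sigma_a(x,t)
//   quasi-static balance     d(sigma)/dx = kM w          (constraint)
//   substrate friction       dw/dt = v - (kM/gamma) w
//
// Discretely, sp lives on the N-1 elements and u, v, w on the N nodes.
// w is slaved to the constraint, so the states are (sp, u).  Differentiating
// the constraint in time and substituting the friction law yields a
// tridiagonal system for v at every step:
//   E v'' - kM v = -d/dx[ sadot - (E/eta) sp ] - (kM^2/gamma) w
// with natural (stress-free, sigma=0 beyond the ends) or clamped (v=0)
// boundary rows.  sp then advances by an exponential update that is exact
// for piecewise-constant dv/dx, which keeps the scheme stable for
// relaxation times far below the step size.

static void thomas_solve(std::vector<double>& a, std::vector<double>& b,
                         std::vector<double>& c, std::vector<double>& d) {
  // in-place tridiagonal solve; solution returned in d
  const int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// ramp f(t) and its derivative
static inline double ramp_f(double t, double t_on, double t_off,
                            double tau_a, double tau_d) {
  if (t < t_on) return 0.0;
  if (t < t_off) return 1.0 - std::exp(-(t - t_on) / tau_a);
  double f_off = 1.0 - std::exp(-(t_off - t_on) / tau_a);
  return f_off * std::exp(-(t - t_off) / tau_d);
}
static inline double ramp_df(double t, double t_on, double t_off,
                             double tau_a, double tau_d) {
  if (t < t_on) return 0.0;
  if (t < t_off) return std::exp(-(t - t_on) / tau_a) / tau_a;
  double f_off = 1.0 - std::exp(-(t_off - t_on) / tau_a);
  return -f_off * std::exp(-(t - t_off) / tau_d) / tau_d;
}

// [[Rcpp::export(name = ".simulate_1d_cpp")]]
List simulate_1d_cpp(double E, double eta, double gamma, double kM,
                     double sigma0, double dsigma, double L,
                     double reg_a, double reg_b,
                     double t_on, double t_off, double tau_a, double tau_d,
                     int n_nodes, double dt_step, double dt_output,
                     double t_end, bool clamped) {
  const int N = n_nodes;
  const int M = N - 1;            // elements
  const double dx = L / (N - 1);
  const double tau = eta / E;

  // align the internal step with the output cadence
  int sub = (int)std::ceil(dt_output / dt_step - 1e-12);
  if (sub < 1) sub = 1;
  const double h = dt_output / sub;
  const int n_out = (int)std::floor(t_end / dt_output + 1e-9) + 1;

  std::vector<double> sp(M, -sigma0), u(N, 0.0);
  std::vector<double> chi(M);      // activation indicator at element midpoints
  for (int j = 0; j < M; ++j) {
    double xm = (j + 0.5) * dx;
    chi[j] = (xm >= reg_a && xm <= reg_b) ? 1.0 : 0.0;
  }

  NumericMatrix U(N, n_out), V(N, n_out), W(N, n_out);
  NumericMatrix SP(M, n_out);
  NumericVector times(n_out);

  std::vector<double> sig(M), w(N), g(M), v(N);
  std::vector<double> ta(N), tb(N), tc(N), td(N);

  const double ed2 = E / (dx * dx);
  const double kf = kM * kM / gamma;
  const double decay = std::exp(-h / tau);
  const double gain = eta * (1.0 - decay);   // sp_ss = eta * dv/dx

  int out_idx = 0;
  double t = 0.0;
  long total_steps = (long)(n_out - 1) * sub;

  for (long step = 0; step <= total_steps; ++step) {
    // total element stress and slaved substrate displacement
    double fnow = ramp_f(t, t_on, t_off, tau_a, tau_d);
    for (int j = 0; j < M; ++j) sig[j] = sp[j] + sigma0 + dsigma * chi[j] * fnow;
    w[0] = sig[0] / (dx * kM);
    for (int i = 1; i < N - 1; ++i) w[i] = (sig[i] - sig[i - 1]) / (dx * kM);
    w[N - 1] = -sig[M - 1] / (dx * kM);

    // record output
    if (step % sub == 0) {
      times[out_idx] = t;
      for (int i = 0; i < N; ++i) { U(i, out_idx) = u[i]; W(i, out_idx) = w[i]; }
      for (int j = 0; j < M; ++j) SP(j, out_idx) = sp[j];
      // v recorded after the solve below
    }
    if (step == total_steps) {
      // final velocity for the last output column
      double fd = ramp_df(t, t_on, t_off, tau_a, tau_d);
      for (int j = 0; j < M; ++j) g[j] = dsigma * chi[j] * fd - (E / eta) * sp[j];
      for (int i = 1; i < N - 1; ++i) {
        ta[i] = ed2; tc[i] = ed2; tb[i] = -2.0 * ed2 - kM;
        td[i] = (g[i - 1] - g[i]) / dx - kf * w[i];
      }
      if (clamped) {
        ta[0] = 0; tb[0] = 1; tc[0] = 0; td[0] = 0;
        ta[N-1] = 0; tb[N-1] = 1; tc[N-1] = 0; td[N-1] = 0;
      } else {
        tb[0] = -ed2 - kM; tc[0] = ed2; ta[0] = 0;
        td[0] = -g[0] / dx - kf * w[0];
        ta[N-1] = ed2; tb[N-1] = -ed2 - kM; tc[N-1] = 0;
        td[N-1] = g[M - 1] / dx - kf * w[N - 1];
      }
      thomas_solve(ta, tb, tc, td);
      for (int i = 0; i < N; ++i) V(i, out_idx) = td[i];
      break;
    }

    // velocity solve at mid-step time for the forcing rate
    double tm = t + 0.5 * h;
    double fd = ramp_df(tm, t_on, t_off, tau_a, tau_d);
    for (int j = 0; j < M; ++j) g[j] = dsigma * chi[j] * fd - (E / eta) * sp[j];
    for (int i = 1; i < N - 1; ++i) {
      ta[i] = ed2; tc[i] = ed2; tb[i] = -2.0 * ed2 - kM;
      td[i] = (g[i - 1] - g[i]) / dx - kf * w[i];
    }
    if (clamped) {
      ta[0] = 0; tb[0] = 1; tc[0] = 0; td[0] = 0;
      ta[N-1] = 0; tb[N-1] = 1; tc[N-1] = 0; td[N-1] = 0;
    } else {
      tb[0] = -ed2 - kM; tc[0] = ed2; ta[0] = 0;
      td[0] = -g[0] / dx - kf * w[0];
      ta[N-1] = ed2; tb[N-1] = -ed2 - kM; tc[N-1] = 0;
      td[N-1] = g[M - 1] / dx - kf * w[N - 1];
    }
    thomas_solve(ta, tb, tc, td);
    for (int i = 0; i < N; ++i) v[i] = td[i];
    if (step % sub == 0)
      for (int i = 0; i < N; ++i) V(i, out_idx) = v[i];
    if (step % sub == 0) ++out_idx;

    // advance states
    for (int j = 0; j < M; ++j) {
      double dvdx = (v[j + 1] - v[j]) / dx;
      sp[j] = sp[j] * decay + gain * dvdx;
    }
    for (int i = 0; i < N; ++i) u[i] += v[i] * h;
    t += h;

    if (!std::isfinite(sp[0]) || !std::isfinite(u[0]))
      stop("1D integration diverged at t = %f s; reduce dt_step", t);
  }

  return List::create(_["times"] = times, _["u"] = U, _["v"] = V,
                      _["w"] = W, _["sigma_p"] = SP);
}
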