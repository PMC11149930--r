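#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation into a table sampled uniformly with spacing 1/inv_step.
static inline double tab_interp(const std::vector<double>& tab,
                                double inv_step, double v) {
  double u = v * inv_step;
  if (u <= 0.0) return tab.front();
  int n = (int)tab.size();
  if (u >= n - 1) return tab.back();
  int i = (int)u;
  double f = u - i;
  return tab[i] + f * (tab[i + 1] - tab[i]);
}

// Marsaglia polar method on R's RNG; caches the spare deviate.
struct PolarNormal {
  bool has_spare = false;
  double spare = 0.0;
  inline double draw() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// Run-and-tumble ensemble simulation with MWC signaling.
//
// Cells carry position, a heading unit vector, methylation and motor state.
// Per step and cell: read the local potassium concentration, Euler-update
// methylation, recompute activity -> CheY-P -> CW bias -> switching rates,
// draw the motor transition, and move runners at constant speed with
// rotational diffusion. y is periodic, x reflective. Uses R's RNG so
// set.seed() governs runs.
//
// field_type: 0 oscillating semi-infinite source at x=0, concentration
// L0*(1 - cos(w t - k x) exp(-k x)); 1 linear in x, c0 + slope*x (>= 0).
//
// Numerical shortcuts (errors orders of magnitude below stochastic noise):
// smooth single-argument maps (field envelope/phase factors, ligand free
// energy, bias-vs-activity) are tabulated on 4096-point grids with linear
// interpolation; the per-step rotational-diffusion rotation uses a 4th-order
// small-angle expansion with first-order renormalisation of the heading
// vector; the post-Euler activity update uses a second-order expansion of
// exp(g + delta) in the per-step free-energy increment delta (~1e-4).
// [[Rcpp::export]]
List simulate_swim_cpp(NumericVector x0, NumericVector y0,
                       NumericVector theta0, NumericVector m0_,
                       LogicalVector tumbling0,
                       int field_type, double L0, double period, double kwave,
                       double c0, double slope,
                       double N, double alpha, double m_offset,
                       double Koff, double Kon, double kR, double kB,
                       double yp_scale, double motor_hill, double motor_K,
                       double tumble_rate_scale, double detumble_rate,
                       double m_lo, double m_hi,
                       double arena_x, double arena_y,
                       double speed, double rot_diffusion,
                       double dt, double t_start, int n_steps,
                       int record_every, int signal_every) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> cx(n), cy(n), m(m0_.begin(), m0_.end());
  std::vector<char> tum(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = std::cos(theta0[i]);
    cy[i] = std::sin(theta0[i]);
    tum[i] = tumbling0[i] ? 1 : 0;
  }

  // ligand free-energy table over the field's concentration range
  double Lmax;
  if (field_type == 0) Lmax = 2.0 * L0;
  else {
    double a = c0, b = c0 + slope * arena_x;
    Lmax = a > b ? a : b;
  }
  if (Lmax <= 0) Lmax = 1e-6;
  const int NT = 4096;
  std::vector<double> fL_tab(NT);
  double L_step = Lmax / (NT - 1);
  for (int i = 0; i < NT; ++i) {
    double L = i * L_step;
    fL_tab[i] = std::log1p(L / Koff) - std::log1p(L / Kon);
  }
  const double fL_inv = 1.0 / L_step;

  // CW bias as a function of activity
  std::vector<double> B_tab(NT);
  double a_step = 1.0 / (NT - 1);
  double Kh = std::pow(motor_K, motor_hill);
  for (int i = 0; i < NT; ++i) {
    double Yp = yp_scale * (i * a_step);
    double Yph = std::pow(Yp, motor_hill);
    B_tab[i] = Yph / (Yph + Kh);
  }
  const double B_inv = 1.0 / a_step;

  // field spatial factors over [0, arena_x]: exp(-kx)cos(kx), exp(-kx)sin(kx)
  std::vector<double> fc_tab(NT), fs_tab(NT);
  const double x_inv = (NT - 1) / arena_x;
  if (field_type == 0) {
    double x_step = arena_x / (NT - 1);
    for (int i = 0; i < NT; ++i) {
      double kx = kwave * (i * x_step), e = std::exp(-kx);
      fc_tab[i] = e * std::cos(kx);
      fs_tab[i] = e * std::sin(kx);
    }
  }

  const double max_rt = B_tab[NT - 1] / tumble_rate_scale;
  if (max_rt * dt > 1.0 || detumble_rate * dt > 1.0)
    stop("rate * dt exceeds 1: timestep too coarse for the switching rates");

  const double sig_rot = std::sqrt(2.0 * rot_diffusion * dt);
  const double vdt = speed * dt;
  const double w = (period > 0) ? 2.0 * M_PI / period : 0.0;
  const double kRB = kR + kB;
  const double p_detumble = detumble_rate * dt;
  const double rt_fac = dt / tumble_rate_scale;
  // signaling (ligand read, methylation Euler, bias) is refreshed every
  // signal_every steps with the correspondingly longer Euler step; the
  // fastest signaling timescale (~200 s) is orders above this interval
  if (signal_every < 1) signal_every = 1;
  const double dt_sig = dt * signal_every;
  std::vector<double> Bv(n, 0.0);

  int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_mx(n_rec), rec_my(n_rec);
  int ir = 0;
  {
    double sx = 0, sy = 0;
    for (int i = 0; i < n; ++i) { sx += x[i]; sy += y[i]; }
    rec_t[ir] = t_start; rec_mx[ir] = sx / n; rec_my[ir] = sy / n; ++ir;
  }

  RNGScope scope;
  PolarNormal nrm;
  for (int s = 1; s <= n_steps; ++s) {
    const bool refresh = ((s - 1) % signal_every) == 0;
    double ca = 1.0, sa = 0.0;
    if (refresh && field_type == 0) {
      double A = w * (t_start + (s - 1) * dt);  // phase at the step's start
      ca = std::cos(A); sa = std::sin(A);
    }
    for (int i = 0; i < n; ++i) {
      if (refresh) {
        double L;
        if (field_type == 0) {
          double fc = tab_interp(fc_tab, x_inv, x[i]);
          double fs = tab_interp(fs_tab, x_inv, x[i]);
          L = L0 * (1.0 - (ca * fc + sa * fs));
          if (L < 0) L = 0;
        } else {
          L = c0 + slope * x[i];
          if (L < 0) L = 0;
        }
        double fL = tab_interp(fL_tab, fL_inv, L);
        double g = N * (alpha * (m[i] - m_offset) + fL);
        double E = std::exp(g);
        double a = 1.0 / (1.0 + E);
        double m_new = m[i] + dt_sig * (kR - kRB * a);
        if (m_new < m_lo) m_new = m_lo; else if (m_new > m_hi) m_new = m_hi;
        double delta = N * alpha * (m_new - m[i]);
        m[i] = m_new;
        double E2 = E * (1.0 + delta * (1.0 + 0.5 * delta));
        a = 1.0 / (1.0 + E2);
        Bv[i] = tab_interp(B_tab, B_inv, a);
      }
      const double B = Bv[i];

      double u = unif_rand();
      if (tum[i]) {
        if (u < p_detumble) {
          tum[i] = 0;
          // tumble angle: cos(theta) = 2*sqrt(u)-1 by inverse CDF of
          // P(theta) = 0.5(1+cos theta) sin theta; random in-plane sign
          double ct = 2.0 * std::sqrt(unif_rand()) - 1.0;
          double st = std::sqrt(1.0 - ct * ct > 0 ? 1.0 - ct * ct : 0.0);
          if (unif_rand() < 0.5) st = -st;
          double ncx = cx[i] * ct - cy[i] * st;
          cy[i] = cx[i] * st + cy[i] * ct;
          cx[i] = ncx;
        }
      } else {
        if (u < B * rt_fac) tum[i] = 1;
      }

      if (!tum[i]) {
        // rotational diffusion: rotate heading by sig_rot * z, z ~ N(0,1),
        // via 4th-order small-angle cos/sin and renormalisation
        double dth = sig_rot * nrm.draw();
        double q = dth * dth;
        double cr = 1.0 - 0.5 * q * (1.0 - q / 12.0);
        double sr = dth * (1.0 - q / 6.0 * (1.0 - 0.05 * q));
        double ncx = cx[i] * cr - cy[i] * sr;
        double ncy = cx[i] * sr + cy[i] * cr;
        double nrm2 = ncx * ncx + ncy * ncy;
        double corr = 0.5 * (3.0 - nrm2);
        cx[i] = ncx * corr; cy[i] = ncy * corr;

        double xn = x[i] + vdt * cx[i];
        double yn = y[i] + vdt * cy[i];
        if (xn < 0)            { xn = -xn;                cx[i] = -cx[i]; }
        else if (xn > arena_x) { xn = 2.0 * arena_x - xn; cx[i] = -cx[i]; }
        if (yn < 0) yn += arena_y; else if (yn >= arena_y) yn -= arena_y;
        x[i] = xn; y[i] = yn;
      }
    }
    if (s % record_every == 0) {
      double sx = 0, sy = 0;
      for (int i = 0; i < n; ++i) { sx += x[i]; sy += y[i]; }
      rec_t[ir] = t_start + s * dt; rec_mx[ir] = sx / n; rec_my[ir] = sy / n;
      ++ir;
    }
  }

  NumericVector theta_out(n);
  for (int i = 0; i < n; ++i) theta_out[i] = std::atan2(cy[i], cx[i]);
  return List::create(
    _["time"] = rec_t, _["mean_x"] = rec_mx, _["mean_y"] = rec_my,
    _["x"] = NumericVector(x.begin(), x.end()),
    _["y"] = NumericVector(y.begin(), y.end()),
    _["theta"] = theta_out,
    _["m"] = NumericVector(m.begin(), m.end()),
    _["tumbling"] = LogicalVector(tum.begin(), tum.end()));
}
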