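// Compiled core of the agent-based shoal simulator.
//
// Mirrors the pure-R reference implementation in R/simulator.R
// (wall_force, pair_interactions, sim_step); the two are cross-checked in
// the test suite with zero noise. Uses R's RNG so that set.seed() in R
// makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  a = std::remainder(a, 2.0 * M_PI);
  if (a <= -M_PI) a = M_PI;
  return a;
}

// [[Rcpp::export]]
List sim_core_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                  NumericVector vs0, List cfg, int n_steps, int burn_in,
                  int stride, bool variable_speed) {
  const int N = x0.size();
  const double v0 = cfg["v0"], D = cfg["d_phi"];
  const double R = cfg["arena_radius"], dt = cfg["dt"];
  const double kw = cfg["k_wall"], lw = cfg["lambda_wall"];
  const double ka = cfg["k_att"], req = cfg["r_eq"], rcut = cfg["r_cut"];
  const double fmax = cfg["f_max"];
  const double kal = cfg["k_align"], ral = cfg["r_align"];
  const double sh = cfg["s_hydro"], rreg = cfg["r_reg"];
  const double fov = as<double>(cfg["fov_deg"]) * M_PI / 180.0;
  const double cos_fov = std::cos(fov);
  const double tau_v = cfg["tau_v"], vfloor = cfg["v_floor"];
  const double sig = std::sqrt(2.0 * D * dt);

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> v(vs0.begin(), vs0.end());
  std::vector<double> fx(N), fy(N), tq(N), ux(N), uy(N);

  const int n_rec = n_steps / stride;
  NumericMatrix X(n_rec, N), Y(n_rec, N), PHI(n_rec, N);
  NumericMatrix VX(n_rec, N), VY(n_rec, N), VS(n_rec, N);
  int n_coincident = 0;

  const int total = burn_in + n_steps;
  int rec = 0;
  for (int s = 0; s < total; ++s) {
    // forces from the current (synchronous) state
    for (int i = 0; i < N; ++i) {
      const double r = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      const double mag = kw * std::exp(-(R - r) / lw);
      if (r > 1e-12) { fx[i] = -x[i] * mag / r; fy[i] = -y[i] * mag / r; }
      else { fx[i] = 0.0; fy[i] = 0.0; }
      tq[i] = 0.0; ux[i] = 0.0; uy[i] = 0.0;
    }
    for (int i = 0; i < N; ++i) {
      const double ci = std::cos(phi[i]), si = std::sin(phi[i]);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double r = std::sqrt(dx * dx + dy * dy);
        if (r < 1e-12) { dx = 1e-6; dy = 0.0; r = 1e-6; ++n_coincident; }
        const bool seen = (ci * dx + si * dy) / r >= cos_fov;
        if (seen) {
          if (r <= rcut) {
            double f = ka * (r - req);
            if (f > fmax) f = fmax; else if (f < -fmax) f = -fmax;
            fx[i] += f * dx / r;
            fy[i] += f * dy / r;
          }
          tq[i] += kal * std::sin(phi[j] - phi[i]) * std::exp(-r / ral);
        }
        if (sh > 0.0) {
          // dipole shed by j, evaluated at i; rho = r_i - r_j
          double rx = -dx, ry = -dy;
          if (r < rreg) { rx *= rreg / r; ry *= rreg / r; }
          const double r2 = rx * rx + ry * ry;
          const double s_ = sh * v[j];
          const double dxj = std::cos(phi[j]), dyj = std::sin(phi[j]);
          const double dn = dxj * rx + dyj * ry;
          ux[i] += s_ * (2.0 * dn * rx / r2 - dxj) / r2;
          uy[i] += s_ * (2.0 * dn * ry / r2 - dyj) / r2;
          // velocity gradient G_kl = d u_k / d x_l
          const double r4 = r2 * r2, r6 = r4 * r2;
          const double G11 = s_ * (2.0 * rx * dxj + 2.0 * dn + 2.0 * dxj * rx) / r4 -
                             8.0 * s_ * dn * rx * rx / r6;
          const double G12 = s_ * (2.0 * rx * dyj + 2.0 * dxj * ry) / r4 -
                             8.0 * s_ * dn * rx * ry / r6;
          const double G21 = s_ * (2.0 * ry * dxj + 2.0 * dyj * rx) / r4 -
                             8.0 * s_ * dn * rx * ry / r6;
          const double G22 = s_ * (2.0 * ry * dyj + 2.0 * dn + 2.0 * dyj * ry) / r4 -
                             8.0 * s_ * dn * ry * ry / r6;
          // slender-body rotation rate: p_perp . (G p)
          tq[i] += (-si) * (G11 * ci + G12 * si) + ci * (G21 * ci + G22 * si);
        }
      }
    }
    // synchronous update
    for (int i = 0; i < N; ++i) {
      const double eps_x = -std::sin(phi[i]), eps_y = std::cos(phi[i]);
      const double fproj = fx[i] * eps_x + fy[i] * eps_y;
      const double dphi = dt * (fproj / v[i] + tq[i]) + sig * norm_rand();
      double v_new = v[i];
      if (variable_speed) {
        const double fpar = fx[i] * std::cos(phi[i]) + fy[i] * std::sin(phi[i]);
        v_new = v[i] + dt * ((v0 - v[i]) / tau_v + fpar);
        if (v_new < vfloor) v_new = vfloor;
      }
      phi[i] = wrap_pi(phi[i] + dphi);
      v[i] = v_new;
      x[i] += (v[i] * std::cos(phi[i]) + ux[i]) * dt;
      y[i] += (v[i] * std::sin(phi[i]) + uy[i]) * dt;
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(phi[i]) || !std::isfinite(v[i]))
        stop("non-finite state at step %d, fish %d (step diverged)", s, i + 1);
    }
    if (s >= burn_in && (s - burn_in + 1) % stride == 0 && rec < n_rec) {
      for (int i = 0; i < N; ++i) {
        X(rec, i) = x[i];
        Y(rec, i) = y[i];
        PHI(rec, i) = phi[i];
        VX(rec, i) = v[i] * std::cos(phi[i]) + ux[i];
        VY(rec, i) = v[i] * std::sin(phi[i]) + uy[i];
        VS(rec, i) = v[i];
      }
      ++rec;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["phi"] = PHI,
                      _["vx"] = VX, _["vy"] = VY, _["v"] = VS,
                      _["n_coincident"] = n_coincident);
}
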