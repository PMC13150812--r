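#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Ideal linear-quadrupole RF field plus dipolar SWIM excitation along x.
// Radial (x, y) dynamics only: in an ideal trap the axial motion decouples
// and the laser propagates along the axis, so photon exposure depends only
// on the radial coordinates. Velocities keep a z component so hard-sphere
// collisions thermalize all three degrees of freedom.

static inline double pulse_at(const NumericVector &pulse, double pulse_rate,
                              double t) {
  if (pulse.size() == 0) return 0.0;
  double x = t * pulse_rate;
  int i = (int)std::floor(x);
  if (i < 0 || i >= pulse.size() - 1) return 0.0;
  double f = x - i;
  return pulse[i] * (1.0 - f) + pulse[i + 1] * f;
}

// [[Rcpp::export(name = ".cpp_single_trajectory")]]
NumericMatrix cpp_single_trajectory(NumericVector pos0, NumericVector vel0,
                                    double mass_kg, double charge_C,
                                    double v_trap, double f_trap, double r0,
                                    NumericVector pulse, double pulse_rate,
                                    double dt, int n_steps, int save_stride) {
  double x = pos0[0], y = pos0[1];
  double vx = vel0[0], vy = vel0[1];
  const double w = 2.0 * M_PI * f_trap;
  const double cq = 2.0 * charge_C * v_trap / (mass_kg * r0 * r0);
  const double cd = charge_C / (mass_kg * r0);
  int n_save = n_steps / save_stride + 1;
  NumericMatrix out(n_save, 3); // t, x, y
  int k = 0;
  double ax = -cq * std::cos(0.0) * x + cd * pulse_at(pulse, pulse_rate, 0.0);
  double ay = cq * std::cos(0.0) * y;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    if (s % save_stride == 0 && k < n_save) {
      out(k, 0) = t; out(k, 1) = x; out(k, 2) = y; ++k;
    }
    // velocity Verlet (forces position-dependent only)
    x += vx * dt + 0.5 * ax * dt * dt;
    y += vy * dt + 0.5 * ay * dt * dt;
    double tn = t + dt;
    double c = std::cos(w * tn);
    double axn = -cq * c * x + cd * pulse_at(pulse, pulse_rate, tn);
    double ayn = cq * c * y;
    vx += 0.5 * (ax + axn) * dt;
    vy += 0.5 * (ay + ayn) * dt;
    ax = axn; ay = ayn;
  }
  if (k < n_save) { out(k, 0) = n_steps * dt; out(k, 1) = x; out(k, 2) = y; }
  return out;
}

// [[Rcpp::export(name = ".cpp_ensemble_pulse")]]
NumericMatrix cpp_ensemble_pulse(NumericMatrix pos0, NumericMatrix vel0,
                                 double mass_kg, double charge_C,
                                 double v_trap, double f_trap, double r0,
                                 NumericVector pulse, double pulse_rate,
                                 double dt, int n_steps,
                                 bool collisions, double gas_mass_kg,
                                 double n_gas, double sigma_hs, double temp_K,
                                 int coll_stride,
                                 int tail_start, double laser_F0,
                                 double laser_sig, double laser_x0,
                                 double laser_y0) {
  const int n_ions = pos0.nrow();
  const double w = 2.0 * M_PI * f_trap;
  const double cq = 2.0 * charge_C * v_trap / (mass_kg * r0 * r0);
  const double cd = charge_C / (mass_kg * r0);
  const double kB = 1.380649e-23;
  const double sd_gas = std::sqrt(kB * temp_K / gas_mass_kg);
  const double r0sq = r0 * r0;
  // per-step field tables shared by all ions
  std::vector<double> cosw(n_steps + 1), drive(n_steps + 1);
  for (int s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    cosw[s] = std::cos(w * t);
    drive[s] = cd * pulse_at(pulse, pulse_rate, t);
  }
  // columns: exposure, rmax_tail(m), lost(0/1), x, y, vx, vy
  NumericMatrix out(n_ions, 7);

  for (int i = 0; i < n_ions; ++i) {
    double x = pos0(i, 0), y = pos0(i, 1);
    double vx = vel0(i, 0), vy = vel0(i, 1), vz = vel0(i, 2);
    bool lost = false;
    double expo_sum = 0.0; int expo_n = 0; double rmax = 0.0;
    double ax = -cq * x + drive[0];
    double ay = cq * y;
    for (int s = 0; s < n_steps; ++s) {
      x += vx * dt + 0.5 * ax * dt * dt;
      y += vy * dt + 0.5 * ay * dt * dt;
      double r2 = x * x + y * y;
      if (r2 >= r0sq) { lost = true; break; }
      double c = cosw[s + 1];
      double axn = -cq * c * x + drive[s + 1];
      double ayn = cq * c * y;
      vx += 0.5 * (ax + axn) * dt;
      vy += 0.5 * (ay + ayn) * dt;
      ax = axn; ay = ayn;
      if (collisions && (s % coll_stride == 0)) {
        double gx = R::rnorm(0.0, sd_gas), gy = R::rnorm(0.0, sd_gas),
               gz = R::rnorm(0.0, sd_gas);
        double rx = vx - gx, ry = vy - gy, rz = vz - gz;
        double g = std::sqrt(rx * rx + ry * ry + rz * rz);
        double pcol = n_gas * sigma_hs * g * (dt * coll_stride);
        if (R::runif(0.0, 1.0) < pcol) {
          double mu = gas_mass_kg / (mass_kg + gas_mass_kg);
          double cmx = vx - mu * rx, cmy = vy - mu * ry, cmz = vz - mu * rz;
          // isotropic scattering of the relative velocity
          double u1 = R::runif(0.0, 1.0), u2 = R::runif(0.0, 1.0);
          double ct = 2.0 * u1 - 1.0, st = std::sqrt(1.0 - ct * ct);
          double ph = 2.0 * M_PI * u2;
          vx = cmx + mu * g * st * std::cos(ph);
          vy = cmy + mu * g * st * std::sin(ph);
          vz = cmz + mu * g * ct;
        }
      }
      if (s >= tail_start) {
        double d2 = (x - laser_x0) * (x - laser_x0) +
                    (y - laser_y0) * (y - laser_y0);
        expo_sum += laser_F0 * std::exp(-d2 / (2.0 * laser_sig * laser_sig));
        ++expo_n;
        double r = std::sqrt(r2);
        if (r > rmax) rmax = r;
      }
    }
    out(i, 0) = expo_n > 0 ? expo_sum / expo_n : 0.0;
    out(i, 1) = rmax;
    out(i, 2) = lost ? 1.0 : 0.0;
    out(i, 3) = x; out(i, 4) = y; out(i, 5) = vx; out(i, 6) = vy;
  }
  return out;
}
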