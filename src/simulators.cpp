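#include <Rcpp.h>
using namespace Rcpp;

// Underdamped Langevin dynamics (BAOAB splitting, unit mass) on the 2D
// three-hole potential and on the 2D Lennard-Jones 7-particle cluster.
// Gaussian noise is drawn from R's RNG so runs are reproducible via
// set.seed() on the R side.

static inline void three_hole_force(double x, double y,
                                    double &fx, double &fy) {
  const double e1 = exp(-x * x - (y - 1.0 / 3.0) * (y - 1.0 / 3.0));
  const double e2 = exp(-x * x - (y - 5.0 / 3.0) * (y - 5.0 / 3.0));
  const double e3 = exp(-(x - 1.0) * (x - 1.0) - y * y);
  const double e4 = exp(-(x + 1.0) * (x + 1.0) - y * y);
  // V = 3 e1 - 3 e2 - 5 e3 - 5 e4 + 0.2 x^4 + 0.2 (y - 1/3)^4
  double dVdx = 3.0 * (-2.0 * x) * e1 - 3.0 * (-2.0 * x) * e2
              - 5.0 * (-2.0 * (x - 1.0)) * e3
              - 5.0 * (-2.0 * (x + 1.0)) * e4
              + 0.8 * x * x * x;
  double dVdy = 3.0 * (-2.0 * (y - 1.0 / 3.0)) * e1
              - 3.0 * (-2.0 * (y - 5.0 / 3.0)) * e2
              - 5.0 * (-2.0 * y) * e3
              - 5.0 * (-2.0 * y) * e4
              + 0.8 * pow(y - 1.0 / 3.0, 3);
  fx = -dVdx;
  fy = -dVdy;
}

// [[Rcpp::export(name = ".sim_three_hole_cpp")]]
NumericMatrix sim_three_hole_cpp(double n_steps_d, double dt, double kT,
                                 double gamma, int stride,
                                 double x0, double y0) {
  const long long n_steps = (long long)n_steps_d;
  const long long n_frames = n_steps / stride;
  NumericMatrix out(n_frames, 2);
  const double c1 = exp(-gamma * dt);
  const double c2 = sqrt(kT * (1.0 - c1 * c1));
  double x = x0, y = y0, vx = 0.0, vy = 0.0, fx, fy;
  three_hole_force(x, y, fx, fy);
  GetRNGstate();
  long long k = 0;
  for (long long s = 1; s <= n_steps; ++s) {
    vx += 0.5 * dt * fx;  vy += 0.5 * dt * fy;
    x  += 0.5 * dt * vx;  y  += 0.5 * dt * vy;
    vx = c1 * vx + c2 * norm_rand();
    vy = c1 * vy + c2 * norm_rand();
    x  += 0.5 * dt * vx;  y  += 0.5 * dt * vy;
    three_hole_force(x, y, fx, fy);
    vx += 0.5 * dt * fx;  vy += 0.5 * dt * fy;
    if (!R_finite(x) || !R_finite(y) || fabs(x) > 1e3 || fabs(y) > 1e3) {
      PutRNGstate();
      stop("trajectory diverged at step %lld; reduce dt (current dt = %g)",
           s, dt);
    }
    if (s % stride == 0 && k < n_frames) {
      out(k, 0) = x;
      out(k, 1) = y;
      ++k;
    }
  }
  PutRNGstate();
  return out;
}

static const int N_LJ = 7;

// 12-6 Lennard-Jones (epsilon = sigma = 1) plus a half-harmonic restraint
// pulling particles back once they stray more than r_conf from the
// instantaneous cluster centroid (prevents evaporation at high kT). The
// centroid contribution to the restraint gradient is included, so the
// restraint force is conservative.
static double lj7_forces(const double *px, const double *py,
                         double *fx, double *fy,
                         double r_conf, double k_conf) {
  double energy = 0.0;
  for (int i = 0; i < N_LJ; ++i) { fx[i] = 0.0; fy[i] = 0.0; }
  for (int i = 0; i < N_LJ; ++i) {
    for (int j = i + 1; j < N_LJ; ++j) {
      const double dx = px[i] - px[j];
      const double dy = py[i] - py[j];
      const double r2 = dx * dx + dy * dy;
      const double inv2 = 1.0 / r2;
      const double inv6 = inv2 * inv2 * inv2;
      energy += 4.0 * inv6 * (inv6 - 1.0);
      const double fmag = 24.0 * inv6 * (2.0 * inv6 - 1.0) * inv2;
      fx[i] += fmag * dx;  fy[i] += fmag * dy;
      fx[j] -= fmag * dx;  fy[j] -= fmag * dy;
    }
  }
  if (k_conf > 0.0) {
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < N_LJ; ++i) { cx += px[i]; cy += py[i]; }
    cx /= N_LJ; cy /= N_LJ;
    double sumx = 0.0, sumy = 0.0;
    double gx[N_LJ], gy[N_LJ];
    for (int i = 0; i < N_LJ; ++i) {
      const double dx = px[i] - cx, dy = py[i] - cy;
      const double d = sqrt(dx * dx + dy * dy);
      gx[i] = 0.0; gy[i] = 0.0;
      if (d > r_conf) {
        const double exc = d - r_conf;
        energy += 0.5 * k_conf * exc * exc;
        gx[i] = k_conf * exc * dx / d;
        gy[i] = k_conf * exc * dy / d;
        sumx += gx[i]; sumy += gy[i];
      }
    }
    for (int i = 0; i < N_LJ; ++i) {
      fx[i] -= gx[i] - sumx / N_LJ;
      fy[i] -= gy[i] - sumy / N_LJ;
    }
  }
  return energy;
}

// [[Rcpp::export(name = ".lj7_energy_forces_cpp")]]
List lj7_energy_forces_cpp(NumericMatrix coords, double r_conf,
                           double k_conf) {
  if (coords.nrow() != N_LJ || coords.ncol() != 2)
    stop("coords must be a 7 x 2 matrix");
  double px[N_LJ], py[N_LJ], fx[N_LJ], fy[N_LJ];
  for (int i = 0; i < N_LJ; ++i) { px[i] = coords(i, 0); py[i] = coords(i, 1); }
  for (int i = 0; i < N_LJ; ++i)
    for (int j = 0; j < N_LJ; ++j)
      if (i != j) {
        const double dx = px[i] - px[j], dy = py[i] - py[j];
        if (dx * dx + dy * dy == 0.0)
          stop("coincident particles (%d, %d): r = 0", i + 1, j + 1);
      }
  double e = lj7_forces(px, py, fx, fy, r_conf, k_conf);
  NumericMatrix f(N_LJ, 2);
  for (int i = 0; i < N_LJ; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; }
  return List::create(_["energy"] = e, _["forces"] = f);
}

// [[Rcpp::export(name = ".sim_lj7_cpp")]]
NumericMatrix sim_lj7_cpp(double n_steps_d, double dt, double kT,
                          double gamma, int stride, NumericMatrix coords0,
                          double r_conf, double k_conf) {
  if (coords0.nrow() != N_LJ || coords0.ncol() != 2)
    stop("coords0 must be a 7 x 2 matrix");
  const long long n_steps = (long long)n_steps_d;
  const long long n_frames = n_steps / stride;
  NumericMatrix out(n_frames, 2 * N_LJ);
  const double c1 = exp(-gamma * dt);
  const double c2 = sqrt(kT * (1.0 - c1 * c1));
  double px[N_LJ], py[N_LJ], vx[N_LJ], vy[N_LJ], fx[N_LJ], fy[N_LJ];
  for (int i = 0; i < N_LJ; ++i) {
    px[i] = coords0(i, 0); py[i] = coords0(i, 1);
    vx[i] = 0.0; vy[i] = 0.0;
  }
  lj7_forces(px, py, fx, fy, r_conf, k_conf);
  GetRNGstate();
  long long k = 0;
  for (long long s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < N_LJ; ++i) {
      vx[i] += 0.5 * dt * fx[i];  vy[i] += 0.5 * dt * fy[i];
      px[i] += 0.5 * dt * vx[i];  py[i] += 0.5 * dt * vy[i];
      vx[i] = c1 * vx[i] + c2 * norm_rand();
      vy[i] = c1 * vy[i] + c2 * norm_rand();
      px[i] += 0.5 * dt * vx[i];  py[i] += 0.5 * dt * vy[i];
    }
    lj7_forces(px, py, fx, fy, r_conf, k_conf);
    for (int i = 0; i < N_LJ; ++i) {
      vx[i] += 0.5 * dt * fx[i];  vy[i] += 0.5 * dt * fy[i];
    }
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < N_LJ; ++i) { cx += px[i]; cy += py[i]; }
    cx /= N_LJ; cy /= N_LJ;
    for (int i = 0; i < N_LJ; ++i) {
      const double dx = px[i] - cx, dy = py[i] - cy;
      if (!R_finite(dx) || !R_finite(dy) ||
          dx * dx + dy * dy > 9.0 * r_conf * r_conf) {
        PutRNGstate();
        stop("particle %d escaped beyond 3*r_conf at step %lld; "
             "use a stronger confining restraint", i + 1, s);
      }
    }
    if (s % stride == 0 && k < n_frames) {
      for (int i = 0; i < N_LJ; ++i) {
        out(k, i) = px[i];
        out(k, N_LJ + i) = py[i];
      }
      ++k;
    }
  }
  PutRNGstate();
  return out;
}

// Smooth coordination numbers per frame: c_i = sum_j 1/(1 + (r_ij/r0)^8)
// (the continuous limit of (1-(r/r0)^8)/(1-(r/r0)^16)), sorted in
// decreasing order within each frame.
// [[Rcpp::export(name = ".coordination_cpp")]]
NumericMatrix coordination_cpp(NumericMatrix coords, double r0,
                               bool sorted) {
  const int n = coords.nrow();
  if (coords.ncol() != 2 * N_LJ)
    stop("coords must have 14 columns (x1..x7, y1..y7)");
  NumericMatrix out(n, N_LJ);
  for (int f = 0; f < n; ++f) {
    double c[N_LJ];
    for (int i = 0; i < N_LJ; ++i) c[i] = 0.0;
    for (int i = 0; i < N_LJ; ++i) {
      for (int j = i + 1; j < N_LJ; ++j) {
        const double dx = coords(f, i) - coords(f, j);
        const double dy = coords(f, N_LJ + i) - coords(f, N_LJ + j);
        const double x2 = (dx * dx + dy * dy) / (r0 * r0);
        const double x8 = x2 * x2 * x2 * x2;
        const double w = 1.0 / (1.0 + x8);
        c[i] += w; c[j] += w;
      }
    }
    if (sorted) std::sort(c, c + N_LJ, std::greater<double>());
    for (int i = 0; i < N_LJ; ++i) out(f, i) = c[i];
  }
  return out;
}
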