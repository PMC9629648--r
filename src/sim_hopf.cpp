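#include <Rcpp.h>
using namespace Rcpp;

// Coupled Stuart-Landau whole-brain integrator.
//
// Drift per node i (cartesian coordinates, z = x + iy):
//   dx = a*x + (x^2+y^2)*(beta*y - x) - omega*y + G*sum_j C_ij (x_j - x_i)
//   dy = a*y - (x^2+y^2)*(beta*x + y) + omega*x + G*sum_j C_ij (y_j - y_i)
// plus additive periodic forcing F0_j*(cos(wf t), sin(wf t)) while the
// schedule is on, and additive Gaussian noise of SD nu in each coordinate.
//
// Time stepping is the stochastic Heun scheme (deterministic RK2 trapezoidal
// drift, additive noise): an explicit Euler-Maruyama step is unstable at
// usable step sizes in the supercritical regime with large shear, where the
// amplitude-dependent rotation omega - beta*r^2 is fast. Heun keeps the
// published working points (beta up to 6) stable at dt ~ TR/16.
//
// Noise comes from the R RNG, so runs are reproducible under set.seed().
// `sub` substeps are taken per output volume; the state at the end of each
// volume is recorded. Returns diverged = true with the offending
// volume/node when |z| exceeds `guard`.

static inline void drift(const int N, const double *x, const double *y,
                         const double *a, const double *omega,
                         const double beta, const double G,
                         const double *cdat, const double *rs,
                         const bool on, const double *F0, const double *wf,
                         const double t, double *dx, double *dy) {
  for (int i = 0; i < N; ++i) {
    const double *ci = cdat + static_cast<size_t>(i) * N; // C symmetric:
    double sx = 0.0, sy = 0.0;                            // column i == row i
    for (int j = 0; j < N; ++j) {
      sx += ci[j] * x[j];
      sy += ci[j] * y[j];
    }
    const double r2 = x[i] * x[i] + y[i] * y[i];
    double fx = 0.0, fy = 0.0;
    if (on && F0[i] > 0.0) {
      fx = F0[i] * std::cos(wf[i] * t);
      fy = F0[i] * std::sin(wf[i] * t);
    }
    dx[i] = a[i] * x[i] + r2 * (beta * y[i] - x[i]) - omega[i] * y[i] +
      G * (sx - rs[i] * x[i]) + fx;
    dy[i] = a[i] * y[i] - r2 * (beta * x[i] + y[i]) + omega[i] * x[i] +
      G * (sy - rs[i] * y[i]) + fy;
  }
}

// [[Rcpp::export]]
List sim_hopf_cpp(NumericVector a, NumericVector omega, double beta, double G,
                  NumericMatrix C, double nu, double dt, int sub, int n_total,
                  NumericVector x0, NumericVector y0,
                  NumericVector F0, NumericVector omega_f,
                  LogicalVector forcing_on, double guard, bool shared_noise) {
  const int N = a.size();
  NumericMatrix X(N, n_total), Y(N, n_total);
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> rs(N), d1x(N), d1y(N), d2x(N), d2y(N), xp(N), yp(N),
    ex(N), ey(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int j = 0; j < N; ++j) s += C(i, j);
    rs[i] = s;
  }
  const double sq = std::sqrt(dt);
  const double g2 = guard * guard;
  const double *cdat = C.begin();
  bool any_force = false;
  for (int i = 0; i < N; ++i)
    if (F0[i] > 0.0) { any_force = true; break; }
  double t = 0.0;
  for (int v = 0; v < n_total; ++v) {
    const bool on = any_force && forcing_on[v];
    for (int s = 0; s < sub; ++s) {
      {
        NumericVector e1 = rnorm(N);
        NumericVector e2 = shared_noise ? e1 : rnorm(N);
        for (int i = 0; i < N; ++i) {
          ex[i] = sq * nu * e1[i];
          ey[i] = sq * nu * e2[i];
        }
      }
      drift(N, x.data(), y.data(), a.begin(), omega.begin(), beta, G, cdat,
            rs.data(), on, F0.begin(), omega_f.begin(), t,
            d1x.data(), d1y.data());
      for (int i = 0; i < N; ++i) {
        xp[i] = x[i] + dt * d1x[i] + ex[i];
        yp[i] = y[i] + dt * d1y[i] + ey[i];
      }
      drift(N, xp.data(), yp.data(), a.begin(), omega.begin(), beta, G, cdat,
            rs.data(), on, F0.begin(), omega_f.begin(), t + dt,
            d2x.data(), d2y.data());
      bool bad = false;
      for (int i = 0; i < N; ++i) {
        x[i] += 0.5 * dt * (d1x[i] + d2x[i]) + ex[i];
        y[i] += 0.5 * dt * (d1y[i] + d2y[i]) + ey[i];
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
            x[i] * x[i] + y[i] * y[i] > g2)
          bad = true;
      }
      if (bad) {
        int node = 1;
        double worst = -1.0;
        for (int i = 0; i < N; ++i) {
          double r2 = x[i] * x[i] + y[i] * y[i];
          if (!std::isfinite(r2)) r2 = R_PosInf;
          if (r2 > worst) { worst = r2; node = i + 1; }
        }
        return List::create(_["diverged"] = true, _["volume"] = v + 1,
                            _["node"] = node);
      }
      t += dt;
    }
    for (int i = 0; i < N; ++i) {
      X(i, v) = x[i];
      Y(i, v) = y[i];
    }
  }
  return List::create(_["diverged"] = false, _["x"] = X, _["y"] = Y);
}
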