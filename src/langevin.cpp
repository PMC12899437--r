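#include <Rcpp.h>
using namespace Rcpp;

// minimal-image wrap to (-180, 180]
static inline double wrapdeg(double x) {
  x = x - 360.0 * std::floor((x + 180.0) / 360.0);
  if (x == -180.0) x = 180.0;
  return x;
}

// nearest-center bin index (0-based) on an nbins grid with centers at
// -180 + j * width
static inline int binof(double x, double width, int nbins) {
  int j = (int)std::lround((x + 180.0) / width);
  j %= nbins;
  if (j < 0) j += nbins;
  return j;
}

// Overdamped Langevin (Euler-Maruyama) on a periodic 2D von-Mises-well
// potential, with the real coordinate z harmonically coupled to an
// extended coordinate lambda; optional eABF bias on lambda. Accumulates
// per-bin statistics for the adaptive bias and the CZAR estimator.
// State matrices are modified in place (caller passes fresh copies).
// [[Rcpp::export]]
List langevin_eabf_cpp(NumericMatrix wells, double offset,
                       double z_phi, double z_psi,
                       double l_phi, double l_psi,
                       int n_steps, double dt, double friction,
                       double temperature, double k_ext, bool eabf,
                       int nbins, double width, int n_full, int stride,
                       IntegerMatrix count_lambda,
                       NumericMatrix sum_spring_phi,
                       NumericMatrix sum_spring_psi,
                       IntegerMatrix count_z,
                       NumericMatrix sum_dlambda_phi,
                       NumericMatrix sum_dlambda_psi) {
  const double kB = 0.0019872041;
  const double kT = kB * temperature;
  const double deg = M_PI / 180.0;
  const int nw = wells.nrow();
  const double mob = dt / friction;
  const double sigma = std::sqrt(2.0 * kT * dt / friction);
  const int n_out = n_steps / stride;
  NumericMatrix traj(n_out, 7);
  int iout = 0;

  for (int step = 0; step < n_steps; ++step) {
    // potential gradient at z (kcal/mol/deg)
    double gx = 0.0, gy = 0.0;
    for (int w = 0; w < nw; ++w) {
      double dx = (z_phi - wells(w, 0)) * deg;
      double dy = (z_psi - wells(w, 1)) * deg;
      double e = std::exp(wells(w, 3) * (std::cos(dx) + std::cos(dy) - 2.0));
      gx += wells(w, 2) * wells(w, 3) * std::sin(dx) * e * deg;
      gy += wells(w, 2) * wells(w, 3) * std::sin(dy) * e * deg;
    }
    // spring force on z from lambda (minimal image)
    double fs_phi = k_ext * wrapdeg(l_phi - z_phi);
    double fs_psi = k_ext * wrapdeg(l_psi - z_psi);
    if (!std::isfinite(gx) || !std::isfinite(gy))
      stop("langevin_eabf_cpp: non-finite potential force at step %d", step);

    // accumulate statistics at the current sample
    int bi = binof(z_phi, width, nbins), bj = binof(z_psi, width, nbins);
    int li = binof(l_phi, width, nbins), lj = binof(l_psi, width, nbins);
    count_z(bi, bj) += 1;
    sum_dlambda_phi(bi, bj) += wrapdeg(l_phi - z_phi);
    sum_dlambda_psi(bi, bj) += wrapdeg(l_psi - z_psi);
    count_lambda(li, lj) += 1;
    sum_spring_phi(li, lj) += fs_phi;
    sum_spring_psi(li, lj) += fs_psi;

    if (step % stride == 0 && iout < n_out) {
      traj(iout, 0) = step;
      traj(iout, 1) = z_phi;  traj(iout, 2) = z_psi;
      traj(iout, 3) = l_phi;  traj(iout, 4) = l_psi;
      traj(iout, 5) = fs_phi; traj(iout, 6) = fs_psi;
      ++iout;
    }

    // bias force on lambda from the running mean spring force
    double fb_phi = 0.0, fb_psi = 0.0;
    if (eabf) {
      int nsmp = count_lambda(li, lj);
      if (nsmp > 0) {
        double ramp = nsmp < n_full ? (double)nsmp / n_full : 1.0;
        fb_phi = ramp * sum_spring_phi(li, lj) / nsmp;
        fb_psi = ramp * sum_spring_psi(li, lj) / nsmp;
      }
    }

    // Euler-Maruyama updates; spring force on lambda is minus that on z
    z_phi = wrapdeg(z_phi + mob * (-gx + fs_phi) + sigma * norm_rand());
    z_psi = wrapdeg(z_psi + mob * (-gy + fs_psi) + sigma * norm_rand());
    l_phi = wrapdeg(l_phi + mob * (-fs_phi + fb_phi) + sigma * norm_rand());
    l_psi = wrapdeg(l_psi + mob * (-fs_psi + fb_psi) + sigma * norm_rand());
  }

  return List::create(_["traj"] = traj,
                      _["z"] = NumericVector::create(z_phi, z_psi),
                      _["lambda"] = NumericVector::create(l_phi, l_psi));
}
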