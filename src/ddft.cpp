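#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Carnahan-Starling excess chemical potential (k_B T units)
static inline double mu_ex_cs(double phi) {
  double om = 1.0 - phi;
  return (8.0 * phi - 9.0 * phi * phi + 3.0 * phi * phi * phi) / (om * om * om);
}

// Conservative finite-volume integrator for the radial drift-diffusion
// (Smoluchowski) continuity equation in spherical symmetry,
//   drho/dt = -(1/r^2) d(r^2 J)/dr,
//   J = -D_eff(r) [ drho/dr + rho d(beta u_eff + beta mu_ex)/dr ],
// with the drift handled through the exponential (Boltzmann-exact) flux
//   A J = -g e^{-psi_f} (rho_j e^{psi_j} - rho_i e^{psi_i}),
// so that rho ~ e^{-psi} is a discrete equilibrium. psi includes the lagged
// excess chemical potential. Zero flux at r = 0; outer boundary absorbing
// (ghost density 0, absorbed flux accumulated) or reflecting.
//
// scheme: 0 = explicit Euler (fixed dt), 1 = implicit backward Euler
// (tridiagonal Thomas solve, dt allowed to grow as dt <= dt_growth * t).
// [[Rcpp::export]]
List ddft_integrate_cpp(NumericVector faces, NumericVector centers,
                        NumericVector volumes, NumericVector D_face,
                        NumericVector psi_ext, double psi_ext_R,
                        NumericVector rho_init, double vol_mol,
                        bool include_excess, int scheme, double dt0,
                        double dt_growth, double t_max, double f_stop,
                        bool absorbing, LogicalVector inside,
                        double store_factor, int snapshot_every) {
  const int n = centers.size();
  if (faces.size() != n + 1 || volumes.size() != n || psi_ext.size() != n ||
      rho_init.size() != n || inside.size() != n || D_face.size() != n + 1)
    stop("inconsistent grid/field lengths");

  std::vector<double> rho(rho_init.begin(), rho_init.end());
  std::vector<double> psi(n), g(n + 1), em(n + 1), ep(n + 1);
  std::vector<double> aa(n), bb(n), cc(n), dd(n), cp(n), dp(n), rho_new(n);

  // geometric face coefficients g_j = D_j A_j / dx_j
  for (int j = 1; j < n; ++j) {
    double A = 4.0 * M_PI * faces[j] * faces[j];
    g[j] = D_face[j] * A / (centers[j] - centers[j - 1]);
  }
  g[0] = 0.0;
  {
    double R = faces[n];
    double A = 4.0 * M_PI * R * R;
    g[n] = absorbing ? D_face[n] * A / (R - centers[n - 1]) : 0.0;
  }

  double N0 = 0.0, mass_in0 = 0.0;
  for (int i = 0; i < n; ++i) {
    N0 += rho[i] * volumes[i];
    if (inside[i]) mass_in0 += rho[i] * volumes[i];
  }
  if (N0 <= 0) stop("empty initial condition");
  const double rho_scale = *std::max_element(rho.begin(), rho.end());

  std::vector<double> t_out, f_out, mass_out;
  List snaps;
  std::vector<double> snap_times;

  double t = 0.0, dt = dt0, released = 0.0;
  double next_store = 0.0;  // store the very first step
  long step = 0;
  int stored = 0;
  bool complete = false;
  double f_rel = 0.0;

  // explicit stability bound (row-sum criterion incl. drift weights is
  // state-dependent; check the pure-diffusion bound up front and the full
  // one each step)
  while (t < t_max) {
    // psi at centers (external potential + lagged excess term)
    for (int i = 0; i < n; ++i) {
      double p = psi_ext[i];
      if (include_excess && vol_mol > 0.0) {
        double phi = vol_mol * rho[i];
        if (phi >= 1.0)
          stop("local packing fraction reached 1 at step %ld (jamming: model invalid)", step);
        p += mu_ex_cs(phi);
      }
      psi[i] = p;
    }
    for (int j = 1; j < n; ++j) {
      double dpsi = psi[j] - psi[j - 1];
      em[j] = std::exp(-0.5 * dpsi);
      ep[j] = std::exp(0.5 * dpsi);
    }
    if (g[n] > 0.0) {
      double dpsi = psi_ext_R - psi[n - 1];
      em[n] = std::exp(-0.5 * dpsi);
      ep[n] = std::exp(0.5 * dpsi);
    } else {
      em[n] = ep[n] = 0.0;
    }

    if (scheme == 0) {
      // stability: explicit Euler needs dt * rowsum/V < 1
      double bound = R_PosInf;
      for (int i = 0; i < n; ++i) {
        double out_w = g[i] * ep[i] + g[i + 1] * em[i + 1];
        if (out_w > 0) bound = std::min(bound, volumes[i] / out_w);
      }
      if (dt >= bound)
        stop("explicit time step dt = %g violates the stability bound %g "
             "(use a smaller dt or the implicit scheme)", dt, bound);
      double F_prev = 0.0;  // A*J through face i (outward positive)
      for (int i = 0; i < n; ++i) {
        double F_next;
        if (i + 1 < n)
          F_next = g[i + 1] * (em[i + 1] * rho[i] - ep[i + 1] * rho[i + 1]);
        else
          F_next = g[n] * em[n] * rho[i];  // ghost density 0 beyond R
        rho_new[i] = rho[i] + dt / volumes[i] * (F_prev - F_next);
        F_prev = F_next;
        if (i == n - 1) released += F_next * dt;
      }
      rho.swap(rho_new);
    } else {
      // backward Euler: (I - dt L) rho_new = rho
      for (int i = 0; i < n; ++i) {
        double w = dt / volumes[i];
        aa[i] = (i > 0) ? -w * g[i] * em[i] : 0.0;
        double out_w = g[i] * ep[i] + g[i + 1] * em[i + 1];
        bb[i] = 1.0 + w * out_w;
        cc[i] = (i + 1 < n) ? -w * g[i + 1] * ep[i + 1] : 0.0;
        dd[i] = rho[i];
      }
      // Thomas algorithm
      cp[0] = cc[0] / bb[0];
      dp[0] = dd[0] / bb[0];
      for (int i = 1; i < n; ++i) {
        double m = bb[i] - aa[i] * cp[i - 1];
        cp[i] = cc[i] / m;
        dp[i] = (dd[i] - aa[i] * dp[i - 1]) / m;
      }
      rho[n - 1] = dp[n - 1];
      for (int i = n - 2; i >= 0; --i) rho[i] = dp[i] - cp[i] * rho[i + 1];
      released += g[n] * em[n] * rho[n - 1] * dt;
    }

    // positivity
    for (int i = 0; i < n; ++i) {
      if (rho[i] < -1e-12 * rho_scale)
        stop("negative density %g in cell %d at step %ld: numerical failure",
             rho[i], i + 1, step);
      if (rho[i] < 0.0) rho[i] = 0.0;
    }

    t += dt;
    ++step;
    if (scheme == 1 && dt_growth > 0.0)
      dt = std::min(1.25 * dt, std::max(dt0, dt_growth * t));

    double mass_in = 0.0, mass_tot = 0.0;
    for (int i = 0; i < n; ++i) {
      mass_tot += rho[i] * volumes[i];
      if (inside[i]) mass_in += rho[i] * volumes[i];
    }
    f_rel = 1.0 - mass_in / N0;
    bool done = (f_rel >= f_stop) || (t + 0.5 * dt >= t_max);

    if (t >= next_store || done) {
      t_out.push_back(t);
      f_out.push_back(f_rel);
      mass_out.push_back(mass_tot + released);
      ++stored;
      next_store = (next_store <= 0.0) ? t * store_factor : t * store_factor;
      if (snapshot_every > 0 && (stored % snapshot_every == 0 || done)) {
        snaps.push_back(NumericVector(rho.begin(), rho.end()));
        snap_times.push_back(t);
      }
      if (step % 100000 == 0) Rcpp::checkUserInterrupt();
    }
    if (done) {
      complete = (f_rel >= f_stop);
      break;
    }
  }

  return List::create(
      _["times"] = NumericVector(t_out.begin(), t_out.end()),
      _["f_rel"] = NumericVector(f_out.begin(), f_out.end()),
      _["mass_total"] = NumericVector(mass_out.begin(), mass_out.end()),
      _["released"] = released, _["N0"] = N0,
      _["density"] = NumericVector(rho.begin(), rho.end()),
      _["time"] = t, _["steps"] = (double)step, _["complete"] = complete,
      _["snapshots"] = snaps,
      _["snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end()));
}
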