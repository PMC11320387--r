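#' Solver configuration for the release integrator
#'
#' @param scheme `"explicit"` (forward Euler, fixed time step; the fidelity
#'   default) or `"implicit"` (backward Euler with a lagged excess term and
#'   a slowly growing time step, unconditionally stable; use for slow
#'   molecules).
#' @param dt Initial time step in units of tau0 = l0^2 / D_w (l0 = 1 nm).
#'   Default 1e-4. For the explicit scheme this is the fixed step and must
#'   satisfy dt < dr_min^2 / (2 D_max); the solver refuses otherwise.
#' @param dt_growth For the implicit scheme, the time step is allowed to
#'   grow up to `dt_growth * t` (relative temporal resolution). Default
#'   0.002 (0.2% of elapsed time). Ignored by the explicit scheme.
#' @param t_max Integration horizon (tau0 units). `NULL` (default) picks
#'   `200 x` the analytic half-release estimate.
#' @param f_stop Stop once this released fraction is reached. Default 0.99.
#' @param outer_bc `"absorbing"` (default; infinite-dilution sink at R,
#'   absorbed flux accumulated) or `"reflecting"` (closed cell, for
#'   conservation and equilibrium checks).
#' @param include_excess Include the Carnahan-Starling excluded-volume
#'   excess chemical potential (needs the molecule's Stokes radius)?
#'   Default TRUE.
#' @param store_factor Successive stored frames are spaced by this factor
#'   in time. Default 1.02.
#' @param snapshot_every Store a full density snapshot every k-th frame
#'   (0 = never).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(scheme = c("explicit", "implicit"), dt = 1e-4,
                          dt_growth = 0.002, t_max = NULL, f_stop = 0.99,
                          outer_bc = c("absorbing", "reflecting"),
                          include_excess = TRUE, store_factor = 1.02,
                          snapshot_every = 0L) {
  scheme <- match.arg(scheme)
  outer_bc <- match.arg(outer_bc)
  stopifnot(dt > 0, f_stop > 0, f_stop <= 1, store_factor > 1,
            is.null(t_max) || t_max > 0)
  structure(list(scheme = scheme, dt = dt, dt_growth = dt_growth,
                 t_max = t_max, f_stop = f_stop, outer_bc = outer_bc,
                 include_excess = include_excess, store_factor = store_factor,
                 snapshot_every = as.integer(snapshot_every)),
            class = "solver_config")
}

#' Local packing fraction of cargo molecules
#'
#' phi = (4 pi / 3) a_w^3 rho, treating each molecule as a hard sphere of
#' its Stokes radius. Values at or above 1 signal jamming, outside the
#' model's validity.
#'
#' @param density Number density (nm^-3), non-negative.
#' @param a_w Stokes radius (nm).
#' @return Dimensionless volume fraction.
#' @export
local_packing_fraction <- function(density, a_w) {
  stopifnot(all(density >= 0), a_w > 0)
  phi <- 4 * pi / 3 * a_w^3 * density
  if (any(phi >= 1)) {
    stop("packing fraction >= 1: jammed state outside model validity",
         call. = FALSE)
  }
  phi
}

#' Carnahan-Starling excess chemical potential
#'
#' Hard-sphere excluded-volume contribution to the chemical potential,
#' \deqn{\beta\mu_{ex}(\phi) = \frac{8\phi - 9\phi^2 + 3\phi^3}{(1-\phi)^3},}
#' vanishing as phi -> 0 (with second-virial slope 8) and strictly
#' increasing.
#'
#' @param phi Packing fraction in \[0, 1).
#' @return beta * mu_ex, dimensionless.
#' @export
excess_chemical_potential <- function(phi) {
  if (any(phi < 0) || any(phi >= 1)) {
    stop("packing fraction must lie in [0, 1)", call. = FALSE)
  }
  (8 * phi - 9 * phi^2 + 3 * phi^3) / (1 - phi)^3
}

#' Molar concentration to number density
#'
#' @param conc_M Concentration in mol/L.
#' @return Number density in nm^-3 (1 M = 0.6022 nm^-3).
#' @export
molar_to_number_density <- function(conc_M) conc_M * 6.02214076e23 * 1e-24

#' Initial cargo distribution
#'
#' Loads the microgel uniformly: density `rho0` in every cell whose center
#' lies at r <= b, zero outside (a sharp step at the particle radius). Set
#' `smooth = TRUE` for the optional smoothed variant rho0 * f(r).
#'
#' @param grid A [build_grid()] result.
#' @param gel A [microgel_spec()].
#' @param rho0 Initial interior number density (nm^-3), positive.
#' @param smooth Use rho0 * f(r) instead of the sharp step? Default FALSE.
#' @return An object of class `cargo_state`: fields `time` (tau0 units),
#'   `density` (per cell, nm^-3), `released` (absorbed molecule count) and
#'   `N0` (initially encapsulated count).
#' @export
initial_condition <- function(grid, gel, rho0, smooth = FALSE) {
  stopifnot(rho0 > 0)
  r <- grid$cell_centers
  density <- if (smooth) rho0 * interface_profile(r, gel) else
    ifelse(r <= gel$b, rho0, 0)
  structure(list(time = 0, density = density, released = 0,
                 N0 = sum(density * grid$shell_volumes)),
            class = "cargo_state")
}

# shared marshalling for the C++ integrator; molecule only needs
# Dstar_over_Dw, beta_dG and (optionally) a_w
ddft_call <- function(state, grid, gel, molecule, config, t_max, f_stop) {
  D_star <- molecule$Dstar_over_Dw  # time unit tau0 => D_w = 1
  D_face <- effective_diffusion(grid$cell_faces, gel, D_star, 1)
  psi <- effective_potential(grid$cell_centers, gel)
  vol_mol <- if (!is.na(molecule$a_w)) 4 * pi / 3 * molecule$a_w^3 else 0
  inside <- grid$cell_centers <= gel$b + 2 * gel$delta
  ddft_integrate_cpp(
    faces = grid$cell_faces, centers = grid$cell_centers,
    volumes = grid$shell_volumes, D_face = D_face, psi_ext = psi,
    psi_ext_R = effective_potential(grid$R, gel), rho_init = state$density,
    vol_mol = vol_mol, include_excess = config$include_excess,
    scheme = if (config$scheme == "explicit") 0L else 1L,
    dt0 = config$dt, dt_growth = config$dt_growth, t_max = t_max,
    f_stop = f_stop, absorbing = config$outer_bc == "absorbing",
    inside = inside, store_factor = config$store_factor,
    snapshot_every = config$snapshot_every)
}

#' Advance the cargo density by one time step
#'
#' Single conservative finite-volume step of the DDFT continuity equation.
#' Mainly useful for testing and inspection; use [run_release()] for full
#' release curves.
#'
#' @param state A [initial_condition()] result (or previous step output).
#' @param grid,gel,molecule,config As in [run_release()].
#' @return An updated `cargo_state`.
#' @export
ddft_step <- function(state, grid, gel, molecule, config = solver_config()) {
  res <- ddft_call(state, grid, gel, molecule, config,
                   t_max = config$dt, f_stop = 2)
  structure(list(time = state$time + res$time, density = res$density,
                 released = state$released + res$released, N0 = state$N0),
            class = "cargo_state")
}

#' Simulate a full release experiment
#'
#' Integrates the DDFT continuity equation for the cargo density from the
#' uniformly loaded initial state until the released fraction reaches
#' `f_stop` (or `t_max`). A molecule is counted as released once it is past
#' the outer edge of the interface, r > b + 2*delta. Internally all times
#' are in units of tau0 = l0^2 / D_w with l0 = 1 nm; if the molecule's bulk
#' diffusivity is known (via its Stokes radius) times are also reported in
#' ns.
#'
#' @param gel A [microgel_spec()]; its `beta_dG` is overridden by the
#'   molecule's.
#' @param molecule A [molecule_spec()] (or registry symbol string).
#' @param grid A [build_grid()] result; defaults to the standard nonuniform
#'   grid for `gel`.
#' @param config A [solver_config()].
#' @param rho0 Initial interior number density (nm^-3). Default 0.01 M.
#' @return A `release_trajectory`: data.frame-like object with fields
#'   `times` (tau0 units), `times_ns` (or NA), `f_rel`, plus attributes
#'   `N0`, `complete`, `mass_total`, `molecule`, `gel`, `config`,
#'   `snapshots`.
#' @examples
#' \donttest{
#' gel <- microgel_spec(b = 25)
#' traj <- run_release(gel, "He", config = solver_config("implicit"))
#' half_release_time(traj)
#' }
#' @export
run_release <- function(gel, molecule, grid = build_grid(gel),
                        config = solver_config(), rho0 = molar_to_number_density(0.01)) {
  if (is.character(molecule)) molecule <- registry_lookup(molecule)
  gel <- microgel_spec(b = gel$b, delta = gel$delta, phi_p0 = gel$phi_p0,
                       beta_dG = molecule$beta_dG, R_over_b = gel$R_over_b)
  state <- initial_condition(grid, gel, rho0)
  t_max <- config$t_max
  if (is.null(t_max)) {
    est <- analytic_half_release_time(gel$b, D_star = molecule$Dstar_over_Dw,
                                      D_w = 1, beta_dG = molecule$beta_dG)
    t_max <- 200 * est
  }
  res <- ddft_call(state, grid, gel, molecule, config, t_max = t_max,
                   f_stop = config$f_stop)
  tau0_ns <- if (!is.na(molecule$D_w)) 1 / molecule$D_w else NA_real_
  structure(list(times = res$times, times_ns = res$times * tau0_ns,
                 f_rel = res$f_rel),
            N0 = res$N0, complete = res$complete,
            mass_total = res$mass_total, released = res$released,
            final_density = res$density, steps = res$steps,
            snapshots = res$snapshots, snapshot_times = res$snapshot_times,
            tau0_ns = tau0_ns, molecule = molecule, gel = gel,
            config = config, grid = grid,
            class = "release_trajectory")
}

#' @export
print.release_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "<release trajectory: %d frames, t up to %.4g tau0, f_rel up to %.4f%s>\n",
    n, x$times[n], x$f_rel[n],
    if (isTRUE(attr(x, "complete"))) "" else " (incomplete)"))
  invisible(x)
}

#' Half-release time from a trajectory
#'
#' Time at which half of the initially encapsulated cargo has been
#' released, by linear interpolation between the bracketing stored frames.
#'
#' @param traj A [run_release()] trajectory.
#' @param units `"tau0"` (default) or `"ns"` (requires a known D_w).
#' @return tau_1/2 in the requested units.
#' @export
half_release_time <- function(traj, units = c("tau0", "ns")) {
  units <- match.arg(units)
  t <- c(0, traj$times)
  f <- c(0, traj$f_rel)
  if (max(f) < 0.5) {
    stop(sprintf("trajectory never reaches f_rel = 0.5 (max %.4f)", max(f)),
         call. = FALSE)
  }
  i <- which(f >= 0.5)[1]
  tau <- if (f[i] == 0.5) t[i] else
    t[i - 1] + (0.5 - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
  if (units == "ns") {
    tau0_ns <- attr(traj, "tau0_ns")
    if (is.na(tau0_ns)) stop("D_w unknown: cannot convert to ns", call. = FALSE)
    tau <- tau * tau0_ns
  }
  tau
}

#' Mean release time from a trajectory
#'
#' First moment of the release-rate distribution, computed by parts as
#' `integral of (1 - f_rel) dt` (trapezoidal rule) plus an exponential tail
#' correction beyond the last stored frame (the absorbing-boundary decay is
#' asymptotically exponential).
#'
#' @param traj A [run_release()] trajectory with `f_rel` reaching at least
#'   0.99 (or set `allow_incomplete = TRUE`).
#' @param allow_incomplete Extrapolate even if the trajectory stops short
#'   of f_rel = 0.99.
#' @param units `"tau0"` (default) or `"ns"`.
#' @return Mean release time, positive.
#' @export
mean_release_time <- function(traj, allow_incomplete = FALSE,
                              units = c("tau0", "ns")) {
  units <- match.arg(units)
  t <- c(0, traj$times)
  f <- pmin(c(0, traj$f_rel), 1)
  n <- length(t)
  if (f[n] < 0.99 && !allow_incomplete) {
    stop("trajectory incomplete (f_rel < 0.99); rerun with a larger t_max ",
         "or set allow_incomplete = TRUE", call. = FALSE)
  }
  s <- 1 - f
  core <- sum(diff(t) * (s[-1] + s[-n]) / 2)
  # exponential tail: decay rate from the last e-fold of stored survival
  tail_int <- 0
  if (s[n] > 0) {
    j <- which(s <= exp(1) * s[n] & s > s[n])
    j <- if (length(j)) j[1] else n - 1
    rate <- log(s[j] / s[n]) / (t[n] - t[j])
    tail_int <- if (is.finite(rate) && rate > 0) s[n] / rate else 0
  }
  tau <- core + tail_int
  if (units == "ns") {
    tau0_ns <- attr(traj, "tau0_ns")
    if (is.na(tau0_ns)) stop("D_w unknown: cannot convert to ns", call. = FALSE)
    tau <- tau * tau0_ns
  }
  tau
}

#' Export a release trajectory as CSV
#'
#' @param traj A [run_release()] trajectory.
#' @param file Output path.
#' @return The written data.frame, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  out <- data.frame(t_over_tau0 = traj$times, t_ns = traj$times_ns,
                    f_rel = traj$f_rel)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
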