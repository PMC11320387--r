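test_that("packing fraction and Carnahan-Starling term behave as stated", {
  expect_equal(local_packing_fraction(0, 0.1), 0)
  expect_equal(local_packing_fraction(6.022e-3, 0.114),
               4 * pi / 3 * 0.114^3 * 6.022e-3, tolerance = 1e-12)
  expect_lt(abs(local_packing_fraction(6.022e-3, 0.114) - 3.7e-5), 1e-6)
  expect_equal(local_packing_fraction(c(1, 2) * 1e-3, 0.1),
               2 * local_packing_fraction(c(0.5, 1) * 1e-3, 0.1))
  expect_error(local_packing_fraction(10, 1), "jammed")

  expect_equal(excess_chemical_potential(0), 0)
  # second-virial limit: slope 8 as phi -> 0 (series of the CS form)
  expect_equal(excess_chemical_potential(1e-7) / 1e-7, 8, tolerance = 1e-5)
  phi <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(excess_chemical_potential(phi)) > 0))
  expect_error(excess_chemical_potential(1), "\\[0, 1\\)")
})

test_that("the initial condition is a uniform step holding N0 molecules", {
  gel <- microgel_spec(b = 50)
  g <- build_grid(gel)
  rho0 <- molar_to_number_density(0.01)
  expect_equal(rho0, 6.022e-3, tolerance = 1e-4)
  st <- initial_condition(g, gel, rho0)
  expect_equal(st$time, 0)
  expect_equal(st$released, 0)
  # quadrature of the step agrees with the sphere volume to one cell
  cell_vol <- max(g$shell_volumes)
  expect_lt(abs(st$N0 - rho0 * 4 * pi / 3 * 50^3), rho0 * cell_vol)
  expect_true(all(st$density[g$cell_centers > 50] == 0))
  expect_true(all(st$density[g$cell_centers <= 50] == rho0))
})

test_that("a uniform potential-free state is a fixed point with reflecting walls", {
  gel <- microgel_spec(b = 10, beta_dG = 0, R_over_b = 4)
  g <- build_grid(gel, dr_fine = 0.1)
  mol <- toy_molecule(1, 0)  # uniform diffusivity
  st <- initial_condition(g, gel, 1e-3)
  st$density[] <- 1e-3  # uniform everywhere
  cfg <- solver_config("explicit", dt = 1e-3, outer_bc = "reflecting")
  st2 <- ddft_step(st, g, gel, mol, cfg)
  expect_equal(st2$density, st$density, tolerance = 1e-13)
  expect_equal(st2$released, 0)
})

test_that("total cargo is conserved in flux form", {
  gel <- microgel_spec(b = 10, beta_dG = -2, R_over_b = 4)
  g <- build_grid(gel, dr_fine = 0.05)
  mol <- toy_molecule(0.1, -2)
  # reflecting: interior mass constant over the whole run
  cfg <- solver_config("implicit", dt = 1e-3, dt_growth = 0.002,
                       t_max = 2e3, f_stop = 1, outer_bc = "reflecting")
  traj <- run_release(gel, mol, g, cfg)
  mt <- attr(traj, "mass_total")
  expect_lt(max(abs(mt - mt[1])) / mt[1], 1e-8)
  # absorbing: interior + absorbed constant
  cfgE <- solver_config("explicit", dt = 1e-3, t_max = 10, f_stop = 1)
  gE <- build_grid(gel, dr_fine = 0.1)
  trajE <- run_release(gel, mol, gE, cfgE)
  mtE <- attr(trajE, "mass_total")
  expect_lt(max(abs(mtE - mtE[1])) / mtE[1], 1e-8)
})

test_that("potential-free release matches the eigenfunction-series solution", {
  b <- 10; R <- 100
  gel <- microgel_spec(b = b, delta = 1, beta_dG = 0, R_over_b = R / b)
  mol <- toy_molecule(1, 0)  # D uniform; interface has no effect
  g <- build_grid(gel, dr_fine = 0.05, dr_coarse = 0.1)
  cfg <- solver_config("explicit", dt = 1e-3, t_max = 120, f_stop = 1,
                       store_factor = 1.01)
  traj <- run_release(gel, mol, g, cfg)
  rho0 <- molar_to_number_density(0.01)
  N0 <- 4 * pi / 3 * b^3 * rho0
  for (tt in c(5, 20, 50, 100)) {
    i <- which.min(abs(traj$times - tt))
    f_oracle <- 1 - series_mass_inside(traj$times[i], b, R, 1, rho0,
                                       redge = b + 2) / N0
    expect_equal(traj$f_rel[i], f_oracle, tolerance = 1e-3)
  }
})

test_that("reflecting equilibrium recovers the Boltzmann partition ratio", {
  gel <- microgel_spec(b = 10, delta = 1, beta_dG = -2, R_over_b = 3)
  mol <- toy_molecule(0.5, -2)
  g <- build_grid(gel, dr_fine = 0.05, dr_coarse = 0.2)
  cfg <- solver_config("implicit", dt = 1e-3, dt_growth = 0.002, t_max = 5e4,
                       f_stop = 1, outer_bc = "reflecting")
  traj <- run_release(gel, mol, g, cfg)
  rho <- attr(traj, "final_density")
  r <- g$cell_centers
  ratio <- mean(rho[r < 5]) / mean(rho[r > 25])
  expect_equal(ratio, exp(2), tolerance = 0.01)
})

test_that("release curves are monotone, complete, and free-energy ordered", {
  gel <- microgel_spec(b = 10)
  g <- build_grid(gel)
  cfg <- solver_config("implicit", dt = 1e-4, dt_growth = 0.002)
  tr0 <- run_release(gel, toy_molecule(0.1, 0), g, cfg)
  tr3 <- run_release(gel, toy_molecule(0.1, -3), g, cfg)
  expect_true(all(diff(tr0$f_rel) >= -1e-12))
  expect_true(attr(tr0, "complete"))
  expect_gte(max(tr0$f_rel), 0.99)
  # an attractive network slows the release down
  expect_gt(half_release_time(tr3), 2 * half_release_time(tr0))
})

test_that("the explicit scheme enforces its stability bound", {
  gel <- microgel_spec(b = 10)
  g <- build_grid(gel)  # dr_min = 0.02 => bound 2e-4 at D_max = 1
  cfg <- solver_config("explicit", dt = 5e-3)
  expect_error(run_release(gel, toy_molecule(0.5, 0), g, cfg),
               "stability bound")
})

test_that("explicit and implicit stepping agree on the half-release time", {
  gel <- microgel_spec(b = 10, beta_dG = -1)
  mol <- toy_molecule(0.1, -1)
  g <- build_grid(gel, dr_fine = 0.1, dr_coarse = 0.3)
  tE <- half_release_time(run_release(gel, mol, g,
    solver_config("explicit", dt = 2e-3, f_stop = 0.6)))
  tI <- half_release_time(run_release(gel, mol, g,
    solver_config("implicit", dt = 1e-4, dt_growth = 0.001, f_stop = 0.6)))
  expect_equal(tI, tE, tolerance = 2e-3)
})

test_that("half-release time interpolates and is robust to subsampling", {
  tr <- fake_trajectory(c(10, 20), c(0.4, 0.6))
  expect_equal(half_release_time(tr), 15)
  tr2 <- fake_trajectory(c(5, 12, 30), c(0.2, 0.5, 0.8))
  expect_equal(half_release_time(tr2), 12)
  expect_error(half_release_time(fake_trajectory(c(1, 2), c(0.1, 0.2))),
               "never reaches")
  # thinning a dense stored curve moves tau_1/2 only within interpolation error
  gel <- microgel_spec(b = 10)
  traj <- run_release(gel, toy_molecule(0.1, -1), build_grid(gel),
                      solver_config("implicit", dt = 1e-4, f_stop = 0.8))
  thin <- fake_trajectory(traj$times[c(TRUE, FALSE, FALSE)],
                          traj$f_rel[c(TRUE, FALSE, FALSE)])
  expect_equal(half_release_time(thin), half_release_time(traj),
               tolerance = 1e-3)
})

test_that("mean release time matches the closed-form mean of a synthetic curve", {
  p <- weibull_params(chi = 0.64, nu = 0.79, tau_half = 3)
  t <- seq(0.001, 250, by = 0.005)
  tr <- fake_trajectory(t, weibull_frel(t, p))
  expect_equal(mean_release_time(tr), weibull_mean_time(p), tolerance = 1e-3)
  # time rescaling scales the mean linearly
  tr2 <- fake_trajectory(2 * t, weibull_frel(t, p))
  expect_equal(mean_release_time(tr2), 2 * weibull_mean_time(p),
               tolerance = 1e-3)
  expect_gt(mean_release_time(tr), 0)
  expect_error(mean_release_time(fake_trajectory(t[1:100], weibull_frel(t[1:100], p))),
               "incomplete")
})
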