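test_that("MFPT quadrature reproduces the free-diffusion closed form", {
  gel <- microgel_spec(b = 20, delta = 1, beta_dG = 0, R_over_b = 10)
  R <- gel$R
  for (s in c(0, 10, 50, 150)) {
    expect_equal(mfpt_quadrature(s, gel, D_star = 1, D_w = 1),
                 (R^2 - s^2) / 6, tolerance = 1e-6)
  }
  expect_equal(mfpt_quadrature(R, gel, 1, 1), 0)
  # monotone decreasing in the start radius
  taus <- vapply(c(20, 60, 100, 180), function(s)
    mfpt_quadrature(s, gel, 0.01, 1), numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_error(mfpt_quadrature(10, gel, 1, 1, R = Inf), "finite")
})

test_that("the sharp-interface closed form agrees with the quadrature oracle", {
  # transcription gate at the reference configuration
  gel <- microgel_spec(b = 100, delta = 0.01, beta_dG = -3, R_over_b = 20)
  q <- mfpt_quadrature(50, gel, D_star = 1e-3, D_w = 1, R = 2000)
  s <- mfpt_sharp(50, b = 100, R = 2000, D_star = 1e-3, D_w = 1, beta_dG = -3)
  expect_equal(s, q, tolerance = 1e-4)
  # neutral, uniform diffusivity reduces to the free-diffusion form
  expect_equal(mfpt_sharp(30, 100, 2000, 1, 1, 0), (2000^2 - 30^2) / 6,
               tolerance = 1e-12)
  # starting at the interface, the interior-diffusion contribution vanishes
  expect_equal(mfpt_sharp(100, 100, 2000, 1e-4, 1, -2),
               mfpt_sharp(100, 100, 2000, 1, 1, -2), tolerance = 1e-12)
  expect_error(mfpt_sharp(150, 100, 2000, 1, 1, 0), "0 <= s <= b")
})

test_that("the volume-averaged MFPT matches analytic and Monte-Carlo oracles", {
  # neutral case: averaging (R^2 - s^2)/(6D) over a uniform sphere
  b <- 50; R <- 500; D <- 0.3
  expect_equal(mean_mfpt(b, R, D, D, 0)$tau_mean,
               (R^2 - 3 * b^2 / 5) / (6 * D), tolerance = 1e-12)
  # interior term arithmetic
  expect_equal(mean_mfpt(100, 2000, 1e-3, 1, -2)$term_interior,
               100^2 / (15 * 1e-3), tolerance = 1e-12)
  # Monte-Carlo oracle: 1e4 uniform-in-volume start positions
  set.seed(42)
  s_mc <- b * runif(1e4)^(1 / 3)
  mc <- mean(mfpt_sharp(s_mc, b, R, 0.1, 1, -2))
  m <- mean_mfpt(b, R, 0.1, 1, -2)
  expect_equal(m$tau_mean, mc, tolerance = 1e-3)
  # decomposition: non-negative terms summing to the total
  expect_gte(m$term_interior, 0)
  expect_gte(m$term_barrier, 0)
  expect_gte(m$term_exterior, 0)
  expect_equal(m$tau_mean,
               m$term_interior + m$term_barrier + m$term_exterior)
})

test_that("escape time has the stated limits, scaling and consistency", {
  # strongly repulsive gel: pure interior diffusion remains
  expect_equal(escape_time(100, 1e-3, 1, 50)$tau_mean, 100^2 / (15 * 1e-3),
               tolerance = 1e-6)
  # both terms scale as b^2
  e1 <- escape_time(50, 0.01, 1, -3)$tau_mean
  e2 <- escape_time(100, 0.01, 1, -3)$tau_mean
  expect_equal(e2 / e1, 4, tolerance = 1e-12)
  # monotone: slower inside, deeper well, bigger particle => longer
  expect_gt(escape_time(50, 0.001, 1, -3)$tau_mean,
            escape_time(50, 0.01, 1, -3)$tau_mean)
  expect_gt(escape_time(50, 0.01, 1, -4)$tau_mean,
            escape_time(50, 0.01, 1, -3)$tau_mean)
  # dilute-limit consistency with the finite-R average
  for (g in c(-4, -1, 0)) {
    m <- mean_mfpt(50, 50 * 1000, 0.01, 1, g)
    expect_equal(escape_time(50, 0.01, 1, g)$tau_mean,
                 m$tau_mean - m$term_exterior, tolerance = 0.01)
  }
  # Arrhenius regime: ln(tau) linear in -beta dG with unit slope
  gs <- seq(-9, -5)
  lt <- log(vapply(gs, function(g) escape_time(50, 0.05, 1, g)$tau_mean,
                   numeric(1)))
  slope <- stats::coef(stats::lm(lt ~ gs))[[2]]
  expect_equal(slope, -1, tolerance = 0.02)
  # interior-dominated regime for repulsive gels
  expect_equal(escape_time(50, 0.001, 1, 3)$tau_mean,
               50^2 / (15 * 0.001), tolerance = 0.05)
})

test_that("the analytic half-release time is a fixed fraction of the escape time", {
  ratio0 <- analytic_half_release_time(50, 0.01, 1, -2) /
    escape_time(50, 0.01, 1, -2)$tau_mean
  for (b in c(10, 200)) for (d in c(1e-3, 0.5)) for (g in c(-5, 0, 2)) {
    r <- analytic_half_release_time(b, d, 1, g) / escape_time(b, d, 1, g)$tau_mean
    expect_equal(r, ratio0, tolerance = 1e-12)
  }
  # the constant is the Weibull mean-median factor at chi=0.64, nu=0.79
  expect_equal(ratio0, 0.64^(1 / 0.79) / gamma(1 + 1 / 0.79), tolerance = 1e-12)
  expect_equal(ratio0, 0.497, tolerance = 1e-3)
})

test_that("the anchored Weibull curve passes through its own half-time", {
  for (chi in c(0.3, 0.64, 1.5)) for (nu in c(0.5, 0.79, 2)) {
    p <- weibull_params(chi, nu, tau_half = 7)
    expect_equal(weibull_frel(0, p), 0)
    expect_equal(weibull_frel(7, p), 0.5, tolerance = 1e-12)
    expect_equal(weibull_frel(1e6, p), 1, tolerance = 1e-6)
    t <- seq(0, 50, by = 0.5)
    expect_true(all(diff(weibull_frel(t, p)) > 0))
  }
})

test_that("the Weibull mean agrees with numerical quadrature and scales linearly", {
  for (nu in c(0.5, 0.79, 1.7)) {
    p <- weibull_params(chi = 0.64, nu = nu, tau_half = 2)
    num <- stats::integrate(function(t) 1 - weibull_frel(t, p), 0, Inf,
                            rel.tol = 1e-10)$value
    expect_equal(weibull_mean_time(p), num, tolerance = 1e-6)
    p10 <- weibull_params(chi = 0.64, nu = nu, tau_half = 20)
    expect_equal(weibull_mean_time(p10), 10 * weibull_mean_time(p),
                 tolerance = 1e-12)
    expect_true(is.finite(weibull_mean_time(p)) && weibull_mean_time(p) > 0)
  }
})

test_that("Weibull fitting recovers known constants and pools consistently", {
  # raw-axis round trip: synthesized from the master-curve form
  x <- seq(0.005, 8, by = 0.005)
  f <- 1 - exp(-0.64 * x^0.79)
  tr <- fake_trajectory(x, f)
  est <- fit_weibull(tr, rescale = FALSE)
  expect_equal(est$chi, 0.64, tolerance = 1e-3)
  expect_equal(est$nu, 0.79, tolerance = 1e-3)
  # after rescaling by the measured half-time, an exact Weibull collapses
  # onto the anchored form: chi -> log(2), nu preserved
  est2 <- fit_weibull(tr, rescale = TRUE)
  expect_equal(est2$chi, log(2), tolerance = 1e-3)
  expect_equal(est2$nu, 0.79, tolerance = 1e-3)
  # a pooled fit of identical copies equals the single-curve fit
  est3 <- fit_weibull(list(tr, tr, tr), rescale = FALSE)
  expect_equal(est3$chi, est$chi, tolerance = 1e-9)
  expect_equal(est3$nu, est$nu, tolerance = 1e-9)
  expect_error(fit_weibull(fake_trajectory(x[1:50], f[1:50])), "0.9")
})
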