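#' Mean first passage time by adaptive quadrature
#'
#' Expected time for a molecule started at radius `s` to first reach the
#' absorbing outer cell boundary at `R`, diffusing in the smooth radial
#' landscape of the microgel (erf interface profile for both the potential
#' and the diffusivity):
#' \deqn{\bar\tau(s) = \int_s^R \frac{e^{\beta u(r)}}{D_{eff}(r)\, r^2}
#'   \int_0^r r'^2 e^{-\beta u(r')}\, dr'\, dr.}
#' This is the reference oracle against which the sharp-interface closed
#' forms are validated.
#'
#' @param s Start radius (nm), `0 <= s < R`.
#' @param gel A [microgel_spec()] (its `beta_dG` and `R` are used).
#' @param D_star,D_w Diffusivities (consistent units; the result is in
#'   nm^2 / those units).
#' @param R Outer absorbing radius (nm). Defaults to `gel$R`. Must be
#'   finite.
#' @param rel_tol Quadrature relative tolerance.
#' @return Mean first passage time (time units of 1/\[D\]).
#' @export
mfpt_quadrature <- function(s, gel, D_star, D_w, R = gel$R,
                            rel_tol = 1e-9) {
  stopifnot(s >= 0, is.finite(R), R >= s, D_star > 0, D_w > 0)
  if (s == R) return(0)  # started on the absorbing boundary
  b <- gel$b
  delta <- gel$delta
  # interface window outside which the erf profile is constant to machine
  # precision (erf(+-8) differs from +-1 by < 1e-28)
  wlo <- max(0, b + delta - 8 * delta)
  whi <- min(R, b + delta + 8 * delta)

  u <- function(r) effective_potential(r, gel)
  Deff <- function(r) effective_diffusion(r, gel, D_star, D_w)

  # inner integral I(r) = int_0^r r'^2 exp(-beta u) dr', split into the
  # sharp-step analytic part plus a spline-tabulated interface correction
  G <- gel$beta_dG
  I_step <- function(r) {
    ifelse(r <= b, exp(-G) * r^3 / 3, exp(-G) * b^3 / 3 + (r^3 - b^3) / 3)
  }
  corr_grid <- seq(wlo, whi, length.out = 4001L)
  integrand_corr <- corr_grid^2 * (exp(-u(corr_grid)) -
                                     ifelse(corr_grid <= b, exp(-G), 1))
  h <- diff(corr_grid)[1]
  corr_cum <- c(0, cumsum((integrand_corr[-1] + integrand_corr[-4001]) / 2 * h))
  corr_fun <- stats::splinefun(corr_grid, corr_cum, method = "natural")
  I_inner <- function(r) {
    cc <- ifelse(r <= wlo, 0, ifelse(r >= whi, corr_cum[4001L], corr_fun(r)))
    I_step(r) + cc
  }

  outer_integrand <- function(r) exp(u(r)) / (Deff(r) * r^2) * I_inner(r)
  pieces <- sort(unique(pmax(s, pmin(R, c(s, wlo, whi, R)))))
  total <- 0
  for (k in seq_len(length(pieces) - 1L)) {
    if (pieces[k + 1] > pieces[k]) {
      total <- total + stats::integrate(outer_integrand, pieces[k],
                                        pieces[k + 1], rel.tol = rel_tol,
                                        subdivisions = 400L)$value
    }
  }
  total
}

#' Sharp-interface mean first passage time
#'
#' Closed form of the MFPT integral for a molecule started at `s <= b`,
#' treating the microgel interface as a sharp boundary: potential `dG`
#' (k_B T) and diffusivity `D_star` inside the particle radius b, zero potential and `D_w`
#' outside, absorbing at `R`:
#' \deqn{\bar\tau(s) = \frac{b^2 - s^2}{6 D^*}
#'  + \frac{b^3}{3 D_w}\left(e^{-\beta\Delta G} - 1\right)
#'    \left(\frac1b - \frac1R\right)
#'  + \frac{R^2 - b^2}{6 D_w}.}
#'
#' @param s Start radius, `0 <= s <= b`.
#' @param b Microgel radius (nm).
#' @param R Outer absorbing radius (nm), `R > b`.
#' @param D_star,D_w Diffusivities.
#' @param beta_dG Dimensionless transfer free energy.
#' @return Mean first passage time.
#' @export
mfpt_sharp <- function(s, b, R, D_star, D_w, beta_dG) {
  stopifnot(b > 0, R > b, D_star > 0, D_w > 0)
  if (any(s < 0) || any(s > b)) {
    stop("the sharp closed form requires 0 <= s <= b (use mfpt_quadrature ",
         "for exterior starts)", call. = FALSE)
  }
  (b^2 - s^2) / (6 * D_star) +
    b^3 / (3 * D_w) * (exp(-beta_dG) - 1) * (1 / b - 1 / R) +
    (R^2 - b^2) / (6 * D_w)
}

#' Mean escape/transit times averaged over the loaded microgel
#'
#' `mean_mfpt()` volume-averages the sharp-interface MFPT over the
#' uniformly distributed initial positions (weight s^2 on \[0, b\]) and
#' reports the three-term decomposition: interior diffusion
#' `b^2 / (15 D_star)`, barrier crossing
#' `b^2 e^{-beta_dG} (1 - b/R) / (3 D_w)`, and exterior transit from b to
#' the absorbing radius R (which absorbs the remaining algebra so the terms
#' sum exactly to the s-average).
#'
#' `escape_time()` is the dilute limit (`R >> b`) keeping only the interior
#' and barrier terms:
#' \deqn{\bar\tau_{esc} = \frac{b^2}{15 D^*} +
#'       \frac{b^2}{3 D_w} e^{-\beta\Delta G},}
#' the mean time to leave the microgel itself.
#'
#' @inheritParams mfpt_sharp
#' @return An object of class `mfpt_result`: list with `tau_mean`,
#'   `term_interior`, `term_barrier`, `term_exterior`, `method`.
#' @examples
#' escape_time(b = 50, D_star = 0.0071, D_w = 1, beta_dG = -1.88)
#' @export
mean_mfpt <- function(b, R, D_star, D_w, beta_dG) {
  stopifnot(b > 0, R > b, D_star > 0, D_w > 0)
  term_interior <- b^2 / (15 * D_star)
  term_barrier <- b^2 / (3 * D_w) * exp(-beta_dG) * (1 - b / R)
  term_exterior <- (R^2 - b^2) / (6 * D_w) - b^2 / (3 * D_w) * (1 - b / R)
  mfpt_result(term_interior, term_barrier, term_exterior, "closed_form")
}

#' @rdname mean_mfpt
#' @export
escape_time <- function(b, D_star, D_w, beta_dG) {
  stopifnot(b > 0, D_star > 0, D_w > 0)
  mfpt_result(term_interior = b^2 / (15 * D_star),
              term_barrier = b^2 / (3 * D_w) * exp(-beta_dG),
              term_exterior = 0, method = "closed_form")
}

mfpt_result <- function(term_interior, term_barrier, term_exterior, method) {
  stopifnot(term_interior >= 0, term_barrier >= 0, term_exterior >= 0)
  structure(list(tau_mean = term_interior + term_barrier + term_exterior,
                 term_interior = term_interior, term_barrier = term_barrier,
                 term_exterior = term_exterior, method = method),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("<MFPT (%s): tau = %.6g = %.6g (interior) + %.6g (barrier) + %.6g (exterior)>\n",
              x$method, x$tau_mean, x$term_interior, x$term_barrier,
              x$term_exterior))
  invisible(x)
}

#' Analytic half-release time
#'
#' Converts the mean escape time into the half-release time through the
#' Weibull mean-median relation of the universal master curve:
#' \deqn{\tau_{1/2} = \bar\tau_{esc}\, \frac{\chi^{1/\nu}}{\Gamma(1 + 1/\nu)},}
#' with the master-curve shape constants chi = 0.64, nu = 0.79 by default
#' (the proportionality constant is then ~ 0.497).
#'
#' @inheritParams mfpt_sharp
#' @param weibull_constants `c(chi, nu)` of the master curve.
#' @return tau_1/2 in the time units implied by the diffusivities.
#' @examples
#' analytic_half_release_time(b = 50, D_star = 0.0071, D_w = 1, beta_dG = -1.88)
#' @export
analytic_half_release_time <- function(b, D_star, D_w, beta_dG,
                                       weibull_constants = c(chi = 0.64, nu = 0.79)) {
  chi <- weibull_constants[[1]]
  nu <- weibull_constants[[2]]
  stopifnot(chi > 0, nu > 0)
  escape_time(b, D_star, D_w, beta_dG)$tau_mean * chi^(1 / nu) / gamma(1 + 1 / nu)
}

#' Weibull master-curve parameters
#'
#' Shape constants of the universal release profile. The cumulative curve
#' is internally anchored so that it passes through (tau_half, 0.5)
#' exactly for any (chi, nu), matching the master-curve construction.
#'
#' @param chi,nu Positive shape constants (defaults: the master-curve fit
#'   values 0.64 and 0.79).
#' @param tau_half Half-release time setting the time scale (default 1).
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(chi = 0.64, nu = 0.79, tau_half = 1) {
  stopifnot(chi > 0, nu > 0, tau_half > 0)
  structure(list(chi = chi, nu = nu, tau_half = tau_half),
            class = "weibull_params")
}

#' Weibull release curve
#'
#' The master-curve cumulative released fraction
#' \eqn{f(t) = 1 - \exp[-\chi\,(t/t_s)^\nu]} with the internal time scale
#' `t_s` chosen so that `f(tau_half) = 0.5` exactly.
#'
#' @param t Time(s), >= 0 (same units as `params$tau_half`).
#' @param params A [weibull_params()].
#' @return Released fraction in \[0, 1\].
#' @export
weibull_frel <- function(t, params = weibull_params()) {
  stopifnot(all(t >= 0))
  ts <- params$tau_half * (params$chi / log(2))^(1 / params$nu)
  1 - exp(-params$chi * (t / ts)^params$nu)
}

#' Mean release time of the Weibull master curve
#'
#' Closed-form first moment of the anchored Weibull release profile,
#' \eqn{\bar\tau = \tau_{1/2}\, \Gamma(1 + 1/\nu) / (\ln 2)^{1/\nu}}
#' (the anchoring makes chi drop out of the mean).
#'
#' @param params A [weibull_params()].
#' @return Mean release time (same units as `tau_half`), finite and
#'   positive.
#' @export
weibull_mean_time <- function(params = weibull_params()) {
  params$tau_half * gamma(1 + 1 / params$nu) / log(2)^(1 / params$nu)
}

#' Fit the Weibull shape constants to pooled release curves
#'
#' Rescales each trajectory's time axis by its half-release time, pools the
#' rescaled (t/tau_half, f_rel) points with f_rel <= 0.99, and
#' least-squares fits the master curve `f = 1 - exp(-chi x^nu)`. By
#' default each curve is first resampled onto a uniform grid in rescaled
#' time so that every curve contributes equal weight per unit of
#' normalized time, independent of how the solver spaced its stored frames
#' (`resample = FALSE` pools the stored frames as-is).
#'
#' @param trajectories A list of [run_release()] trajectories (each must
#'   reach f_rel >= 0.9), or a single trajectory.
#' @param resample Resample each curve to a uniform rescaled-time grid
#'   before pooling? Default TRUE.
#' @param n_per_curve Number of resampled points per curve. Default 400.
#' @param rescale Divide each curve's time axis by its half-release time
#'   before pooling (the master-curve construction)? Default TRUE; set
#'   FALSE to fit curves on their raw time axes (e.g. to recover known
#'   shape constants from synthetic data).
#' @return A list with `chi`, `nu`, their standard errors `chi_se`,
#'   `nu_se`, the number of pooled points `n_points`, and the `fit` object.
#' @export
fit_weibull <- function(trajectories, resample = TRUE, n_per_curve = 400L,
                        rescale = TRUE) {
  if (inherits(trajectories, "release_trajectory")) {
    trajectories <- list(trajectories)
  }
  pts <- lapply(trajectories, function(tr) {
    if (max(tr$f_rel) < 0.9) {
      stop("each trajectory must reach f_rel >= 0.9 before fitting",
           call. = FALSE)
    }
    x <- if (rescale) tr$times / half_release_time(tr) else tr$times
    f <- tr$f_rel
    if (resample) {
      xi <- seq(0, max(x[f <= 0.99]), length.out = n_per_curve + 1L)[-1]
      f <- stats::approx(c(0, x), c(0, f), xout = xi)$y
      x <- xi
    }
    data.frame(x = x, f = f)
  })
  pooled <- do.call(rbind, pts)
  pooled <- pooled[pooled$f <= 0.99 & pooled$x > 0, ]
  if (nrow(pooled) < 5L || stats::sd(pooled$f) == 0) {
    stop("degenerate pooled data: cannot fit the master curve", call. = FALSE)
  }
  fit <- minpack.lm::nlsLM(f ~ 1 - exp(-chi * x^nu), data = pooled,
                           start = list(chi = 0.7, nu = 0.9),
                           lower = c(1e-6, 1e-6), upper = c(20, 10),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  list(chi = est["chi", "Estimate"], nu = est["nu", "Estimate"],
       chi_se = est["chi", "Std. Error"], nu_se = est["nu", "Std. Error"],
       n_points = nrow(pooled), fit = fit)
}
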