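#' Define a microgel carrier
#'
#' A collapsed spherical microgel of radius `b` with a narrow diffuse
#' interface of full width `2*delta`, uniform interior polymer volume
#' fraction `phi_p0`, and a dimensionless water-to-gel transfer free energy
#' `beta_dG` for the cargo. The surrounding bath is truncated at the outer
#' cell radius `R = R_over_b * b`, where the absorbing (infinite-dilution)
#' boundary condition is applied.
#'
#' @param b Microgel radius (nm), positive.
#' @param delta Interface half-width (nm); the polymer fraction decays over
#'   `[b, b + 2*delta]`. Default 1 nm (sharp collapsed interface).
#' @param phi_p0 Interior polymer volume fraction, in (0, 1). Default 0.5.
#' @param beta_dG Dimensionless transfer free energy of the cargo (negative
#'   = the gel attracts the molecule). Default 0.
#' @param R_over_b Outer cell radius in units of `b`. Default 20.
#' @return An object of class `microgel_spec`.
#' @examples
#' microgel_spec(b = 50)
#' @export
microgel_spec <- function(b, delta = 1, phi_p0 = 0.5, beta_dG = 0,
                          R_over_b = 20) {
  stopifnot(is.numeric(b), b > 0, delta > 0, R_over_b > 1,
            phi_p0 > 0, phi_p0 < 1)
  if (2 * delta > b / 2) {
    warning("interface width 2*delta exceeds b/2; the collapsed-microgel ",
            "sharp-interface picture is questionable", call. = FALSE)
  }
  structure(list(b = b, delta = delta, phi_p0 = phi_p0, beta_dG = beta_dG,
                 R_over_b = R_over_b, R = R_over_b * b),
            class = "microgel_spec")
}

#' @export
print.microgel_spec <- function(x, ...) {
  cat(sprintf(
    "<microgel: b = %g nm, delta = %g nm, phi_p0 = %g, beta*dG = %g, R = %g nm>\n",
    x$b, x$delta, x$phi_p0, x$beta_dG, x$R))
  invisible(x)
}

#' Radial interface profile
#'
#' Smoothed step describing how the polymer matrix fades into the bath:
#' \deqn{f(r) = \tfrac12\left[1 - \mathrm{erf}\!\left(\frac{r - b - \delta}{\delta}\right)\right],}
#' equal to 1 deep inside the particle, 0 far outside, with the transition
#' localized to `[b, b + 2*delta]` and midpoint value 1/2 at radius
#' b + delta.
#' All radial fields (polymer fraction, effective diffusivity, effective
#' potential) derive from this single profile.
#'
#' @param r Radius (nm), vectorised, non-negative.
#' @param gel A [microgel_spec()].
#' @return Dimensionless profile in \[0, 1\].
#' @export
interface_profile <- function(r, gel) {
  stopifnot(all(r >= 0))
  x <- (r - gel$b - gel$delta) / gel$delta
  0.5 * (1 - erf(x))
}

# error function via the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @rdname interface_profile
#' @return `polymer_volume_fraction()`: phi_p0 * f(r), in \[0, phi_p0\].
#' @export
polymer_volume_fraction <- function(r, gel) {
  gel$phi_p0 * interface_profile(r, gel)
}

#' Effective diffusion coefficient profile
#'
#' Switches between the in-gel value `D_star` (deep inside) and the
#' bulk-water value `D_w` (far outside) through the interface profile:
#' \deqn{D_{eff}(r) = D_w \left(D^*/D_w\right)^{f(r)},}
#' i.e. log-linear in `f`. Because obstructed diffusion in a dense network
#' depends exponentially on the local polymer fraction (free-volume
#' picture), the logarithm of the diffusivity — not the diffusivity
#' itself — tracks `phi_p(r)`; this keeps `D_eff ~ D_star` throughout the
#' particle even when `D_w/D_star` spans several decades, so the switch
#' stays localized at the interface for every ratio.
#'
#' @inheritParams interface_profile
#' @param D_star In-gel diffusion coefficient (same units as `D_w`).
#' @param D_w Bulk diffusion coefficient.
#' @return Diffusivity profile, monotone non-decreasing in `r` when
#'   `D_star <= D_w`.
#' @export
effective_diffusion <- function(r, gel, D_star, D_w) {
  stopifnot(D_star > 0, D_w > 0)
  if (D_star > D_w) {
    warning("D_star > D_w: faster diffusion inside the gel than in bulk ",
            "is outside the collapsed-network regime", call. = FALSE)
  }
  f <- interface_profile(r, gel)
  D_w * (D_star / D_w)^f
}

#' Effective microgel-molecule interaction
#'
#' The radial free-energy landscape felt by the cargo,
#' `u_eff(r) = beta_dG * f(r)` in k_B T units: a flat well (or barrier) of
#' depth `beta_dG` inside the particle decaying to zero across the
#' interface.
#'
#' @inheritParams interface_profile
#' @return beta * u_eff(r), dimensionless.
#' @export
effective_potential <- function(r, gel) {
  gel$beta_dG * interface_profile(r, gel)
}

#' Nonuniform spherical finite-volume grid
#'
#' Builds the radial mesh for the release solver: fine, uniform spacing
#' `dr_fine` in a window around the interface (where the diffusivity and
#' potential gradients live), geometrically graded (ratio <= 1.3) out to the
#' coarse spacing `dr_coarse` used deep inside the particle and in the bath,
#' with faces pinned exactly at 0 and R.
#'
#' @param gel A [microgel_spec()].
#' @param dr_fine Spacing inside the interface window (nm). Default 0.02.
#' @param dr_coarse Spacing elsewhere (nm). Default 0.5.
#' @param window_halfwidth Half-width of the fine window centred on
#'   `b + delta` (nm). Default `4 * delta`.
#' @return An object of class `radial_grid` with fields `cell_faces`
#'   (length n+1, from 0 to R), `cell_centers` (length n), `shell_volumes`
#'   (4*pi/3 * (r_{i+1}^3 - r_i^3)), and `R`.
#' @examples
#' g <- build_grid(microgel_spec(b = 50))
#' sum(g$shell_volumes) - 4 * pi / 3 * g$R^3  # ~0 (telescoping)
#' @export
build_grid <- function(gel, dr_fine = 0.02, dr_coarse = 0.5,
                       window_halfwidth = 4 * gel$delta) {
  stopifnot(dr_fine > 0, dr_fine <= dr_coarse)
  if (window_halfwidth < 2 * gel$delta) {
    stop("the fine window must cover the interface: window_halfwidth >= 2*delta",
         call. = FALSE)
  }
  R <- gel$R
  ctr <- gel$b + gel$delta  # interface midpoint
  lo <- ctr - window_halfwidth
  hi <- ctr + window_halfwidth
  if (lo < 0 || hi > R) {
    warning("fine window clipped to [0, R]", call. = FALSE)
    lo <- max(lo, 0)
    hi <- min(hi, R)
  }

  graded_zone <- function(width) {
    # spacings marching away from the fine window, growing by <= 1.3 per
    # cell up to dr_coarse, rescaled so they tile `width` exactly
    if (width <= 0) return(numeric(0))
    if (width <= dr_fine) return(width)
    dr <- dr_fine
    steps <- numeric(0)
    acc <- 0
    while (acc < width) {
      dr <- min(dr * 1.3, dr_coarse)
      steps <- c(steps, dr)
      acc <- acc + dr
    }
    steps * (width / acc)
  }

  n_fine <- max(1L, ceiling((hi - lo) / dr_fine))
  fine_faces <- seq(lo, hi, length.out = n_fine + 1L)
  left_faces <- lo - rev(cumsum(graded_zone(lo)))   # from ~0 up to just below lo
  if (length(left_faces)) left_faces[1] <- 0        # snap to the origin
  right_faces <- hi + cumsum(graded_zone(R - hi))
  if (length(right_faces)) right_faces[length(right_faces)] <- R  # snap to R
  faces <- c(left_faces, fine_faces, right_faces)
  stopifnot(all(diff(faces) > 0))
  centers <- (faces[-1] + faces[-length(faces)]) / 2
  vols <- 4 * pi / 3 * diff(faces^3)
  structure(list(cell_faces = faces, cell_centers = centers,
                 shell_volumes = vols, R = R),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  dr <- diff(x$cell_faces)
  cat(sprintf("<radial grid: %d cells on [0, %g] nm, dr in [%.3g, %.3g] nm>\n",
              length(x$cell_centers), x$R, min(dr), max(dr)))
  invisible(x)
}

#' Export the radial fields of a microgel/molecule pair
#'
#' Tabulates the interface profile, polymer fraction, effective diffusivity
#' and effective potential on the grid's cell centers, for plotting or
#' debugging; optionally written as CSV.
#'
#' @param gel A [microgel_spec()].
#' @param grid A [build_grid()] result.
#' @param D_star,D_w Diffusivities (nm^2/ns).
#' @param file Optional CSV path.
#' @return A data.frame with columns `r_nm`, `f`, `phi_p`, `D_eff_nm2_ns`,
#'   `beta_u_eff` (invisibly if written to `file`).
#' @export
field_profiles <- function(gel, grid = build_grid(gel), D_star, D_w,
                           file = NULL) {
  r <- grid$cell_centers
  out <- data.frame(
    r_nm = r,
    f = interface_profile(r, gel),
    phi_p = polymer_volume_fraction(r, gel),
    D_eff_nm2_ns = effective_diffusion(r, gel, D_star, D_w),
    beta_u_eff = effective_potential(r, gel)
  )
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
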