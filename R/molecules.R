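#' Gyration-tensor eigenvalues
#'
#' Container for the three eigenvalues of a molecule's gyration tensor, the
#' semiaxes of the equivalent ellipsoid. Order does not matter; all values
#' must be non-negative and at least one must be positive.
#'
#' @param alpha1,alpha2,alpha3 Non-negative eigenvalues (nm).
#' @return An object of class `gyration_eigenvalues`.
#' @export
gyration_eigenvalues <- function(alpha1, alpha2, alpha3) {
  a <- c(alpha1, alpha2, alpha3)
  if (length(a) != 3L || !is.numeric(a) || anyNA(a)) {
    stop("three finite numeric eigenvalues are required", call. = FALSE)
  }
  if (any(a < 0)) stop("gyration-tensor eigenvalues must be non-negative", call. = FALSE)
  if (all(a == 0)) stop("all-zero eigenvalues: shape is undefined", call. = FALSE)
  structure(list(alpha = a), class = "gyration_eigenvalues")
}

#' Relative shape anisotropy
#'
#' Scalar shape descriptor derived from the gyration tensor. For eigenvalues
#' (a1, a2, a3) it is
#' \deqn{\kappa = 1 - 3\,\frac{a_1 a_2 + a_2 a_3 + a_3 a_1}{(a_1+a_2+a_3)^2},}
#' ranging from 0 (tetrahedral or higher symmetry, e.g. spheres) through 0.25
#' (regular planar geometry) to 1 (linear arrangement of atoms). The value is
#' invariant under permutation and uniform rescaling of the eigenvalues.
#'
#' @param eig A [gyration_eigenvalues()] object, or a numeric vector of
#'   length 3.
#' @return Dimensionless anisotropy in \[0, 1\].
#' @examples
#' relative_shape_anisotropy(c(1, 1, 1))  # 0, spherical
#' relative_shape_anisotropy(c(1, 1, 0))  # 0.25, planar
#' relative_shape_anisotropy(c(1, 0, 0))  # 1, linear
#' @export
relative_shape_anisotropy <- function(eig) {
  if (!inherits(eig, "gyration_eigenvalues")) {
    eig <- gyration_eigenvalues(eig[1], eig[2], eig[3])
  }
  a <- eig$alpha
  s <- sum(a)
  pair <- a[1] * a[2] + a[2] * a[3] + a[3] * a[1]
  kappa <- 1 - 3 * pair / s^2
  # guard tiny negative round-off for near-degenerate triples
  min(max(kappa, 0), 1)
}

#' Classify a molecule's shape from its relative anisotropy
#'
#' Maps the relative shape anisotropy onto the three diffusion classes used
#' for collapsed-network transport: spherical, planar, linear. Default
#' thresholds reproduce the packaged registry grouping exactly.
#'
#' @param kappa Relative shape anisotropy in \[0, 1\].
#' @param thresholds Two increasing cut points `c(spherical_planar,
#'   planar_linear)`.
#' @return `"spherical"`, `"planar"` or `"linear"` (vectorised over `kappa`).
#' @export
classify_shape <- function(kappa, thresholds = c(0.18, 0.33)) {
  if (any(!is.finite(kappa)) || any(kappa < 0) || any(kappa > 1)) {
    stop("kappa must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(thresholds) == 2L, diff(thresholds) > 0)
  ifelse(kappa < thresholds[1], "spherical",
         ifelse(kappa < thresholds[2], "planar", "linear"))
}

#' Shape-dependent fit parameters for in-gel diffusion
#'
#' Parameters of the empirical relations giving the decay length
#' \eqn{\lambda(\kappa) = m_1 \kappa + n_1} and diffusion prefactor
#' \eqn{D_0(\kappa) = n_2 e^{m_2 \kappa}} entering the exponential size
#' dependence of the in-gel diffusion coefficient. Defaults are the fitted
#' group-average values for a collapsed PNIPAM network at 340 K.
#'
#' @param m1 Slope of lambda(kappa) (nm). Default 0.047.
#' @param n1 Intercept of lambda(kappa) (nm). Default 0.0160.
#' @param m2 Exponential rate of D0(kappa) (dimensionless). Default -8.8.
#' @param n2 Prefactor of D0(kappa) (nm^2/ns). Default 3.37.
#' @return An object of class `shape_fit_params`.
#' @export
shape_fit_params <- function(m1 = 0.047, n1 = 0.0160, m2 = -8.8, n2 = 3.37) {
  if (n1 <= 0 || n2 <= 0) {
    stop("n1 and n2 must be positive so that lambda and D0 stay positive",
         call. = FALSE)
  }
  structure(list(m1 = m1, n1 = n1, m2 = m2, n2 = n2),
            class = "shape_fit_params")
}

#' @rdname shape_fit_params
#' @param kappa Relative shape anisotropy in \[0, 1\].
#' @param fit A [shape_fit_params()] object.
#' @export
decay_length <- function(kappa, fit = shape_fit_params()) {
  stopifnot(all(kappa >= 0), all(kappa <= 1))
  fit$m1 * kappa + fit$n1
}

#' @rdname shape_fit_params
#' @export
diffusion_prefactor <- function(kappa, fit = shape_fit_params()) {
  stopifnot(all(kappa >= 0), all(kappa <= 1))
  fit$n2 * exp(fit$m2 * kappa)
}

#' In-gel diffusion coefficient from size and shape
#'
#' The diffusion coefficient of a nonionic molecule inside a collapsed
#' polymer network decays exponentially with its Stokes radius,
#' \eqn{D^* = D_0(\kappa)\, e^{-a_w/\lambda(\kappa)}}, with shape entering
#' only through the prefactor and decay length. It is independent of the
#' molecule's chemistry (transfer free energy).
#'
#' @param a_w Stokes radius (nm), positive.
#' @param kappa Relative shape anisotropy in \[0, 1\].
#' @param fit A [shape_fit_params()] object.
#' @return Diffusion coefficient D* (nm^2/ns).
#' @export
internal_diffusion <- function(a_w, kappa, fit = shape_fit_params()) {
  if (any(a_w <= 0)) stop("Stokes radius must be positive", call. = FALSE)
  diffusion_prefactor(kappa, fit) * exp(-a_w / decay_length(kappa, fit))
}

#' Bath (solvent) conditions
#'
#' @param temperature Absolute temperature (K). Default 340 K, above the
#'   PNIPAM volume transition so the microgel is collapsed.
#' @param viscosity Solvent shear viscosity (Pa s). Default is water at
#'   340 K.
#' @param boltzmann_constant J/K.
#' @return An object of class `bath_conditions`.
#' @export
bath_conditions <- function(temperature = 340, viscosity = 4.206e-4,
                            boltzmann_constant = 1.380649e-23) {
  if (temperature <= 0 || viscosity <= 0) {
    stop("temperature and viscosity must be positive", call. = FALSE)
  }
  structure(list(temperature = temperature, viscosity = viscosity,
                 boltzmann_constant = boltzmann_constant),
            class = "bath_conditions")
}

#' Stokes-Einstein relation in nm^2/ns
#'
#' `bulk_diffusion()` maps a Stokes radius to the bulk-water diffusion
#' coefficient, \eqn{D_w = k_B T / (6\pi\eta a_w)}; `stokes_radius()` is the
#' exact inverse.
#'
#' @param a_w Stokes radius (nm), positive.
#' @param D_w Bulk diffusion coefficient (nm^2/ns), positive.
#' @param bath A [bath_conditions()] object.
#' @return Diffusivity in nm^2/ns, or radius in nm.
#' @examples
#' bulk_diffusion(0.114)                # methane-sized molecule
#' stokes_radius(bulk_diffusion(0.114)) # round trip
#' @export
bulk_diffusion <- function(a_w, bath = bath_conditions()) {
  if (any(a_w <= 0)) stop("Stokes radius must be positive", call. = FALSE)
  # k_B T / (6 pi eta a) in SI is m^2/s; 1 m^2/s = 1e9 nm^2/ns
  D_SI <- bath$boltzmann_constant * bath$temperature /
    (6 * pi * bath$viscosity * (a_w * 1e-9))
  D_SI * 1e9
}

#' @rdname bulk_diffusion
#' @export
stokes_radius <- function(D_w, bath = bath_conditions()) {
  if (any(D_w <= 0)) stop("diffusion coefficient must be positive", call. = FALSE)
  a_SI <- bath$boltzmann_constant * bath$temperature /
    (6 * pi * bath$viscosity * (D_w / 1e9))
  a_SI * 1e9
}

#' Surface-area model for the transfer free energy
#'
#' Phenomenological model for the water-to-gel transfer free energy of a
#' nonionic molecule: \eqn{\Delta G = \Delta G_0 + \gamma_0\, 4\pi a_{AS}^2},
#' where \eqn{a_{AS} = a_w + } `a_AS_offset` is the equivalent spherical
#' radius of the solvent-accessible surface. `dG0` captures the molecule's
#' polarity; `gamma0` the polymer-vs-water surface-tension difference.
#'
#' @param dG0 Offset term (k_B T).
#' @param gamma0 Surface coefficient (k_B T / nm^2).
#' @param a_AS_offset Added to the Stokes radius to form a_AS (nm).
#' @return An object of class `free_energy_model_params`.
#' @export
free_energy_model_params <- function(dG0 = 0, gamma0 = 0, a_AS_offset = 0.233) {
  if (a_AS_offset < 0) stop("a_AS_offset must be non-negative", call. = FALSE)
  structure(list(dG0 = dG0, gamma0 = gamma0, a_AS_offset = a_AS_offset),
            class = "free_energy_model_params")
}

#' @rdname free_energy_model_params
#' @param a_w Stokes radius (nm), positive.
#' @param params A [free_energy_model_params()] object.
#' @return `transfer_free_energy()`: Delta G in k_B T units (sign
#'   unrestricted; negative means the gel attracts the molecule).
#' @export
transfer_free_energy <- function(a_w, params = free_energy_model_params()) {
  if (any(a_w <= 0)) stop("Stokes radius must be positive", call. = FALSE)
  a_AS <- a_w + params$a_AS_offset
  params$dG0 + params$gamma0 * 4 * pi * a_AS^2
}

#' Define a cargo molecule
#'
#' Bundles the transport identity of a cargo molecule: shape anisotropy,
#' Stokes radius, transfer free energy, and diffusion coefficients in the
#' gel and in water. Either supply `Dstar_over_Dw` directly (as tabulated
#' for the packaged registry) or let it be predicted from `a_w` and `kappa`
#' via the empirical size/shape relations.
#'
#' @param name,symbol Identifying labels.
#' @param beta_dG Dimensionless transfer free energy, beta * Delta G.
#' @param kappa Relative shape anisotropy in \[0, 1\].
#' @param a_w Stokes radius (nm), or `NA` if unknown.
#' @param Dstar_over_Dw In-gel to bulk diffusivity ratio; if `NULL` it is
#'   computed as `internal_diffusion(a_w, kappa, fit) / bulk_diffusion(a_w)`.
#' @param fit A [shape_fit_params()] object (used only when predicting).
#' @param bath A [bath_conditions()] object.
#' @param shape_class Optional override; by default [classify_shape()] of
#'   `kappa`.
#' @return An object of class `molecule_spec` with fields `name`, `symbol`,
#'   `kappa`, `shape_class`, `a_w`, `beta_dG`, `Dstar_over_Dw`, `D_star`,
#'   `D_w` (the last two in nm^2/ns, `NA` when `a_w` is unknown).
#' @examples
#' molecule_spec("Methane", "Me", beta_dG = -1.88, kappa = 0.002383,
#'               a_w = 0.114, Dstar_over_Dw = 71e-4)
#' @export
molecule_spec <- function(name, symbol = name, beta_dG, kappa,
                          a_w = NA_real_, Dstar_over_Dw = NULL,
                          fit = shape_fit_params(), bath = bath_conditions(),
                          shape_class = NULL) {
  if (!is.finite(kappa) || kappa < 0 || kappa > 1) {
    stop("kappa must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(a_w) && a_w <= 0) stop("a_w must be positive", call. = FALSE)
  D_w <- if (is.na(a_w)) NA_real_ else bulk_diffusion(a_w, bath)
  if (is.null(Dstar_over_Dw)) {
    if (is.na(a_w)) {
      stop("either Dstar_over_Dw or a_w must be supplied", call. = FALSE)
    }
    D_star <- internal_diffusion(a_w, kappa, fit)
    Dstar_over_Dw <- D_star / D_w
  } else {
    D_star <- if (is.na(a_w)) NA_real_ else Dstar_over_Dw * D_w
  }
  if (Dstar_over_Dw <= 0 || Dstar_over_Dw > 1) {
    stop("D*/D_w must lie in (0, 1]: in-gel diffusion cannot exceed bulk",
         call. = FALSE)
  }
  if (is.null(shape_class)) shape_class <- classify_shape(kappa)
  structure(list(name = name, symbol = symbol, kappa = kappa,
                 shape_class = shape_class, a_w = a_w, beta_dG = beta_dG,
                 Dstar_over_Dw = Dstar_over_Dw, D_star = D_star, D_w = D_w),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("<molecule %s (%s): %s>\n", x$symbol, x$name, x$shape_class))
  cat(sprintf("  kappa = %.6f, beta*dG = %.2f, D*/D_w = %.3g\n",
              x$kappa, x$beta_dG, x$Dstar_over_Dw))
  if (!is.na(x$a_w)) {
    cat(sprintf("  a_w = %.3f nm, D_w = %.3f nm^2/ns, D* = %.3g nm^2/ns\n",
                x$a_w, x$D_w, x$D_star))
  }
  invisible(x)
}

registry_path <- function() {
  system.file("extdata", "table2_registry.tsv", package = "gelrelease",
              mustWork = TRUE)
}

#' Packaged molecule registry
#'
#' Transport parameters (shape anisotropy, dimensionless transfer free
#' energy, in-gel to bulk diffusivity ratio) for fifteen nonionic
#' sub-nanometer molecules in a collapsed PNIPAM network at 340 K, as
#' obtained in earlier atomistic simulation work: 3 linear, 5 planar and 7
#' spherical species. Stokes radii are included for the three molecules for
#' which they are tabulated (He, Ne, Me); otherwise only the diffusivity
#' ratio is known.
#'
#' @param path Optional path to an alternative registry TSV with columns
#'   `symbol`, `name`, `shape_class`, `kappa`, `beta_dG`,
#'   `Dstar_over_Dw_e4`, `a_w_nm`.
#' @return `molecule_registry()`: a data.frame, one row per molecule.
#' @examples
#' nrow(molecule_registry())   # 15
#' registry_lookup("He")$beta_dG
#' @export
molecule_registry <- function(path = registry_path()) {
  reg <- utils::read.delim(path, na.strings = "NA",
                           colClasses = c(rep("character", 3), rep("numeric", 4)))
  stopifnot(nrow(reg) > 0)
  reg
}

#' @rdname molecule_registry
#' @param symbol Registry symbol, e.g. `"Me"` or `"CCl4"`.
#' @return `registry_lookup()`: a [molecule_spec()] for that entry.
#' @export
registry_lookup <- function(symbol, path = registry_path()) {
  reg <- molecule_registry(path)
  i <- match(symbol, reg$symbol)
  if (is.na(i)) {
    stop(sprintf("molecule '%s' not found in registry (known: %s)", symbol,
                 paste(reg$symbol, collapse = ", ")), call. = FALSE)
  }
  row <- reg[i, ]
  molecule_spec(name = row$name, symbol = row$symbol, beta_dG = row$beta_dG,
                kappa = row$kappa, a_w = row$a_w_nm,
                Dstar_over_Dw = row$Dstar_over_Dw_e4 * 1e-4,
                shape_class = row$shape_class)
}
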