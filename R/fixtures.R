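#' Canonical gyration-eigenvalue fixtures
#'
#' Labeled eigenvalue triples spanning the three shape classes — the exact
#' reference geometries (sphere, regular plane, line) plus slightly
#' perturbed variants — for exercising the anisotropy and classification
#' code.
#'
#' @return A data.frame with columns `label`, `alpha1..3`, `kappa`
#'   (computed), `shape_class` (computed).
#' @export
make_toy_eigenvalues <- function() {
  base <- rbind(
    data.frame(label = "sphere", alpha1 = 1, alpha2 = 1, alpha3 = 1),
    data.frame(label = "plane", alpha1 = 1, alpha2 = 1, alpha3 = 0),
    data.frame(label = "line", alpha1 = 1, alpha2 = 0, alpha3 = 0),
    data.frame(label = "sphere_perturbed", alpha1 = 1, alpha2 = 1.01, alpha3 = 0.99),
    data.frame(label = "plane_perturbed", alpha1 = 1.05, alpha2 = 0.95, alpha3 = 0.02),
    data.frame(label = "line_perturbed", alpha1 = 1, alpha2 = 0.03, alpha3 = 0.01)
  )
  base$kappa <- vapply(seq_len(nrow(base)), function(i) {
    relative_shape_anisotropy(c(base$alpha1[i], base$alpha2[i], base$alpha3[i]))
  }, numeric(1))
  base$shape_class <- classify_shape(base$kappa)
  base
}

#' Small reference release run for regression testing
#'
#' A fast, fixed configuration (b = 10 nm, D*/D_w = 0.1, beta_dG = -1,
#' coarse grid, implicit scheme) whose trajectory is fully deterministic:
#' reruns are bit-identical, so a content hash of the stored frames can
#' serve as a regression anchor.
#'
#' @return A list with the `trajectory`, its `tau_half` (tau0 units), the
#'   escape-oracle prediction `tau_half_analytic` (evaluated at the release
#'   radius b + 2*delta, where molecules are counted as escaped — at b = 10
#'   nm the interface width is a 20% radius correction, not negligible),
#'   and a `digest` (sum-based content fingerprint of times and f_rel).
#' @export
make_reference_run <- function() {
  gel <- microgel_spec(b = 10, delta = 1, beta_dG = -1, R_over_b = 20)
  mol <- molecule_spec(name = "reference", beta_dG = -1, kappa = 0,
                       Dstar_over_Dw = 0.1)
  grid <- build_grid(gel, dr_fine = 0.05, dr_coarse = 0.5)
  traj <- run_release(gel, mol, grid,
                      solver_config("implicit", dt = 1e-4, dt_growth = 0.002))
  digest <- sprintf("%.15e|%.15e|%d",
                    sum(traj$times), sum(traj$f_rel), length(traj$times))
  b_release <- gel$b + 2 * gel$delta
  list(trajectory = traj, tau_half = half_release_time(traj),
       tau_half_analytic = analytic_half_release_time(b_release, D_star = 0.1,
                                                      D_w = 1, beta_dG = -1),
       digest = digest)
}
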