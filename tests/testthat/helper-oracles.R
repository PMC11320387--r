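# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever the quantity can be computed another way.

# Eigenfunction-series solution for free diffusion (constant D, no
# potential) from a uniformly loaded sphere of radius b, absorbing at R:
# returns the number of molecules at r <= redge at time t.
series_mass_inside <- function(t, b, R, D, rho0, redge, K = 2000) {
  k <- seq_len(K)
  lam <- k * pi / R
  ck <- (2 * rho0 / R) * (sin(lam * b) / lam^2 - b * cos(lam * b) / lam)
  I <- sin(lam * redge) / lam^2 - redge * cos(lam * redge) / lam
  4 * pi * sum(ck * exp(-D * lam^2 * t) * I)
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch), normalized so the
# weights sum to 1.
gauss_legendre01 <- function(n = 16) {
  j <- seq_len(n - 1)
  off <- j / sqrt(4 * j^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(j, j + 1)] <- off
  A[cbind(j + 1, j)] <- off
  e <- eigen(A, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1, ]^2)
}

# s^2-weighted (uniform-in-volume) average of a function of the start
# radius over [0, b]; exact for the quadratic sharp-interface MFPT.
volume_average <- function(fun, b, n = 16) {
  gq <- gauss_legendre01(n)
  sum(gq$w * 3 * gq$x^2 * vapply(b * gq$x, fun, numeric(1)))
}

# quick synthetic molecule for solver tests (transport ratio + free energy
# only; no Stokes radius so the cargo is treated as ideal)
toy_molecule <- function(Dstar_over_Dw, beta_dG, kappa = 0) {
  molecule_spec(name = "toy", beta_dG = beta_dG, kappa = kappa,
                Dstar_over_Dw = Dstar_over_Dw)
}

# wrap bare (times, f_rel) samples as a trajectory for the time-series
# utilities
fake_trajectory <- function(times, f_rel, tau0_ns = NA_real_) {
  structure(list(times = times, times_ns = times * tau0_ns, f_rel = f_rel),
            tau0_ns = tau0_ns, complete = max(f_rel) >= 0.99,
            class = "release_trajectory")
}
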