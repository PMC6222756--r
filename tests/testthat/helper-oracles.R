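# Shared oracles and fixtures, all computed in code at test time.

# reduced-unit thermodynamic state at a given inverse temperature
reduced_thermo <- function(beta) thermo_state(1 / beta, reduced = TRUE)

# Exact finite-P harmonic heavy/light ratio by dense Gaussian quadrature
# over the centroid-projected free-particle measure: per nonzero ring mode
# with covariance eigenvalue c, E[exp(-a d^2)] = (1 + 2 a c)^(-1/2) with
# a = beta k s^2 / (2 P); the ratio of the two Gaussian expectations times
# the classical mass factor is the discretized Q_H/Q_L.
finite_p_harmonic_ratio <- function(beta, k, m_L, m_H, P, dims = 1) {
  th <- reduced_thermo(beta)
  C <- fp_ring_covariance(P, thermal_wavelength_sq(m_L, th))
  ck <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ck <- ck[ck > 1e-12]
  s2 <- m_L / m_H
  per_dim <- prod(sqrt((1 + beta * k * ck / P) /
                         (1 + beta * k * s2 * ck / P)))
  ((m_H / m_L)^(1 / 2) * per_dim)^dims
}

# analytic Morse bound-state energies (reduced units, hbar = 1)
morse_levels <- function(D, a, mass) {
  omega <- a * sqrt(2 * D / mass)
  lam <- sqrt(2 * mass * D) / a
  n <- 0:floor(lam - 0.5)
  omega * (n + 0.5) - (omega * (n + 0.5))^2 / (4 * D)
}

# Centroid-projected ring covariance built by an independent route:
# pseudo-inverse of the spring precision matrix via its full eigensystem,
# then projection with J = I - 11^T / P on both sides.
ring_covariance_by_pinv <- function(P, lambda2) {
  A <- matrix(0, P, P)
  for (i in seq_len(P)) {
    j <- if (i == P) 1L else i + 1L
    A[i, i] <- A[i, i] + 2
    A[i, j] <- A[i, j] - 1
    A[j, i] <- A[j, i] - 1
  }
  A <- (P / lambda2) * A
  ev <- eigen(A, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-12
  Apinv <- ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  J <- diag(P) - matrix(1 / P, P, P)
  J %*% Apinv %*% J
}

# standard harmonic-1d test fixture in reduced units
harmonic_fixture <- function(beta = 3, k = 1, n_configs = 100,
                             seed = 1) {
  th <- reduced_thermo(beta)
  surf <- make_model(model_spec("harmonic-1d", list(k = k)))
  ens <- run_metropolis(surf, matrix(0, 1, 3), th,
                        n_steps = n_configs * 40L, step_size = 1.5,
                        save_interval = 40L, n_equilibration = 0L,
                        seed = seed)
  list(thermo = th, surface = surf, ensemble = ens)
}
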