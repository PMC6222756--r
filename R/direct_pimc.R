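#' Direct path-integral Monte Carlo estimate of the isotope ratio
#'
#' Independent cross-check of the double-average PI-FEP estimator: a naive
#' Metropolis simulation of the full ring-polymer system under the
#' discretized effective potential ([effective_potential()]) of the light
#' isotopologue -- single-bead displacement moves plus whole-ring
#' translation moves, with no centroid constraint and no free-particle
#' reference. The heavy/light ratio is accumulated as the FEP average of
#' `e^{-beta dU}` where `dU` is the bead-averaged potential-energy change
#' under mass-scaling of the bead displacements about each ring's own
#' centroid (the spring-energy change vanishes identically under that
#' scaling, and the same analytic mass factor as in [estimate_ratio()]
#' restores the full ratio).
#'
#' At a common bead count `P`, this estimator and [estimate_ratio()] target
#' exactly the same discretized partition-function ratio.
#'
#' Currently supports surfaces whose quantized region covers all atoms
#' (the gas-phase model systems).
#'
#' @param surface a `potential_surface`.
#' @param region a [quantized_region()] covering every atom of `surface`.
#' @param thermo a [thermo_state()].
#' @param P bead count (power of two, >= 4).
#' @param n_sweeps Monte Carlo sweeps (one sweep = one trial move per bead
#'   plus one ring-translation trial per atom).
#' @param n_equilibration sweeps discarded before accumulation.
#' @param step_size maximum bead displacement per coordinate.
#' @param translate_size maximum whole-ring translation per coordinate.
#' @param n_walkers independent replicas run in parallel (vectorized).
#' @param n_blocks blocks (over sweeps) for the error estimate.
#' @param seed integer seed.
#' @param start optional `n_atoms x 3` starting configuration (defaults to
#'   the origin-centered fixture configuration).
#' @return a `ratio_estimate` (metadata records the acceptance rates).
#' @seealso [estimate_ratio()]
#' @export
direct_pimc_ratio <- function(surface, region, thermo, P, n_sweeps,
                              n_equilibration, step_size,
                              translate_size = step_size, n_walkers = 32L,
                              n_blocks = 10L, seed = 1L, start = NULL) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(region, "quantized_region"),
            inherits(thermo, "thermo_state"))
  check_bead_count(P)
  if (!setequal(region$atom_indices, seq_len(surface$n_atoms))) {
    stop("direct_pimc_ratio requires every atom of the surface to be quantized",
         call. = FALSE)
  }
  if (n_equilibration < 0 || n_sweeps <= n_equilibration) {
    stop("require n_sweeps > n_equilibration >= 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  beta <- thermo$beta
  dims <- surface$dims
  n_atoms <- surface$n_atoms
  M <- length(region$atom_indices)
  ord <- order(region$atom_indices)
  atoms <- region$atom_indices[ord]
  m_light <- region$masses_light[ord]
  m_heavy <- region$masses_heavy[ord]
  if (is.null(start)) start <- matrix(0, n_atoms, 3)

  # bead coordinates: list over atoms of [n_walkers, P, dims]
  beads <- lapply(seq_len(M), function(q) {
    b <- array(0, dim = c(n_walkers, P, dims))
    for (d in seq_len(dims)) b[, , d] <- start[atoms[q], d]
    b
  })
  spring_k <- (P / (2 * beta)) /
    thermal_wavelength_sq(m_light, thermo) # per atom, kcal/mol/A^2

  # slice energies for all walkers: build [n_walkers * P, n_atoms, 3]
  slice_energy_matrix <- function(bds) {
    X <- aperm(array(t(start), dim = c(3L, n_atoms, n_walkers * P)),
               c(3L, 2L, 1L))
    for (q in seq_len(M)) {
      for (d in seq_len(dims)) {
        X[, atoms[q], d] <- as.vector(bds[[q]][, , d]) # walker fastest, bead outer
      }
    }
    matrix(surface$energy_many(X), nrow = n_walkers) # [n_walkers, P]
  }
  # X row index must be walker + (bead-1)*n_walkers: as.vector of
  # [n_walkers, P] gives exactly that ordering.

  e_slice <- slice_energy_matrix(beads) # [n_walkers, P]
  acc_bead <- 0
  tot_bead <- 0
  acc_ring <- 0
  tot_ring <- 0
  fep_sweep <- numeric(n_sweeps - n_equilibration)
  mf <- classical_mass_factor(region, dims)
  s_disp <- sqrt(m_light / m_heavy)

  for (sweep in seq_len(n_sweeps)) {
    for (q in seq_len(M)) {
      kq <- spring_k[q]
      for (i in seq_len(P)) {
        ip <- if (i == P) 1L else i + 1L
        im <- if (i == 1L) P else i - 1L
        old <- matrix(beads[[q]][, i, ], n_walkers, dims)
        prop <- old + matrix(stats::runif(n_walkers * dims, -step_size,
                                          step_size), n_walkers, dims)
        nb1 <- matrix(beads[[q]][, ip, ], n_walkers, dims)
        nb2 <- matrix(beads[[q]][, im, ], n_walkers, dims)
        d_spring <- kq * (rowSums((prop - nb1)^2) + rowSums((prop - nb2)^2) -
                            rowSums((old - nb1)^2) - rowSums((old - nb2)^2))
        # potential change: slice i with atom q moved
        X <- aperm(array(t(start), dim = c(3L, n_atoms, n_walkers)),
                   c(3L, 2L, 1L))
        for (q2 in seq_len(M)) {
          X[, atoms[q2], seq_len(dims)] <- matrix(beads[[q2]][, i, ],
                                                  n_walkers, dims)
        }
        X[, atoms[q], seq_len(dims)] <- prop
        e_new <- surface$energy_many(X)
        d_pot <- (e_new - e_slice[, i]) / P
        accept <- stats::runif(n_walkers) <
          exp(-beta * (d_spring + d_pot))
        accept[!is.finite(e_new)] <- FALSE
        if (any(accept)) {
          beads[[q]][accept, i, ] <- prop[accept, ]
          e_slice[accept, i] <- e_new[accept]
        }
        acc_bead <- acc_bead + sum(accept)
        tot_bead <- tot_bead + n_walkers
      }
      # whole-ring translation (spring energy invariant)
      shift <- matrix(stats::runif(n_walkers * dims, -translate_size,
                                   translate_size), n_walkers, dims)
      prop_beads <- beads[[q]]
      for (d in seq_len(dims)) prop_beads[, , d] <- prop_beads[, , d] + shift[, d]
      tmp <- beads[[q]]
      beads[[q]] <- prop_beads
      e_new_slice <- slice_energy_matrix(beads)
      d_pot <- rowMeans(e_new_slice) - rowMeans(e_slice)
      accept <- stats::runif(n_walkers) < exp(-beta * d_pot)
      accept[!is.finite(d_pot)] <- FALSE
      beads[[q]][!accept, , ] <- tmp[!accept, , ]
      e_slice[accept, ] <- e_new_slice[accept, , drop = FALSE]
      acc_ring <- acc_ring + sum(accept)
      tot_ring <- tot_ring + n_walkers
    }
    if (sweep > n_equilibration) {
      # FEP weight: scale displacements about each ring's centroid
      heavy <- lapply(seq_len(M), function(q) {
        b <- beads[[q]]
        for (d in seq_len(dims)) {
          cen <- rowMeans(b[, , d])
          b[, , d] <- cen + s_disp[q] * (b[, , d] - cen)
        }
        b
      })
      e_heavy <- slice_energy_matrix(heavy)
      dU <- rowMeans(e_heavy) - rowMeans(e_slice) # per walker
      fep_sweep[sweep - n_equilibration] <- mean(exp(-beta * dU))
    }
  }
  bs <- block_statistics(fep_sweep, n_blocks)
  ratio_estimate(
    ratio = mf * bs$mean, stderr = mf * bs$stderr,
    block_values = mf * bs$block_means, P = as.integer(P),
    metadata = list(estimator = "direct-pimc", n_sweeps = n_sweeps,
                    n_walkers = n_walkers, seed = as.integer(seed),
                    acceptance_bead = acc_bead / max(1, tot_bead),
                    acceptance_ring = acc_ring / max(1, tot_ring),
                    mass_factor = mf, ratio_reduced = bs$mean)
  )
}
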