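#' Quantized region with isotope mass pairs
#'
#' Names the atoms whose nuclei are treated quantum mechanically (in the
#' solute/solvent application: atoms within two covalent bonds of the site
#' of isotope exchange) and carries their light/heavy mass pairs for the
#' alchemical FEP mutation.
#'
#' @param atom_indices integer indices of the quantized atoms.
#' @param masses_light light-isotope masses (amu), aligned with
#'   `atom_indices`.
#' @param masses_heavy heavy-isotope masses (amu), aligned with
#'   `atom_indices`.
#' @return object of class `quantized_region`.
#' @examples
#' quantized_region(1, masses_light = 16, masses_heavy = 18)
#' @export
quantized_region <- function(atom_indices, masses_light, masses_heavy) {
  atom_indices <- as.integer(atom_indices)
  masses_light <- rep_len(as.numeric(masses_light), length(atom_indices))
  masses_heavy <- rep_len(as.numeric(masses_heavy), length(atom_indices))
  if (length(atom_indices) == 0) {
    stop("at least one quantized atom is required", call. = FALSE)
  }
  if (any(masses_light <= 0) || any(masses_heavy <= 0)) {
    stop("all masses must be positive", call. = FALSE)
  }
  structure(
    list(atom_indices = atom_indices, masses_light = masses_light,
         masses_heavy = masses_heavy),
    class = "quantized_region"
  )
}

#' @export
print.quantized_region <- function(x, ...) {
  cat(sprintf("<quantized_region> atoms {%s}: m_L = {%s}, m_H = {%s} amu\n",
              paste(x$atom_indices, collapse = ","),
              paste(x$masses_light, collapse = ","),
              paste(x$masses_heavy, collapse = ",")))
  invisible(x)
}

# classical mass factor Q_FP^H / Q_FP^L = prod_q (m_H/m_L)^(dims/2); the
# analytic remainder of the free-particle normalization after the
# mass-scaled, centroid-constrained variable switch.
classical_mass_factor <- function(region, dims) {
  prod((region$masses_heavy / region$masses_light)^(dims / 2))
}

#' Difference potential of a ring-polymer configuration
#'
#' The averaged slice potential minus the classical potential,
#' `(1/P) sum_i U(slice_i, S) - U(s, S)`, where slice `i` places all
#' quantized atoms at their bead-`i` positions simultaneously and the bath
#' stays at its classical coordinates. This is the quantity whose Boltzmann
#' factor is accumulated in the inner free-particle average.
#'
#' @param paths list of [ring_polymer_path()], one per quantized atom, all
#'   with the same bead count; each path's centroid must coincide with the
#'   configuration's coordinates for its atom (to 1e-8 A).
#' @param config `n_atoms x 3` classical configuration (A).
#' @param surface a `potential_surface`.
#' @param u_classical optional precomputed classical energy `U(s, S)`
#'   (cacheable per configuration).
#' @return difference potential (kcal/mol).
#' @export
delta_u_bar <- function(paths, config, surface, u_classical = NULL) {
  stopifnot(is.list(paths), inherits(surface, "potential_surface"))
  config <- as.matrix(config)
  P <- paths[[1]]$P
  for (p in paths) {
    stopifnot(inherits(p, "ring_polymer_path"))
    if (p$P != P) stop("all paths must share one bead count", call. = FALSE)
    mism <- max(abs(p$centroid - config[p$atom_index, ]))
    if (mism > 1e-8) {
      stop(sprintf(
        "path centroid for atom %d deviates from the classical configuration by %.3g A (> 1e-8)",
        p$atom_index, mism), call. = FALSE)
    }
  }
  if (is.null(u_classical)) u_classical <- surface$energy(config)
  X <- aperm(array(config, dim = c(nrow(config), 3L, P)), c(3L, 1L, 2L))
  for (p in paths) X[, p$atom_index, ] <- p$beads
  mean(surface$energy_many(X)) - u_classical
}

#' Inner average result for one centroid configuration
#' @keywords internal
inner_average_result <- function(log_numerator, log_denominator, n_paths,
                                 config_index = NA_integer_) {
  structure(
    list(numerator_mean = exp(log_numerator),
         denominator_mean = exp(log_denominator),
         log_numerator = log_numerator, log_denominator = log_denominator,
         n_paths = n_paths, config_index = config_index),
    class = "inner_average_result"
  )
}

#' Free-particle inner average at one centroid configuration
#'
#' For one classical configuration, draws `n_discard + n_paths` closed
#' free-particle paths per quantized atom at the light-isotope masses
#' (discarding the first `n_discard`), builds the companion heavy paths by
#' [scale_path_for_mass()] sharing the same bisection vectors, and
#' accumulates the two free-particle ensemble means of the PI-FEP estimator
#' (numerator `e^{-beta dU_H}` = `e^{-beta ddU} e^{-beta dU_L}`, denominator
#' `e^{-beta dU_L}`). Accumulation is done in log space with a max shift, so
#' large difference potentials cannot overflow.
#'
#' @param config `n_atoms x 3` classical configuration (A).
#' @param surface a `potential_surface`.
#' @param region a [quantized_region()].
#' @param thermo a [thermo_state()].
#' @param P bead count (power of two, >= 4).
#' @param n_paths free-particle draws retained for averaging (default 200).
#' @param n_discard initial draws discarded (default 10; the free-particle
#'   draws are i.i.d., so this is a protocol convention rather than an
#'   equilibration need).
#' @param seed integer seed for this configuration's substream.
#' @param u_classical optional precomputed classical energy.
#' @param config_index index recorded in the result.
#' @return an `inner_average_result` with fields `numerator_mean`,
#'   `denominator_mean` (both strictly positive), `log_numerator`,
#'   `log_denominator`, `n_paths`, `config_index`.
#' @export
inner_fp_average <- function(config, surface, region, thermo, P,
                             n_paths = 200L, n_discard = 10L, seed = 1L,
                             u_classical = NULL,
                             config_index = NA_integer_) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(region, "quantized_region"),
            inherits(thermo, "thermo_state"))
  check_bead_count(P)
  if (n_paths < 1) stop("`n_paths` must be >= 1", call. = FALSE)
  config <- as.matrix(config)
  set.seed(as.integer(seed))
  n_tot <- n_discard + n_paths
  dims <- surface$dims
  if (is.null(u_classical)) u_classical <- surface$energy(config)
  keep <- (n_discard + 1L):n_tot

  # displacements per quantized atom: [n_paths, P, dims]
  disp <- lapply(seq_along(region$atom_indices), function(qi) {
    lambda2 <- thermal_wavelength_sq(region$masses_light[qi], thermo)
    d <- sample_fp_displacements(n_tot, P, lambda2, dims)
    d[keep, , , drop = FALSE]
  })

  slice_energies <- function(scale) {
    # one big [n_paths * P, n_atoms, 3] array; slice s = (path-1)*P + i
    X <- aperm(array(config, dim = c(nrow(config), 3L, n_paths * P)),
               c(3L, 1L, 2L))
    for (qi in seq_along(region$atom_indices)) {
      atom <- region$atom_indices[qi]
      for (d in seq_len(dims)) {
        # flatten [n_paths, P] -> bead index fastest within path
        X[, atom, d] <- config[atom, d] +
          scale[qi] * as.vector(t(disp[[qi]][, , d]))
      }
    }
    matrix(surface$energy_many(X), nrow = P) # column = one path
  }

  e_light <- slice_energies(rep(1, length(region$atom_indices)))
  du_light <- colMeans(e_light) - u_classical
  s <- sqrt(region$masses_light / region$masses_heavy)
  if (all(s == 1)) {
    du_heavy <- du_light # identity perturbation, exactly
  } else {
    e_heavy <- slice_energies(s)
    du_heavy <- colMeans(e_heavy) - u_classical
  }
  beta <- thermo$beta
  if (any(!is.finite(du_light)) || any(!is.finite(du_heavy))) {
    stop("non-finite difference potential encountered in inner average",
         call. = FALSE)
  }
  inner_average_result(
    log_numerator = logmeanexp(-beta * du_heavy),
    log_denominator = logmeanexp(-beta * du_light),
    n_paths = n_paths, config_index = config_index
  )
}

#' Partition-function ratio estimate with block uncertainty
#' @keywords internal
ratio_estimate <- function(ratio, stderr, block_values, P, metadata = list()) {
  structure(
    list(ratio = ratio, stderr = stderr, block_values = block_values,
         n_blocks = length(block_values), P = P, metadata = metadata),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate> Q_H/Q_L = %.6f +/- %.6f  (P = %d, %d blocks)\n",
              x$ratio, x$stderr, x$P, x$n_blocks))
  invisible(x)
}

#' PI-FEP estimate of the heavy/light partition-function ratio
#'
#' The double-average estimator: for every configuration of the classical
#' (centroid) ensemble, an inner free-particle average over
#' centroid-constrained ring polymers of the light isotopologue yields the
#' per-configuration numerator and denominator means; the ratio of their
#' outer (ensemble) averages, multiplied by the analytic free-particle mass
#' factor `prod_q (m_H/m_L)^{dims/2}`, is the full quantum partition
#' function ratio `Q_H/Q_L`. A single simulation of the light isotopologue
#' suffices; the heavy paths are obtained by mass-scaling the same
#' bisection vectors.
#'
#' The uncertainty is estimated from `n_blocks` contiguous blocks of
#' configurations: the standard deviation of the block ratios divided by
#' `sqrt(n_blocks)`.
#'
#' @param ensemble a [centroid_ensemble()] (non-empty).
#' @param surface a `potential_surface`.
#' @param region a [quantized_region()].
#' @param thermo a [thermo_state()].
#' @param P bead count (power of two, >= 4; default 32).
#' @param n_paths free-particle draws per configuration (default 200).
#' @param n_discard initial draws discarded per configuration (default 10).
#' @param n_blocks number of blocks for the error estimate (default 10).
#' @param seed master seed; every configuration gets its own substream.
#' @return a `ratio_estimate` with fields `ratio` (full `Q_H/Q_L`),
#'   `stderr`, `block_values`, `n_blocks`, `P` and `metadata` (including
#'   `ratio_reduced`, the Bigeleisen-convention reduced ratio without the
#'   classical mass factor, plus counts and the seed).
#' @examples
#' surf <- make_model(model_spec("harmonic-1d"))
#' th <- thermo_state(1 / 3, reduced = TRUE)
#' ens <- run_metropolis(surf, matrix(0, 1, 3), th, 2000, 1,
#'                       save_interval = 50, seed = 4)
#' reg <- quantized_region(1, 1, 2)
#' estimate_ratio(ens, surf, reg, th, P = 16, n_paths = 50, seed = 7)
#' @export
estimate_ratio <- function(ensemble, surface, region, thermo, P = 32L,
                           n_paths = 200L, n_discard = 10L, n_blocks = 10L,
                           seed = 1L) {
  stopifnot(inherits(ensemble, "centroid_ensemble"))
  n_conf <- length(ensemble)
  if (n_conf == 0) stop("empty centroid ensemble", call. = FALSE)
  if (n_blocks < 2) stop("`n_blocks` must be >= 2", call. = FALSE)
  if (n_conf < n_blocks) {
    stop(sprintf("%d configurations cannot fill %d blocks", n_conf, n_blocks),
         call. = FALSE)
  }
  log_num <- numeric(n_conf)
  log_den <- numeric(n_conf)
  for (j in seq_len(n_conf)) {
    res <- inner_fp_average(
      ensemble$configurations[[j]], surface, region, thermo, P,
      n_paths = n_paths, n_discard = n_discard,
      seed = substream_seed(seed, j), config_index = j
    )
    log_num[j] <- res$log_numerator
    log_den[j] <- res$log_denominator
  }
  mf <- classical_mass_factor(region, surface$dims)
  ratio_of_means <- function(idx) {
    mf * exp(logmeanexp(log_num[idx]) - logmeanexp(log_den[idx]))
  }
  blocks <- block_indices(n_conf, n_blocks)
  block_values <- vapply(blocks, ratio_of_means, numeric(1))
  ratio_estimate(
    ratio = ratio_of_means(seq_len(n_conf)),
    stderr = stats::sd(block_values) / sqrt(n_blocks),
    block_values = block_values, P = as.integer(P),
    metadata = list(n_configs = n_conf, n_paths = n_paths,
                    n_discard = n_discard, seed = as.integer(seed),
                    mass_factor = mf,
                    ratio_reduced = ratio_of_means(seq_len(n_conf)) / mf)
  )
}

# contiguous block index partition; trailing remainder goes to the last block
block_indices <- function(n, n_blocks) {
  size <- n %/% n_blocks
  lapply(seq_len(n_blocks), function(b) {
    from <- (b - 1L) * size + 1L
    to <- if (b == n_blocks) n else b * size
    from:to
  })
}

#' Block-average statistics
#'
#' Partitions an ordered series into `n_blocks` contiguous blocks (any
#' trailing remainder is appended to the last block) and estimates the
#' standard error of the mean as the standard deviation of the block means
#' divided by `sqrt(n_blocks)` -- the standard error analysis for correlated
#' simulation output.
#'
#' @param values ordered numeric series.
#' @param n_blocks number of blocks (>= 2, and at most `length(values)`).
#' @return list with `mean`, `stderr` and `block_means`.
#' @examples
#' block_statistics(c(1, 2, 3, 4), 2) # mean 2.5, block means 1.5, 3.5
#' @export
block_statistics <- function(values, n_blocks) {
  if (n_blocks < 2) stop("`n_blocks` must be >= 2", call. = FALSE)
  if (length(values) < n_blocks) {
    stop(sprintf("series of length %d cannot fill %d blocks",
                 length(values), n_blocks), call. = FALSE)
  }
  blocks <- block_indices(length(values), n_blocks)
  block_means <- vapply(blocks, function(idx) mean(values[idx]), numeric(1))
  list(mean = mean(values), stderr = stats::sd(block_means) / sqrt(n_blocks),
       block_means = block_means)
}

#' Quantum-reweighted ensemble average of a classical observable
#'
#' Umbrella-style reweighting of the classical configurational average by
#' the free-particle Boltzmann factor of the difference potential:
#' `<O e^{-beta dU}> / <e^{-beta dU}>` over the double average. With a free
#' particle (`U = 0`) this reduces to the plain classical average.
#'
#' @param observable `function(config)` returning a scalar.
#' @inheritParams estimate_ratio
#' @return the reweighted average (scalar).
#' @export
reweight_observable <- function(observable, ensemble, surface, region,
                                thermo, P = 32L, n_paths = 200L,
                                n_discard = 10L, seed = 1L) {
  stopifnot(is.function(observable), inherits(ensemble, "centroid_ensemble"))
  n_conf <- length(ensemble)
  if (n_conf == 0) stop("empty centroid ensemble", call. = FALSE)
  obs <- numeric(n_conf)
  log_w <- numeric(n_conf)
  for (j in seq_len(n_conf)) {
    cfg <- ensemble$configurations[[j]]
    res <- inner_fp_average(cfg, surface, region, thermo, P,
                            n_paths = n_paths, n_discard = n_discard,
                            seed = substream_seed(seed, j), config_index = j)
    obs[j] <- observable(cfg)
    log_w[j] <- res$log_denominator
  }
  w <- exp(log_w - max(log_w))
  sum(obs * w) / sum(w)
}

#' Discretized effective potential of a ring-polymer configuration
#'
#' The primitive path-integral effective potential: harmonic spring energy
#' between adjacent beads plus the bead-averaged slice potential,
#' `sum_q (P / (2 beta lambda_q^2)) sum_i (r_i^q - r_{i+1}^q)^2 +
#' (1/P) sum_i U(slice_i, S)` with cyclic bead indexing. Provided as the
#' basis of the direct path-integral Monte Carlo cross-check
#' ([direct_pimc_ratio()]).
#'
#' @param paths list of [ring_polymer_path()], one per quantized atom.
#' @param config `n_atoms x 3` classical configuration carrying the
#'   non-quantized atoms.
#' @param surface a `potential_surface`.
#' @param thermo a [thermo_state()].
#' @return effective potential (kcal/mol).
#' @export
effective_potential <- function(paths, config, surface, thermo) {
  stopifnot(is.list(paths), inherits(surface, "potential_surface"),
            inherits(thermo, "thermo_state"))
  config <- as.matrix(config)
  P <- paths[[1]]$P
  spring <- 0
  for (p in paths) {
    lambda2 <- thermal_wavelength_sq(p$mass, thermo)
    d <- p$beads - p$beads[c(2:P, 1L), , drop = FALSE]
    spring <- spring + (P / (2 * thermo$beta * lambda2)) * sum(d^2)
  }
  X <- aperm(array(config, dim = c(nrow(config), 3L, P)), c(3L, 1L, 2L))
  for (p in paths) X[, p$atom_index, ] <- p$beads
  spring + mean(surface$energy_many(X))
}

#' Bead-count convergence scan
#'
#' Runs [estimate_ratio()] for each bead count in `P_values` against one
#' shared centroid ensemble, giving each bead count a fresh free-particle
#' substream, and returns a tidy table of ratios with uncertainties.
#'
#' @param P_values integer vector of bead counts (each a power of two).
#' @inheritParams estimate_ratio
#' @return `data.frame` with columns `P`, `n_configs`, `n_paths`, `ratio`,
#'   `stderr`; the full `ratio_estimate` objects are attached as the
#'   `"estimates"` attribute.
#' @export
convergence_scan <- function(P_values, ensemble, surface, region, thermo,
                             n_paths = 200L, n_discard = 10L, n_blocks = 10L,
                             seed = 1L) {
  for (P in P_values) check_bead_count(P)
  estimates <- lapply(seq_along(P_values), function(k) {
    estimate_ratio(ensemble, surface, region, thermo, P = P_values[k],
                   n_paths = n_paths, n_discard = n_discard,
                   n_blocks = n_blocks,
                   seed = substream_seed(seed, 1000L + k))
  })
  out <- data.frame(
    P = as.integer(P_values),
    n_configs = length(ensemble),
    n_paths = as.integer(n_paths),
    ratio = vapply(estimates, function(e) e$ratio, numeric(1)),
    stderr = vapply(estimates, function(e) e$stderr, numeric(1))
  )
  attr(out, "estimates") <- estimates
  out
}
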