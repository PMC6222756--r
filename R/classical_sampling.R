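#' Centroid (classical configuration) ensemble
#'
#' Ordered collection of classical configurations that supplies the centroid
#' positions for the outer average of the PI-FEP double average. Usually
#' produced by [run_metropolis()] or [run_langevin_md()]; can also be read
#' from a multi-frame XYZ file with [read_xyz()].
#'
#' @param configurations list of `n_atoms x 3` coordinate matrices (A), all
#'   with the same atom count and ordering.
#' @param temperature sampling temperature (K or reduced).
#' @param save_interval spacing (in sampler steps) between stored frames.
#' @param provenance named list recording the sampler, seed and parameters.
#' @return object of class `centroid_ensemble`.
#' @export
centroid_ensemble <- function(configurations, temperature,
                              save_interval = 1L, provenance = list()) {
  if (!is.list(configurations) || length(configurations) == 0) {
    stop("`configurations` must be a non-empty list of coordinate matrices",
         call. = FALSE)
  }
  dims <- vapply(configurations, function(m) dim(m)[1], numeric(1))
  if (length(unique(dims)) != 1) {
    stop("all configurations must have the same atom count", call. = FALSE)
  }
  if (save_interval < 1) stop("`save_interval` must be >= 1", call. = FALSE)
  structure(
    list(configurations = configurations, temperature = temperature,
         save_interval = as.integer(save_interval), provenance = provenance),
    class = "centroid_ensemble"
  )
}

#' @export
length.centroid_ensemble <- function(x) length(x$configurations)

#' @export
print.centroid_ensemble <- function(x, ...) {
  cat(sprintf(
    "<centroid_ensemble> %d frame(s) of %d atom(s), T = %g, every %d step(s) [%s]\n",
    length(x), nrow(x$configurations[[1]]), x$temperature, x$save_interval,
    if (!is.null(x$provenance$sampler)) x$provenance$sampler else "unknown"))
  invisible(x)
}

#' Metropolis Monte Carlo sampling of the classical ensemble
#'
#' Single-atom displacement Metropolis sampling of the Boltzmann
#' distribution `exp(-beta U)` on a potential surface. Only the surface's
#' active dimensions are perturbed. Configurations after `n_equilibration`
#' steps are retained every `save_interval` steps.
#'
#' @param surface a `potential_surface`.
#' @param start `n_atoms x 3` starting configuration.
#' @param thermo a [thermo_state()].
#' @param n_steps total number of Metropolis proposals.
#' @param step_size maximum displacement per coordinate (A).
#' @param save_interval keep every `save_interval`-th configuration.
#' @param n_equilibration proposals discarded before retention starts.
#' @param seed integer seed (deterministic for a fixed seed).
#' @return a [centroid_ensemble()]; its provenance records the acceptance
#'   rate.
#' @examples
#' surf <- make_model(model_spec("harmonic-1d"))
#' th <- thermo_state(1, reduced = TRUE)
#' ens <- run_metropolis(surf, matrix(0, 1, 3), th, 1000, 0.5,
#'                       save_interval = 100, n_equilibration = 500, seed = 1)
#' length(ens) # 5
#' @export
run_metropolis <- function(surface, start, thermo, n_steps, step_size,
                           save_interval = 1L, n_equilibration = 0L,
                           seed = 1L) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(thermo, "thermo_state"))
  if (n_equilibration < 0 || n_steps <= n_equilibration) {
    stop("require n_steps > n_equilibration >= 0", call. = FALSE)
  }
  if (step_size <= 0) stop("`step_size` must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  conf <- as.matrix(start)
  beta <- thermo$beta
  dims <- surface$dims
  n_atoms <- surface$n_atoms
  e_cur <- surface$energy(conf)
  if (!is.finite(e_cur)) stop("non-finite energy at start", call. = FALSE)
  kept <- vector("list", (n_steps - n_equilibration) %/% save_interval + 1L)
  n_kept <- 0L
  n_acc <- 0L
  for (step in seq_len(n_steps)) {
    atom <- if (n_atoms == 1L) 1L else sample.int(n_atoms, 1L)
    prop <- conf
    prop[atom, seq_len(dims)] <- prop[atom, seq_len(dims)] +
      stats::runif(dims, -step_size, step_size)
    e_new <- surface$energy(prop)
    if (is.finite(e_new) &&
        (e_new <= e_cur || stats::runif(1) < exp(-beta * (e_new - e_cur)))) {
      conf <- prop
      e_cur <- e_new
      n_acc <- n_acc + 1L
    }
    if (step > n_equilibration &&
        (step - n_equilibration) %% save_interval == 0L) {
      n_kept <- n_kept + 1L
      kept[[n_kept]] <- conf
    }
  }
  if (n_kept == 0L) {
    stop("no configurations retained; increase n_steps or reduce save_interval",
         call. = FALSE)
  }
  centroid_ensemble(
    kept[seq_len(n_kept)], temperature = thermo$temperature,
    save_interval = save_interval,
    provenance = list(sampler = "metropolis", seed = as.integer(seed),
                      n_steps = n_steps, step_size = step_size,
                      n_equilibration = n_equilibration,
                      acceptance = n_acc / n_steps)
  )
}

#' Langevin molecular dynamics sampling of the classical ensemble
#'
#' BAOAB velocity-Verlet integration with a Langevin thermostat, using the
#' surface's analytic gradient. In physical units the timestep is in fs and
#' the friction in 1/fs; in reduced units all conversion factors are 1.
#'
#' @inheritParams run_metropolis
#' @param timestep integration step (fs).
#' @param friction Langevin friction (1/fs).
#' @return a [centroid_ensemble()]; provenance records the mean kinetic
#'   temperature over the production phase.
#' @export
run_langevin_md <- function(surface, start, thermo, n_steps, timestep,
                            friction, save_interval = 1L,
                            n_equilibration = 0L, seed = 1L) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(thermo, "thermo_state"))
  if (is.null(surface$gradient)) {
    stop("surface provides no gradient; Langevin MD unavailable",
         call. = FALSE)
  }
  if (timestep <= 0) stop("`timestep` must be positive", call. = FALSE)
  if (n_equilibration < 0 || n_steps <= n_equilibration) {
    stop("require n_steps > n_equilibration >= 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  conv <- if (thermo$reduced) 1 else 1 / .kcal_per_amu_A2_fs2 # force -> accel
  ke_conv <- if (thermo$reduced) 1 else .kcal_per_amu_A2_fs2 # amu A^2/fs^2 -> kcal/mol
  n_atoms <- surface$n_atoms
  dims <- surface$dims
  active <- seq_len(dims)
  m <- surface$masses
  kT <- thermo$kB * thermo$temperature
  conf <- as.matrix(start)
  # Maxwell-Boltzmann start velocities on active dims
  v <- matrix(0, n_atoms, 3)
  sd_v <- sqrt(kT / (m * ke_conv))
  v[, active] <- stats::rnorm(n_atoms * dims) * sd_v
  g <- surface$gradient(conf)
  acc <- -g * conv / m
  c1 <- exp(-friction * timestep)
  c2 <- sqrt(pmax(0, 1 - c1^2)) * sd_v
  kept <- vector("list", (n_steps - n_equilibration) %/% save_interval + 1L)
  n_kept <- 0L
  t_kin_sum <- 0
  t_kin_n <- 0L
  half <- timestep / 2
  for (step in seq_len(n_steps)) {
    v[, active] <- v[, active] + half * acc[, active]
    conf[, active] <- conf[, active] + half * v[, active]
    v[, active] <- c1 * v[, active] +
      c2 * matrix(stats::rnorm(n_atoms * dims), n_atoms, dims)
    conf[, active] <- conf[, active] + half * v[, active]
    g <- surface$gradient(conf)
    if (any(!is.finite(g))) {
      stop(sprintf("energy divergence at MD step %d (non-finite gradient)",
                   step), call. = FALSE)
    }
    acc <- -g * conv / m
    v[, active] <- v[, active] + half * acc[, active]
    if (step > n_equilibration) {
      t_kin_sum <- t_kin_sum +
        sum(m * rowSums(v[, active, drop = FALSE]^2)) * ke_conv /
        (n_atoms * dims * thermo$kB)
      t_kin_n <- t_kin_n + 1L
      if ((step - n_equilibration) %% save_interval == 0L) {
        n_kept <- n_kept + 1L
        kept[[n_kept]] <- conf
      }
    }
  }
  if (n_kept == 0L) {
    stop("no configurations retained; increase n_steps or reduce save_interval",
         call. = FALSE)
  }
  centroid_ensemble(
    kept[seq_len(n_kept)], temperature = thermo$temperature,
    save_interval = save_interval,
    provenance = list(sampler = "langevin", seed = as.integer(seed),
                      n_steps = n_steps, timestep = timestep,
                      friction = friction, n_equilibration = n_equilibration,
                      kinetic_temperature = t_kin_sum / max(1L, t_kin_n))
  )
}
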