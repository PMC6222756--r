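#' Run the classical sampler described by a run configuration
#'
#' Builds the surface and fixture configuration from the config's model
#' block and runs the configured sampler (Metropolis or Langevin MD) with a
#' substream of the master seed.
#'
#' @param config a `run_config` from [parse_config()].
#' @return a [centroid_ensemble()].
#' @export
run_sampler <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- thermo_state(config$temperature, reduced = config$reduced)
  fix <- generate_fixture_system(config$model,
                                 seed = substream_seed(config$seed, 11L))
  s <- config$sampler
  if (s$name == "metropolis") {
    run_metropolis(fix$surface, fix$configuration, th,
                   n_steps = s$n_steps, step_size = s$step_size,
                   save_interval = s$save_interval,
                   n_equilibration = s$n_equilibration,
                   seed = substream_seed(config$seed, 12L))
  } else {
    run_langevin_md(fix$surface, fix$configuration, th,
                    n_steps = s$n_steps, timestep = s$timestep,
                    friction = s$friction, save_interval = s$save_interval,
                    n_equilibration = s$n_equilibration,
                    seed = substream_seed(config$seed, 12L))
  }
}

#' Run the PI-FEP estimator described by a run configuration
#'
#' @param config a `run_config`.
#' @param ensemble a [centroid_ensemble()]; when `NULL`, [run_sampler()] is
#'   invoked first (full-pipeline determinism from the single master seed).
#' @return a `ratio_estimate`.
#' @export
run_estimate <- function(config, ensemble = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(ensemble)) ensemble <- run_sampler(config)
  th <- thermo_state(config$temperature, reduced = config$reduced)
  surface <- make_model(config$model)
  region <- quantized_region(config$isotopes$atom_indices,
                             config$isotopes$masses_light,
                             config$isotopes$masses_heavy)
  est <- config$estimator
  estimate_ratio(ensemble, surface, region, th, P = est$P,
                 n_paths = est$n_paths, n_discard = est$n_discard,
                 n_blocks = est$n_blocks,
                 seed = substream_seed(config$seed, 13L))
}

#' Tidy one or more ratio estimates for CSV output
#'
#' @param estimates a `ratio_estimate` or list of them.
#' @return `data.frame` with columns `P`, `n_configs`, `n_paths`, `ratio`,
#'   `stderr`, `block_means` (semicolon-joined on write), `seed`.
#' @export
ratio_results_table <- function(estimates) {
  if (inherits(estimates, "ratio_estimate")) estimates <- list(estimates)
  data.frame(
    P = vapply(estimates, function(e) e$P, integer(1)),
    n_configs = vapply(estimates, function(e)
      as.integer(e$metadata$n_configs %||% NA_integer_), integer(1)),
    n_paths = vapply(estimates, function(e)
      as.integer(e$metadata$n_paths %||% NA_integer_), integer(1)),
    ratio = vapply(estimates, function(e) e$ratio, numeric(1)),
    stderr = vapply(estimates, function(e) e$stderr, numeric(1)),
    block_means = I(lapply(estimates, function(e) e$block_values)),
    seed = vapply(estimates, function(e)
      as.integer(e$metadata$seed %||% NA_integer_), integer(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
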