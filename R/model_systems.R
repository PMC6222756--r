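#' Specify a model potential-energy surface
#'
#' A `model_spec` names one of the built-in model systems and its parameters.
#' The models stand in for a solute/solvent simulation while preserving the
#' solute (quantum region) / bath (classical region) partition contract:
#'
#' * `"harmonic-1d"`: one atom in a one-dimensional harmonic well,
#'   `E = k/2 (x - r0)^2`.
#' * `"harmonic-3d"`: one atom in an isotropic three-dimensional harmonic
#'   well, `E = k/2 |r - center|^2`.
#' * `"morse-1d"`: one atom in a one-dimensional Morse well,
#'   `E = D (1 - exp(-a (x - r0)))^2`.
#' * `"diatomic-in-bath"`: a harmonically bonded diatomic solute surrounded
#'   by `n_bath` Lennard-Jones particles. Solute-bath interactions are
#'   scaled by `coupling` and all intermolecular pair interactions are
#'   feathered to zero between `r_on` and `r_off` by [switching_function()].
#'   A soft harmonic wall beyond half the box length keeps the bath bound
#'   (there are no periodic boundaries).
#'
#' @param kind one of `"harmonic-1d"`, `"harmonic-3d"`, `"morse-1d"`,
#'   `"diatomic-in-bath"`.
#' @param parameters named list of model parameters; unset entries take the
#'   defaults listed in Details. Units: `k` kcal/mol/A^2, `r0` A,
#'   `D` kcal/mol, `a` 1/A, `epsilon` kcal/mol, `sigma` A.
#' @param masses per-atom masses (amu); recycled defaults of 1 amu per atom.
#' @return an object of class `model_spec`.
#' @details Parameter defaults:
#' \describe{
#'   \item{harmonic-1d}{`k = 1`, `r0 = 0`}
#'   \item{harmonic-3d}{`k = 1`, `center = c(0, 0, 0)`}
#'   \item{morse-1d}{`D = 8`, `a = 0.8`, `r0 = 0`}
#'   \item{diatomic-in-bath}{`k = 200`, `r0 = 1.1`, `n_bath = 16`,
#'     `epsilon = 0.2`, `sigma = 3.0`, `coupling = 1`, `box = 14`,
#'     `r_on = 13`, `r_off = 13.5`, `wall_k = 5`}
#' }
#' @seealso [make_model()], [generate_fixture_system()]
#' @export
model_spec <- function(kind, parameters = list(), masses = NULL) {
  kinds <- c("harmonic-1d", "harmonic-3d", "morse-1d", "diatomic-in-bath")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop(sprintf("unknown model kind '%s'; available kinds: %s",
                 as.character(kind)[1], paste(kinds, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- switch(kind,
    "harmonic-1d" = list(k = 1, r0 = 0),
    "harmonic-3d" = list(k = 1, center = c(0, 0, 0)),
    "morse-1d" = list(D = 8, a = 0.8, r0 = 0),
    "diatomic-in-bath" = list(k = 200, r0 = 1.1, n_bath = 16, epsilon = 0.2,
                              sigma = 3.0, coupling = 1, box = 14,
                              r_on = 13, r_off = 13.5, wall_k = 5)
  )
  unknown <- setdiff(names(parameters), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown parameter(s) for kind '%s': %s", kind,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  p <- utils::modifyList(defaults, parameters)
  for (nm in intersect(c("k", "D", "a", "epsilon", "sigma"), names(p))) {
    if (!is.numeric(p[[nm]]) || any(p[[nm]] <= 0)) {
      stop(sprintf("parameter '%s' must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (kind == "diatomic-in-bath") {
    if (p$n_bath < 0 || p$n_bath != round(p$n_bath)) {
      stop("`n_bath` must be a non-negative integer", call. = FALSE)
    }
    if (p$r_on >= p$r_off) {
      stop("`r_on` must be smaller than `r_off`", call. = FALSE)
    }
  }
  n_atoms <- switch(kind,
    "harmonic-1d" = 1L, "harmonic-3d" = 1L, "morse-1d" = 1L,
    "diatomic-in-bath" = 2L + as.integer(p$n_bath))
  if (is.null(masses)) masses <- rep(1, n_atoms)
  masses <- rep_len(as.numeric(masses), n_atoms)
  if (any(masses <= 0)) stop("all masses must be positive", call. = FALSE)
  structure(list(kind = kind, parameters = p, masses = masses,
                 n_atoms = n_atoms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d atom%s)\n", x$kind, x$n_atoms,
              if (x$n_atoms > 1) "s" else ""))
  invisible(x)
}

#' Intermolecular switching (feathering) function
#'
#' Smoothly feathers intermolecular interactions to zero between `r_on` and
#' `r_off`, the standard cubic-in-r^2 switching polynomial used in
#' biomolecular simulation. The function is 1 for `r <= r_on`, 0 for
#' `r >= r_off`, and C1-continuous and monotone decreasing in between.
#'
#' @param r distance(s), A.
#' @param r_on switch-on distance, A (default 13.0).
#' @param r_off cutoff distance, A (default 13.5); must exceed `r_on`.
#' @return numeric vector of values in \[0, 1\].
#' @examples
#' switching_function(c(5, 13.2, 14), 13, 13.5)
#' @export
switching_function <- function(r, r_on = 13.0, r_off = 13.5) {
  if (!is.numeric(r_on) || !is.numeric(r_off) || r_on <= 0 || r_on >= r_off) {
    stop("require 0 < r_on < r_off", call. = FALSE)
  }
  r2 <- r^2
  on2 <- r_on^2
  off2 <- r_off^2
  s <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  out <- ifelse(r <= r_on, 1, ifelse(r >= r_off, 0, s))
  out
}

# derivative of the switching function wrt r (for gradients)
switching_function_deriv <- function(r, r_on = 13.0, r_off = 13.5) {
  r2 <- r^2
  on2 <- r_on^2
  off2 <- r_off^2
  # d/dr2 = [-2(off2-r2)(off2+2r2-3on2) + 2(off2-r2)^2] / (off2-on2)^3
  ds_dr2 <- (-2 * (off2 - r2) * (off2 + 2 * r2 - 3 * on2) +
               2 * (off2 - r2)^2) / (off2 - on2)^3
  ifelse(r <= r_on | r >= r_off, 0, ds_dr2 * 2 * r)
}

#' Build a potential-energy surface from a model specification
#'
#' Returns a `potential_surface`: a deterministic, finite energy model over
#' `n_atoms x 3` Cartesian coordinates (A, energies in kcal/mol) together
#' with the solute/bath index partition. All built-in surfaces provide an
#' analytic gradient and a vectorized batch evaluator `energy_many()` used
#' by the path-integral machinery.
#'
#' @param spec a [model_spec()].
#' @return an object of class `potential_surface` with fields:
#' \describe{
#'   \item{n_atoms}{number of atoms}
#'   \item{dims}{number of active Cartesian dimensions (1 for the 1-D
#'     models, 3 otherwise); inactive dimensions do not enter the energy}
#'   \item{energy}{`function(conf)` with `conf` an `n_atoms x 3` matrix,
#'     returning a scalar energy}
#'   \item{energy_many}{`function(X)` with `X` an `n x n_atoms x 3` array,
#'     returning `n` energies}
#'   \item{gradient}{`function(conf)` returning the `n_atoms x 3` gradient}
#'   \item{solute_indices, bath_indices}{index partition of the atoms}
#'   \item{masses}{per-atom masses (amu)}
#' }
#' @examples
#' surf <- make_model(model_spec("harmonic-1d", list(k = 1)))
#' surf$energy(matrix(c(2, 0, 0), 1)) # 0.5 * 1 * 2^2 = 2
#' @export
make_model <- function(spec) {
  if (!inherits(spec, "model_spec")) {
    stop("`spec` must be a model_spec", call. = FALSE)
  }
  p <- spec$parameters
  surface <- switch(spec$kind,
    "harmonic-1d" = {
      energy_many <- function(X) 0.5 * p$k * (X[, 1, 1] - p$r0)^2
      gradient <- function(conf) {
        g <- matrix(0, 1, 3)
        g[1, 1] <- p$k * (conf[1, 1] - p$r0)
        g
      }
      list(dims = 1L, energy_many = energy_many, gradient = gradient,
           solute_indices = 1L, bath_indices = integer(0))
    },
    "harmonic-3d" = {
      energy_many <- function(X) {
        d <- sweep(matrix(X[, 1, ], ncol = 3), 2, p$center)
        0.5 * p$k * rowSums(d^2)
      }
      gradient <- function(conf) {
        g <- matrix(0, 1, 3)
        g[1, ] <- p$k * (conf[1, ] - p$center)
        g
      }
      list(dims = 3L, energy_many = energy_many, gradient = gradient,
           solute_indices = 1L, bath_indices = integer(0))
    },
    "morse-1d" = {
      energy_many <- function(X) {
        e <- exp(-p$a * (X[, 1, 1] - p$r0))
        p$D * (1 - e)^2
      }
      gradient <- function(conf) {
        e <- exp(-p$a * (conf[1, 1] - p$r0))
        g <- matrix(0, 1, 3)
        g[1, 1] <- 2 * p$D * (1 - e) * p$a * e
        g
      }
      list(dims = 1L, energy_many = energy_many, gradient = gradient,
           solute_indices = 1L, bath_indices = integer(0))
    },
    "diatomic-in-bath" = diatomic_in_bath_surface(spec)
  )
  structure(
    c(list(n_atoms = spec$n_atoms, masses = spec$masses, spec = spec,
           label = spec$kind),
      surface,
      list(energy = local({
        em <- surface$energy_many
        n_atoms <- spec$n_atoms
        function(conf) {
          X <- aperm(array(conf, dim = c(n_atoms, 3L, 1L)), c(3L, 1L, 2L))
          em(X)[1]
        }
      }))),
    class = "potential_surface"
  )
}

# Lennard-Jones diatomic-in-bath model. Atoms 1:2 are the bonded solute,
# the rest an LJ bath. Pairwise LJ is feathered by the switching function;
# a soft wall beyond box/2 keeps the cluster bound.
diatomic_in_bath_surface <- function(spec) {
  p <- spec$parameters
  n_atoms <- spec$n_atoms
  n_bath <- as.integer(p$n_bath)
  pair_idx <- if (n_atoms >= 2) utils::combn(n_atoms, 2) else
    matrix(integer(0), 2, 0)
  # classify pairs: bond (1-2), solute-bath, bath-bath
  i <- pair_idx[1, ]
  j <- pair_idx[2, ]
  is_bond <- i == 1L & j == 2L
  is_sb <- (i <= 2L & j > 2L)
  lj_scale <- ifelse(is_bond, 0, ifelse(is_sb, p$coupling, 1))
  wall_r <- p$box / 2

  # vectorized over configurations: loop over the O(n_atoms^2) pair list,
  # not over the (much larger) slice batch
  energy_many <- function(X) {
    n <- dim(X)[1]
    e <- numeric(n)
    for (k in seq_along(i)) {
      d2 <- (X[, i[k], 1] - X[, j[k], 1])^2 +
        (X[, i[k], 2] - X[, j[k], 2])^2 +
        (X[, i[k], 3] - X[, j[k], 3])^2
      if (is_bond[k]) {
        e <- e + 0.5 * p$k * (sqrt(d2) - p$r0)^2
      } else if (lj_scale[k] != 0) {
        sr6 <- (p$sigma^2 / d2)^3
        r <- sqrt(d2)
        e <- e + lj_scale[k] * 4 * p$epsilon * (sr6^2 - sr6) *
          switching_function(r, p$r_on, p$r_off)
      }
    }
    for (at in seq_len(n_atoms)) {
      radial <- sqrt(X[, at, 1]^2 + X[, at, 2]^2 + X[, at, 3]^2)
      e <- e + p$wall_k * pmax(0, radial - wall_r)^2
    }
    e
  }
  gradient <- function(conf) {
    g <- matrix(0, n_atoms, 3)
    d <- conf[i, , drop = FALSE] - conf[j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    # bond term
    bi <- which(is_bond)
    if (length(bi) == 1) {
      f <- p$k * (r[bi] - p$r0) / r[bi]
      g[1, ] <- g[1, ] + f * d[bi, ]
      g[2, ] <- g[2, ] - f * d[bi, ]
    }
    # LJ with switching (product rule)
    sr6 <- (p$sigma / r)^6
    lj <- 4 * p$epsilon * (sr6^2 - sr6)
    dlj_dr <- 4 * p$epsilon * (-12 * sr6^2 + 6 * sr6) / r
    sw <- switching_function(r, p$r_on, p$r_off)
    dsw <- switching_function_deriv(r, p$r_on, p$r_off)
    dE_dr <- lj_scale * (dlj_dr * sw + lj * dsw)
    for (k in which(dE_dr != 0)) {
      u <- d[k, ] / r[k]
      g[i[k], ] <- g[i[k], ] + dE_dr[k] * u
      g[j[k], ] <- g[j[k], ] - dE_dr[k] * u
    }
    # wall
    radial <- sqrt(rowSums(conf^2))
    out <- radial > wall_r
    if (any(out)) {
      f <- 2 * p$wall_k * (radial[out] - wall_r) / radial[out]
      g[out, ] <- g[out, ] + f * conf[out, , drop = FALSE]
    }
    g
  }
  list(dims = 3L, energy_many = energy_many, gradient = gradient,
       solute_indices = 1:2,
       bath_indices = if (n_bath > 0) 2L + seq_len(n_bath) else integer(0))
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> %s: %d atom(s), %d active dim(s), %d bath\n",
              x$label, x$n_atoms, x$dims, length(x$bath_indices)))
  invisible(x)
}

#' Generate a deterministic fixture system
#'
#' Builds the potential surface for `spec` plus an initial configuration:
#' the solute at the box center (or at the potential minimum for the 1-D
#' models), and bath atoms placed uniformly at random without overlaps
#' (minimum pair distance `0.8 * sigma`). Deterministic for a fixed seed.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the bath placement.
#' @param max_tries placement retries per bath atom before giving up.
#' @return list with elements `surface` ([make_model()] result) and
#'   `configuration` (`n_atoms x 3` matrix, A).
#' @export
generate_fixture_system <- function(spec, seed, max_tries = 500) {
  surface <- make_model(spec)
  p <- spec$parameters
  conf <- matrix(0, spec$n_atoms, 3)
  if (spec$kind == "harmonic-1d" || spec$kind == "morse-1d") {
    conf[1, 1] <- p$r0
  } else if (spec$kind == "harmonic-3d") {
    conf[1, ] <- p$center
  } else if (spec$kind == "diatomic-in-bath") {
    conf[1, ] <- c(-p$r0 / 2, 0, 0)
    conf[2, ] <- c(p$r0 / 2, 0, 0)
    n_bath <- as.integer(p$n_bath)
    if (n_bath > 0) {
      set.seed(as.integer(seed))
      min_d <- 0.8 * p$sigma
      half <- p$box / 2
      for (b in seq_len(n_bath)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- stats::runif(3, -half, half)
          prev <- conf[seq_len(2 + b - 1), , drop = FALSE]
          dmin <- min(sqrt(rowSums(sweep(prev, 2, cand)^2)))
          if (dmin >= min_d) {
            conf[2 + b, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf(
            "could not place bath atom %d without overlap after %d tries; reduce n_bath or enlarge box",
            b, max_tries), call. = FALSE)
        }
      }
    }
  }
  list(surface = surface, configuration = conf)
}
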