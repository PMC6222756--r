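#' Squared de Broglie thermal wavelength
#'
#' `lambda^2 = beta hbar^2 / m` in internal units (A^2 when mass is in amu
#' and beta in mol/kcal; dimensionless in reduced units). Sets the spatial
#' scale of quantum dispersion of a particle and hence the spread of its
#' free-particle ring polymer.
#'
#' @param mass particle mass (amu); must be positive.
#' @param thermo a [thermo_state()].
#' @return squared thermal wavelength (A^2).
#' @examples
#' thermal_wavelength_sq(1, thermo_state(1, reduced = TRUE)) # 1
#' @export
thermal_wavelength_sq <- function(mass, thermo) {
  stopifnot(inherits(thermo, "thermo_state"))
  if (!is.numeric(mass) || any(mass <= 0)) {
    stop("`mass` must be positive", call. = FALSE)
  }
  thermo$beta * thermo$hbar2 / mass
}

is_power_of_two <- function(P) {
  P == round(P) && P >= 1 && bitwAnd(as.integer(P), as.integer(P) - 1L) == 0L
}

check_bead_count <- function(P) {
  if (!is_power_of_two(P) || P < 4) {
    stop(sprintf(
      "P = %s is not a power of two >= 4; the recursive bisection sampler requires power-of-two bead counts",
      format(P)), call. = FALSE)
  }
}

# Vectorized bisection sampler for centroid-zero free-particle ring-polymer
# displacements. Returns an n x P x dims array. The closed ring measure
# exp[-(P / (2 lambda^2)) sum_i (r_i - r_{i+1})^2] conditioned on bead 1 at
# the origin is a Brownian bridge with P links of variance lambda^2 / P
# each; recursive midpoint bisection draws it exactly (every draw is
# "accepted"). The ring is then re-centered so the bead mean is zero --
# conditioning on bead 1 versus constraining the centroid both only gauge-fix
# the translational zero mode, so the centered distribution is the exact
# centroid-projected Gaussian.
sample_fp_displacements <- function(n, P, lambda2, dims) {
  check_bead_count(P)
  sigma2_link <- lambda2 / P
  out <- array(0, dim = c(n, P, dims))
  for (d in seq_len(dims)) {
    B <- matrix(0, n, P + 1L)
    h <- P
    while (h >= 2L) {
      half <- h %/% 2L
      starts <- seq.int(1L, P + 1L - h, by = h)
      mids <- starts + half
      sd_mid <- sqrt(sigma2_link * h / 4)
      B[, mids] <- 0.5 * (B[, starts, drop = FALSE] +
                            B[, starts + h, drop = FALSE]) +
        sd_mid * matrix(stats::rnorm(n * length(mids)), n, length(mids))
      h <- half
    }
    beads <- B[, seq_len(P), drop = FALSE]
    out[, , d] <- beads - rowMeans(beads)
  }
  out
}

#' Ring-polymer path for one quantized atom
#'
#' Holds the `P` bead positions of a discretized imaginary-time path, closed
#' by convention (`bead P + 1 = bead 1`), with its centroid bookkeeping.
#'
#' @param beads `P x 3` matrix of bead positions (A).
#' @param atom_index index of the quantized atom this path belongs to.
#' @param mass particle mass (amu).
#' @return object of class `ring_polymer_path` with fields `beads`, `P`,
#'   `atom_index`, `mass`, `centroid`.
#' @export
ring_polymer_path <- function(beads, atom_index = 1L, mass = 1) {
  beads <- as.matrix(beads)
  if (ncol(beads) != 3) stop("`beads` must be a P x 3 matrix", call. = FALSE)
  check_bead_count(nrow(beads))
  if (mass <= 0) stop("`mass` must be positive", call. = FALSE)
  structure(
    list(beads = beads, P = nrow(beads), atom_index = as.integer(atom_index),
         mass = mass, centroid = colMeans(beads)),
    class = "ring_polymer_path"
  )
}

#' @export
print.ring_polymer_path <- function(x, ...) {
  cat(sprintf("<ring_polymer_path> P = %d beads, atom %d, m = %g amu, gyration %.4g A^2\n",
              x$P, x$atom_index, x$mass, path_gyration(x)))
  invisible(x)
}

#' Draw a closed free-particle ring-polymer path by bisection
#'
#' Samples bead displacements exactly from the closed free-particle Gaussian
#' measure by recursive bisection (levelwise Brownian-bridge midpoints with
#' first bead = last bead), then rigidly translates the whole ring so that
#' its centroid coincides with the requested centroid. Because the draw is
#' exact, every path is accepted; no Metropolis test is involved.
#'
#' @param mass particle mass (amu).
#' @param P bead count; must be a power of two, `P >= 4` (required by the
#'   bisection scheme).
#' @param thermo a [thermo_state()].
#' @param centroid length-3 centroid position (A).
#' @param dims number of active dimensions to spread (1 for 1-D models,
#'   3 otherwise); inactive dimensions stay at the centroid.
#' @param atom_index stored atom index.
#' @return a [ring_polymer_path()] whose bead mean equals `centroid` to
#'   within 1e-10 per component.
#' @export
sample_free_particle_path <- function(mass, P, thermo,
                                      centroid = c(0, 0, 0), dims = 3L,
                                      atom_index = 1L) {
  lambda2 <- thermal_wavelength_sq(mass, thermo)
  disp <- sample_fp_displacements(1L, P, lambda2, dims)
  beads <- matrix(rep(centroid, each = P), P, 3)
  beads[, seq_len(dims)] <- beads[, seq_len(dims)] +
    matrix(disp[1L, , ], P, dims)
  ring_polymer_path(beads, atom_index = atom_index, mass = mass)
}

#' Mass-scale a ring polymer to a companion isotope
#'
#' The perturbed (heavy) isotope path shares the bisection vectors of the
#' reference (light) path: each bead displacement from the centroid is
#' multiplied by `sqrt(mass_light / mass_heavy)` (the ratio of thermal
#' wavelengths), and the centroid is left untouched. This realizes the
#' alchemical mass mutation of PI-FEP with no additional sampling.
#'
#' @param path_light a [ring_polymer_path()] for the light isotope.
#' @param mass_heavy mass of the companion isotope (amu); must be positive.
#' @return a [ring_polymer_path()] for the heavy isotope with identical
#'   centroid.
#' @examples
#' th <- thermo_state(298.15)
#' p16 <- sample_free_particle_path(16, 32, th)
#' p18 <- scale_path_for_mass(p16, 18)
#' path_gyration(p18) / path_gyration(p16) # = 16/18
#' @export
scale_path_for_mass <- function(path_light, mass_heavy) {
  stopifnot(inherits(path_light, "ring_polymer_path"))
  if (!is.numeric(mass_heavy) || mass_heavy <= 0) {
    stop("`mass_heavy` must be positive", call. = FALSE)
  }
  s <- sqrt(path_light$mass / mass_heavy)
  cen <- path_light$centroid
  disp <- sweep(path_light$beads, 2, cen)
  beads <- sweep(s * disp, 2, cen, "+")
  structure(
    list(beads = beads, P = path_light$P, atom_index = path_light$atom_index,
         mass = mass_heavy, centroid = cen),
    class = "ring_polymer_path"
  )
}

#' Radius of gyration (squared) of a ring polymer
#'
#' Mean squared bead displacement from the centroid, the diagnostic for the
#' quantum-mechanical spread of the particle density.
#'
#' @param path a [ring_polymer_path()].
#' @return mean squared displacement (A^2).
#' @export
path_gyration <- function(path) {
  stopifnot(inherits(path, "ring_polymer_path"))
  disp <- sweep(path$beads, 2, path$centroid)
  mean(rowSums(disp^2))
}

#' Exact centroid-projected free-particle ring covariance
#'
#' Dense linear-algebra reference for the bisection sampler: the covariance
#' of centroid-zero bead coordinates (one dimension) under the closed
#' free-particle measure, obtained by eigendecomposition of the ring
#' Laplacian. The spring precision matrix is `(P / lambda^2) L` with `L` the
#' cyclic second-difference matrix; projecting out the uniform (centroid)
#' mode and inverting on the complement gives the covariance.
#'
#' @param P bead count.
#' @param lambda2 squared thermal wavelength ([thermal_wavelength_sq()]).
#' @return `P x P` covariance matrix (A^2).
#' @export
fp_ring_covariance <- function(P, lambda2) {
  check_bead_count(P)
  L <- diag(2, P)
  L[cbind(seq_len(P), c(2:P, 1L))] <- L[cbind(seq_len(P), c(2:P, 1L))] - 1
  L[cbind(c(2:P, 1L), seq_len(P))] <- L[cbind(c(2:P, 1L), seq_len(P))] - 1
  ev <- eigen(L, symmetric = TRUE)
  keep <- ev$values > 1e-9
  V <- ev$vectors[, keep, drop = FALSE]
  (lambda2 / P) * V %*% (t(V) / ev$values[keep])
}
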