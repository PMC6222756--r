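# Internal unit system: kcal/mol (energy), Angstrom (length), amu (mass),
# Kelvin (temperature), fs (time for molecular dynamics).

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
.kB <- 0.0019872041

# hbar^2 expressed in (kcal/mol) * amu * A^2, derived from CODATA values:
#   hbar = 1.054571817e-34 J s, N_A = 6.02214076e23 /mol,
#   1 amu = 1.66053906660e-27 kg, 1 kcal = 4184 J.
# hbar^2 [J^2 s^2] / (kcal/mol -> J) / amu / (A -> m)^2
.hbar2 <- {
  hbar_SI <- 1.054571817e-34
  avogadro <- 6.02214076e23
  amu_SI <- 1.66053906660e-27
  hbar_SI^2 * avogadro / 4184 / amu_SI / 1e-20 # = 0.09639676...
}

# 1 amu A^2/fs^2 in kcal/mol (kinetic-energy conversion for MD):
# amu[kg] * (1e-10 m)^2 / (1e-15 s)^2 * N_A / 4184  = 2390.057...
.kcal_per_amu_A2_fs2 <- 1.66053906660e-27 * 1e10 * 6.02214076e23 / 4184

#' Thermodynamic state for path-integral calculations
#'
#' Bundles the temperature with the inverse temperature `beta = 1/(kB T)` and
#' the constant `hbar^2` in the internal unit system (kcal/mol, Angstrom,
#' amu). In reduced mode (`reduced = TRUE`) both `kB` and `hbar^2` are set to
#' 1, so that closed-form harmonic-oscillator checks are exact and legible:
#' `beta * hbar * omega` is then simply `omega / temperature`.
#'
#' @param temperature temperature (K, or reduced temperature when
#'   `reduced = TRUE`); must be positive.
#' @param reduced logical; use reduced units (`hbar = kB = 1`)?
#' @return an object of class `thermo_state` with fields `temperature`,
#'   `beta`, `kB`, `hbar2` and `reduced`.
#' @examples
#' thermo_state(298.15)
#' thermo_state(1 / 3, reduced = TRUE) # beta = 3 in reduced units
#' @export
thermo_state <- function(temperature, reduced = FALSE) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number", call. = FALSE)
  }
  kB <- if (reduced) 1 else .kB
  hbar2 <- if (reduced) 1 else .hbar2
  structure(
    list(
      temperature = temperature,
      beta = 1 / (kB * temperature),
      kB = kB,
      hbar2 = hbar2,
      reduced = isTRUE(reduced)
    ),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  units <- if (x$reduced) "reduced units (hbar = kB = 1)" else
    "kcal/mol, Angstrom, amu"
  cat(sprintf("<thermo_state> T = %g, beta = %g  [%s]\n",
              x$temperature, x$beta, units))
  invisible(x)
}

# Derive a reproducible substream seed from a master seed. MINSTD LCG steps
# keep all arithmetic exact in doubles (products < 2^53).
substream_seed <- function(master, stream_id) {
  stopifnot(is.numeric(master), is.numeric(stream_id))
  x <- (abs(master) + 7919 * abs(stream_id)) %% 2147483646 + 1
  x <- (48271 * x) %% 2147483647
  x <- (48271 * x) %% 2147483647
  as.integer(x)
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}
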