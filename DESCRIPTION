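Package: pifrac
Title: Path-Integral Free Energy Perturbation for Equilibrium Isotope
    Fractionation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes equilibrium isotope effects and fractionation factors
    by path-integral free energy perturbation (PI-FEP) with double averaging:
    a classical configurational ensemble supplies centroid positions, and
    centroid-constrained free-particle ring-polymer sampling (recursive
    bisection, every draw accepted) supplies the nuclear quantum correction.
    Isotope substitution is performed alchemically by mass-scaling the bead
    displacements of a single simulation, so one trajectory of the light
    isotopologue yields the heavy-to-light partition function ratio with the
    statistical precision needed for per-mil scale fractionation. Includes
    model potential-energy surfaces (harmonic, Morse, diatomic in a
    Lennard-Jones bath), exact quantum oracles (closed-form harmonic
    partition functions and a sine-DVR grid eigensolver), block-average
    error analysis, bead-count convergence scans, and delta/alpha
    fractionation algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
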