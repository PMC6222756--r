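# pifrac

Path-integral free energy perturbation (PI-FEP) for equilibrium isotope
effects and fractionation factors.

Equilibrium isotope fractionation — why ¹⁸O accumulates in a carbonyl
group relative to water, or deuterium at one site of a molecule over
another — is a pure nuclear quantum effect: the Born–Oppenheimer surface
does not depend on nuclear mass, so the heavy/light partition-function
ratio R = Q_H/Q_L is set entirely by zero-point energy and quantum
delocalization. The observables are ratios of such ratios,

    alpha_{A/B} = R_A / R_B,     delta = 1000 (R_sample/R_standard − 1)  [permil]

and for heavy atoms they differ from unity by only a few per mil, so the
estimator has to be precise to ~1e-4. pifrac is for computational
chemists, geochemists and ecohydrologists who want that precision from
statistical-mechanical simulation rather than from harmonic frequency
tables, which miss anharmonicity and condensed-phase effects.

## Method

pifrac computes R by a double average with an alchemical mass
perturbation:

1. **Outer (classical) average** — Metropolis Monte Carlo or Langevin MD
   samples the Boltzmann ensemble of the full system on a model
   potential-energy surface (`run_metropolis()`, `run_langevin_md()`).
2. **Inner (free-particle) average** — at each configuration, closed
   ring polymers of P beads are drawn *exactly* for every quantized atom
   by recursive bisection (Brownian-bridge midpoints, first bead = last
   bead, every draw accepted), then rigidly translated so each path
   centroid sits on its classical coordinate.
3. **Mass perturbation** — heavy-isotope paths reuse the same Gaussian
   variates with bead displacements scaled by sqrt(m_L/m_H), so a single
   simulation of the light isotopologue yields

       Q_H/Q_L = (m_H/m_L)^(d/2) · ⟨⟨e^{−β ΔŪ_H}⟩_FP⟩_U / ⟨⟨e^{−β ΔŪ_L}⟩_FP⟩_U

   where ΔŪ is the bead-averaged difference potential and the analytic
   prefactor is the surviving free-particle normalization
   (`estimate_ratio()`; the Bigeleisen-convention reduced ratio is
   reported alongside). Uncertainties come from 10 contiguous block
   averages.

Everything is validated against exact quantum oracles: closed-form
harmonic partition functions, a sine-DVR grid eigensolver for arbitrary
1-D wells (`grid_eigensolve()`), a dense-Gaussian covariance oracle for
the path sampler, and an independent direct path-integral Monte Carlo
estimator built on the discretized effective potential
(`direct_pimc_ratio()`).

## Worked example

A particle in a 1-D harmonic well in reduced units with
beta·hbar·omega = 3, alchemically doubling its mass — the case with a
closed-form answer sinh(u_L/2)/sinh(u_H/2) = 1.675246:

```r
library(pifrac)

th   <- thermo_state(1/3, reduced = TRUE)          # beta = 3, hbar = kB = 1
surf <- make_model(model_spec("harmonic-1d", list(k = 1)))
ens  <- run_metropolis(surf, matrix(0, 1, 3), th, n_steps = 10000,
                       step_size = 1.5, save_interval = 40, seed = 1)
est  <- estimate_ratio(ens, surf, quantized_region(1, 1, 2), th,
                       P = 64, n_paths = 200, seed = 2)
est
#> <ratio_estimate> Q_H/Q_L = 1.673063 +/- 0.000452  (P = 64, 10 blocks)
harmonic_isotope_ratio_exact(1, 1, 2, th)
#> [1] 1.675246
```

The estimate sits within a few combined standard errors of the exact
ratio (the residual ~1e-3 includes the small P = 64 discretization bias).
Fractionation algebra on two ratio estimates — here the published
¹⁸O/¹⁶O partition-function ratios of acetone and water in solution:

```r
alpha_from_ratio_estimates(list(ratio = 1.1251, stderr = 0.0007),
                           list(ratio = 1.0828, stderr = 0.0024))
#> <fractionation_result> alpha = 1.039065 +/- 0.002392  (delta = 39.07 permil)
#>   R_A = 1.125100 +/- 0.000700, R_B = 1.082800 +/- 0.002400
```

i.e. a ~39 permil ¹⁸O enrichment of the carbonyl compound over water.

A thin command-line wrapper over these functions lives at
`inst/cli/pifrac.R` (subcommands `simulate`, `estimate`, `scan-beads`,
`fractionation`, `validate`); a documented YAML run configuration is in
`inst/extdata/harmonic1d.yaml`.

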