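---
title: "PI-FEP double averaging: model, estimator, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PI-FEP double averaging: model, estimator, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifrac)
```

## The problem

Equilibrium isotope fractionation — the preference of a heavy isotope for
one chemical environment over another — is a pure nuclear quantum effect.
On a Born–Oppenheimer surface the potential energy is independent of
nuclear mass, so the heavy/light ratio of partition functions

$$R = \frac{Q_H}{Q_L}$$

is controlled entirely by zero-point energy, quantum delocalization and
tunneling. Fractionation observables follow from ratios of such ratios:
the fractionation factor $\alpha_{A/B} = R_A / R_B$ between two substances
or phases, and the per-mil enrichment
$\delta = 1000\,(R_\text{sample}/R_\text{standard} - 1)$.

The difficulty is precision: for heavy-atom substitutions such as
$^{18}$O/$^{16}$O, $R$ differs from 1 by a few percent, and $\alpha$ by a
few per mil. A free-energy estimate whose statistical error is "only" 1%
is useless here. pifrac implements the path-integral free energy
perturbation (PI-FEP) strategy that reaches this precision by computing
$R$ *directly* from a single simulation, rather than as a difference of
two large absolute free energies.

## The estimator

### Double averaging

The quantum partition function of the quantized atoms embedded in a
classical environment factorizes exactly into

$$Q = Q_\text{cm}\,Q_\text{fp}\,
\Big\langle \big\langle e^{-\beta \Delta\bar U} \big\rangle_{\text{FP},\bar r}
\Big\rangle_U ,$$

where the outer average runs over the *classical* Boltzmann ensemble of
the full system, and the inner average runs over closed free-particle
ring polymers whose centroid is constrained to the classical coordinates.
$\Delta\bar U$ is the difference potential: the bead-averaged potential
energy of the path minus the potential energy of the classical
configuration,

$$\Delta\bar U = \frac{1}{P}\sum_{i=1}^{P} U(r_i^{\{M\}}, S) - U(s, S),$$

with slice $i$ placing **all** quantized atoms at their bead-$i$ positions
simultaneously. (An alternative reading sums single-atom slice energies
per atom; the two coincide for additive potentials, and the whole-region
slice evaluation is the one consistent with the discretized effective
potential, so it is the one implemented — `delta_u_bar()`.)

This factorization, implemented in `estimate_ratio()`, has two practical
advantages. The classical ensemble can be generated cheaply and long
(configurational convergence), and the inner free-particle paths are drawn
*independently and exactly* from a known Gaussian, so path-integral
convergence is not entangled with configurational sampling and the paths
can never be trapped in a local minimum of the potential.

### Alchemical mass perturbation

The heavy isotopologue is never simulated. For every light-isotope path,
the companion heavy path shares the same underlying Gaussian (bisection)
variates; because the free-particle path distribution scales with the
thermal wavelength $\lambda^2 = \beta\hbar^2/m$, the heavy bead
displacements about the (common) centroid are the light ones multiplied by
$\sqrt{m_L/m_H}$ (`scale_path_for_mass()`). The estimator accumulates

$$\frac{Q_H}{Q_L} \;=\;
\left(\frac{m_H}{m_L}\right)^{d/2}
\frac{\big\langle\langle e^{-\beta \Delta\bar U_H}\rangle_\text{FP}\big\rangle_U}
     {\big\langle\langle e^{-\beta \Delta\bar U_L}\rangle_\text{FP}\big\rangle_U},$$

a ratio of double averages (not an average of per-configuration ratios —
the factored form is what the partition-function algebra dictates, and it
is what the block error analysis is applied to).

**On the mass prefactor.** The coordinate scaling maps the heavy-isotope
spring action onto the light one exactly, and almost — but not quite —
cancels the free-particle normalization: with the centroid held fixed,
$P-1$ of the $P$ bead degrees of freedom per dimension are scaled, leaving
the analytic factor $(m_H/m_L)^{d/2}$ per quantized atom ($d$ = active
dimensions). That factor is precisely the classical (momentum) partition
function ratio. Including it, `estimate_ratio()` returns the **full**
quantum ratio $Q_H/Q_L$ — the quantity the closed-form harmonic oracle
$\sinh(u_L/2)/\sinh(u_H/2)$ and the grid eigensolver compute. Omitting it
gives the **reduced** (Bigeleisen-style) ratio, the convention in which
condensed-phase isotope ratios are usually tabulated (e.g. liquid-water
$^{18}$O values near 1.08 at room temperature); that value is carried in
`metadata$ratio_reduced`. Fractionation factors are identical in both
conventions because the classical factors cancel in $R_A/R_B$.

### Bisection sampling

`sample_free_particle_path()` draws closed free-particle paths by
recursive midpoint bisection: bead 1 is the seed (first and last beads
identical, closing the ring), and each level fills segment midpoints with
Brownian-bridge Gaussians of variance $\sigma^2_\text{link}\,h/4$ for
segment length $h$. The construction requires $P$ to be a power of two
($P \ge 4$), and every draw is an exact sample — there is no accept/reject
step. The centroid constraint is applied afterwards by rigid translation
of the whole ring, which is volume-preserving and identical for the light
and heavy companions, so it requires no Jacobian correction.
Gauge-fixing the translational zero mode by the seed bead or by the
centroid yields the same internal-coordinate distribution; the package
verifies this against the dense centroid-projected Gaussian covariance
(`fp_ring_covariance()`), an independent linear-algebra construction.

The "shared bisection variates" between isotopes are realized as shared
standard-normal draws: scaling the displacement field by
$\sqrt{m_L/m_H}$ after the fact is algebraically identical to rescaling
every level's bridge standard deviation, which is the cleanest
implementable reading of sharing the sampler's internal position vectors.

## Model systems

The built-in surfaces (`model_spec()` / `make_model()`) are deliberately
minimal stand-ins for a solvated-molecule simulation that keep the
solute/bath partition contract:

* `harmonic-1d`, `harmonic-3d` — exactly solvable oracles
  ($Q = 1/(2\sinh(\beta\hbar\omega/2))$ per dimension).
* `morse-1d` — bound but anharmonic; validated against a sine-DVR grid
  eigensolver. Anharmonicity is the physical reason a frequency-only
  (harmonic) treatment of fractionation is biased, and the package
  quantifies that bias.
* `diatomic-in-bath` — a harmonically bonded diatomic in a Lennard-Jones
  bath with a switching function that feathers intermolecular
  interactions to zero between `r_on = 13` and `r_off = 13.5` Å (the
  standard cubic-in-$r^2$ switching polynomial; any C¹ monotone form
  satisfying the endpoint contract would do, and no particular form is
  canonical). Solute–bath coupling is a dial: `coupling = 0` must — and
  does — reproduce the gas-phase ratio, a nontrivial end-to-end
  consistency check. A soft spherical wall replaces periodic boundaries;
  model clusters have no meaningful pressure, so sampling is NVT
  throughout (the estimator itself is ensemble-agnostic).

The bath is classical by construction: solvent nuclear quantum effects are
regarded as folded into the effective bath potential, and only the atoms
named in `quantized_region()` are quantized. In molecular applications
the conventional choice is every atom within two covalent bonds of the
substituted site.

What the models do *not* emulate: electronic structure (the surfaces are
fixed analytic forms, not responsive to bath fluctuations), long-range
electrostatics, many-molecule solvents, and rotational/librational
congestion of real liquids. Passing the oracle tests therefore
demonstrates correctness of the *estimator machinery* — sampling measure,
mass scaling, averaging order, error analysis — not the realism of any
force field.

## Defaults and units

Internal units are kcal/mol, Å, amu, K, fs, with
$k_B = 0.0019872041$ kcal/(mol·K) and $\hbar^2 = 0.0963968$
(kcal/mol)·amu·Å², derived once from CODATA constants. A reduced-units
mode ($\hbar = k_B = 1$, `thermo_state(..., reduced = TRUE)`) makes the
closed-form checks exact and legible; all oracle validations run in it.

Estimator protocol defaults follow the established free-particle
path-integral practice: `P = 32` beads (64 for the lightest atoms or very
quantum regimes), `n_paths = 200` retained free-particle configurations
per centroid with `n_discard = 10` (a convention only — the draws are
i.i.d., so no equilibration is actually needed), and `n_blocks = 10`
contiguous blocks for the standard error (standard deviation of block
ratios over $\sqrt{n_\text{blocks}}$).

## Numerical choices

* **Log-space accumulation.** Inner averages are accumulated as
  log-mean-exp with a max shift, so large $\beta\Delta\bar U$ cannot
  overflow; `numerator_mean`/`denominator_mean` are exponentiated views.
* **Identity perturbation is exact.** Equal masses short-circuit the
  heavy-path energy evaluation, so $R = 1$ with zero variance to the last
  bit — a structural, not statistical, invariant.
* **Grid eigensolver.** Sine-DVR (particle-in-a-box basis; kinetic energy
  exact in the basis, potential diagonal on the grid), spectrally
  accurate for smooth wells; Boltzmann sums truncate when a term falls
  below $10^{-14}$ of the running total. Doubling the grid *density*
  changes $Q$ by $<10^{-8}$ relative; enlarging the *box* shifts
  near-dissociation Morse states at the $10^{-6}$–$10^{-5}$ level, an
  intrinsic property of boxed continua that sits far below the
  statistical tolerances the oracle is compared against.
* **Determinism.** Every stochastic stage draws a substream seed from the
  master seed via an exact-integer LCG hash; per-configuration inner
  averages get their own substreams, so results are independent of
  internal batching.
* **Tail sampling.** For strongly anharmonic wells the FEP weight
  distribution is right-skewed; with too few paths per configuration the
  ratio is systematically under-sampled. The bundled validations use up
  to 1200 paths per configuration on the Morse well, where the skew bias
  is well below the statistical error.

## Problem sizes in the bundled validations

The test suite and `scripts/acceptance.R` run at desk scale, chosen so
the whole suite completes in about a minute while every comparison is
resolved at its stated significance: harmonic oracle equivalence at
$P = 64$ with 250 centroid configurations × 200 paths for
$\beta\hbar\omega_L \in \{1, 3\}$ and $m_H/m_L \in \{18/16, 2\}$ (and the
3-D isotropic analogue); Morse versus eigensolver with 800 configurations
× 1200 paths; sampler covariance at $10^5$ draws for
$P \in \{4, 8, 16\}$; a bead scan over $P = 4 \dots 64$ against a shared
ensemble; and a direct path-integral Monte Carlo cross-check at matched
$P$, where both estimators target the same discretized ratio.

```{r example, eval = FALSE}
th <- thermo_state(1 / 3, reduced = TRUE) # beta*hbar*omega = 3 for k = m = 1
surf <- make_model(model_spec("harmonic-1d", list(k = 1)))
ens <- run_metropolis(surf, matrix(0, 1, 3), th, n_steps = 10000,
                      step_size = 1.5, save_interval = 40, seed = 1)
est <- estimate_ratio(ens, surf, quantized_region(1, 1, 2), th,
                      P = 64, n_paths = 200, seed = 2)
est$ratio - harmonic_isotope_ratio_exact(1, 1, 2, th) # O(stderr)
```

## Known limitations

* Equilibrium isotope effects only: no transition-state sampling, hence
  no kinetic isotope effects; no centroid or ring-polymer molecular
  dynamics.
* The exact oracles are one-dimensional (and separable 3-D); they
  validate every estimator pathway, but there is no multidimensional
  eigensolver.
* The direct-PIMC cross-check supports fully quantized gas-phase systems;
  it exists to validate the double-average estimator, not as a production
  path.
* Bead counts are restricted to powers of two by the bisection
  construction; staging or normal-mode samplers that lift the restriction
  are out of scope.
* Real-solvent absolute ratios depend on the quality of the
  potential-energy surface; on model surfaces the package is exact in the
  $P \to \infty$, infinite-sampling limit, and that is the claim the
  validation suite tests.
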