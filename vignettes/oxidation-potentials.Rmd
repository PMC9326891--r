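---
title: "Computing one-electron oxidation potentials with oxpot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing one-electron oxidation potentials with oxpot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxpot)
```

## The problem

The one-electron oxidation potential of a solvated molecule -- quoted, by
electrochemical convention, as the reduction potential of the N+/N couple
-- is the bridge between quantum-chemical energies and measurable redox
behaviour. For the DNA/RNA nucleobases the experimental values span wide
ranges (irreversible electrochemistry, low solubility), and the computed
values depend strongly on protocol: whether vibrational sampling is
included, whether the solvent is a polarizable continuum or explicit
fixed-charge water, and how the free energy of oxidation is estimated.

`oxpot` implements the complete post-processing layer of this workflow.
It consumes scalar energies and per-snapshot vertical energy gaps --
whatever electronic-structure or MD engine produced them -- and turns
them into potentials versus the standard hydrogen electrode (SHE),
with validity diagnostics, tautomer weighting and benchmarking. The
electronic-structure and MD calculations themselves are out of scope by
design: ingestion is via a neutral CSV/JSON schema only.

## Reference conventions

Every protocol shares three constants, collected in `energy_constants()`:

* the absolute SHE reduction potential, 4.281 V;
* the gas-phase free energy of the electron from Fermi-Dirac statistics,
  -0.867 kcal/mol. The 4.281 V value was derived *with* this electron
  term, so each half-reaction free energy computed here subtracts
  G_c(e-) explicitly to cancel it;
* kT at 298.15 K, 0.025693 eV.

For one exchanged electron, 1 eV of free energy corresponds to 1 V, so
the working equation is simply `E = -dG_red[eV]/n - 4.281`. All readers
convert to eV on ingest (27.211386 eV/hartree, 0.0433641 eV per
kcal/mol). Which absolute SHE value is strictly consistent with a given
continuum-solvent parameterisation is an open question in the
literature; the constant is therefore exposed for override (a YAML/JSON
config file or arguments) rather than resolved here.

The electron is treated as a gas-phase species throughout -- a pure
formalism that cancels between half reactions -- so its solvation free
energy in the thermodynamic cycles is zero by default, with an
`electron_solvation_eV` override for solvated-electron conventions.

## Static protocols

`static_direct()` evaluates

dG_red = [E_e(N) + G_T(N)] - [E_e(N+) + G_T(N+)] - G_c(e-)

from solvent-phase records at solvent-optimized geometries, i.e. the
adiabatic ionization energy route. Computing the thermal correction
G_T in a continuum solvent is however formally questionable (the
ideal-gas partition functions do not apply in solution, and thermal
effects are partly double counted), which motivates the thermodynamic
cycles implemented in `cycle_potential()`:

dG_red = dG_red,gas + dG_s(N) - dG_s(N+)

with gas-phase thermal corrections and solvation free energies
dG_s = E_e(solvent) - E_e(gas). Cycle 1 evaluates the solvent-phase
energy at the solvent-optimized geometry (solute relaxation upon
solvation included); cycle 2 stays at the gas-phase geometry, the
cheaper variant common in the literature. Gas-phase G_T is used in the
cycles even when solvent-phase G_T records exist. No gas-to-solution
standard-state correction term is applied anywhere: the protocols as
implemented contain no such term, and adding one is a user-level
adjustment of the input energies. Component breakdowns are returned and
sum to the total exactly, which the test suite asserts at machine
precision.

## Dynamic protocols

With an ensemble of sampled geometries, `dynamic_direct()` replaces the
explicit thermal correction by ensemble averages of the total potential
energy in each state's own phase space. `marcus_free_energy()` instead
uses the two vertical gap ensembles: the vertical ionization energies
(VIE, neutral trajectory) and vertical attachment energies (VAE, cation
trajectory). Under linear solvent response both gap distributions are
Gaussian with equal variance and the oxidation free energy is the
half-sum of their means:

dA_ox = (<VIE> + <VAE>)/2,   lambda = (<VIE> - <VAE>)/2.

`convergence_curve()` re-estimates either protocol on seeded random
subsamples without replacement (snapshots are assumed exchangeable;
upstream time correlation is treated as already handled by the snapshot
selection) and `converged_at()` reports the first n at which a trailing
window of the curve stays inside a tolerance band. The defaults --
window 5, 0.02 V -- were chosen so that the qualitative contrast of the
two solvent regimes is resolved on matched-width synthetic data:
ensembles with gap widths around 0.1 eV (continuum-like) settle within
roughly 40--60 snapshots, while widths around 1 eV (explicit-solvent
like) need on the order of 100 or more. These defaults are reporting
conventions, not physics; both are arguments.

## When is the Marcus picture valid?

`linear_response_report()` tests the three conditions behind the
half-sum: Gaussian gap distributions, equal standard deviations, and
agreement of the Stokes-shift reorganization energy with the
fluctuation-based ones, lambda_state = sigma_state^2/(2kT). Design
choices, all exposed as tolerances:

* **Gaussian shape.** Skewness and excess-kurtosis bounds (0.5 and 1.0)
  plus a normality test at alpha = 0.05 (Shapiro-Wilk up to n = 5000,
  Anderson-Darling beyond). An ensemble is flagged non-Gaussian only
  when a moment bound is violated *and* the test rejects: at n ~ 200 the
  significance test alone rejects genuinely Gaussian data 5% of the
  time, and the moment bounds alone fluctuate; requiring agreement keeps
  the false-alarm rate near 1% while still failing decisively on
  skewed (lognormal-type) violations.
* **Equal widths.** max(sigma)/min(sigma) <= 1.25. Continuum-solvent
  width pairs like 0.10/0.11 eV pass; explicit-solvent pairs like
  0.81/1.20 eV fail.
* **Lambda consistency.** Each fluctuation-based lambda must agree with
  the gap-based one within 25% relative. The comparison is anchored on
  the gap-based estimate (each state against it) rather than on the
  spread of all three, whose sampling noise at n = 200 would flag
  linear-response data roughly 8% of the time.

The verdicts mirror the physics of the two embedding schemes: a
polarizable continuum responds linearly almost by construction, whereas
fixed-charge explicit water cannot relax its charges upon vertical
ionization, producing wide, unequal, weakly non-Gaussian gap
distributions.

`gap_distribution()` builds the histogram view of this: mean-centered
populations p and free energies A = -kT ln p (Freedman-Diaconis bins by
default; empty bins are flagged rather than given an infinite A). For a
Gaussian ensemble A is a parabola of curvature kT/(2 sigma^2), and
matched VIE/VAE pairs satisfy the linear free-energy relation
A_red(E) = A_ox(E) + E + const, both of which are asserted in the tests.

## The nonlinear-response correction

When the conditions fail, `matyushov_voth_corrected()` replaces the
half-sum by a three-parameter quadratic-coupling estimate in the spirit
of the Matyushov-Voth Q-model: one Gaussian solvent mode with
state-dependent force constants k1, k2, displaced minima, and an energy
offset. The vertical gap is then quadratic in the mode, the free-energy
surfaces along the gap are non-parabolic, and the two gap variances
differ. Scaling invariance of the mode leaves three physical
parameters: the curvature ratio r = k2/k1, a displacement energy
z = k1 q0^2, and the offset. The model supplies four moment predictions
for three parameters, so a fitting choice is unavoidable; `oxpot` fits
r and z to the two most robust observables -- the variance *ratio* and
the Stokes shift -- and reports the unconstrained residual (absolute
variance scale) among the model parameters. The free-energy gap then
follows in closed form from the two harmonic partition functions:

dA = (m1 + m2)/2 - kT (r^2 - 1)/(4r) - z (r - 1)/4 + (kT/2) ln r.

Three properties are exact by construction, not tuned: at equal sample
variances r = 1 and the Marcus result is recovered identically; swapping
which ensemble carries the larger variance maps (r, z) to (1/r, zr) and
flips the sign of the whole correction; and inputs the model cannot
represent (mean VIE not above mean VAE, or no positive r/z solution)
raise an error instead of silently falling back. In
`run_full_comparison()` the correction is applied automatically to
pairs whose diagnostics report a non-Marcus regime (`auto_correct =
TRUE`), to every pair (`"always"`), or never (`FALSE`) -- published
workflows differ on whether such corrections are applied selectively or
across the board, so both behaviours are available.

## Tautomer weighting

Protic solvents host several tautomers of one parent species, with
Boltzmann populations (`boltzmann_populations()`, and
`populations_to_relative_energies()` for rescaling low-level energies
to reference populations). The observable potential of the mixture is
computed by `ensemble_potential()` from the per-tautomer reduction
equilibrium constants K_j = exp(F E_j / RT):

E = (kT/2) [ ln sum_i chi_i e^{E_i/kT}  -  ln sum_j chi'_j e^{-E_j/kT} ]

with chi the cation (oxidized) and chi' the neutral (reduced)
populations. The two log-mean terms are the oxidized-side and
reduced-side estimates of the mixture potential; for populations that
are Boltzmann-consistent with the potentials they coincide and the
half-sum is thermodynamically exact. Two contracts pin the
implementation: when all member potentials are equal, the result is that
potential exactly, for any populations; and the result always lies
within the range of the member potentials. Printed population vectors
that sum slightly below 1 (unlisted minor tautomers) are renormalised
with a warning; a `min_population` filter reproduces the common
"ignore tautomers below 1%" convention but defaults to keeping all
members.

## Benchmarking

`mue()` scores computed potentials against experimental ranges: the
unsigned error per species is the distance to the *midpoint* of the
range (the canonical choice; `reference = "low"`/`"high"` for
sensitivity analysis) and the MUE is the group mean. The package ships
two plain-text reference tables: `experimental_ranges.csv` (aqueous
ranges for A, C, G, T, U) and `reference_dft_potentials.csv` (potentials
for three DFT functionals under seven protocols, with ensemble spreads
for the dynamic entries) used in the worked examples and tests.

## The synthetic generator

All statistical behaviour is validated against
`sample_linear_response()`, which realises exactly the regime the
Marcus estimator presupposes: VIE ~ N(dA + lambda, sigma),
VAE ~ N(dA - lambda, sigma), sigma = sqrt(2 lambda kT), using R's
Mersenne-Twister generator with an explicit seed (the caller's RNG
state is restored). `sample_nonlinear()` produces controlled
violations: per-state reorganization energies set unequal widths, and a
`skew` parameter swaps the Gaussian deviates for standardised
shifted-lognormal ones with exactly the requested skewness.
`mock_static_records()` solves the inverse problem for the static
protocols, producing a record set whose ground-truth potential and
cycle components are known exactly.

What the generator does *not* emulate: time correlation between
snapshots, multimodality from slow conformational states, the
systematic inconsistency between fluctuation-based and Stokes-shift
reorganization energies typical of fixed-charge force fields, or any
coupling between the VIE and VAE ensembles. Passing tests therefore
demonstrate correctness of the estimators under their stated
assumptions, not robustness to every pathology of real trajectories.

Validation problem sizes used in the suite: ensembles of 200 snapshots
(matching common practice) across 50 seeds for recovery and
classification rates, single runs at n = 5000 to 20000 for
distributional identities, parameterised down to n = 2 for the exact
arithmetic identities.

## Numerical choices and degenerate inputs

* Canonical unit eV everywhere after ingest; sample (N-1) standard
  deviations throughout.
* Constant ensembles are legal everywhere except the diagnostics
  (normality is undefined; minimum 8 snapshots there) and produce flat
  convergence curves, single-bin distributions and zero spreads.
* The quadratic-coupling root search runs on log r with a bracket
  around the large-displacement limit r = (sigma1/sigma2)^(2/3),
  widening the bracket before failing; equal sample variances shortcut
  to r = 1 exactly.
* Boltzmann weights and equilibrium-constant averages use shifted
  log-sum-exp forms, so potentials of ~1 V (40 kT) do not overflow.
* Tie-breaking in `converged_at()` is "first window that qualifies";
  the sentinel for a curve that never settles is `NA`.

## Limitations

The package post-processes energies; it cannot detect upstream problems
such as unequilibrated trajectories or basis-set artifacts. The
nonlinear correction is one member of the family of quadratic models --
with strongly inconsistent input moments (fluctuation lambdas an order
of magnitude above the Stokes-shift lambda, as fixed-charge explicit
solvation can produce) any three-parameter model is a compromise, and
the reported `variance_scale_residual` should be inspected before
trusting the corrected number. Potentials are one-electron only, and no
alternative reference electrodes are built in beyond overriding the SHE
constant.
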