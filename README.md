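# oxpot

One-electron oxidation potentials of solvated molecules from static and
dynamic quantum-chemical protocols.

`oxpot` is the post-processing layer between electronic-structure / MD
output and redox chemistry: it converts electronic energies, thermal
corrections and per-snapshot vertical energy-gap ensembles into
reduction potentials of the N+/N couple referenced to the standard
hydrogen electrode (SHE), for users who compute the energies elsewhere
(any DFT/MD engine) and need consistent, diagnosable protocols on top of
them. Its test system is the five DNA/RNA nucleobases in water, but
nothing in the machinery is nucleobase-specific.

## What it computes

All protocols share the reference conventions (overridable via
`energy_constants()` or a config file): absolute SHE potential
E_SHE = 4.281 V, electron gas-phase free energy G_c(e-) = -0.867
kcal/mol, kT = 0.025693 eV at 298.15 K, and for n = 1

    E_red = -dG_red[eV] - E_SHE .

* **Static direct** (`static_direct`):
  dG_red = [E_e(N) + G_T(N)] - [E_e(N+) + G_T(N+)] - G_c(e-) from
  solvent-phase, solvent-optimized records (the adiabatic route).
* **Thermodynamic cycles** (`cycle_potential`, variants `cycle1` /
  `cycle2`): dG_red = dG_red,gas + dG_s(N) - dG_s(N+), with gas-phase
  thermal corrections and solvation energies dG_s = E_e(solv) -
  E_e(gas) evaluated with (cycle 1) or without (cycle 2) solute
  relaxation in solvent.
* **Dynamic direct** (`dynamic_direct`):
  dG_red = <E(N)>_N - <E(N+)>_N+ - G_c(e-) from total-energy ensembles.
* **Dynamic Marcus** (`marcus_free_energy`): linear-response half-sum
  dA_ox = (<VIE> + <VAE>)/2 of the vertical ionization/attachment gap
  ensembles, with reorganization energy lambda = (<VIE> - <VAE>)/2.
* **Validity diagnostics** (`linear_response_report`): Gaussian shape,
  equal widths, and consistency of lambda with sigma^2/(2kT) per state;
  `gap_distribution` builds the p(dE) and A(dE) = -kT ln p surfaces.
* **Nonlinear correction** (`matyushov_voth_corrected`): three-parameter
  quadratic-coupling model for unequal-variance pairs; exactly equal to
  the Marcus result at equal variances.
* **Tautomer weighting** (`ensemble_potential`): population-weighted
  average of reduction equilibrium constants over a `tautomer_set`.
* **Benchmarking** (`mue`): unsigned errors against the midpoints of
  experimental ranges; packaged range and reference-potential tables.
* **Convergence** (`convergence_curve`, `converged_at`) and a one-call
  driver (`run_full_comparison`), plus a synthetic generator
  (`sample_linear_response`, `sample_nonlinear`, `mock_static_records`)
  with exact ground truth for validation.

## Worked example

Guanine with a GGA functional in a polarizable continuum: the ensemble
averages of the vertical gaps are <VIE> = 5.30 eV and <VAE> = 4.90 eV.

```r
library(oxpot)
vie <- gap_ensemble(c(5.28, 5.30, 5.32), "G", "VIE",
                    solvent_model = "implicit", method_tag = "PBEOP")
vae <- gap_ensemble(c(4.88, 4.90, 4.92), "G", "VAE",
                    solvent_model = "implicit", method_tag = "PBEOP")
marcus_free_energy(vie, vae)
#> dynamic_marcus potential for G (implicit solvent): 0.781 +/- 0.014 V vs SHE
#>   Delta G_red = -5.0624 eV over 3 + 3 snapshots
```

The half-sum gap is 5.10 eV; subtracting the electron term (-0.0376 eV)
and the SHE reference gives 0.78 V -- guanine is the most easily
oxidized nucleobase. Whether that half-sum is *valid* is a separate
question, answered on the ensembles themselves (here on synthetic
linear-response data with the same magnitudes):

```r
s <- sample_linear_response(delta_a = 5.10, lam = 0.20, n = 200, seed = 1)
linear_response_report(s$vie, s$vae)
#> Marcus linear-response diagnostics: synthetic (implicit solvent)
#>   sigma_VIE = 0.094 eV, sigma_VAE = 0.102 eV  [sigma_equal: pass]
#>   lambda: gap 0.200, neutral 0.173, cation 0.204 eV  [consistent: pass]
#>   Gaussian shape: VIE pass (skew 0.19, p 0.427), VAE pass (skew -0.28, p 0.272)
#>   regime: marcus
```

Benchmarking the packaged reference potentials (three functionals,
seven protocols) against the experimental ranges:

```r
mue(reference_potentials())
#> Benchmark vs experimental ranges (reference: mid point)
#>  method_tag                protocol n_species mue_V mue_spread_V
#>       PBEOP dynamic_direct_implicit         5  0.24         0.30
#>       PBEOP dynamic_marcus_implicit         5  0.23         0.14
#>       PBEOP           static_direct         5  0.22           NA
#>  ...
```

The pattern the numbers show: the static direct, dynamic direct
implicit and dynamic Marcus implicit protocols agree closely (sampling
matters little for these rigid solutes), implicit solvation outperforms
fixed-charge explicit water, and the GGA functional gives the smallest
errors overall.

Tautomer weighting, e.g. guanine's canonical and N7-H forms (0.85 V at
68.0/84.2% and 0.86 V at 31.8/15.8% neutral/cation populations):

```r
tg <- tautomer_set("G", c("canonical", "N7H"), c(0.85, 0.86),
                   c(0.680, 0.318), c(0.842, 0.158))
round(ensemble_potential(tg), 2)
#> [1] 0.85
```

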