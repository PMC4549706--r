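# kinhibit

Enzyme inhibition kinetics for slow- and fast-binding inhibitors, with the
hit-to-lead triage layer used in fungicide discovery against the cytochrome
*bc*₁ complex (ubiquinol–cytochrome *c* oxidoreductase).

The package is for enzymologists and agrochemical/drug-discovery scientists
who need to go from raw assay tables to inhibition constants and candidate
decisions:

* **Slow-binding analysis.** Progress curves P(t) = v_s·t + (v₀ − v_s)(1 −
  e^(−k_obs·t))/k_obs are fitted per trace for the initial rate v₀, the
  steady-state rate v_s and the observed relaxation constant k_obs; k_obs is
  regressed on inhibitor concentration to give the apparent association and
  dissociation constants (A = slope, B = intercept); the substrate
  dependence of A and B diagnoses modality (A falling with [S] at flat B ⇒
  competitive; no [S] dependence ⇒ noncompetitive); and the microscopic
  constants follow, with **K_i = k₋₀ / k₊₀**.
* **Fast-binding analysis.** Initial-rate grids are fitted globally against
  the competitive / noncompetitive / uncompetitive / mixed Michaelis–Menten
  inhibition laws with AICc model selection, double-reciprocal diagnostics,
  and apparent-K_m/V_max trends (K_m,app = K_m(1 + I/K_i) for competitive).
* **Triage layer.** ΔG = RT·ln K_i conversions, free-energy shifts ΔΔG =
  RT·ln(K_i^new/K_i^ref), fold improvements, ligand efficiency per heavy
  atom, enumeration of the 80-candidate substitution grid, strict triage at
  −1.37 kcal/mol (a 10-fold potency gain at 300 K), and the six-rule
  pesticide-likeness filter (MW ≤ 435, ClogP ≤ 6, HBA ≤ 6, HBD ≤ 2,
  ROB ≤ 9, ARB ≤ 17).
* **Synthetic-assay generator.** Seeded, deterministic datasets at the
  reference assay designs (succinate–cytochrome *c* reductase and
  DBH₂–cytochrome *c* systems), so every inference stage is verifiable by
  parameter-recovery simulation without instrument data.

## Worked example

Simulate a slow-binding study at the fixed-substrate design (cytochrome *c*
60 µM; inhibitor 0–50 nM; 2% additive noise) and run the full inference
chain:

```r
library(kinhibit)

designs <- reference_designs()
truths  <- reference_truths()   # k+0 = 6.6e5 s^-1 M^-1, k-0 = 0.00271 s^-1

curves <- generate_progress_curves(designs$lead_cytc_slow,
                                   truths$lead_cytc_slow, seed = 42)
study <- analyze_slow_binding(curves)
study
#> <slow_binding_study> 6 curves, 1 kobs regressions, modality: noncompetitive
#> <microscopic_constants> noncompetitive: k+0 = 6.739e+05, k-0 = 0.002537, Ki = 3.764e-09 (I units)
study$regressions[[1]]
#> <kobs_regression> A = 6.739e+05 +/- 3.1e+04, B = 0.002537 +/- 0.001 (r^2 = 0.9937, n = 5)
```

The apparent association constant A (here in s⁻¹ M⁻¹ because inhibitor
concentrations are molar internally) is 6.74e5 ≈ 0.00067 s⁻¹ nM⁻¹, the
dissociation constant B is 0.0025 s⁻¹, and their ratio gives K_i ≈ 3.8 nM
for this noisy realisation (truth: 0.00066, 0.00271, 4.1 nM). Convert the
potency into decision-layer quantities against a 297.6 nM reference
inhibitor with 30 heavy atoms (the optimised compound has 28):

```r
potency_record(c(297.6e-9, study$constants$Ki), ki_ref = 297.6e-9,
               n_heavy = c(30, 28))[, c("ddG", "fold_change", "LE")]
#>     ddG fold_change   LE
#> 1  0.00        1.00 0.30
#> 2 -2.61       79.07 0.41
```

A ΔΔG of −2.6 kcal/mol is a ~79-fold improvement — comfortably below the
−1.37 kcal/mol (10-fold) triage threshold — and the ligand efficiency rises
from 0.30 to 0.41 kcal/mol per heavy atom. A fast-binding counterpart:

```r
tab <- generate_rate_table(designs$az_dbh2, truths$az_dbh2, seed = 42)
fit_inhibition_models(tab)
#> <steady_state_fit> modality: competitive (n = 36, proportional weighting)
#>    Vmax = 9.929e-08, Km = 7.686e-05, Ki = 3.773e-07
```

i.e. K_m ≈ 77 µM and K_i ≈ 377 nM recovered from one noisy grid whose truth
is 80 µM and 394.7 nM.

A thin command-line wrapper over the same functions is installed at
`inst/cli/kinhibit.R` (subcommands `simulate`, `fit-progress`, `slowbind`,
`fit-rates`, `triage`, `likeness`), and a synthetic 80-candidate table for
the triage subcommands ships in `inst/extdata/candidates_synthetic.csv`.

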