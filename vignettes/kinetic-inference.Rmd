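---
title: "Inhibition kinetics and hit-to-lead triage with kinhibit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibition kinetics and hit-to-lead triage with kinhibit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinhibit)
```

## The scientific problem

Respiration inhibitors of the cytochrome *bc*~1~ complex (ubiquinol–cytochrome
*c* oxidoreductase) are a major fungicide class. Characterising a new
inhibitor requires answering three kinetic questions: *how tightly* does it
bind (the inhibition constant $K_i$), *against which substrate* does it
compete (modality), and *how fast* does it equilibrate with the enzyme
(fast-binding versus slow-binding). The answers come from two experiment
types that this package analyses end to end:

* **initial-rate grids** — rates measured on a substrate × inhibitor
  concentration grid, the classical Michaelis–Menten inhibition experiment;
* **progress curves** — timed product-formation traces that, for a
  slow-binding inhibitor, start linearly and relax towards a slower
  steady-state slope.

On top of the kinetics sits the hit-to-lead decision layer: converting $K_i$
values into binding free energies, ranking substitution candidates by their
calculated free-energy shift, and filtering by agrochemical (pesticide-)
likeness rules.

## Models

### Fast binding: the Michaelis–Menten inhibition family

`mm_rate()` implements the four classical rate laws (concentrations molar,
rates in signal units per second):

$$v_\text{comp} = \frac{V_{max} S}{K_m(1 + I/K_i) + S}, \qquad
  v_\text{noncomp} = \frac{V_{max} S}{(K_m + S)(1 + I/K_i)},$$
$$v_\text{uncomp} = \frac{V_{max} S}{K_m + S(1 + I/K_i)}, \qquad
  v_\text{mixed} = \frac{V_{max} S}{K_m(1 + I/K_{ic}) + S(1 + I/K_{iu})}.$$

`fit_inhibition_models()` fits all four to the untransformed rates by
nonlinear least squares and selects a modality by small-sample-corrected
AICc. Double-reciprocal (Lineweaver–Burk) plots are provided by
`reciprocal_diagnostics()` purely as a diagnostic view: lines sharing the
$1/v$-axis intercept indicate competitive inhibition, a common crossing at
$-1/K_m$ on the $1/S$ axis indicates noncompetitive, parallel lines
uncompetitive. Because the reciprocal transform inflates noise at low rates,
the global nonlinear fit is always the report of record; a test asserts that
the two disagree under heteroscedastic noise, which is the reason for the
separation.

### Slow binding: the one-step scheme

For an inhibitor whose equilibration is slow on the assay timescale, a trace
at fixed $(S, I)$ follows the integrated one-step equation

$$P(t) = v_s t + \frac{(v_0 - v_s)\left(1 - e^{-k_{obs} t}\right)}{k_{obs}},$$

with initial slope $v_0$, steady-state slope $v_s$ and observed relaxation
constant $k_{obs}$. The two-state interpretation (binding at
$k_{+0}^{app} I$, release at $k_{-0}$, turnover proportional to free enzyme)
integrates to exactly this form; a test verifies agreement with numerical
ODE integration to a relative $10^{-6}$. Two identities connect the scheme's
levels and are satisfied by the synthetic generator by construction:

$$k_{obs} = k_{-0} + k_{+0}\frac{I}{1 + S/K_m} \;\;(\text{competitive}),
\qquad k_{obs} = k_{-0} + k_{+0} I \;\;(\text{noncompetitive}),$$
$$v_s = v_0\,\frac{k_{-0}}{k_{obs}} = \frac{v_0}{1 + I/K_i^{app}},
\qquad K_i^{app} = K_i\,(1 + S/K_m)\ \text{for competitive}.$$

The inference chain (`analyze_slow_binding()`) mirrors how these
experiments are analysed at the bench:

1. fit every trace for $(v_0, v_s, k_{obs})$ (`fit_progress_curve()`);
2. at each substrate level with at least three inhibitor levels, regress
   $k_{obs}$ on $I$: slope $A$ (apparent association constant) and intercept
   $B$ (apparent dissociation constant) (`regress_kobs_vs_inhibitor()`);
3. diagnose modality from the substrate dependence of $A$ and $B$
   (`classify_slow_binding_modality()`): $A$ falling with $S$ while $B$
   stays flat is the competitive signature; no $S$ dependence at all is
   noncompetitive;
4. derive the microscopic constants (`derive_microscopic_constants()`):
   noncompetitive reduces to $k_{+0} = A$, $k_{-0} = B$; competitive uses
   $1/A = (1 + S/K_m)/k_{+0}$, either with $K_m$ fixed (regression through
   the origin on $1 + S/K_m$) or with $K_m$ co-estimated from the intercept
   and slope of the $1/A$-versus-$S$ line. Always $K_i = k_{-0}/k_{+0}$.

Two-step (isomerisation) slow binding and tight-binding depletion
corrections are out of scope: the one-step model is identified by a single
$(k_{+0}, k_{-0})$ pair, which is the regime this package addresses.

### The decision layer

With $\Delta G = RT\ln K_i$ ($K_i$ molar; more negative = tighter), a
substitution candidate's shift against the parent is
$\Delta\Delta G = RT \ln (K_i^{new}/K_i^{ref})$. At the default
$T = 300\,$K and $R = 1.9872\times10^{-3}\,$kcal mol^-1^ K^-1^,
$RT\ln 10 = 1.373$, so the default triage threshold of $-1.37$ kcal/mol is a
ten-fold potency improvement; the threshold is strict (a candidate exactly
at $-1.37$ is excluded) and both the temperature and the threshold are
configurable (`thermo_context()`, `run_config()`). Ligand efficiency is
$-\Delta G$ per non-hydrogen atom. `enumerate_candidates()` spans the
2 scaffold series × 4 sites × 10 substituent groups = 80-candidate grid,
numbering compounds 2–81 series-major, then site, then group — an ordering
assumption consistent with the printed series ranges and recorded in the
output. The pesticide-likeness filter applies MW ≤ 435 Da, ClogP ≤ 6,
HBA ≤ 6, HBD ≤ 2, rotatable bonds ≤ 9 and aromatic bonds ≤ 17, with
boundary values passing; descriptors are consumed as inputs, never computed
from structures.

## The synthetic-assay generator

Because instrument traces for these assays are not generally deposited, the
package ships a seeded generator whose defaults are the reference study
conditions, so that every inference stage can be validated by
parameter-recovery simulation:

| design | system | grid | mechanism |
|---|---|---|---|
| `az_dbh2` | DBH2–cytochrome *c* | DBH2 20–120 µM (6), AZ 0–5000 nM (6) | fast competitive, $K_m$ 80 µM, $K_i$ 394.7 nM |
| `hit_cytc` | SCR | cyt *c* 1.13–15.6 µM (6 geometric), 0–60 nM (5) | fast noncompetitive, $K_m$ 4.3 µM, $K_i$ 31.1 nM |
| `hit_dbh2` | DBH2–cytochrome *c* | DBH2 20–120 µM, 0–500 nM (6) | fast competitive, $K_i$ 96.5 nM |
| `lead_cytc_slow` | SCR | cyt *c* 60 µM, inhibitor 0/15/20/30/40/50 nM | slow noncompetitive, $k_{+0}$ 0.00066 s^-1^ nM^-1^, $k_{-0}$ 0.00271 s^-1^ |
| `lead_dbh2_slow` | DBH2–cytochrome *c* | DBH2 20–120 µM, per-level ladder 0–(60+S[µM]) nM (5) | slow competitive, $k_{+0}$ 0.00038, $k_{-0}$ 0.00509, $K_m$ 80 µM |

Where a published design states only ranges, the generator fixes one
concrete realisation: six geometric cytochrome-*c* levels across
1.13–15.6 µM, and a linear interpolation of the slow-competitive inhibitor
ladder between its printed endpoints (maximum 80 nM at 20 µM DBH2 and
180 nM at 120 µM, i.e. $I_{max}[\text{nM}] = 60 + S[\mu M]$, five evenly
spaced levels including 0).

Noise defaults: 3% proportional Gaussian noise for rate tables and additive
Gaussian noise with standard deviation 2% of each trace's final signal for
progress curves — realistic spectrophotometric scatter under which recovery
at the reference designs succeeds. Progress traces span ≥ 3/k~obs~ (300 s
and 400 s defaults, 60 points), so $v_s$ is identifiable; the generator
warns when a grid point violates $k_{obs}\cdot T_{end} \ge 1$. The RNG is
pinned (Mersenne–Twister, inversion) so a seed reproduces a dataset
byte-for-byte across sessions, and the seed perturbs only the noise, never
the noiseless backbone.

What the generator deliberately does **not** emulate: enzyme or inhibitor
depletion (tight binding), instrument drift and baseline artifacts,
pre-incubation equilibration experiments, or correlated residuals. Passing
recovery tests therefore demonstrate correctness of the inference chain
under the stated error model, not robustness to every pathology of real
traces.

## Numerical choices

* **Progress-curve fitting** uses Levenberg–Marquardt with a deterministic
  five-point multistart on $k_{obs} \in \{0.5, 1, 2, 5, 10\}/T_{end}$; $v_0$
  starts at the first-decile secant slope and $v_s$ at the last-quintile
  secant slope. Best SSE wins; near-ties go to the smaller $k_{obs}$.
  Convergence: relative SSE change $<10^{-10}$ or parameter step
  $<10^{-8}$, at most 500 iterations. A profile-likelihood grid search (the
  model is linear in $v_0, v_s$ at fixed $k_{obs}$) serves as an independent
  oracle in the tests.
* **Linearity sentinel.** A trace without a detectable slow phase must not
  be forced through the three-parameter model: the slow-binding fit is
  compared with a straight line through the origin by an F-test and the
  sentinel ($v_0 = v_s$ = slope, $k_{obs}$ = NA) is returned when curvature
  is not significant at $\alpha = 0.05$. Uninhibited traces land here by
  design.
* **Model selection.** Weighted residual sums of squares are floored at a
  numerical-noise level ($n\,(10^{-9}\sigma_w)^2$) so that models which
  reproduce the data exactly tie instead of being ranked by floating-point
  jitter; within a 2-unit AICc band the model with fewest parameters wins.
  This matters because the mixed law nests the three 3-parameter laws: on
  exact competitive data the mixed model also fits exactly and its extra
  constant is unidentifiable, so parsimony — not RSS noise — must break the
  tie. "Undetermined" is reserved for ties between non-nested models, and
  the full AICc table (with an `exact` flag) is always returned.
* **Weighting.** Rate fits default to $1/v^2$ weights (constant-CV error
  model, matching the generator's proportional noise); unweighted is an
  option. The $k_{obs}$ regressions are unweighted by default, matching how
  such lines are conventionally fitted, with inverse-variance weighting as
  an option.
* **Pooling $k_{-0}$ across substrate levels** uses a DerSimonian–Laird
  random-effects weight, $1/(se^2 + \tau^2)$: with only four or five points
  behind each per-level intercept, an occasional spuriously small standard
  error would otherwise dominate a fixed-effect pool and can even drag the
  estimate negative. The random-effects pool reduces to inverse-variance
  weighting when the levels are homogeneous and to the plain mean when they
  are not.
* **"Invariable B"** is tested two ways, both required: a slope t-test of
  $B$ against $S$ at $\alpha = 0.05$ and a practical-equivalence band (the
  fitted change of $B$ across the $S$ range must stay below 20% of its
  mean).

## Power of the modality classifier

The type-I side of the slow-binding classifier is calibrated: under true
noncompetitive data with 5% scatter on $k_{obs}$, "competitive" is returned
in well under 7% of studies at $\alpha = 0.05$ (tested over 1000
simulations). The power side is intrinsically limited at realistic noise:
with four positive inhibitor levels per substrate level, the per-level $B$
estimates scatter far more than 20% of their mean, so genuinely competitive
studies often fail the B-equivalence arm and are reported "undetermined"
rather than "competitive". This is a conservative failure mode — the
classifier refuses to over-read noisy intercepts — and it is why
`analyze_slow_binding()` accepts an explicit `modality` argument: once
competition has been established (e.g. from the classifier on richer data,
or a $k_{obs}$ horizontality test against the other substrate), the
microscopic-constant derivation can and should be run with the modality
asserted and $K_m$ fixed from the uninhibited fits.

## Simulation study sizes

The package's recovery studies (tests and the acceptance script) use 100
seeded replicates per design — enough for the replicate means to sit well
inside the 5–10% recovery bands while keeping a full run around a minute —
and 1000 replicates for the classifier's type-I calibration and the
law-of-large-numbers check on the generator.

## Known limitations

* One-step slow binding only; a genuine two-step inhibitor will show a
  hyperbolic (not linear) $k_{obs}$–$I$ relation that this package will fit
  with a straight line. Inspect the regression $r^2$.
* No depletion corrections: designs must keep the inhibitor in large excess
  over the enzyme (nanomolar enzyme, as in the reference assays).
* $v_0$ is fitted per curve and not constrained across inhibitor levels.
* The compound-numbering convention of `enumerate_candidates()` is an
  assumption (series-major, then site, then group) consistent with the
  printed block ranges; downstream joins should use the explicit
  series/site/group columns, not the number, when in doubt.
* Descriptors for the likeness filter are inputs; no cheminformatics is
  performed.
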