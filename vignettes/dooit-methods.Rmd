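---
title: "Dual-objective nuSVR model selection for binary-mixture solubility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-objective nuSVR model selection for binary-mixture solubility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dooit)
```

## The problem

Predicting how well a drug-like solute dissolves in a *binary* solvent
mixture is hard because mixing effects are non-additive: water–organic
hydrogen-bond networking can either amplify or suppress solvation, and
physics-based thermodynamics (COSMO-RS) anchored on neat-solvent reference
solubilities interpolates poorly between the endpoints, especially when the
two neat solubilities differ by orders of magnitude (water/DMSO being the
canonical offender). This package treats the physics-based prediction not as
the answer but as one descriptor among several, and learns a nonlinear
correction with a ν-support-vector regression (nuSVR, RBF kernel) whose
descriptor set and hyperparameters are chosen by an automated, stability-
focused pipeline ("DOO-IT": dual-objective optimization with iterative
feature pruning).

Solubility is carried everywhere as the decadic log of the solute mole
fraction, `log10(x1)`; natural logs appear only inside the thermodynamic
curation models, where they are canonical.

## Descriptors

Each molecule (solute or solvent) carries five interaction descriptors from
a COSMO-RS calculation — total interaction energy, its electrostatic-misfit,
hydrogen-bonding and van der Waals components, and the chemical potential —
plus, optionally, a σ-potential curve: the molecule's affinity as a function
of surface screening-charge density, sampled at 61 points on the fixed grid
−0.03 … +0.03 e/Å² (step 0.001). Units of the energy terms are carried as-is
and never converted; only internal consistency matters to the regression.

For a mixture record (solute, solvent 1, solvent 2, solute-free organic mole
fraction `x2_star`):

* solvent descriptors are the mole-fraction-weighted averages
  `(1 − x2*)·comp1 + x2*·comp2`, applied element-wise to σ-curves too
  (`weight_solvent_descriptors()`); the weighting is symmetric and neither
  component is assumed to be water;
* "relative difference" descriptors are arithmetic differences (solute −
  solvent), since ratios are ill-defined near zero (`diff_descriptors()`; a
  ratio mode exists for exploration);
* **set 1** (16 descriptors) = COSMO-RS predicted log-solubility + 5 solute
  + 5 weighted-solvent + 5 difference terms;
* **set 2** (28) appends twelve condensed σ-potential features.

σ-curves are condensed by averaging over 0.005-wide intervals, giving a
12-step function spanning the hydrogen-bond-donor (HBD1–4), hydrophobic
(HH1–4) and hydrogen-bond-acceptor (HBA1–4) regions. With 61 points at 0.001
spacing, half-open bins `[lo, lo+0.005)` hold 5 points each and the single
point at exactly +0.03 is assigned to the last bin (6 points) — the only
convention that loses no grid point (`bin_sigma_potential()`).

All three 12-bin blocks (solute, solvent mixture, difference) are computed
internally; which one enters set 2 is a design choice with no single
canonical answer, and the package defaults to the **difference** block — it
encodes both sides in twelve features and keeps the set-2 total at 28 — with
`sigma_block = "api"` or `"solvent"` available. Temperature is not an
explicit feature: it enters through the conditions of the underlying
COSMO-RS calculation that produced the descriptors.

## Curation models

Literature solubility tables are frequently inconsistent between the
temperatures and compositions at which neat solvents and mixtures were
measured. `categorize()` classifies each system: (1) coherent; (2)
temperature mismatch, compositions shared; (3) composition mismatch,
temperatures shared; (4) both. Equality tolerances are 0.01 K and 1e-6 on
mole fraction, matching the rounding of published tables. Categories 2–4 are
repaired by back-computation with three standard models, all fit by least
squares on ln x (solubilities span ~4 orders of magnitude, so residuals on x
would be dominated by the most soluble points):

* **Buchowski–Ksiazczak λh**:
  `ln(1 + λ(1−x)/x) = λh(1/T − 1/T_m)`, solved in closed form
  `x = λ / (exp(λh(1/T − 1/T_m)) + λ − 1)`. Two parameters, so three
  measurements suffice; the melting temperature is a known constant, not
  fitted. The (λ, h) likelihood surface is banana-shaped at small λ, so the
  fitter multi-starts over λ ∈ {0.05, 0.2, 1, 3} with slope-derived h and
  keeps the lowest residual (`fit_lambda_h()`).
* **Three-parameter van't Hoff**: `ln x = a + b/T + c·ln T`, an ordinary
  linear solve; needs at least four points at distinct temperatures. The
  basis (1, 1/T, ln T) is near-collinear over realistic temperature spans,
  so the solve is done on centered regressors and mapped back — exact
  algebraically, far better conditioned numerically (`fit_vanthoff3()`).
  Note the *individual* coefficients only become statistically identifiable
  on wide, dense temperature designs; on a 45 K span their estimates can
  swing by tens of percent under 1% noise even though the fitted curve is
  excellent.
* **Jouyban–Acree** (one isotherm):
  `ln x_m = w1·ln x1 + w2·ln x2 + (w1 w2/T)·Σ_{i=0..2} J_i (w1 − w2)^i`.
  Endpoint-exact for any J by construction; the J's are obtained linearly
  after moving the log-linear blend to the left-hand side; needs three
  interior compositions (`fit_jouyban_acree()`). A large positive `J0`
  produces the mid-composition solubility maximum typical of these systems.

When several literature values exist for a neat solvent, the arithmetic mean
of x (then logged) is the reference.

## One DOO-IT run

`dooit(formula, data, ...)` performs one run:

1. **Split.** Rows are partitioned 80/20 (`round(0.2·n)` test rows),
   deterministically per seed.
2. **Per pruning level**, on the training split only:
   a dual-objective hyperparameter search (`run_doo()`) evaluates nuSVR
   configurations by 5-fold cross-validation. Per fold, descriptors are
   standardized to zero mean and unit variance (population variance, the
   usual machine-learning scaler convention) on the fold-training rows; the
   frozen transform is applied to the fold's held-out rows. The RBF width is
   anchored to `gamma_base = 1/median(‖x_i − x_j‖²)` of the standardized
   fold-training rows — the classical median heuristic, which makes a
   log-scale factor of 0 the natural center of the search — and the
   optimizer searches `nu ∈ [0.01, 1)`, `C ∈ [1e-2, 1e3]` (log-uniform) and
   `log10_gamma_scale ∈ [−2, 2]`. The two objectives, both minimized, are
   the mean fold MAE and the mean support-vector ratio (support vectors /
   fold-training rows) — an intrinsic complexity measure for nuSVR, since ν
   lower-bounds the support-vector fraction.
3. **Pareto front and 1-SE pick.** The non-dominated set is extracted
   exactly (`pareto_front()`); the candidate is the front member with the
   lowest SV ratio among those within one standard error
   (`sd(fold MAEs)/√k`) of the front's best CV MAE (`select_1se()`), ties
   breaking toward lower MAE then lower trial id.
4. **Prune.** The candidate is refit per fold at its chosen hyperparameters
   and features are ranked by permutation importance — the mean rise in MAE
   over 10 seeded permutations, scored on each fold's *held-out* block
   (out-of-fold scoring avoids the optimism of permuting on training rows;
   which rows the reference pipeline used is not documented, and this is the
   conservative choice). The least important feature is dropped and the
   cycle repeats down to `min_features` (default 5), yielding one candidate
   per feature count.

### Sampler

The search over (ν, C, γ-scale) uses a seeded multi-objective local
refinement sampler: a uniform warm-up over the box (10 % of the trial
budget, at least 20 trials — conservative relative to the ~10 startup trials
customary for TPE-style samplers), then Gaussian perturbations of randomly
chosen members of the *current Pareto front* (σ = 0.08 on ν, 0.25 on log10
C, 0.2 on the γ exponent, clipped to the box), with a 10 % uniform
exploration fallback. Perturbing front members rather than best-MAE points
keeps both ends of the accuracy/complexity trade-off populated. A plain
seeded uniform sampler (`sampler = "random"`) is available, and none of the
selection logic depends on which sampler produced the trials.

### Numerical choices

* libsvm's KKT stopping tolerance is set to `max(0.01, 1e-4·C)` rather than
  the absolute default 1e-3. The dual gradients scale with C, so a fixed
  absolute tolerance forces iteration counts at the large-C end of the box
  that grow without measurably changing predictions: across random
  configurations the cross-validated MAE moves by well under the
  fold-to-fold standard error (≤ 0.005 log units) while the worst-case cost
  per fit drops by an order of magnitude.
* Failed fits mark their trial as failed (with the cause logged); failed
  trials are excluded from the front rather than imputed.
* Zero-variance descriptor columns abort standardization with the column
  named; identical training rows abort the γ anchor. Both indicate broken
  upstream data rather than conditions to silently absorb.
* `cv_mae_se = sd(per-fold MAE)/√k`.

### Reproducibility and leakage

Every random element — the 80/20 split, fold assignment, sampler draws,
permutations — derives from the single `seed` argument via fixed offsets,
and all seeded sections restore the caller's RNG state. Two runs with the
same configuration are identical down to the serialized JSON artifact
(`as_run_artifact()` / `write_run_artifact()`, 17 significant digits, no
timestamps). Fold contexts record the global row indices their scaler and γ
anchor were computed from, so the absence of test-row leakage is directly
auditable; the test suite additionally verifies that perturbing held-out
rows changes no training-side quantity.

## Multi-run stability selection

Single runs of this pipeline are exposed to an unstable, non-convex search
landscape, so the final model is chosen across many independent runs
(`dooit_stability()`):

1. Each run votes for a feature count: the smallest count whose held-out
   test MAE is within one standard error (the fold-level SE of the run's
   best candidate) of the run's minimum — the same parsimony-within-1-SE
   logic as the per-level pick, applied along the trace.
2. A count is admissible as the final **architecture** if it received at
   least 30 % of the votes *and* its mean test MAE lies within one cross-run
   standard error of the global minimum mean, where the SE is taken over all
   runs' chosen test MAEs (`sd/√runs`) — a per-count SE would collapse to
   zero whenever the best count holds a single vote. Among admissible counts the best mean test MAE wins, ties
   toward fewer features.
3. The **champion** is the run-level candidate at that architecture with the
   highest composite score: 0.5·accuracy + 0.3·explanatory power (test R²)
   + 0.2·generalization (negative train–test MAE gap), each component
   min–max normalized over the candidate pool so that the weights compare
   unitless and unit-bearing quantities fairly. A component that is constant
   across the pool contributes 0.5 of its weight to everyone (the neutral
   midpoint). Ties break toward higher summed per-descriptor selection
   frequency — descriptor stability is deliberately a tie-breaker, not a
   hard filter — then toward lower test MAE.

The number of runs is a configuration choice; 5–15 runs are practical on a
desk machine, and the acceptance checks here use 10.

## Validation utilities

Random 80/20 splits measure interpolation; `loco_splits()` builds
leave-one-compound-out splits — every row of one solute held out — for the
much harsher extrapolation question. A large gap between the two is a
property of sparse chemical coverage, not necessarily a defect of the model.

## Synthetic data: what it does and does not emulate

`gen_qspr_table()` generates the planted-feature tables used throughout the
tests: independent standard-normal descriptors, of which a known subset
drives the target through a smooth nonlinearity (default: a mixture of three
seeded Gaussian bumps over the informative subspace — qualitatively the kind
of smooth, interacting response an RBF regression faces on real descriptor
tables), small per-solute offsets for LOCO-style grouping, and Gaussian
target noise. Defaults mirror the set-1 study conditions: n = 400 rows, 16
features with 5 informative, 11 solutes, noise sd 0.05 log units — chosen so
attainable MAE values land in the 0.05–0.3 range typical of log-solubility
modeling. The recorded ground truth (informative set, generating function,
offsets) supports oracle checks without fitting.

What this does *not* emulate: correlated descriptors (real COSMO-RS terms
co-vary strongly), heteroscedastic experimental error, composition-dependent
structure along `x2_star`, or solutes occupying disjoint descriptor regions.
Passing the planted-recovery tests therefore demonstrates that the machinery
selects genuinely informative features under known conditions — not that any
particular accuracy will be achieved on a specific laboratory dataset.

`gen_sigma_curve()` (parabola-plus-wings on the fixed 61-point grid) and
`gen_solubility_curves()` (forward curation models plus ln-x noise) supply
the remaining fixtures. The Monte-Carlo recovery studies use λ = 0.4,
h = 3000 K, T_m = 500 K over 278–323 K for λh; (a, b, c) = (93, −9000, −12)
over 273–353 K for the van't Hoff model — the wide span is what makes those
three near-collinear coefficients individually identifiable at all; and
J = (1500, 600, 500), magnitudes typical of published cosolvency fits, at
nine compositions for Jouyban–Acree.

## Problem sizes used in the checks

The automated checks run ten independent DOO-IT runs at 200 trials per
pruning level on the 400-row planted table (pruning 16 → 5 features), plus
50-seed Monte-Carlo recovery studies and 100-case property sweeps — sizes
chosen as the package's desk-scale standard study, large enough for the
stability analysis to be meaningful and small enough to run attended. The
`scripts/acceptance.R` reproduction uses five runs.

## Known limitations

* The champion's absolute accuracy on real mixture data depends entirely on
  the descriptor quality of the upstream COSMO-RS calculations; the package
  neither computes descriptors from structure nor validates their physics.
* Permutation importance is computed feature-by-feature and shares the usual
  blind spot for strongly correlated descriptor pairs (importance splits
  between them); on real descriptor sets the pruning order between close
  correlates should not be over-interpreted.
* The λh fitter requires T ≤ T_m and a known melting temperature; it will
  not rescue systems measured above their melting point.
* `categorize()` implements the four-way consistency taxonomy; deciding
  *which* repair model to apply to a category-4 system remains a judgment
  call, and the package records rather than automates it.
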