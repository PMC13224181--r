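---
title: "Hybrid thermodynamic and symbolic-regression modeling of organic electrode material solubility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid thermodynamic and symbolic-regression modeling of organic electrode material solubility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oemsol)
```

## The problem

Organic electrode materials (OEMs) — redox-active organic molecules used
as battery electrodes — lose capacity when they dissolve into the
electrolyte. Their solubility in nonaqueous electrolytes is therefore a
design property, but it is slow to measure and hard to predict.
`oemsol` implements an analysis chain for this problem at the scale of a
small curated data set (a few dozen compounds):

1. a **voltammetric measurement analysis**: peak currents from cyclic
   voltammetry are linear in analyte concentration for a
   diffusion-controlled response, so a serial-dilution calibration line
   converts a saturated sample's peak current into a solubility;
2. a **thermodynamic cycle**: crystal → gas → solution, predicting
   logS from computed solvation and sublimation energetics;
3. a **sparse symbolic-regression engine** that learns a compact
   closed-form correction from thermodynamic plus topological molecular
   descriptors; and
4. **validation protocols** built for very small n: fixed-structure
   cross-validation, full-rerun repeated cross-validation, and a
   random-forest overfitting benchmark.

## The thermodynamic cycle

Dissolution is decomposed as $\Delta G_{sol} = \Delta G_{sub} + \Delta
G_{solv}$ with $\Delta G_{sub} = \Delta H_{sub} - T\,\Delta S_{sub}$,
and converted to a base-10 log solubility through
$\Delta G_{sol} = -\ln(10)\,R\,T\,\log_{10}(S_0 V_m)$.
The package carries energies in kJ/mol, entropies in J/(mol K), molar
volumes in L/mol, and defaults to T = 298.15 K; the gas constant is
R = 8.31446e-3 kJ/(mol K). The prefactor is implemented as
$\ln(10)RT$ (= 5.708 kJ/mol at 298.15 K); the familiar "2.303" is its
printed rounding. Sublimation enthalpies derive from per-molecule
lattice energies through the standard empirical offset
$\Delta H_{sub} = -U_{latt} - 2RT$, and sublimation entropies compose as
$\Delta S_{sub} = \Delta S_{vib} - (\Delta S_{trans} + \Delta S_{rot})$.

Computed sublimation entropies are known to carry large systematic
errors — their correlation with experiment can be near zero even when
solvation energies and sublimation enthalpies are individually
accurate. The synthetic-data module reproduces this failure mode with a
corrupted entropy channel $\tilde S = a S + b + \varepsilon$ whose
population $R^2$ against the true channel has the closed form
$a^2 V / (a^2 V + s^2)$; the default emulation tunes it to 0.05 with a
+60 J/(mol K) bias. Cycle predictions through the corrupted channel
collapse while the true channel stays accurate — the package's tests
assert this contrast as a paired Monte-Carlo property.

A linear re-parametrization of the cycle,

$$\log S = \alpha\,\Delta G_{solv} - \beta\,(\Delta H_{sub} -
\Delta S_{sub} T) - \gamma \log_{10} V_m - \delta,$$

is fit by L-BFGS on the mean squared error (`fit_thermo_model()`).
Because the model is linear in its four coefficients this optimization
coincides with closed-form least squares — the test suite uses that
equivalence (to 1e-8) as the module's primary oracle, and the optimizer
is warm-restarted once so it polishes to machine precision. The
regressor columns are standardized internally for conditioning and the
coefficients mapped back exactly, so the result is
initialization-independent. Coefficients are unit-tagged; published
reference values are available via `published_thermo_coefficients()`.

## Topological descriptors

The learned solubility model uses eight graph-theoretic descriptors:
valence Chi path indices of orders 4, 6 and 7 (`Xp4dv`, `Xp6dv`,
`Xp7dv`), the ETA core count (`ETA_alpha`), the Galvez mean topological
charge index of order 2 (`JGI2`), a centered Moreau-Broto
autocorrelation of lag 3 weighted by intrinsic state (`ATSC3s`), the
molecular walk count of order 7 (`MWC07`) and the Labute approximate
surface area (`ASA`). These are computed natively from SMILES
(ChemmineR/OpenBabel handles the conversion to a connection table); the
Chi and ASA implementations reproduce an independent reference
calculator exactly on a frozen fixture panel, including the reference's
treatment of ring-containing bond trails and its shared-hydrogen-sphere
surface-area scheme. Two documented ambiguities: the walk count is
log-scaled by default (`ln(1 + count)`; raw counts grow combinatorially
and the log form keeps the descriptor on the O(10) scale the published
coefficient magnitudes imply), and aromaticity perception can differ
between toolkits for exotic quinoid systems (about 1% in ASA on the one
such fixture molecule; flagged in the tests). The catalogue targets
neutral organic molecules; formal charges are not modeled.

## The symbolic-regression engine

`discover()` composes five stages, each independently exposed and
tested:

- **Preprocessing** (`preprocess_design_matrix()`): non-numeric columns
  dropped, zero-variance columns removed (exactly zero by default; an
  epsilon is available but off), missing values fail loudly — with
  n ≈ 44, silent imputation would distort everything downstream.
- **MI screening** (`mi_screen()`): primary descriptors ranked by a
  k-nearest-neighbor (Kraskov) mutual-information estimate against
  logS, k = 3; an equal-frequency binning estimator is the config
  alternative. Default keep: 6 descriptors.
- **Operator expansion** (`expand_features()`): the screened
  descriptors are recursively combined with `{+, -, *, /, ^2}` for two
  rounds. Commutative operands are kept sorted and associative chains
  flattened, so commutatively equal trees have one canonical string;
  duplicates, non-finite columns (division blow-ups) and constant
  columns are dropped and logged. A candidate cap (50,000) guards
  runaway growth.
- **Screened exhaustive l0 search**: `l0_regress()` solves the
  best-subset problem exactly over its candidate matrix (all supports
  up to `max_support`, Cholesky-bordered enumeration in compiled code).
  Inside `discover()` the candidate pool for that exhaustive search is
  assembled by sure-independence screening in three complementary
  ways: a complexity-stratified marginal screen (70% of the budget goes
  to shallow candidates, complexity ≤ 5 — every deep recombination of
  relevant primaries correlates with the target, so a flat ranking
  drowns the simple terms the parsimony objective prefers), residual
  batches along a greedy path (later terms only become visible once
  dominant ones are fitted), and conditional anchored re-screens of the
  provisional winners. A local combinatorial refinement (single-column
  swaps against the full candidate space) polishes each support size.
- **Selection**: the per-size optima are compared under the l0 penalty
  grid (default 0, 1e-4, 1e-3, 1e-2) and the per-penalty winners by
  BIC. Ties anywhere break deterministically: lower total complexity,
  then lexicographic canonical string.

Every stage is deterministic given the seed; the full configuration,
seed and selected penalty are stored in the returned `symbolic_model`,
which serializes to JSON with prefix-notation expression strings.

The published three-term model is available as
`published_solubility_model()`. Its flattened typography is ambiguous
between products and fractions; the default loader reads each term as a
pure product of its printed factors and `interpretation = "fraction"`
treats the trailing factor as a denominator — the choice is recorded in
the model's config rather than silently guessed.

## Validation protocols

For a 44-compound data set, a single train/test split is meaningless.
Two protocols are implemented:

- `fixed_structure_cv()` freezes the discovered symbolic form and
  re-estimates only its coefficients per training fold — a stress test
  of structural stability (not an unbiased generalization estimate when
  the structure was selected on the full data; the documentation says
  so).
- `full_rerun_cv()` reruns the entire discovery inside every training
  fold across several seeds, averages the per-sample held-out
  predictions over seeds before computing metrics, and keeps all
  discovered structures for `feature_recurrence()` analysis.

Fold assignment is a seeded uniform random partition without
stratification, persisted in every report, and aggregate statistics are
recomputable from the stored per-fold values. Preprocessing and
screening statistics are computed on training rows only; a leakage test
asserts that a held-out outlier cannot influence a training-fold refit.
`baseline_ensemble_cv()` fits a random forest (500 trees, library
defaults otherwise, hyperparameters recorded verbatim) under the same
fold scheme; its train-minus-CV gap is the overfitting benchmark the
sparse model is compared against.

## The synthetic-data generator

The generator (`generate_synthetic()`) emulates the statistical
structure the analysis assumes, not the chemistry: correlated
continuous descriptors (exchangeable latent correlation 0.15 by
default, 8 columns), mixed marginals — normal for signed descriptors,
a rescaled lognormal for magnitude-like ones, each column with its own
nonzero location, as real descriptor catalogues have — and a planted
sparse law with additive Gaussian noise (default sd 0.2 logS units at
n = 44). The default planted law has three product terms plus an
intercept, the complexity class of the published model:

$$\log S = 1.0\,d_{01}(d_{03}-d_{04}) - 0.8\,d_{02}(d_{01}-d_{03})
- 0.5\,d_{04}(d_{02}-d_{03}) + 1.55.$$

The three terms interlock over four descriptors through six distinct
descriptor-pair products with well-separated coefficients. That design
is deliberate: a planted law whose terms share products (or whose
coefficients coincide) admits algebraically merged representations
inside the depth-2 expression space and is not identifiable from 44
noisy rows by any method — piloting the generator made this failure
mode explicit. The chosen law keeps each term individually visible to
marginal screening and makes the exact support the unique in-sample
optimum with high probability. Ground truth (law, noise-free signal,
Monte-Carlo noise ceiling $R^2 = V_{signal}/(V_{signal}+\sigma^2)$)
is returned with the data; `noise_sd_for_r2()` inverts the ceiling.

What passing these tests shows — and what it does not: the pipeline
recovers planted structure of the published model's complexity class
under realistic noise at the study's sample size, and its validation
protocols behave as designed. It does not show that real descriptor
catalogues contain an exact sparse law, nor that the particular
published coefficients transfer beyond their chemical domain.

## Electrochemical calibration

`dilution_series()` reproduces the sequential-addition schedule
(C_i = C_0 V_0 / (V_0 + i V_a); the study's schedule is 2.0 mL of
stock plus six 0.5 mL additions, giving factors 1, 0.8, 2/3, 4/7, 1/2,
4/9, 2/5). `fit_calibration()` fits the peak-current line by ordinary
least squares with a free intercept (baseline offsets exist in
practice; a through-origin flag is available) and enforces the strict
r² > 0.97 acceptance filter; rejected curves carry their computed r²
rather than being discarded silently. `solubility_from_cv()` inverts an
accepted line, scales by the aliquot dilution factor, warns outside the
calibrated current range and refuses non-positive implied
concentrations. The peak-current law itself
(`randles_sevcik_current()`) is implemented in the standard square-root
form $i_p = 2.69\times 10^5 n^{3/2} A C \sqrt{D v}$ (25 °C constant);
flattened reprints sometimes lose the square root, but only linearity
in C matters for the solubility pipeline, so the choice does not affect
any solubility output. Whether currents are baseline-corrected before
or after the dilution fit is an upstream instrument-software question;
the analysis assumes the supplied currents are already the quantity the
calibration should be linear in.

## Numerical choices and problem sizes

- Exhaustive subset search: bordered Cholesky with a 1e-10 relative
  pivot tolerance; numerically singular supports are skipped and
  counted. Exact RSS ties (1e-12 relative) are all surfaced and broken
  by complexity, then canonical string.
- Division guards: candidates with any non-finite value are dropped at
  expansion time; at evaluation time a non-finite intermediate is an
  error naming the term and row.
- The KSG estimator uses strict inequalities and the max-norm;
  estimates can be slightly negative under independence, which is
  harmless for ranking.
- Default problem sizes keep every stage interactive: 44 rows, 8
  primary descriptors, 6 screened, depth-2 expansion (~3 x 10^4
  candidates), screening pool ~500-700, exhaustive search over all
  supports of size ≤ 3. The recovery studies in the tests use 50
  seeded replicates; the repeated-CV protocol uses 5 folds x 5 seeds.
- V_m is accepted as a supplied column; whether it derives from a
  crystal unit cell or a computed molecular volume is not resolvable
  downstream and is documented as an input ambiguity.

## Known limitations

- Exact numeric reproduction of the published coefficient values
  requires the original curated tables in their original units; the
  package reproduces the *procedures* and verifies them on synthetic
  data with known ground truth.
- The descriptor catalogue covers the families the published model
  needs (plus their low-order siblings), not a full descriptor
  library.
- Aromaticity perception follows the OpenBabel model; see the quinoid
  caveat above.
- The symbolic search is exhaustive only over its screened pool; the
  screening heuristics are tuned for laws in the published model's
  complexity class (shallow product terms), which is the regime the
  parsimony objective targets.
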