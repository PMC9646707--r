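---
title: "Ranking clinical predictors with symbolic regression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking clinical predictors with symbolic regression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srgprank)
```

## The problem

Renal biopsy studies are small. A cohort of a few dozen patients with dozens
of mixed-type clinical, laboratory, and histological variables cannot support
a conventional multivariable model over all candidate predictors: with 15
positive outcomes, the events-per-variable rule caps a logistic model at
three terms, and correlation-based screening tends to pull in collinear
variables (body weight alongside body mass index) that inflate variance
without adding information.

`srgprank` implements a two-stage strategy for this setting, demonstrated on
glomerular hypertrophy — maximal glomerular diameter (MaxGD) at or above
242.3 µm — in an IgA nephropathy cohort of 43 subjects with 60 candidate
predictors:

1. **Data-driven screening.** Symbolic regression via genetic programming
   (SR via GP) evolves thousands of explicit formulas predicting the binary
   outcome under leave-one-out cross-validation (LOO-CV). A variable's
   importance — its *ML score* — is the frequency with which it is used by
   the "suitable" models on the accuracy/complexity trade-off, rescaled so
   all scores sum to 100.
2. **Model-driven validation.** The top-ranked variables (top-k by ML score
   versus top-k by absolute point-biserial correlation) are compared in
   ordinary multivariable logistic and linear models using McFadden's
   pseudo-R², the small-sample corrected AIC (AICc), the concordance
   statistic, and variance inflation factors (VIFs).

A permutation test run before the expensive evolutionary stage checks that
the data set carries any label signal at all, controlling the type-I risk of
interpreting importance ranks computed from noise.

## The evolutionary model

Candidate models are expression trees over the building blocks
`+`, `−`, `×`, `÷`, `√`, variable references, and numeric constants.
Division is protected (returns 1 when the denominator's magnitude is below
`1e-12`) and the square root acts on the absolute value, so every tree maps
finite inputs to finite outputs; results are additionally clamped at
magnitude `1e15` to guard against overflow in deep products.

**Fitness** is `1 − R²` of the tree output after the optimal affine
calibration `y ≈ a + b · tree(x)`, the linear-scaling device standard in
symbolic regression. The search therefore explores the *form* of the
relationship while the outer scale and offset — which carry no structural
information — are solved exactly instead of being evolved. This matters for
a dichotomous target: tree outputs live on the predictor scale, and without
calibration nearly every variable-bearing tree scores worse than the mean
constant, collapsing the population onto constants. The calibration pair is
stored with each model and applied at prediction time. Errors are clipped to
`[0, 1.5]`; a constant tree scores exactly 1 (nothing explained).

**Complexity** is visitation length — the sum over all nodes of the size of
the subtree rooted there. It grows strictly with any added node and
penalizes both size and depth, so a deep chain is costlier than a shallow
tree with the same node count. The method's original description leaves the
complexity metric unspecified; visitation length is the convention of the
commercial symbolic-regression engine it was demonstrated with.

**Evolution** uses tournament selection (size 3) on error plus a small
complexity penalty (`parsimony_coef`, default `1e-3` per complexity unit),
subtree crossover (rate 0.9), point/subtree mutation (rate 0.15), elitism of
one, and ramped initial depths of 2 to `max_depth` (default 6, with a slack
of 4 before offspring are rejected). Constants start uniform in [−5, 5] and
drift by Gaussian perturbation. None of these values are claims about the
original engine, whose hyperparameters are not documented; they are conventional
tree-GP settings, all overridable through `gp_config()`.

The **archive** of a run is its final generation. Under the default LOO-CV
design — 43 folds × 4 species × the best of 10 trials — the merged archive
holds tens of thousands of models, matching the scale at which the
usage-frequency statistic becomes stable. Frequencies from a *single* run
are unreliable: a converged population is one inbred lineage, and whatever
junk variables ride along in its best tree inherit its frequency. Pooling
independent folds and species is what turns usage frequency into a usable
importance measure, which is why the cross-validation structure is part of
the scoring procedure and not just of its validation.

## From archive to ranking

Suitable models are selected by iterated non-dominated sorting: the Pareto
front in (complexity, error) is peeled off and accumulated until the
selection reaches 8% of all generated models; if the last front overshoots
20%, it is truncated by ascending error. The band operationalizes
"approximately the top 10%, neither overfitting nor underfitting"; peeling
is the natural reading of "lower complexity and lower 1 − R²" when one
front alone is too small. Within the selection, `variable_frequencies()`
counts each model once per variable it uses syntactically (no algebraic
simplification is attempted — a variable that cancels analytically still
counts, which slightly favours variables entangled in complex expressions);
`ml_scores()` rescales frequencies to sum 100, preserving ranks exactly.
Variables used by more than 5% of the selected models (strict inequality)
are reported as *dominant*.

## The statistical validation layer

* **Logistic models** are fitted by maximum likelihood with Wald 95%
  intervals on the odds-ratio scale. McFadden's pseudo-R² is
  `1 − lnL_model / lnL_null`; AICc uses `k = terms + 1`; discrimination is
  the concordance statistic (midrank Mann–Whitney AUC of the fitted
  probabilities). Complete separation is flagged (`converged = FALSE`)
  rather than silently reported. The number of terms follows the
  five-events-per-variable rule: 15 positives admit 3 terms.
* **Linear models** for the continuous MaxGD report raw-scale R² and AICc
  (`k = terms + 2`, counting the residual variance), standardized β
  (`b · sd(x)/sd(y)`), t-ratios, and VIFs, plus the model-level VIF
  threshold `1 / (1 − R²)` used as a secondary collinearity rule. The
  linear validation uses eight terms: the continuous target frees the
  events-per-variable constraint.
* **Group comparisons** choose the unpaired (pooled-variance) t-test for
  normal-like continuous variables, the Mann–Whitney U test for variables
  the schema declares skewed, and the chi-square test for categorical
  variables, replaced by Fisher's exact test when any expected cell is
  below 5 or the table total is under 40 (a Cochran-style validity rule).
  The method's description does not fix a per-variable test rule, so the
  choice is declared in the schema rather than guessed from the data.
* **AICc** is `−2 lnL + 2k + 2k(k+1)/(n−k−1)` throughout.

The permutation test scores a cross-validated classifier (stratified 5-fold,
splits held fixed across permutations, the convention of the scikit-learn
procedure this stage mirrors) on the true labels and on B uniform label permutations, with the
add-one p-value `(1 + #{null ≥ observed}) / (B + 1)` — never zero, and
exact by construction. The originally reported accuracy of 0.84 came from an unnamed classifier;
the default here is a random forest, and the value is engine-dependent. A nearest-centroid classifier is provided for simulation
work where thousands of CV evaluations are needed; under the null the test's
size does not depend on the classifier.

In the nine-learner benchmark, "logistic regression" is ridge-penalized
(`glmnet`), since with 60 predictors and 42 training subjects the
unpenalized likelihood has no maximum; this also matches the L2-regularized
default of the common scikit-learn implementation of this baseline.
Lasso/Ridge penalties are chosen by internal cross-validation on the
training folds only. The original baselines were tuned by an automated hyperparameter
search; this package deliberately uses fixed conventional defaults instead, so benchmark numbers are comparable in structure, not in
decimals.

The seven-measure importance suite (ML score, ANOVA F, approximate MIC,
random-forest impurity and permutation importance, XGBoost split count and
cover) rescales every measure to sum 100 before averaging. The MIC is a
grid-search approximation with equal-frequency binning under the
`B = n^0.6` cell budget — adequate for ranking, not a reference MIC
implementation.

## The synthetic cohort generator

`synthetic_spec()` defaults describe the reference design: 43 subjects, 60
predictors, prevalence 15/43, five relevant variables (linear effects 1.0
and 0.8, a threshold effect 0.8, and a product interaction 0.7 contributing
both factors), one collinear pair (ρ = 0.6), 2% missing cells, and the
clinical-style type mix (one third binary, one sixth ordinal 0–3). A latent
score — planted effects on standardized Gaussian predictors plus unit
Gaussian noise — is mapped affinely onto a MaxGD analogue (SD matched to
the biopsy series' 30.8 µm) so that the 242.3 µm threshold cuts at the
target prevalence; the offset is calibrated against a 200,000-draw
Monte-Carlo reference of the score distribution, deterministic given the
seed, so prevalence converges as n grows rather than being forced exactly
in-sample. Each column draws from its own seed-derived stream: adding a
column never perturbs existing ones.

What the generator does *not* emulate: the real cohort's joint
distribution, its measurement scales, informative missingness, or outcome
mechanisms beyond the declared effect kinds. Passing tests on synthetic
cohorts therefore demonstrate that the machinery recovers planted structure
under this shape and noise level — not that any particular clinical
ranking is correct.

## Numerical and design choices

* Ties on the Pareto front (equal complexity and error) are all kept; ranks
  use competition ranking (ties share the minimum rank), with an
  alphabetical tiebreak for display order only.
* The trimmed-mean ensemble drops `floor(0.1 · m)` predictions from each
  tail by default; the method's description fixes no trimming proportion.
* Imputation (column median for continuous/percentage, mode for
  binary/ordinal) runs before GP and regression because both need complete
  design rows; the original engine's missing-data policy is unstated, and
  cohorts of this kind carry only a handful of missing cells. The
  missingness mask is retained, and univariable group tests use observed
  values only.
* The dichotomization threshold is inclusive (≥ 242.3 µm), and ordinal
  grades enter both GP and regression as numeric scores, so an ordinal
  variable occupies a single model term.
* Whether frequencies should be computed over the union of all species'
  archives or per species and averaged is genuinely open; this
  package uses the union, which the duplication-invariance
  property makes scale-free.

## Problem sizes used by the test suite

The package's own checks run at reduced, documented budgets chosen to keep
a full run on one CPU in the tens of minutes: signal-recovery uses LOO-CV
with one species, population 100 and 30 generations over 20 generator
seeds; the permutation test's size is estimated with the nearest-centroid
classifier at B = 99 over 200 null cohorts; the collinearity comparison
uses n = 100, p = 30, linear effects 1.0/0.6/0.5 with a ρ = 0.9 partner
on the strongest signal, and six species of population 100 × 20
generations (n is raised from 43 to stabilize the sample correlation
ordering the contrast depends on); the end-to-end smoke run uses population
50 × 10 generations × 1 trial. These are problem-size choices, not method
parameters: the method's defaults remain 500 × 50 × 4 species × 10 trials.

## Known limitations

* Usage frequency is a syntactic measure: it cannot distinguish a variable
  that drives a model from one that rides along in an unsimplified
  expression; the Pareto selection's parsimony pressure only mitigates
  this.
* With n = 43, single-seed rankings are noisy; the interaction and
  threshold effects planted by the default generator are recovered less
  reliably than the linear ones, which is the honest behaviour of the
  method at this sample size.
* The originally reported stochastic quantities (a usage frequency of 82.9
  for BMI, a benchmark AUC of 0.774, a permutation accuracy of 0.84) derive
  from a proprietary engine with undocumented hyperparameters and are not
  reproduction targets; the
  deterministic statistical layer (pseudo-R², AICc, C-statistic, VIF) is.
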