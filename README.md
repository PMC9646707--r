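# srgprank

Symbolic-regression variable ranking with conventional statistical
validation, for small clinical cohorts with many mixed-type predictors.

## What it does

Small biopsy studies — a few dozen subjects, dozens of candidate clinical,
laboratory, and histological variables — cannot support a conventional
multivariable model over all predictors, and correlation-based screening
tends to select collinear variables. `srgprank` implements a two-stage
method, demonstrated on glomerular hypertrophy (maximal glomerular diameter,
MaxGD ≥ 242.3 µm) in an IgA nephropathy cohort of 43 subjects and 60
predictors:

1. **Screen with machine learning.** Symbolic regression via genetic
   programming (SR via GP) evolves explicit formulas
   (`+ − × ÷ √`, variables, constants) predicting the dichotomized outcome
   under leave-one-out cross-validation (LOO-CV): several independent
   evolution species per fold, best of several consecutive trials by pooled
   AUC. From the merged model archive, the models on and near the Pareto
   front in (complexity, 1 − R²) — 8%–20% of all generated models — are
   selected, and each variable gets
   - **Frequency (GP)**: the percentage of selected models using it, and
   - **ML score (GP)**: frequencies rescaled to sum 100 over all variables,
   with *dominant* variables used by more than 5% of selected models.
2. **Validate with statistics.** The top-k variables by ML score are
   compared against the top-k by absolute point-biserial correlation in
   multivariable logistic models (McFadden pseudo-R², AICc, C-statistic,
   odds ratios with Wald CIs; k from the five-events-per-variable rule) and
   linear models for the continuous MaxGD (R², AICc, standardized β,
   variance inflation factors).

Around this core: a permutation test for data-set signal (add-one p-value,
fixed CV splits), a nine-learner classification benchmark (linear, Lasso,
Ridge, logistic, naive Bayes, SVM, random forest, XGBoost, SR via GP) under
one LOO split, a seven-measure variable-importance suite (each rescaled to
sum 100, plus their average), and a synthetic cohort generator that emulates
the reference design's shape — small n, mixed types, planted linear/threshold/
interaction signal, collinear pairs, sparse missingness — so the whole
pipeline is testable without any data download.

## Worked example

```r
library(srgprank)

g  <- generate_cohort(synthetic_spec(seed = 42))   # 43 x 60 study-shaped cohort
co <- impute_missing(g$cohort)
cv <- loo_cv_srgp(co, gp_config(population_size = 100, generations = 25, seed = 42),
                  species = 2, trials = 1)
tab <- importance_table(cv$archive, names(co$predictors))
print(tab, n = 8)
fit_logistic(co, tab$variable[1:3])
```

Output:

```
AUC 0.745 | accuracy 0.721 | precision 0.667 | recall 0.500 | F1 0.571
Variable importance from 702 suitable models (of 8600 generated)
 variable frequency ml_score freq_rank score_rank
      v03      99.3    33.62         1          1
      v04      47.3    16.02         2          2
      v01      24.2     8.20         3          3
      v08      21.1     7.14         4          4
      v19      19.9     6.75         5          5
      v56      13.2     4.49         6          6
      v60      12.0     4.05         7          7
      v46      11.3     3.81         8          8
  ...  52  more variables

Multivariable logistic model (43 subjects, 16 positives)
  pseudo-R2 = 0.57, AICc = 33.7, C-statistic = 0.94
         OR   2.5%    97.5%      p
v03 16.7443 2.3033 121.7269 0.0054
v04  3.4588 1.1498  10.4045 0.0272
v01  8.7368 1.4191  53.7881 0.0194
```

The first line is the pooled LOO-CV performance of the trimmed-mean
ensemble of each fold's Pareto front. The table ranks variables by how
often the 702 selected models use them: here the three planted signal
variables of this synthetic cohort (`v01`, `v03`, `v04` — ground truth
`g$ground_truth`) head the ranking, and the logistic model on the ML-top-3
then quantifies their association with the outcome on the familiar
odds-ratio scale (16 positives admit 3 terms at five events per variable).

A full run — permutation test, LOO-CV, importance suite, benchmark, and
both validations, written to CSV/JSON — is one call:

```r
report <- run_pipeline(pipeline_config(seed = 1), out_dir = "out")
```

or from a shell via the thin CLI (`inst/cli/srgprank.R`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/srgprank.R", package="srgprank"))')" \
    run --seed 1 --out out
```

To analyse a real cohort, point `load_cohort()` at a CSV with a header row
(one row per subject, empty cells = missing, continuous target column
`MaxGD`) plus an optional JSON schema declaring each variable's kind
(continuous / binary / ordinal grade / percentage) and whether it is skewed.

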