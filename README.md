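# vametrics

Robust validation metrics for verbal autopsy (VA) cause-of-death assignment.

## The problem

Verbal autopsy infers causes of death from structured interviews in settings
without medical certification. Validation studies compare a VA method's
assignments against gold-standard causes and have traditionally reported
sensitivity, specificity, Cohen's kappa, and errors in cause-specific
mortality fractions (CSMFs). Almost all of those numbers depend strongly on
the *cause composition* of the particular test dataset: evaluate the same
method on a test set with a different cause mix and most metrics move, often
enough to reverse the apparent ranking of two methods. `vametrics` implements
the metrics and the study design that fix this, for epidemiologists and
method developers running VA validation studies.

## The metrics

For a cause list of size `N`, with a confusion table of true (rows) versus
predicted (columns) causes:

* **Chance-corrected concordance**, per cause `j`:

  `CCC_j = (sens_j − 1/N) / (1 − 1/N)`

  where `sens_j` is the per-cause sensitivity (diagonal over row total). The
  `1/N` term is the concordance of an assigner with no information; CCC is 0
  at chance, 1 when perfect, negative below chance — and, for a method whose
  misclassification probabilities are fixed given the true cause, invariant
  to the test-set composition. The recommended overall summary is the
  **equal-weight average** of the `CCC_j`.

* **Partial chance-corrected concordance** for ranked or probabilistic
  assignments: with `C(k)` the fraction of deaths whose true cause is in the
  method's top `k` and `PC(k) = k/N` its chance level,

  `PCCC(k) = (C(k) − PC(k)) / (1 − PC(k))`   (undefined at `k = N`).

* **CSMF accuracy**, for population-level estimation:

  `1 − Σ_j |pred_j − true_j| / (2 (1 − min_j true_j))`

  total absolute CSMF error rescaled by its maximum over all possible
  predictions, so 1 is exact, 0 is the worst possible method, and values are
  comparable across cause lists of different sizes.

* **The protocol**: draw 100+ cause compositions from an uninformative
  Dirichlet (uniform on the simplex), resample the test data with
  replacement to each composition, and report the **median** CCC and CSMF
  accuracy across draws, monitoring the running median until additional
  draws change it by less than 0.5%.

Legacy metrics (sensitivity, specificity, Cohen's kappa, absolute/relative
CSMF errors, estimated-versus-true OLS diagnostics) are implemented too —
both because reports should include them for comparability and because the
package's simulator exists to show how unstable they are.

## Worked example

```r
library(vametrics)

path <- system.file("extdata", "example_deaths_synthetic.csv", package = "vametrics")
d <- read_va_csv(path)      # id, true_cause, predicted_cause
confusion_table(d)
#>   A B C
#> A 9 0 4
#> B 0 8 7
#> C 0 7 5
cause_metrics(confusion_table(d))
#> # A tibble: 3 × 5
#>   cause n_true sensitivity specificity   ccc
#> 1 A         13       0.692       1     0.538
#> 2 B         15       0.533       0.72  0.3
#> 3 C         12       0.417       0.607 0.125
overall_ccc(confusion_table(d))          # 0.321 — equal-weight average CCC
cohen_kappa(confusion_table(d))          # 0.325
csmf_accuracy(csmf_true(d), csmf_predicted(d))  # 0.857
```

The per-cause CCC says the method beats chance clearly for cause A
(0.54), modestly for B (0.30), and barely for C (0.13); the CSMF accuracy of
0.857 says the implied cause fractions are 86% of the way from the worst
possible composition estimate to a perfect one.

The bundled two-method simulation study (methods defined purely by their
misclassification matrices, `va_method("method1")` and `"method2"`) runs the
whole protocol:

```r
exp1 <- run_validation_experiment(c("method1", "method2"),
                                  n_draws = 500, seed = 42)
glance(exp1)
#>   method  n_draws median_csmf_accuracy mean_overall_ccc mean_kappa
#> 1 method1     500                0.761            0.325      0.258
#> 2 method2     500                0.803            0.375      0.305
compare_methods(exp1, "method1", "method2")
#>   cause wins_a wins_b  ties share_a
#> 1 A        161    339     0   0.322
#> 2 B        185    315     0   0.37
#> 3 C        239    261     0   0.478
```

Method 2 is better by construction (it differs only in a higher
probability of assigning true-A deaths to A), and the composition-stable
metrics say so: its overall CCC is 0.375 against 0.325. Yet on absolute
cause-C CSMF error, the inferior method 1 "wins" on 48% of single test
sets — a coin flip — which is why conclusions drawn from one test dataset
mislead. `summary_table()`, `experiment_regressions()`, and
`autoplot()` expose the full metric spreads, the estimated-versus-true OLS
diagnostics, and the kappa-versus-CSMF-error scatter.

A thin command-line wrapper over these functions is installed at
`inst/cli/vametrics.R` (subcommands `evaluate`, `resample-evaluate`,
`simulate`, `compare`, `reproduce-paper`).

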