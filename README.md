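# bayesdisc

Supervised discretization of continuous predictors for high-dimensional
biomedical data: a Bayesian score over discretizations, optimized exactly by
dynamic programming, alongside the classical Fayyad–Irani entropy/MDL
baseline, a discrete naive Bayes classifier, and a repeated cross-validation
harness with the evaluation measures this literature reports (accuracy,
multi-class AUC, robustness, selection stability, interval complexity).

## The problem

Many classifiers either require discrete inputs or perform better on them,
and in omics settings (gene-expression, proteomic spectra) discretization
doubles as feature selection: a predictor discretized to a single interval
carries no information about the phenotype and is dropped. Greedy
entropy-based discretization is fast but is not guaranteed to find the best
set of cut points. This package scores a candidate discretization of a
predictor *X* against a *J*-valued target *Z* with a Bayesian model and
finds the global optimum.

For a discretization with intervals *i = 1..W*, class counts *n_ij* and
interval totals *n_i*, the score is the (log of the) product of:

- **Structure prior** — a Poisson process with mean λ spread over the
  predictor's range in proportion to gap width. The probability of at least
  one cut point in the gap between adjacent distinct values *k* and *k+1*
  is `Prior(k) = 1 − exp(−λ·d(k,k+1)/d(1,n'))`; an interval's prior is the
  product of no-cut factors over its internal gaps times the cut factor at
  its right edge. λ is the expected number of cut points (default 0.5).
- **Marginal likelihood** — per interval, the Dirichlet-multinomial
  closed form `Γ(α_i)/Γ(α_i+n_i) · Π_j Γ(α_ij+n_ij)/Γ(α_ij)`, which with
  uniform hyperparameters `α_ij = 1` reduces to
  `(J−1)!/(n_i+J−1)! · Π_j n_ij!`.

Both components decompose over intervals, so the optimum over all
`2^(n'−1)` cut patterns is found by dynamic programming over prefixes of
the sorted distinct values in `O(J·n'²)` time, entirely in log space. An
exhaustive-enumeration oracle (`brute_force_discretize()`) certifies
optimality in the test suite.

## Worked example

The six-instance expression/phenotype dataset used throughout the
documentation has three low values of class 0 and three high values of
class 1:

```r
library(bayesdisc)
d <- toy_expression_data()
fit <- discretize(d, target = "phenotype", method = "ebd")
fit$models$expression
#> <discretization> method = ebd, 2 interval(s)
#>   cut points: 2.65
#>   log score: -4.102019
```

The optimal discretization places a single cut at 2.65, the midpoint of the
wide gap between 1.6 and 3.7; the log score −4.1020 is the sum of the
no-cut prior over the four narrow gaps (−0.1379), the cut prior at the wide
gap (−1.1916), and twice the pure-interval marginal likelihood
`log(0.25)` (−2.7726). Applying the model codes each value by its interval
(values at or above the cut go up):

```r
apply_discretization(fit, d)
#> # A tibble: 6 × 2
#>   expression phenotype
#> 1          0 0
#> ...
#> 6          1 1
```

A full evaluation on synthetic data with known structure — 2 informative
and 8 noise predictors, 120 instances:

```r
sim <- generate_dataset(synthetic_spec(n = 120, n_informative = 2,
                                       n_noise = 8), seed = 42)
cv <- run_cv(sim$data, "class", method = "ebd", folds = 5, reps = 2,
             seed = 42)
glance(cv)
#>   method n_pairs accuracy   auc robustness stability fraction_trivial
#> 1 ebd         10    0.921 0.982       98.5       0.8              0.8
```

Mean test accuracy 0.92 and AUC 0.98 come from the two informative
variables; `fraction_trivial` 0.8 says the noise predictors were (on
average) discretized to a single interval and filtered out, and stability
0.8 is the chance-corrected average overlap of the selected-variable sets
across fold pairs. `run_cv(..., method = "fi")` runs the entropy/MDL
baseline on the identical fold plan, and `compare_cv()` applies the paired
Wilcoxon signed-rank test per measure.

A thin command-line wrapper over these functions is at `exec/bayesdisc`
(subcommands `discretize`, `transform`, `evaluate`, `simulate`; flags can
also be given via a YAML `--config`).

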