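# ml1dif

Anchor-free differential item functioning (DIF) analysis under a MIMIC
two-parameter logistic (2PL) item response model, with minimal-L1
identification, parametric-bootstrap inference, and false discovery rate
control.

## The problem

DIF analysis asks whether a test or questionnaire item behaves differently
across two groups of respondents *after* conditioning on the latent trait
being measured: for item $j$ with discrimination $a_j$, easiness $d_j$ and
DIF effect $\gamma_j$,

$$P(Y_{ij}=1 \mid \theta_i, x_i) = \mathrm{logit}^{-1}(a_j\theta_i + d_j + \gamma_j x_i),
\qquad \theta_i \mid x_i \sim N(\beta x_i,\ 1 + (\sigma^2-1)x_i),$$

with $x_i \in \{0,1\}$ the group label and $e^{\gamma_j}$ the between-group
odds ratio at a fixed trait level. The model is identified only up to a
location shift $\beta \mapsto \beta + c$, $\gamma_j \mapsto \gamma_j - a_j c$.
Classical methods break the tie with *anchor items* assumed DIF-free — an
assumption that silently biases everything when wrong.

`ml1dif` instead selects, within each equivalence class, the representative
whose DIF vector minimises $h(c) = \sum_j |\gamma_j - a_j c|$ — a weighted-
median least-absolute-deviations problem. Estimation is a two-stage
procedure (constrained marginal MLE with Gauss–Hermite quadrature, then L1
re-identification); inference pushes normal perturbations of the stage-1
estimate through the re-identification map to approximate the law of
$\hat\gamma_j - \gamma_j^*$, yielding per-item confidence intervals and
P-values without any anchor, with Benjamini–Hochberg FDR control for
detection. It is aimed at psychometricians and applied researchers in
educational, psychological and health measurement who need defensible
item-level inference when no trusted anchors exist.

## Worked example

Simulate a 25-item study from the packaged design (14 of 25 items with
DIF, focal group $N(0.5, 0.5^2)$), fit, and test every item:

```r
library(ml1dif)

truth <- sim_params(d_regime = "small", dif_size = "large", dif_prop = "high")
dat   <- sim_responses(truth, n = 1000, seed = 1)

fit <- fit_ml1(dat)
glance(fit)
#> # A tibble: 1 × 8
#>    beta sigma2  shift  loglik converged n_iter n_obs n_items
#>   <dbl>  <dbl>  <dbl>   <dbl> <lgl>      <int> <int>   <int>
#> 1 0.497  0.260 0.0850 -13241. TRUE          68  1000      25

inf <- dif_infer(fit, M = 10000, level = 0.95, alpha = 0.05, seed = 2)
dplyr::filter(inf, bh_reject)
#> # A tibble: 14 × 6
#>    item  gamma_hat  ci_lo  ci_hi  p_value bh_reject
#>    <chr>     <dbl>  <dbl>  <dbl>    <dbl> <lgl>
#>  1 y12      -1.42  -1.77  -1.05  0.000200 TRUE
#>  2 y13       0.991  0.630  1.36  0.000200 TRUE
#>  3 y14      -1.45  -1.83  -1.07  0.000200 TRUE
#>  4 y15       1.79   1.23   2.38  0.000200 TRUE
#>  5 y16      -1.28  -1.64  -0.924 0.000200 TRUE
#>  6 y17       1.16   0.795  1.54  0.000200 TRUE
#>  7 y18      -1.22  -1.56  -0.872 0.000200 TRUE
#>  8 y19       1.50   1.15   1.88  0.000200 TRUE
#>  9 y20       0.833  0.351  1.34  0.00120  TRUE
#> 10 y21      -1.23  -1.59  -0.852 0.000200 TRUE
#> 11 y22       1.09   0.745  1.44  0.000200 TRUE
#> 12 y23      -1.14  -1.48  -0.781 0.000200 TRUE
#> 13 y24       1.56   1.19   1.95  0.000200 TRUE
#> 14 y25       1.55   1.05   2.09  0.000200 TRUE
```

`glance()` reports the focal-group latent mean and variance (truth: 0.5,
0.25), the minimal-L1 re-identification shift applied to the constrained
fit (near zero when, as here, the generating DIF vector already has
minimal L1 norm), and the marginal log-likelihood. The inference table
carries one row per item — estimate, basic-bootstrap interval, Monte-Carlo
P-value, B-H decision — and `autoplot(inf)` draws it as a forest plot. In
this run the procedure detects exactly the 14 truly DIF items (y12–y25,
true effects ±1.2 to ±1.4) with no false positive; the floor P-value
0.0002 is the add-one bound 2/(M+1).

Convenience entry points: `lrt_dif()` / `wald_dif()` (anchored
comparators), `check_prop1()` / `check_cor1()` (identification-condition
checks), `run_study()` (replication engine computing MSE, FDR, coverage
and ROC/AUC), and a thin command-line wrapper in
`inst/scripts/ml1dif.R` with `fit`, `infer`, `lrt`, `simulate` and
`benchmark` subcommands.

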