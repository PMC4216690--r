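# burr3dgos

Estimation of the two shape parameters of the **Burr type III** lifetime
distribution from **dual generalized order statistics** (dual GOS) — the
unified model of decreasingly ordered data whose special cases include
lower record values (`m = -1, q = 1`) and reversed order statistics
(`m = 0, q = 1`).

The Burr III distribution on $(0,\infty)$ has
$$F(x) = (1+x^{-c})^{-k},\qquad f(x) = c\,k\,x^{-(c+1)}(1+x^{-c})^{-(k+1)},$$
with shapes $c, k > 0$. Given a dual-GOS sample $x_1 > \dots > x_n$ with
scheme constants $\gamma_r = q + n - r + (n-r)m$, the package provides:

* **Maximum likelihood**: $k$ has a closed form given $c$; $c$ solves a
  scalar profile score equation located by a bracketed, noise-aware root
  search. Samples for which no interior maximum exists (a ~25% event for
  records of BurrIII with $k = 2$) are flagged rather than mis-fitted.
* **Exact expected Fisher information** $Q^*$ of $(k,c)$ via rapidly
  convergent series for the dual-GOS expectations
  $E(\upsilon_i)$ and $E(\upsilon_i\omega_i\log X_i)$, with an
  independent adaptive-quadrature oracle, and the asymptotic
  variance–covariance matrix $Q^{*-1}$.
* **Bayes estimation** under squared error loss with independent gamma
  priors: Lindley's two-parameter approximation evaluated at the MLE
  ($\hat k_B = \hat k + \psi_1$, $\hat c_B = \hat c + \psi_2$), plus
  exact posterior means by two-dimensional Gauss–Legendre quadrature as
  a slow exact mode and oracle.
* A **Monte Carlo harness** (`burr3_study()`) measuring estimator RMSE
  across sample sizes, with per-replicate reproducible substreams and
  explicit accounting of replicates whose MLE does not exist.
* A **command line** (`inst/scripts/burr3dgos.R`, subcommands `fit`,
  `fisher`, `sample`, `simulate`) over the same functions.

See the vignette `vignettes/burr3-dual-gos-methods.Rmd` for the model,
the numerics, and the design decisions.

## Worked example

Eight lower records from BurrIII(c = 3, k = 2), fitted by ML and by
Lindley-approximated Bayes under the prior
$k \sim \Gamma(3, \text{scale } 2)$, $c \sim \Gamma(2, \text{scale } 3)$:

```r
library(burr3dgos)
set.seed(7)
x <- rdgos_records(8, 3, 2)
round(as.numeric(x), 4)
#> [1] 5.6340 1.1893 0.6473 0.3908 0.3059 0.2939 0.2447 0.2435

summary(burr3_fit(x, prior = gamma_prior(3, 2, 2, 3)))
#> Burr III fit from dual GOS (n = 8, m = -1, q = 1)
#>   c_hat = 1.5309   k_hat = 3.5220   (log-likelihood 5.4913)
#>   Lindley Bayes: c_B = 1.7151   k_B = 4.0639
#>   asympt. std. errors: se(k) = 1.7328, se(c) = 0.6134
#>   score norm at optimum: 5.70e-12 (iterations 5)
```

`c_hat`, `k_hat` maximize the dual-GOS likelihood of this record
sequence; the Bayes estimates shrink toward the prior (prior means are 6
for both parameters); the standard errors come from inverting the
observed information. Eight records carry little information about `c`,
which the expected Fisher information quantifies in advance of any data:

```r
Q <- burr3_expected_fisher(dgos_scheme(8, -1, 1), 3, 2)
asymptotic_covariance(Q)[c("var_k", "var_c")]
#> $var_k
#> [1] 1.644017
#> $var_c
#> [1] 2.765559
```

The exact posterior means (2-D quadrature) agree with the Lindley
approximation here to about 5% for `k` and to print accuracy for `c`:

```r
pm <- posterior_mean_quadrature(x, gamma_prior(3, 2, 2, 3))
c(k = pm$k_mean, c = pm$c_mean)
#>        k        c
#> 3.856232 1.715137
```

A small recovery study (200 replicates; the full design uses 1000):

```r
burr3_study(3, 2, n_values = c(4, 6), reps = 200,
            priors = list(gamma_prior(3, 2, 2, 3)), seed = 1)
#> Monte Carlo recovery study: Burr III (c = 3, k = 2), scheme m = -1, q = 1, 200 replicates
#>   prior 1: (alpha, beta, gamma, delta) = (3, 2, 2, 3)
#>  n     c_M    k_M     c_B1    k_B1
#>  4 11.0157 4.2354 963.3605 35.4333
#>  6  5.3184 1.3350 511.6473  2.4701
#> non-converged MLE replicates (excluded): n=4: 54, n=6: 48
#> flagged non-positive Bayes estimates (included): n=4: 29, n=6: 22
```

The RMSE columns are dominated by the heavy upper tail of the
small-sample estimators (see the vignette for why that is intrinsic to
this design); the exclusion and flag counts make the accounting
explicit.

## Command line

```sh
Rscript inst/scripts/burr3dgos.R fisher --n 10 --m -1 --q 1 --c 3 --k 2
Rscript inst/scripts/burr3dgos.R sample --n 4 --m -1 --q 1 --c 3 --k 2 \
    --reps 100 --seed 42 --output records.csv
Rscript inst/scripts/burr3dgos.R fit --input records.csv \
    --alpha 3 --beta 2 --gamma 2 --delta 3
```

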