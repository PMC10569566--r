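# chisqcr

Minimum chi-square estimation of closed-population size from
multi-occasion capture-recapture data under heterogeneous capture
probabilities — for wildlife statisticians and quantitative ecologists
who have sighting-frequency data (how many individuals were seen exactly
once, twice, ...) and need a population-size estimate with interval
estimation and a goodness-of-fit check of the heterogeneity model.

## The model and the estimators

Individual $i$ in a closed population of unknown size $N$ is sighted
$X_i \mid p_i \sim \mathrm{Binomial}(T, p_i)$ times over $T$ occasions,
with $p_i \sim g(p;\theta)$ (homogeneous, beta, or logit-normal).  The
observable frequencies $f^c = (f_1,\dots,f_T)$ omit the $f_0$ individuals
never seen.  With $\pi_g(x) = \int_0^1 \binom{T}{x} p^x(1-p)^{T-x}
g(p;\theta)\,dp$, the package fits $(N, \theta)$ by

* **full likelihood** — maximize the
  $\mathrm{Multinomial}_{T+1}(N, \pi_g)$ likelihood jointly over integer
  $N$ and $\theta$;
* **conditional likelihood** — maximize $[f^c \mid n]$ over $\theta$,
  then the Horvitz–Thompson estimator
  $\hat N = n/\{1-\hat\pi_g(0)\}$;
* **minimum chi-square** — minimize Pearson's
  $X^2(N,\theta) = \sum_{i=0}^{C-1} (O_i - N q_i(\theta))^2 / N q_i(\theta)$
  over a $C$-cell pooled table whose first cell is the unobserved class
  $O_0 = N - n$.  This also yields consonance (test-inversion) sets for
  $N$ and $\theta$ and a conservative $\chi^2_{C-1-d}$ goodness-of-fit
  test of $g$.

Percentile bootstrap confidence intervals (parametric, or resampling of
individuals) combine with any of the three estimators, and simulation
harnesses reproduce the chi-square-calibration, coverage, and bias
studies at configurable scale.

## Worked example: wintering white storks

1684 white storks were banded over 80 daily occasions in southwestern
Spain; aggregating days into ten 8-day occasions gives the bundled
frequency vector:

```r
library(chisqcr)
fv <- stork_frequencies()
fv
#> Sighting frequencies over T = 10 occasions (n = 1684 individuals observed)
#>  x=1  x=2  x=3  x=4  x=5  x=6  x=7  x=8  x=9 x=10
#> 1021  420  166   50   20    6    1    0    0    0

fit_report(fv, "beta", C_values = 4:7)
#>                  method  C N_hat p_hat    X2 df   p_value
#>         full_likelihood NA  3970    NA    NA NA        NA
#>  conditional_likelihood NA  3990    NA    NA NA        NA
#>               min_chisq  4  4033    NA 0.000  1 0.9999197
#>               min_chisq  5  3852    NA 0.226  2 0.8930936
#>               min_chisq  6  4046    NA 1.192  3 0.7549729
#>               min_chisq  7  4036    NA 1.199  4 0.8782202
```

All three estimators agree that, under beta-distributed capture
probabilities, about 4000 storks wintered in the area — matching the
independent census figure — and the near-1 goodness-of-fit p-values say
the beta model is consonant with the data at every pooling.  (A
homogeneous fit, by contrast, is rejected outright: `fit_report(fv,
"homogeneous")` gives $X^2$ between 29 and 111 with p-values below
$10^{-4}$, evidence that capture heterogeneity is real.)  Interval
estimates:

```r
consonance_set_N(pool_tail(fv, 6), "beta", level = 0.95)
#> 95% consonance set for the population size (df = 3)
#>   accepted N: [3151, 6514]  (N_hat = 4046, X^2 = 1.192 <= 7.815)

fit6 <- fit_min_chisq(pool_tail(fv, 6), "beta")
parametric_bootstrap(fit6, m = 1000, seed = 1)
#> Parametric bootstrap (min_chisq estimator, C = 6), m = 1000 replicates
#>   95% CI for N: [3243, 5427]  (median N* = 4040, width = 2184)
```

The consonance set is the honest interval when the chi-square
approximation is accurate (large $N$); at this population size the
bootstrap interval is the recommended one.  A logit-normal fit
(`fit_report(fv, "logit_normal")`) estimates roughly 3350–3500 storks
with equally good fit — an instance of the nonidentifiability of $N$
under unknown heterogeneity, discussed in the vignette.

## Command line

```sh
inst/cli/chisqcr fit --input stork --family beta --C 4,5,6,7 --seed 1
inst/cli/chisqcr bootstrap --family beta --C 6 --scheme individuals --m 1000
```

Subcommands: `fit`, `gof`, `consonance`, `bootstrap`, `simulate`; all
accept `--seed`, `--out`, and `--config` (flat `key: value` file).

## Acceptance script

`scripts/acceptance.R` recomputes, from the bundled stork frequencies and
the installed package, the headline estimates of the three-family
analysis — the full-likelihood, conditional-likelihood, and minimum
chi-square population sizes and two minimized chi-square statistics —
and writes them as a flat JSON record:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — capture models, pooling, likelihood and minimum chi-square
  estimators, consonance sets, bootstrap, simulation harnesses, CSV I/O.
* `inst/extdata/stork_frequencies.csv` — the worked-example data.
* `vignettes/minimum-chisq-abundance.Rmd` — model, assumptions,
  numerical choices, and limitations.
* `tests/testthat/` — unit, property, and acceptance suites.
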