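# selbias

Selection bias in multi-arm randomized trials with permuted block designs.

## The problem

Open-label (or imperfectly masked) randomized clinical trials are vulnerable
to *selection bias*: an investigator who can reconstruct past treatment
assignments may guess the next assignment and — consciously or not — enrol a
patient with better or worse prognosis accordingly. The permuted block
design (PBD), the most common allocation procedure in multi-arm trials,
forces balance at the end of every block and is therefore particularly
predictable. `selbias` quantifies what this does to the global F-test of a
`K`-arm parallel-group trial, and provides a bias-adjusted analysis.

The package is aimed at biostatisticians evaluating randomization procedures
at the trial planning stage: given a design (`K` arms, blocks of length
`cK`, `M` blocks, `N = cKM` patients) and a model of the investigator's
guessing behaviour, it computes — exactly, per randomization sequence — the
conditional probability that a nominal-level F-test falsely rejects, and the
proportion of sequences for which that probability is inflated.

## The model

Outcomes follow the shifted one-way ANOVA model

```
y = X beta + eta * b + eps,      eps ~ N(0, sigma^2 I),
```

where `X` is the allocation design matrix, `b` in `{-1, 0, +1}^N` is a
*bias vector* derived from the history of group counts `N_k(i-1)` by a
*biasing policy* (two generalizations of the Blackwell–Hodges convergence
guessing strategy to `K > 2` arms and a favoured arm set `F`), and `eta` is
the selection effect in residual-SD units. Under a true null
(`beta_1 = ... = beta_K`), the F statistic then follows a **doubly
noncentral F distribution** with `K-1` and `N-K` degrees of freedom and
noncentrality parameters

```
lambda1 = eta^2 [ (1/n) sum_k (b' x_k)^2 - (1/N) (b' 1)^2 ],   n = N/K,
lambda2 = eta^2 [ b'b - (1/n) sum_k (b' x_k)^2 ],
```

so the exact conditional type I error probability of a sequence `X` is

```
r(X) = P( F''_{K-1, N-K}(lambda1, lambda2) > F^{-1}_{K-1, N-K, 1-alpha} ),
```

evaluated via a double-Poisson mixture of regularized incomplete beta
functions with a certified truncation bound. The procedure-level metric is

```
p_infl = sum_X P(X) * 1{ r(X) > alpha },
```

the probability-weighted proportion of sequences whose type I error is
inflated — computed exactly by enumeration for small designs, by Monte
Carlo otherwise. A bias-adjusted F-test (group effect tested given `b` as a
covariate in the augmented model `[x_1 .. x_K, b]`) restores the size and
yields a maximum-likelihood estimate of `eta`.

## Worked example

```r
library(selbias)

design <- pbd_design(K = 3, c = 1, M = 4)        # PBD(K), N = 12
seq1   <- generate_pbd(design, seed = 2024)
#> 2 3 1 2 1 3 2 1 3 1 2 3
pol <- biasing_policy("I", favoured = 1, K = 3)  # strict policy, F = {1}
b   <- bias_vector(seq1, design, pol)
#> 0 0 1 0 0 0 0 0 0 0 -1 0
noncentrality(seq1, design, b, eta = 0.5)
#> lambda1 = 0.125, lambda2 = 0.375
rejection_probability(seq1, design, b, eta = 0.5)
#> 0.0520899
```

For this sequence a modest selection effect (`eta = 0.5` residual SDs)
lifts the true type I error of the nominal 5% test to 5.21%. Across the
whole design the picture is worse:

```r
cfg <- scenario_config(K = 3, m = 4, scheme = "PBD_K", rho = 0.25,
                       replicates = 10000, seed = 1)
assess_monte_carlo(cfg)
#> Selection-bias assessment (monte_carlo, 10000 sequences)
#>   proportion with r(X) > 0.05: 0.8563
#>   r(X): min = 0.0494, q1 = 0.0506, median = 0.0517, mean = 0.0523,
#>         q3 = 0.0530, max = 0.0606
```

With a selection effect only a quarter of the detectable effect size
(`eta = 0.25 * f`, `f = cohens_f(3, 4) = 1.069`), 85.6% of all
block-length-3 sequences have an inflated type I error. The adjusted test
repairs the size at a power cost that depends on the block length:

```r
power_simulation(3, 16, rho = c(0, 1), replicates = 5000, seed = 3)
#>        scheme rho       test  power   # excerpt
#>         PBD_K   1 unadjusted 0.9276   # power inflated by the bias
#>         PBD_K   1   adjusted 0.6478   # size-correct, costly with tiny blocks
#>         PBD_N   1 unadjusted 0.8564
#>         PBD_N   1   adjusted 0.7648   # mild cost with one big block
```

## Command line

```sh
inst/exec/selbias biasvec --seq inst/extdata/example_sequence.txt --K 3 \
    --policy I --favoured 1
inst/exec/selbias assess --scenarios inst/extdata/example_scenarios.csv --out results.csv
inst/exec/selbias power --K 3 --m 16 --rho 0,0.5,1,2 --seed 7 --out power.csv
```

Exit codes: 0 success, 2 usage error, 1 numerical failure. A JSON
`--config` file may supply any flag; explicit flags win. Every `--out` file
is accompanied by a `.manifest.json` recording the configuration and seed.

## Documentation

See `vignettes/selection-bias.Rmd` for the model, the numerical choices
(series truncation, strict inflation indicator, degenerate cases) and the
design decisions behind the defaults.
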