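---
title: "Quantifying selection bias in multi-arm permuted-block trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying selection bias in multi-arm permuted-block trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selbias)
```

## The model and its assumptions

`selbias` studies a `K`-arm parallel-group trial with a continuous,
normally distributed outcome and a balanced permuted block design: `M`
blocks of length `cK`, with exactly `c` patients per arm in every block and
total sample size `N = cKM`. Two assumptions drive everything:

1. **Unmasking.** Before patient `i` is enrolled, the investigator knows
   the past allocation counts `N_k(i-1)` for every arm (full unmasking —
   the worst case; partial knowledge would only weaken the effects shown
   here).
2. **Balance.** Each arm receives `N/K` patients in expectation; for the
   permuted block design this holds exactly by construction.

Selection bias enters as a shift in the outcome model,
`y = X beta + eta * b + eps`. The investigator enrols a patient with
better, neutral, or worse expected prognosis (`b_i = +1, 0, -1`) depending
on which arm they guess will come next; `eta >= 0` is the magnitude of the
induced shift, measured in units of the residual standard deviation. We fix
`sigma = 1` throughout: the F statistic and all derived quantities are
scale invariant, so `eta` is simply a standardized effect.

## Biasing policies

The classical two-arm convergence strategy (guess the arm allocated less
often so far) generalizes non-uniquely when `K > 2` and the investigator
favours a *set* of arms `F`. Two natural readings are implemented:

* **Policy I** (strict): bias only when the guess is unambiguous —
  `b_i = +1` iff *every* favoured arm trails *every* unfavoured arm
  (`max_F N_j < min_FC N_k`), `b_i = -1` in the mirrored situation, `0` on
  any tie. Ties are frequent with many arms, so this policy biases
  relatively few patients.
* **Policy II**: bias as soon as *some* favoured arm trails all unfavoured
  arms (`min_F < min_FC` gives `+1`, `min_F > min_FC` gives `-1`).

Both reduce to the convergence strategy at `K = 2`, and wherever Policy I
is nonzero Policy II agrees, which is the precise sense in which Policy I
is "stricter". Ties always give `b_i = 0`: we model a deterministic
investigator, not a probabilistic guesser.

One genuine ambiguity: for Policy II's `-1` branch, the comparator could be
read as `min_F > min_FC` (the symmetric counterpart of the `+1` branch) or
as the stricter `min_F > max_FC`. No worked example discriminates between
them. The symmetric reading is the default because it makes the policy a
single three-way comparison of `min_F` against `min_FC`; the stricter
reading is available as `biasing_policy(..., variant = "strict_minus")`,
and a property test confirms the two differ only by dropping some `-1`
entries.

## Exact conditional type I error

Under a true null, the one-way ANOVA F statistic of the misspecified
(unadjusted) analysis follows a doubly noncentral F distribution whose
noncentrality parameters are quadratic forms of `b` in the between-group
and residual projection matrices (see `?noncentrality`; the identity
`lambda1 + lambda2 = eta^2 (b'b - (b'1)^2/N)` is tested on random designs
against explicit-matrix evaluation). The conditional type I error of a
sequence is the upper tail of that law at the central-F critical value
(`?rejection_probability`).

Numerical choices:

* **Series truncation.** The CDF is the double Poisson mixture of
  regularized incomplete beta functions. We truncate each Poisson index at
  the quantile leaving at most `tol/4` tail mass and verify that the total
  neglected weight is below `tol` (default `1e-10`); since every beta
  factor is at most 1, this bounds the absolute CDF error by `tol`. The
  alternative of spiralling outward from the modal index pair would save
  terms only when the `lambda` are large, which they never are here
  (`lambda <= eta^2 * N`, and `eta` is a fraction of a detectable effect
  size), so the simpler quantile truncation is used. Exceeding `max_terms`
  raises an error rather than returning a silently truncated value.
* **The central case is exact.** When `lambda1 = lambda2 = 0` — both when
  `eta = 0` and when a sequence's bias vector is identically zero —
  `r(X) = alpha` *analytically*, and the code returns `alpha` rather than
  `1 - pdnf(qf(1 - alpha, ...))`, whose ~1e-12 inversion roundoff would
  land on the wrong side of the strict inflation indicator. This matters
  materially: for the single-block design a few percent of sequences have
  an all-zero bias vector, and miscounting them inflates `p_infl` by a
  similar amount.
* **Strictness.** "Inflated" means `r(X) > alpha` with no further slack.
  Sequences with `r(X) = alpha` exactly (the central case) count as not
  inflated; sequences with `r(X)` below `alpha` (bias can also *deflate*
  the size) likewise.
* **One-sidedness.** The rejection region is `S_F >= q`; the statistic is
  a ratio of nonnegative quadratic forms, so no absolute value is needed.

## Assessing a randomization procedure

`assess_exact()` enumerates the sequence space (refusing above a cap,
default `1e6` — exhaustive evaluation is meant for validation on toy
designs) and computes `p_infl = sum_X P(X) 1{r(X) > alpha}` exactly; all
sequences of a permuted block design are equally likely, with probability
`((c!)^K/(cK)!)^M`. `assess_monte_carlo()` replaces the enumeration with
`r` sampled sequences (default 10,000, matching common practice for this
kind of evaluation, at which the binomial standard error of `p_infl` is at
most 0.005).

`eta_invariance_report()` examines how `p_infl` responds to the bias
magnitude. By default it reuses one sequence sample across the `rho` grid
— only the scaling `eta^2` of the noncentralities changes — which isolates
the magnitude effect from sampling noise; independent redraws are
available (`shared_sequences = FALSE`) and agree within Monte Carlo noise.
The near-invariance itself is a property of the stated world, not an exact
identity: whether a given sequence crosses the `alpha` threshold can in
principle depend on `eta`, and the spread is small but not zero.

### What the generator emulates — and what it does not

The synthetic world is exactly the stated model: normal outcomes, a
deterministic fully informed investigator, equal allocation, complete final
block, a single centre, no covariates, no time trends. A green assessment
establishes that the *distribution theory and its implementation* are
correct under this model. It does not establish anything about real trials
with partial unmasking, probabilistic guessing, non-normal outcomes,
stratification, or chronological bias — all out of scope here.

## The bias-adjusted test

Fitting the correctly specified model `y = [x_1 .. x_K, b] (beta, eta)' +
eps` restores an i.i.d. error term. The group test is the
extra-sum-of-squares F comparing the full model (group indicators plus
`b`) against the reduced model (intercept plus `b`), on `K - 1` and
`N - K - 1` degrees of freedom. In this one-factor-plus-covariate setting
that is identical to the type III group test for every contrast coding, so
the coding-free formulation is used. The coefficient of `b` is the
maximum-likelihood estimate of the selection effect; its recovery of the
truth is verified by simulation. If `b` lies in the span of the group
indicators (all-zero or constant `b`, or `b` proportional to an arm
indicator) the covariate adds nothing or breaks the rank; the
implementation falls back to the unadjusted test and flags the result
(`degenerate = TRUE`).

For power studies (`power_simulation()`) a mean vector is needed. The
published effect-size label for this setting follows a convention we could
not reconcile with the standard noncentrality `lambda = f^2 N` (its printed
value would imply near-certain rejection), so absolute published power
curves are not desk-reproducible; instead the default mean
vector is `mu = (0, ..., 0, Delta)` with `Delta` calibrated by
`delta_for_power()` so that the no-bias design power is 80%, and the power
study is anchored at that `rho = 0` sanity case. Two further choices:

* The default biasing policy in the power study favours arm `K` — the arm
  carrying the treatment effect. This is the canonical story (the
  investigator wants the experimental arm to look good) and yields the
  expected qualitative picture: unadjusted power inflating with `rho`,
  adjusted power flat. Favouring an arm *without* an effect mainly inflates
  the denominator noncentrality and can deflate the unadjusted power — a
  real phenomenon, but not the headline scenario. (Procedure assessment via
  `p_infl` is unaffected by this choice: under the null all arms are
  exchangeable.)
* Common random numbers are used across `rho` within a scheme, so the
  adjusted test's exact invariance to shifts along `b` shows up as exactly
  constant power across `rho`, which is the cleanest form of the flatness
  property.

## Effect-size calibration

`cohens_f(K, m, alpha, power)` inverts the singly noncentral F power
function under the standard convention `lambda = f^2 N` (bracketing plus
`uniroot` at tolerance `1e-12`; the round trip reproduces the target power
to below `1e-8`). Because the published effect-size convention is
ambiguous (see above), scenario configurations also accept `eta` directly;
the inflation-proportion results are insensitive to this choice, as the
`rho`-invariance analysis shows.

## Degenerate inputs and tie-breaking summary

* Invalid design parameters (`K < 2`, `c < 1`, `M < 1`, non-integers) and
  block-imbalanced sequences are rejected, never repaired; incomplete
  final blocks are outside the model.
* `F` must be a non-empty proper subset of `1..K`.
* Ties in the guessing comparisons always give `b_i = 0`; `b_1 = 0`
  always.
* Enumeration above the cap, and mixture series exceeding the term cap,
  raise errors instead of degrading silently.
* Constant outcome vectors give `S_F = 0`, `p = 1`.

## Known limitations

* Only equal allocation, non-adaptive, unstratified permuted block designs;
  the distribution theory extends to any fixed randomization procedure, but
  no other generator is shipped.
* Only two biasing policies, both deterministic; a learning or
  probabilistic investigator is not modelled.
* The doubly noncentral F quantile function and density are not provided
  (not needed for `r(X)`).
* Normal outcomes only; no covariates beyond the bias term.
* The `p_infl` metric summarizes the type I error only; bias of the
  treatment-effect estimates is not computed.
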