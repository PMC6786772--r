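---
title: "Model-based total prediction under non-ignorable non-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based total prediction under non-ignorable non-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpred)
```

## The problem

In the prediction (model-based) view of survey sampling, the `N` population
outcomes are realizations of a superpopulation model linking the outcome to
covariates known for every unit; estimating the total `T_y = W'y` means
predicting the unobserved outcomes from a fitted model. Unit non-response
breaks this cleanly when it is *non-ignorable*: the probability of responding
depends on the outcome itself, so the responding and non-responding parts of
the population follow **different** models, and no fit to respondents alone
can recover the non-respondent stratum.

`subpred` treats the stratification as known through an indicator `R`
(respondent stratum `U1` of size `N1 = lambda1 N`, non-respondent stratum
`U2` of size `N2 = lambda2 N`) with regime models

$$Y_1 = x_1\beta_1 + \epsilon_1, \qquad Y_2 = x_2\beta_2 + \epsilon_2,$$

errors independent, mean zero, with variances $\sigma_1^2$, $\sigma_2^2$
(or known per-unit variance structures). The remedy for the missing stratum is
the classical second-call device: after the first call yields `n1` respondents
`s1` and `n2` non-respondents `s2`, a stronger (more expensive) interview mode
fully observes a sub-sample `s2'` of roughly `n2/k` of the non-respondents,
giving just enough data to fit the second regime.

## Estimators and their error

Three predictors are implemented (`predict_total_full`,
`predict_total_respondents_only`, `predict_total_subsampling`), all of the
form *observed weighted sum + model prediction of the rest*. Their practical
content:

* The **respondent-only** predictor extrapolates `b1` (OLS on `s1`) to all of
  `U2`. Its model bias is `W2' x2 (beta1 - beta2)`
  (`bias_respondents_only`); it is linear in the coefficient gap and does not
  shrink with `n`. Its model variance (`mse_respondents_only`) has the printed
  form `sigma1^2 (n1 + Q(s1bar; H_s1)) + sigma2^2 Q(U2; H_s1)` with
  `Q(A; H) = W_A' x_A H^{-1} x_A' W_A` and `H_s1 = x_s1' x_s1`.
* The **sub-sampling** predictor adds the observed sub-sample and predicts the
  remaining `U2` units with `b2` fitted on `s2'`. Under correct regime models
  it is model-unbiased; its model variance (`var_subsampling`) is
  `n1 sigma1^2 + n2' sigma2^2 + sigma1^2 Q(s1bar; H_s1) + sigma2^2 Q(s2'bar; H_s2')`.

Two honesty notes on the variance formulas, implemented verbatim rather than
"corrected":

1. The leading terms use the observed unit counts (`n1`, `n2'`), which is the
   `W = 1` form of the observed-part contribution; with mean weights
   (`W = 1/N`) the quadratic-form terms still adapt through `W` but the
   leading terms do not. The formulas are therefore intended for totals.
2. The analytic expression targets the variance of the *estimator*, while the
   empirical auditor (`empirical_prediction_moments`) measures the variance of
   the *prediction error* `T_hat - T_y`; these differ by the variance
   contribution of the unobserved outcomes, so the two reports are expected to
   disagree by a modest margin. Both are surfaced; neither is silently
   substituted for the other.

Design expectations over repeated SRSWOR draws (`expected_var_subsampling`,
`expected_var_full`) are Monte-Carlo averages with explicit replication count
and seed: no closed form over the design is available, and we prefer an
auditable average to an ad-hoc approximation.

## Super-collinearity and the ridge regime fit

Because the sub-sample is a fraction of a fraction of the sample, `n2'` is
routinely at or below `p + 1`, making `H_s2'` singular ("super-collinearity").
The fix is deliberately minimal: replace `H` by `H + vI` (`fit_prr`),
penalizing **all** `p + 1` coefficients including the intercept, exactly as
the method prescribes (an `penalize_intercept = FALSE` escape hatch exists but
is off by default). The admissible range `(0, 2[-min(0, psi2)])` with `psi2`
the minimum eigenvalue of `H^{-1} - beta2 beta2'/sigma2^2`
(`ridge_admissible_range`) is expressed in terms of the *true* regime
parameters; in practice `select_tuning` can cap its grid by a plug-in version
of this bound.

Choices made where the method is silent:

* **How `v` is chosen.** No selection criterion is prescribed, so the package
  uses leave-one-out cross-validated squared prediction error over a fixed
  log-spaced grid `10^seq(-4, 4, length.out = 17)`, ties resolved to the
  smallest candidate (least shrinkage). LOOCV is deterministic, cheap at these
  sample sizes via the ridge hat diagonal, and needs no second split of an
  already tiny sub-sample. With a single-observation sub-sample LOOCV is
  undefined and `v = 1` (the grid midpoint) is used.
* **When the fallback triggers.** `auto_fit_and_predict` uses plain OLS for
  the second regime only when `n2' > p + 1`; at `n2' = p + 1` the exact-fit
  solution would leave no residual information, so the policy already switches
  to PRR there, and any numerically ill-conditioned OLS solve (condition
  number above `1e12`) also falls back. The method string of every estimate
  records which path was taken.
* **Error variance under ridge.** `sigma^2` is estimated as `RSS/n` and
  flagged approximate; no ridge effective-degrees-of-freedom correction is
  applied because none is prescribed.

Known heteroscedasticity with a *known* variance structure is handled by WLS
(`fit_wls`); iterative/feasible GLS with an estimated structure is out of
scope.

## Sampling-design primitives and rounding

`draw_srswor` is plain SRSWOR; `subsample_nonrespondents` draws
`max(1, round_half_up(n2/k))` units. The half-up rounding rule is a package
decision (the method writes `n2' = n2/k` with no rule); it is deterministic
and keeps `n2' >= 1` whenever any non-respondent was sampled. The quantile
stratifier `assign_response_by_quantile` marks the top (or bottom) `1-lambda2`
fraction as respondents; units tied exactly at the threshold join the
respondent stratum (deterministic, testable), and an all-equal outcome vector
raises a tie-degenerate error rather than randomizing.

The two evaluation protocols historically use opposite tails: the application
protocol stratifies high outcomes as respondents ("upper"), the simulation
protocol low outcomes ("lower"). Both are exposed via `tail =` /
`response_tail =` rather than hard-coding either; the published error
magnitudes for the donor application are reproducible under the *lower*
convention, which is what the package's own evaluation runs use.

## What the synthetic generators emulate

* `make_two_regime_population` draws covariates from a user law (default iid
  standard normal) and realizes the two regime models exactly; it stores the
  generator truth (`mu`, per-unit error sd, coefficients) so that
  `empirical_prediction_moments` can redraw errors and audit bias/variance
  claims against closed forms.
* `generate_simulation_population` implements the simulation design: `z` is
  `N x p` iid N(100, 1); the covariates are built from `z` per `dgp_variant`;
  the coefficient vector `gamma` is the element-wise average of the unit-norm
  eigenvectors of `H = x'x` with eigenvalue above 1; `y = x gamma + eps`,
  `eps ~ N(0, sigma^2 I)`; response is stratified at rate `1 - lambda2` on the
  configured tail. Two variants exist because the printed covariate formula
  `x = ((1-rho)^0.5 + rho) z` is algebraically a pure rescaling of `z` — under
  it `rho` changes scale but induces no cross-covariate correlation. The
  `"literal"` variant (default) implements exactly that; the `"latent"`
  variant implements the standard collinearity-inducing construction
  `x_j = (1-rho^2)^0.5 z_j + rho z_shared`, which the formula appears to
  intend. Published table values cannot be uniquely tied to either variant, so
  the package asserts only qualitative orderings from this design.
  Eigenvector signs are fixed so each eigenvector's largest-magnitude entry is
  positive before averaging (sign conventions are otherwise arbitrary and
  unspecified).
* `emulate_blood_population` is a **synthetic** 748-donor table standing in
  for the blood-donation application data. It reproduces the real table's
  qualitative joint structure — outcome an exact 250 c.c. multiple of donation
  frequency, strong positive frequency–time association, weak negative
  frequency–recency association, count-like skewed marginals — with
  parameters fixed once from the public summary statistics of the original
  data. It does *not* reproduce the actual records, so evaluation results on
  it match the published application values only to the extent that those
  depend on the joint structure rather than on individual rows. Tests passing
  on it demonstrate the estimator's behavior under realistic non-ignorable
  stratification of a real-shaped table, not row-level agreement with the
  original study.

## Problem sizes for desk-scale runs

The full-scale protocols (5000 x 2000 bootstrap replications; N = 10000,
2000 x 500 simulation replications) are available by passing those counts, but
the package's own tests and evaluation script run reduced configurations
chosen to keep every check a desk-scale computation while leaving Monte-Carlo
error well below the effect sizes asserted: bootstrap 300 x 300 on the
748-unit emulator (the respondent-only bias there is ~0.5 in relative terms,
two orders above the replication noise), simulation N = 2000 with 100 x 50
replications, and 2000 error redraws for the unbiasedness audits (assertions
at 3 Monte-Carlo standard errors).

## Numerical conventions

* Cross-product solves use a symmetric eigenvalue condition check with
  threshold `1e12` to classify super-collinearity; inner Monte-Carlo loops use
  Cholesky solves with the failure branch mapped to the same fallback.
* Equality of closed forms against brute-force oracles is asserted at `1e-9`
  relative; component decompositions must re-add to the total at the same
  tolerance.
* `empirical_prediction_moments` uses the divisor-`n` variance so that
  `MSE = bias^2 + variance` holds as an identity.
* All protocol randomness flows from a single seed; sub-draws are consumed
  sequentially from that stream, so equal seeds give bit-identical evaluation
  rows.
* Degenerate outer draws (no respondents beyond `p`, or no non-respondents
  while `lambda2 > 0`, or singular respondent fits) are rejected, redrawn and
  counted; the count is reported in every evaluation row.

## Known limitations

* The stratification indicator is treated as known; estimating `lambda1`,
  `lambda2` (e.g. by two-phase sampling) or modeling response propensity is
  out of scope.
* The variance formulas assume unit weights in their leading terms (totals,
  not means), as discussed above.
* WLS requires the variance structure to be known; GLS iteration is not
  implemented.
* No design-based (inverse-probability) estimators and no interval estimation:
  the method derives point predictors and their model moments only.
* The donor-table emulator supports structural, not row-level, comparisons
  with the published application.
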