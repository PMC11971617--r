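---
title: "Distribution-free estimation of the random effects GPCM under convexity constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-free estimation of the random effects GPCM under convexity constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The generalized partial credit model (GPCM) describes `k` polytomous items
scored `0..m_i` measured by a single latent trait `theta`.  Conditionally on
`theta`, item scores are independent with adjacent-category logits

    P(Y_i = a | theta) / P(Y_i = a-1 | theta) = exp{alpha_i (theta - delta_ia)},

where `alpha_i` is the item scaling and `delta_ia` the threshold at which
categories `a-1` and `a` are equiprobable.  In the random effects version,
`theta` is a random draw per examinee from an unknown population density.

Rather than assuming that density (usually a standard normal, integrated out
by quadrature), this package uses a closed-form expression for the marginal
probability of a whole score pattern `y`.  Relative to an arbitrary reference
pattern `y0`, with dummy scores `x_tilde` and shifted scores
`y_tilde = y - y0`,

    P(Y = y) = tau * exp{ beta' x_tilde + K(alpha' y_tilde) },

where `beta_is = -alpha_i * sum_{a<=s} delta_ia` are transformed category
locations, `K` is the conditional cumulant-generating function (CGF) of the
latent trait given `Y = y0`, truncated at an even order `v`, and `tau`
normalizes over a finite support `B` of patterns.  The truncation replaces the
infinite cumulant sequence by a degree-`v` polynomial
`K(u) = sum_r lambda_r u^r / r!`; `lambda_r` for `r < v` are the conditional
cumulants of the latent trait at the reference pattern, and `lambda_v` is a
Taylor-remainder coefficient.  Everything about the latent density that the
data can see enters through these few coefficients — no density is ever
specified, so the fit cannot be biased by a misspecified latent distribution.

The support `B` defaults to the observed pattern set `O`, which keeps the
normalizer a sum over at most `n` terms regardless of `k`, and means the model
is fitted to the subpopulation defined by `O`.  A full-product-space support
is available for small designs (`support = "full"`), but categories never
observed then push their `beta` to the boundary; `B = O` is the recommended
and default analysis.

## Convexity constraints

A CGF must be convex; an unconstrained polynomial need not be, and fitting
without the constraint can yield an improper solution (cumulants no latent
variable could have) and multiple likelihood optima.  `K''(u)` is a
polynomial of degree `v - 2 = 2q`, non-negative on the whole line if and only
if it is a sum of two squared polynomials,

    K''(u) = p1(u)^2 + p2(u)^2,  deg p1 = q,  deg p2 = q or q - 1,

with coefficient vectors `eps1` and `eps2`.  Writing
`h_c = sum_{j+j'=c} (eps1_j eps1_j' + eps2_j eps2_j')` gives
`lambda_{c+2} = c! h_c`, and `K` is recovered by integrating twice.  The
scale and location of the latent trait are fixed by `lambda_1 = 0` and
`lambda_2 = 1`, the latter enforced through fixed
`(eps1_0, eps2_0) = (3/5, 4/5)` (the unit-circle pair used throughout;
`(1,1)/sqrt(2)` is available via `eps_fixed`).  A sign convention
(`sum(alpha) >= 0`) resolves the remaining reflection of the latent axis.

Two consequences matter in practice:

* the fitted latent moment sequence is always proper, and
* in the canonical `(beta, lambda)` coordinates the log-likelihood is concave
  over the (convex) cone of valid coefficient vectors, so the maximum is
  unique there.

The `eps` coefficients themselves are auxiliary: they have no statistical
interpretation, the map `eps -> lambda` is quadratic, and a given `lambda`
typically corresponds to several `eps` representations.  Three facts follow
that this package is explicit about:

1. The likelihood is *not* concave in `eps`, and stray stationary points
   exist.  The default fit therefore runs in two stages (a concave warm-up
   with the shape frozen at the normal sub-model, then the full problem) and
   finishes with damped Newton steps on a finite-difference Hessian of the
   analytic gradient.  For the parsimonious `deg2 = q - 1` configurations
   this reaches the global optimum from essentially any start (20 random
   restarts on the worked example agree to 2e-13).  For `deg2 = q` we have
   seen rare convergence to a lower stationary point on simulated data; if a
   `deg2 = q` fit matters, compare a few explicit `start` values and keep the
   best.
2. Wald standard errors for raw `eps` entries can be badly calibrated even
   when those for `beta`, `alpha` and the cumulants are fine, because `eps`
   is only discretely identified given `lambda`.  Report `latent_cumulants()`
   (delta-method standard errors on the `lambda` scale), not raw `eps`.
3. With `deg2 = q` the model class is closed under a change of reference
   pattern, and the maximized log-likelihood is invariant to the choice of
   `y0` (as is the `v = 2` sub-model, exactly).  The parsimonious
   `deg2 = q - 1` slice is *not* closed under reference change — the pinned
   sum-of-squares decomposition singles out a reference-dependent subfamily —
   and refits with different `y0` can differ by a few hundredths of a
   log-likelihood unit.  This is a property of the parameterization, not an
   optimizer artifact; the default `y0` (the most frequent observed pattern)
   makes the choice reproducible.

## Estimation and standard errors

`gpcm()` maximizes the multinomial log-likelihood of the pattern counts

    l = n log tau_B + beta' n_tilde + sum_y n_y K(alpha' y_tilde)

by BFGS with the analytic gradient (exponential-family form: observed minus
model-expected sufficient statistics for `beta`; chain rule through `K'` and
the `h_c` for the rest), from the always-feasible normal start (`beta = 0`,
`alpha = 1`, free `eps = 0`).  All likelihood work is done in log space with
a log-sum-exp normalizer — pattern weights span e^±17 already in the worked
example.  Convergence is declared at gradient infinity-norm below `1e-6`
(`control = list(grad_tol = ...)`).

The covariance of the free parameters is the inverse negative Hessian,
recomputed at the optimum by central finite differences of the analytic
gradient (relative step `1e-5`) rather than taken from BFGS's internal
approximation, which accumulates error.  Interpretable item parameters are
recovered as `delta_is = (beta_{i,s-1} - beta_is)/alpha_i` and
`omega_is = -beta_is/(s alpha_i)` with delta-method standard errors
(`item_parameters()`), and the cumulant coefficients as
`lambda_r = (r-2)! h_{r-2}` (`latent_cumulants()`).

The number of free parameters is `sum(m) + k + q + deg2`; for the worked
five-item example (`m_i = 4`, `v = 6`, `deg2 = 1`) that is 28.

## Person scores and population summaries

The conditional MGF of the latent trait given any pattern `y` is available in
closed form, so the conditional cumulants are polynomial evaluations:
`kappa_j|y = K^(j)(u)` at `u = alpha' y_tilde`.  The EAP person score is
`kappa_1|y`, strictly increasing in `u`, and the conditional variance
`kappa_2|y = K''(u)` is non-negative by construction — the convexity
constraint is what guarantees sensible person scores.  The reference pattern
scores `(0, 1)` by identification, so EAPs are expressed in standard
deviations of the latent trait among examinees with the reference pattern.

Population moments in the subpopulation defined by `B` average the
per-pattern conditional non-central moments with the *fitted* pattern
probabilities (law of total expectation); observed-frequency weighting is
available for sensitivity analysis (`population_cumulants(weights =
"observed")`).  The first four population cumulants follow by the standard
conversions.  For the fourth, the standard identity uses `-3 (mu'_2)^2`; a
`kappa4 = "cubed"` option instead cubes that term, reproducing a variant
conversion found in some published tabulations of these data.  The default is
the standard identity.

## Goodness of fit

With many sparse score patterns, Pearson or saturated-model LR tests are
unusable.  `split_lr_test()` implements a split-sample alternative: patterns
(not persons) are randomly assigned to two parts, the model is fitted to the
whole observed set and to each part with its own observed support, and

    LR = 2 [ (l1 + n1 log(n1/n)) + (l2 + n2 log(n2/n)) - l ]

is referred to chi-squared with free-parameter count plus one degrees of
freedom.  Sub-fits use each part's most frequent pattern as reference.  On
data simulated from the model (three trichotomous items, `v = 2`, 200
replicates) the statistic's mean is within 15% of its degrees of freedom;
parts small enough to saturate the model (fewer patterns than parameters)
break the asymptotics, and occasionally a random part has a divergent
boundary MLE — such fits are flagged and no p-value is reported.  Nested
comparisons (e.g. the convexity-constrained nominal response model
`nominal_gpcm()`, which frees one scaling per item category, against the
GPCM) use `lr_test()`.

## The simulator

`generative_gpcm()` + `simulate_responses()` generate person-by-item scores
by drawing each person's latent value from a pluggable density — normal,
two-component normal mixture, or shifted gamma for skew, since the whole
point of the model is robustness to non-normal latent shapes — and then item
scores from the adjacent-category logit probabilities, person-major from one
seeded stream.  `simulate_patterns()` instead resamples pattern counts from a
fitted discrete model (a multinomial over its support).  The generator
reproduces quadrature-computed marginals at `n = 100000` within Monte Carlo
error, and its category-probability curves cross exactly at the `delta_ia`
(`category_curves()`).

What the simulator does not emulate: missing responses, local dependence
between items, multidimensional traits, or person-level covariates.  Tests
passing on generated data therefore speak to the estimator's correctness
under the model's own assumptions, not to robustness against violations of
conditional independence.

## Numerical choices and problem sizes

* Polynomials are evaluated by Horner's scheme; factorials up to `v` are
  exact integers.
* Degenerate inputs fail loudly: `y0` outside `B`, observed patterns outside
  `B`, single-pattern data (saturated), zero `alpha` in threshold transforms,
  singular observed information (the offending direction is named).
* Test-suite problem sizes were chosen to keep the full suite under a minute
  on one core: the complete worked example (85 patterns, n = 493, seconds per
  fit), a three-item trichotomous design for properties and calibration
  (n = 2000–3000 per fit, 200-replicate null-distribution studies), and a
  single n = 50000 parameter-recovery refit of the worked example.

## Limitations

* `v` must be chosen; cross-validation over `v` is advice, not a feature.
* Only complete score patterns are supported — no missing-data handling.
* The analytic Hessian is not implemented; standard errors rest on
  finite differences of the analytic gradient and should be read with the
  usual caution for numerically differentiated curvature.
* Multigroup, multidimensional and longitudinal extensions are out of scope.
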