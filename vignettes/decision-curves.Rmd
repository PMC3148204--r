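---
title: "Decision curves, the overall net benefit, and case-control adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision curves, the overall net benefit, and case-control adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbenefit)
```

## The model

A prediction model supplies each subject `i` with a probability `p_i` of a
binary outcome (1 = disease or event). Treatment is administered when
`p_i > p_t`, where the threshold probability `p_t = L/(L + P)` encodes the
decision maker's trade-off between the profit `P` of treating a true case
and the loss `L` of treating a non-case; only the ratio `L/P` matters, and
the package therefore works on the `p_t` scale throughout, assuming
`0 < p_t < 1`.

At a given threshold the sample splits into the four joint proportions
`a` (treated cases), `b` (treated non-cases), `c` (untreated cases) and
`d` (untreated non-cases), with `a + b + c + d = 1` and prevalence
`pi = a + c`. Writing `w = p_t/(1 - p_t)`, the three net-benefit
functionals are

* `u_treated = a - b w` — the expected profit among the treated, per
  subject, in units of `P`; maximum `pi`, attained only when `b = 0` with
  `a = pi`;
* `u_untreated = d - c/w` — the expected profit among the untreated in
  units of `L`; maximum `1 - pi`;
* `u_overall = (a + d) - b w - c/w` — their sum; maximum 1, attained only
  by a perfect model.

`u_treated` alone is sensitive to how the outcome is coded: recoding
`y -> 1 - y`, `p -> 1 - p`, `p_t -> 1 - p_t` turns it into `u_untreated`.
The overall form is invariant under that recoding and its maximum does not
drift with the prevalence, which makes model comparisons transferable
across studies. The sum is used as-is: the components are already
normalized per correct decision (by `P` and by `L` respectively), and no
further normalization of the sum presents itself that would preserve both
the recoding invariance and the fixed maximum, so the package treats the
plain sum as definitive.

A decision curve is `u(p_t)` over a threshold grid, read against three
reference strategies: treat none (`u_treated = 0` identically), treat all
(`u_treated = pi - (1 - pi) w`, decreasing without bound), and the perfect
model. A binary test is the degenerate model with `p_i` equal to 1 or 0,
whose classification — hence sensitivity and specificity — is the same at
every threshold.

## Relationship to ROC analysis

With `sens = a/(a + c)` and `spec = d/(b + d)`, the treated net benefit is
`sens * pi - (1 - spec)(1 - pi) w`. Maximizing it over cutoffs at a fixed
`p_t` selects, in the smooth-curve idealization, the ROC point whose slope
is `[(1 - pi)/pi] w`; the accuracy-driven Youden cutoff instead maximizes
`sens + spec - 1`. The two coincide exactly when `p_t = pi`, since at that
threshold `u_treated = pi (sens + spec - 1)` at every cutoff — the package
asserts this as an exact identity, not an approximation.

The empirical ROC is a step function with no usable derivatives, so
`netbenefit_cutoff()` does not differentiate it: it maximizes `u_treated`
directly over every achievable classification, which yields the identical
optimum without differentiation artifacts, and reports the analytic target
slope as a diagnostic. Candidate cutoffs are midpoints between consecutive
distinct probabilities plus sentinels below the minimum and above the
maximum, covering all `m + 1` achievable classifications for `m` distinct
values; ties are resolved toward the highest specificity (fewest treated),
deterministically.

## Case-control designs

When cases are sampled to a design quota, the sample prevalence `pi` says
nothing about the population prevalence `pi0`, and probabilities fitted on
the sample are inflated. Given an externally supplied `pi0` (the package
deliberately provides no way to estimate it from the data), each
probability is rescaled on the odds scale by
`[pi0/(1 - pi0)] / [pi/(1 - pi)]` — an intercept shift on the logit scale.
The map is strictly increasing with 0 and 1 as fixed points, so subject
ranking and the ROC curve are unchanged. Classifying the adjusted
probabilities still yields consistent sensitivity and specificity, and the
net benefit is estimated by plugging those and `pi0` into the
sensitivity/specificity form above. When `pi0` equals the sample
prevalence the whole construction collapses exactly onto the ordinary
decision curve; `adjust_probabilities()` short-circuits this case to the
identity so the reduction is exact rather than within rounding.

When `pi0` is uncertain, `prevalence_sweep()` fixes `p_t` and traces the
net benefit over a grid of assumed prevalences, and `run_dca()` can emit
one curve block per assumed prevalence.

## Parameters and defaults

* **Threshold grid**: 0.01 to 0.99 in steps of 0.01 (probability units).
  The open endpoints are excluded because `u_untreated` and `u_overall`
  diverge as `p_t -> 0` and `u_treated` as `p_t -> 1`. Curves are computed
  pointwise with no smoothing; plots connect grid points linearly and clip
  the y-axis to `[-0.05, 1.05]`, drawing the diverging references only
  where they exceed the clip.
* **Tie rule**: a subject with `p_i = p_t` is *not* treated (strict
  inequality). Some convention is unavoidable on real data even though the
  underlying theory assumes ties away; strict `>` keeps the treat-none
  limit exact. No tie rule can survive the outcome-recoding map (which
  sends `p_i = p_t` to itself while swapping the roles of the two groups),
  so recoding-invariance checks use tie-free data.
* **Logistic fitting**: maximum likelihood via iteratively reweighted
  least squares (`stats::glm`), convergence tolerance 1e-8, at most 100
  iterations; a fit with probabilities numerically at 0 or 1, or that hits
  the iteration cap, triggers a separation warning rather than an error.
* **Equality tolerance**: all algebraic identities (conservation,
  recoding, the Youden identity, the case-control reduction) are asserted
  at 1e-12 — these are pure-arithmetic statements, with no iterative
  fitting in the loop, so only accumulated rounding is tolerated.
* **Degenerate inputs**: single-class samples are accepted by `classify()`
  (the proportions remain well defined) but rejected wherever sensitivity
  or specificity is needed (`roc_points()`, the cutoff searches,
  `adjust_probabilities()`); `reference_curve()` requires a prevalence
  strictly inside (0, 1) because the treat-none/untreated form divides by
  the prevalence odds and the perfect-model constants degenerate.
  Undefined case-control grid points would be reported as `NA` with a
  warning rather than a fabricated 0, though with both classes present
  they cannot arise.

## The synthetic-data generator

`generate_risk_cohort()` emulates the *shape* of a Framingham-style
30-year event cohort: a binary outcome from a logistic model over six
covariates — a balanced binary one standing in for sex and five
standardized continuous ones standing in for age, BMI, serum cholesterol
and diastolic/systolic blood pressure — with coefficients
(0.7, 0.9, 0.25, 0.45, 0.3, 0.5) and intercept −1.4455961, solved by
numerical integration of the logistic-normal mixture so that the marginal
event probability is 0.30. The coefficient magnitudes were chosen once to
give the fitted models realistic, mid-range discrimination; no attempt is
made to match real Framingham coefficients, so any result that depends on
the real data (such as the published optimal cutoff 0.306) is out of the
generator's reach by construction and delegated to the optional external
script. Binary-test data can be generated in an exact-fraction mode (cell
counts hit exactly, no randomness) or stochastically;
`sample_case_control()` samples within outcome classes without replacement
and *refits* the model on the subsample, so the probability distortion the
adjustment corrects genuinely occurs rather than being injected.

What passing simulations do **not** show about real data: covariates here
are independent and linearly related to the log odds, the model is
correctly specified and evaluated in-sample, and outcomes are complete.
Real cohorts have correlated covariates, model misspecification, optimism
(no cross-validation is provided by design), and censoring — which this
framework deliberately ignores, treating the outcome as a plain binary
variable.

All generators take an explicit integer seed, use Mersenne-Twister
locally, and restore the caller's RNG state; identical specs give
identical samples.

## Problem sizes

The test suite's simulation scales were chosen as the smallest that leave
the Monte-Carlo checks comfortably determined: coefficient recovery and
dominance checks on cohorts of 8,000–10,000; the case-control recovery
comparison against a population of 50,000 with a 500+500 sample (maximum
absolute curve deviation bounded by 0.03, about three Monte-Carlo standard
deviations for the treated curve); the unbiasedness check with 200
replicate 500+500 samples against a population of 20,000, asserted within
two standard errors of the replicate mean. Exact-arithmetic properties use
1,000 random small datasets each.

## Known limitations

No confidence intervals or standard errors for net benefit are provided,
and no elicitation of `P` and `L` beyond their ratio; time-to-event
outcomes, matched designs and sampling weights are out of scope. The
untreated and overall curves inherit large variance at small `p_t` (the
`1/w` weight), which is why the case-control recovery guarantee is stated
for the treated curve.
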