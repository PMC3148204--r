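# netbenefit

Decision curve analysis for clinical prediction models and binary
diagnostic tests, built around the **overall net benefit** and its two
components, with the link to ROC analysis and an extension to case-control
designs.

## The problem

A prediction model turns a subject's covariates into a probability `p_i` of
disease; treatment is given when `p_i` exceeds a threshold probability
`p_t = L/(L + P)`, where `P` is the profit of treating a true case and `L`
the loss of treating a non-case. `p_t` encodes how a clinician or patient
weighs false positives against false negatives, so a model's clinical value
must be shown as a function of `p_t` — that display is the decision curve.

With `a, b, c, d` the joint proportions of true positives, false positives,
false negatives and true negatives at threshold `p_t` (a subject counts as
treated when `p_i > p_t`, ties untreated), and `w = p_t/(1 - p_t)`:

```
u_treated   = a - b w            (max = prevalence, for a perfect model)
u_untreated = d - c / w          (max = 1 - prevalence)
u_overall   = (a + d) - b w - c / w = u_treated + u_untreated   (max = 1)
```

`u_treated` is the classical net benefit; `u_untreated` is what it becomes
if the outcome coding is reversed; their sum, the overall net benefit, is
invariant to the coding and has a fixed maximum of 1, attained only by a
perfect model. At `p_t = 0.5` the overall net benefit is simply the
proportion correctly classified minus the proportion misclassified —
a 60%-correct classifier scores `0.6 - 0.4 = 0.2`.

The package also provides:

* **reference strategies** — treat none, treat all, and the perfect model —
  as the standard comparison lines of a decision-curve plot;
* **ROC linkage** — empirical ROC curves, the Youden-optimal cutoff
  (maximizing sensitivity + specificity − 1), the net-benefit-optimal
  operating point at a fixed `p_t` (whose theoretical location is where the
  ROC slope equals `[(1-π)/π][p_t/(1-p_t)]`), and the arc-shaped decision
  curve of a model dichotomized at a fixed cutoff — the sharpest way to see
  that an *accurate* cutoff can have poor *utility* away from it;
* **case-control analysis** — when the sample prevalence π is set by design,
  predicted probabilities are rescaled on the odds scale by the
  prevalence-odds ratio `[π₀/(1-π₀)]/[π/(1-π)]` for an assumed true
  prevalence π₀, and net benefit is estimated from sensitivity and
  specificity (which case-control sampling leaves consistent) with π₀
  plugged in; sweeps over π₀ cover the case where it is uncertain;
* **synthetic cohorts** — a seeded generator for logistic-model populations
  (default: six covariates, marginal prevalence 0.30), binary-test data
  with specified sensitivity/specificity, and case-control subsamples with
  refitted (hence distorted) probabilities.

## Worked example

```r
library(netbenefit)
pop     <- generate_risk_cohort(cohort_spec(n = 5000, seed = 42))
simple  <- fit_logistic_model(pop$covariates[, "chol", drop = FALSE], pop$outcomes, "simple")
complex <- fit_logistic_model(pop$covariates, pop$outcomes, "complex")

g <- as_threshold_grid(c(0.15, 0.30, 0.45))
rbind(decision_curve(simple,  g, "overall"),
      decision_curve(complex, g, "overall"),
      reference_curve(prevalence(simple), g, "treat_all", "overall"),
      reference_curve(prevalence(simple), g, "perfect",   "overall"))
#>    strategy_label    kind  p_t net_benefit
#> 1          simple overall 0.15     0.19169
#> 2          simple overall 0.30     0.14562
#> 3          simple overall 0.45     0.32949
#> 4         complex overall 0.15     0.33427
#> 5         complex overall 0.30     0.40457
#> 6         complex overall 0.45     0.48352
#> 7       treat_all overall 0.15     0.18282
#> 8       treat_all overall 0.30     0.00771
#> 9       treat_all overall 0.45    -0.26291
#> 10        perfect overall 0.15     1.00000
#> 11        perfect overall 0.30     1.00000
#> 12        perfect overall 0.45     1.00000
```

The cohort's realized prevalence is 0.3054. At every threshold the
six-covariate model beats the single-covariate one, and both must be read
against the references: at `p_t = 0.30` the simple model's overall net
benefit (0.146) still beats treating everyone (0.008), but is far from the
perfect model's 1. Accuracy-optimal and utility-optimal cutoffs differ:

```r
youden_cutoff(roc_points(complex))
#> Operating point (criterion: youden)
#>   cutoff = 0.272342, sensitivity = 0.7629, specificity = 0.6539
#>   criterion value = 0.416835
netbenefit_cutoff(complex, 0.2)
#> Operating point (criterion: net_benefit)
#>   cutoff = 0.19607, sensitivity = 0.8671, specificity = 0.5048
#>   criterion value = 0.1788
#>   target ROC slope (1-pi)/pi * p_t/(1-p_t) = 0.568599
```

A command-line tool wrapping the same functions ships in `inst/cli/dca`
(subcommands `curve`, `roc`, `dichotomize`, `casecontrol`, `sweep`,
`simulate`; CSV in, long-format TSV out).

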