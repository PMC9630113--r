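---
title: "Estimating individualized net gain from a higher supplementation dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individualized net gain from a higher supplementation dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(netgain)
```

## The scientific question

Two-arm dose-comparison trials of cholecalciferol typically report an
average difference in the achieved serum 25(OH)D concentration — often a
null one — while the spread of individual responses, especially under the
higher dose, hints that the benefit of the extra dose is concentrated in
a subgroup. `netgain` asks the individualized version of the question:
*given a participant's baseline 25(OH)D concentration x, how much more
serum 25(OH)D can they expect at the end of the trial from receiving the
experimental rather than the standard dose, and for which x is that
advantage statistically clear?*

Three estimation strategies of increasing flexibility are provided, and
they are intended to be read together: a classical subgroup analysis, a
parametric interaction-style contrast of per-arm regressions, and a
semi-parametric robustification of the parametric fit.

## Models and assumptions

### Preliminary mixed model and subgroup analysis

The preliminary model treats the repeated post-baseline measurements
jointly: outcome on dose (arm), visit week (factor), baseline 25(OH)D,
age, sex and body size as fixed effects, with participant-specific random
intercepts, fitted by REML through `lme4`. Its dose term is the average
dose contrast, reported with a Wald interval and a normal two-sided
p-value. The model assumes additive covariate effects, a common
within-participant correlation induced by the random intercept, and
homoscedastic residuals.

The subgroup analysis splits participants at a baseline cut-off (default
30 ng/ml, the conventional minimum concentration for sufficiency) and
refits the same model within each stratum. With two strata, inference is
Bonferroni-adjusted to level $\alpha/2 = 0.025$, i.e. 97.5% intervals. A
baseline exactly at the cut-off is assigned to the sufficient stratum; the
verbal definition of the strata ("below" vs "above") does not cover
equality, so the tie-break had to be fixed somewhere, and assigning the
boundary to the sufficient side keeps the insufficiency stratum strictly
below the clinical threshold.

Two conventions deserve mention because they slightly affect replication
of any published numbers:

* intervals are normal-approximation Wald intervals, not Satterthwaite-t;
  at 30 participants per arm the difference is small, and the same normal
  quantile is used for the delta-method bands below, keeping all interval
  machinery consistent;
* intervals are always reported with `ci_low <= ci_high`.

When a design has a single follow-up visit, each participant contributes
one modelling row and the random intercept is no longer identifiable; the
fit then reduces to ordinary least squares with the random-intercept
variance reported as zero (recorded in the fit's formula descriptor).

### Parametric net gain

Within each arm $k$ the final-week outcome is modelled by OLS,

$$Y_k = X_k \beta_k + \varepsilon_k = m_k(x, \beta_k) + \varepsilon_k ,$$

with regressors (intercept, baseline $x$, age, sex, body size). The
net-gain curve is the difference of the two arm predictions at a common
covariate profile,

$$\Delta(x) = m_2(x,\hat\beta_2) - m_1(x,\hat\beta_1),$$

which for the linear working model is the sum of the intercept difference
and the slope difference times $x$ (profile terms cancel in expectation
when covariate effects are shared). Because arms are randomized and
fitted independently, $\mathrm{Var}\,\hat\Delta(x) =
c(x)^\top V_1 c(x) + c(x)^\top V_2 c(x)$ with $c(x) = (1, x,
\text{profile})$; the delta method is exact here, and the pointwise band
uses the standard normal quantile. Two fitting routes exist for the arm
models: separate per-arm regressions (the default, `fit_arm_model`), and
a joint mixed model with a combined week-by-arm factor (`fit_lmm` on the
full table; the `week_arm` column of the analysis table supports it).
They agree asymptotically; the per-arm route is the package default
because its independence structure makes the band arithmetic transparent.

The **benefit threshold** is computed with a uniform-tail rule: the
smallest grid value from which `ci_low > 0` holds all the way to the
right edge of the grid. A first-crossing rule (the first grid point where
the band excludes zero, ignoring later dips) is available via
`benefit_threshold(curve, "first_crossing")`; the uniform rule is the
default because an isolated significant island inside an otherwise
inconclusive region is not a usable recommendation threshold. The
analogous lower-tail threshold (band entirely below zero, standard dose
preferable) is reported alongside.

The default evaluation grid has 200 evenly spaced points spanning the
observed pooled baseline range (threshold resolution about range/200);
`grid_step = 0.1` gives 0.1 ng/ml resolution when a finer threshold is
wanted. The covariate profile defaults to pooled sample means with sex at
the sample female proportion — the curves must be drawn at *some*
covariate value, and the pooled mean is the least informative choice; for
shared covariate effects the choice only shifts both arms equally.

`net_gain_bivariate` adds age as a second conditioning covariate (one
more slope term). When the estimated age slopes agree across arms the
surface is flat in age — knowing a participant's age then adds nothing to
the dose decision.

### Semi-parametric two-step estimator

The linear working model buys interpretability at the cost of a strong
shape assumption. The two-step estimator relaxes it: per arm,

1. compute the parametric prediction $m_k(x, \hat\beta_k)$;
2. smooth the arm's residuals $r_i = Y_i - m_k(X_i, \hat\beta_k)$
   (each participant at their own covariates) over the baseline with a
   kernel smoother, and add the smoothed residual curve back:
   $\tilde m_k(x) = m_k(x,\hat\beta_k) + \hat r_k(x)$.

The smoothed-residual correction vanishes when the linear model is
correct (residuals average to zero locally) and captures systematic
curvature when it is not, so $\tilde\Delta(x) = \tilde m_2(x) - \tilde
m_1(x)$ is robust to misspecification of the parametric step. The
smoother is Nadaraya–Watson,

$$\hat r(x) = \sum_i W_i(x)\, r_i, \qquad
  W_i(x) = \frac{k\!\left(\frac{x - X_i}{h_n}\right)}
                {\sum_j k\!\left(\frac{x - X_j}{h_n}\right)},$$

or optionally local-linear (the intercept of the kernel-weighted
regression of $r$ on $X - x$), which removes the boundary bias of the
locally constant fit and reproduces linear trends exactly.

Three choices here were genuinely open and are worth recording:

* **What is smoothed.** "Adding a non-parametric step to the parametric
  fit" admits several readings: smoothing the outcomes directly,
  smoothing the residuals, or smoothing per-participant difference
  estimates. The package's default smooths residuals and adds them back,
  because that is the variant with the clean robustification property
  (exact reduction to the parametric curve when residuals vanish);
  `mode = "smooth_outcome"` implements the literal locally weighted
  average of the raw outcomes $\sum_i W_i(x) Y_i$ per arm for comparison.
* **Bandwidth scale.** The conventional bandwidths 0.6 and 0.8 are
  interpreted on the standardized baseline scale (distances divided by
  the sample SD of the baseline, about 9.4 ng/ml in the motivating
  setting). On the raw ng/ml scale a bandwidth of 0.6 would average
  essentially no neighbours. `kernel_spec(scale = "raw")` exposes the raw
  reading.
* **Kernel family.** "Nadaraya–Watson" names the estimator, not the
  kernel function; the default kernel is Gaussian, with Epanechnikov as
  an alternative. Results at these bandwidths are insensitive to the
  family.

No analytic band accompanies the semi-parametric curve; an optional
participant-level percentile bootstrap (`n_boot`) provides one. The
default evaluation grid is clipped to the 5th–95th percentile of pooled
baselines because locally constant estimates at the extreme boundary are
dominated by one or two points.

## The synthetic-trial generator

`simulate_trial` draws two-arm repeated-measures trials with the
structure the analysis assumes: per participant, baseline
$x_i \sim N(\mu_b, \sigma_b^2)$, a random intercept
$u_i \sim N(0, \sigma_u^2)$, and final-week outcome

$$Y_i = a_k + b_k x_i + w\,(s_i - \bar s) + u_i + e_i ,$$

with arm intercepts $a_k$, arm-specific baseline slopes $b_k$ (the
arm-by-baseline interaction that creates individualized effects),
body-size effect $w$, and residual $e_i \sim N(0, \sigma_e^2)$.
Intermediate visits receive the treatment-induced change at fractional
strength (week/final week) — chosen as a simple monotone build-up, since
nothing constrains the within-trajectory shape — while the body-size
association and the random intercept act fully at every follow-up. Age
and sex are drawn (uniform over a range; Bernoulli) but do not enter the
outcome by default, reflecting that age proved uninformative in the
motivating analyses.

Two named configurations encode the study-like conditions:

* `steenhoff_like_config()`: 30/arm, weeks 0/6/12, baseline
  $N(35, 9.4^2)$ ng/ml, body weight 58.3 ± 13.9 kg with
  $w = -0.45$ ng/ml per kg (the inverse adiposity association), ages
  5–51, 50% female, doses 4000 vs 7000 IU/day. Arm intercepts 33.8/23.3
  and slopes 0.6/0.95 were fixed once so that the arm means match the
  published descriptives (36.5 → ≈54.8 standard; 34.5 → ≈56.5
  experimental) while giving the experimental arm the steeper baseline
  slope — the crossing pattern the method is designed to detect. Variance
  components $\sigma_u = 4$, $\sigma_e = 6$ ng/ml reproduce end-of-trial
  SDs near the published 11–14 ng/ml range.
* `finnish_like_config()`: 25/arm, single follow-up at week 20, baseline
  $N(23.4, 3.6^2)$ (an insufficiency inclusion criterion), BMI
  29.1 ± 2.9 as body size, 14% female, ages 60–75, doses 1600 vs
  3200 IU/day; intercepts 20.24/18.68 with slopes 0.6/0.95 reproduce the
  published final means and a net gain of ≈5.4 ng/ml at baseline 20.

The optional kink fields (`kink_arm`, `kink_knot`, `kink_slope`) bend one
arm's mean response piecewise-linearly beyond a knot, producing data for
which the linear working model is deliberately misspecified while
`true_net_gain` remains known — the robustness experiments rely on this.

What the generator does **not** emulate: an S-shaped intake–response
curve (the generating response is linear, or piecewise linear, in the
baseline), informative dropout, measurement error in the baseline
covariate, assay batch effects, and seasonal drift in 25(OH)D. Passing
recovery tests on these data therefore shows that the estimators recover
the quantities they target under their own assumptions — not that those
assumptions hold in any particular real trial.

## Numerical choices and degenerate inputs

* Unit conversions are the exact field conventions (÷2.5 between nmol/L
  and ng/ml; ×40 between µg/day and IU/day) and invert to machine
  precision. Note that applying ÷2.5 to the conventional 75 nmol/L
  inclusion bound gives exactly 30 ng/ml.
* A numerically negative delta-method variance is clipped to zero (with a
  warning beyond tolerance); a zero covariance gives a degenerate
  point-interval.
* Kernel weights that underflow to zero everywhere (evaluation far
  outside the data at a small bandwidth) fall back to a
  nearest-neighbour weight of one, with a warning; a single observation
  always receives weight one.
* Local-linear smoothing requires two distinct covariate values; where
  the *local* weighted design degenerates at an evaluation point, the
  estimate falls back to the locally constant value there.
* Rank-deficient fixed-effect designs (constant or collinear covariates,
  a single arm) are refused with an error rather than silently dropping
  columns; arms with fewer participants than regressors + 2 are refused.
* Completer filtering keeps participants with outcomes at all required
  weeks, is idempotent, and reports the number excluded; sample SDs use
  the n−1 denominator.

## Test problem sizes

The simulation-backed checks run at sizes chosen to make the Monte-Carlo
error small relative to the tolerance being asserted: parameter recovery
and band coverage at 500 participants/arm over 100 replicates
(coverage asserted within 90–99%), threshold recovery at 2000/arm against
an analytic detectability point computed from population regressor
moments (±2 ng/ml), the kinked-response robustness experiment at 150/arm
over 50 replicates (semi-parametric integrated squared error smaller in
at least 80%), delta-method vs Monte-Carlo propagation at $10^5$ draws
(agreement to two decimals), and kernel-smoother oracle equivalence on 20
random small instances (agreement to $10^{-10}$).

## Known limitations

* The parametric curve is a straight line in the baseline; everything
  nonlinear is delegated to the semi-parametric step, which has no
  analytic inference and whose bandwidth is fixed, not data-driven
  (cross-validated bandwidth selection and shrinkage across covariates
  are natural extensions, deliberately out of scope).
* At most two conditioning covariates (baseline, age) are supported for
  the net-gain surface; more would demand far larger trials.
* The benefit threshold inherits the grid resolution and the pointwise
  (not simultaneous) nature of the band; it flags where evidence begins,
  not a clinically validated cut-off.
* Secondary analyses of completers inherit whatever selection the
  original dropout process induced; the package filters and logs, but
  does not model, missingness.
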