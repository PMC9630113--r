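# netgain

Individualized net gain from preferring a high over a standard
supplementation dose in two-arm randomized trials.

## The problem

Supplementation trials are usually summarized by an average treatment
effect, but participants rarely respond uniformly: in vitamin D trials
the variance of the end-of-trial serum 25-hydroxyvitamin D (25(OH)D)
concentration is typically much larger under the higher cholecalciferol
dose, suggesting that some individuals gain a lot from the extra dose and
others nothing. `netgain` implements an outcome-based personalized-nutrition
analysis for this situation: re-using completed two-arm RCT data to
estimate, as a function of a participant's *baseline* 25(OH)D
concentration, how much more serum 25(OH)D they can expect at the end of
the trial from receiving the experimental (high) dose rather than the
standard dose — and from which baseline concentration onward that
advantage is statistically clear.

It is aimed at biostatisticians and nutrition researchers doing secondary
analyses of dose-comparison trials with a continuous biomarker outcome.

## The model

Within each arm *k* (1 = standard, 2 = experimental) the end-of-trial
outcome is modelled by a linear regression

    Y_k = X_k β_k + ε_k = m_k(x, β_k) + ε_k,   k = 1, 2,

where the regressors are an intercept, the baseline concentration *x*,
and adjustment covariates (age, sex, body weight or BMI). The object of
interest is the **net-gain curve**

    Δ(x) = m_2(x, β̂_2) − m_1(x, β̂_1)
         = (β̂_20 − β̂_10) + (β̂_21 − β̂_11)·x + Σ_j (β̂_2j − β̂_1j)·profile_j,

the sum of the intercept difference and the baseline-slope difference
(adjustment covariates fixed at a reference profile, by default the
pooled sample means). Pointwise confidence bands come from the delta
method — exact for a linear contrast c(x) = (1, x, profile):

    Var(Δ̂(x)) = c(x)ᵀ V̂_1 c(x) + c(x)ᵀ V̂_2 c(x),

the two variances adding because randomization makes the arm fits
independent. The **benefit threshold** is the smallest baseline x* from
which the lower band stays above zero out to the edge of the observed
range: individuals starting above x* need the higher dose to achieve a
clearly larger increase.

Around this core the package provides

- **preliminary analyses**: a linear mixed model (dose, time, baseline,
  age, sex, body size; participant random intercepts; REML via `lme4`)
  with its dose contrast, and a cut-off subgroup analysis (default
  30 ng/ml, the conventional sufficiency threshold) with
  Bonferroni-adjusted intervals;
- a **two-step semi-parametric estimator** that relaxes the linearity
  assumption: the per-arm residuals of the parametric fit are smoothed
  over the baseline with a Nadaraya–Watson (or local-linear) kernel
  smoother, W_i(x) = k((x−X_i)/h_n) / Σ_j k((x−X_j)/h_n), at bandwidths
  h_n = 0.6 and 0.8 on the standardized baseline scale, and added back —
  a robustification against misspecification of the linear working model;
- a **synthetic-trial generator** with known ground-truth net-gain
  curves, used throughout the test suite for parameter-recovery,
  coverage and robustness checks;
- CSV ingestion with column mapping, unit conversions
  (1 ng/ml = 2.5 nmol/L; 1 µg/day = 40 IU/day), completer filtering, and
  an end-to-end reporting pipeline.

## Worked example

```r
library(netgain)

tr  <- simulate_trial(steenhoff_like_config(), seed = 42)
rep <- run_full_analysis(tr, cutoff = 30)
rep
```

```
Serum 25(OH)D by arm and week (ng/ml):
          arm visit_week  n  mean    sd
 experimental          0 30 33.85  9.87
 experimental          6 30 45.30 11.93
 experimental         12 30 54.83 13.73
     standard          0 30 35.64 11.80
     standard          6 30 47.75 14.13
     standard         12 30 57.47 11.76
Final-week max-min range: standard=44, experimental=64.4
Cohort: n=60, age 26.7 +/- 13.8 y, 43% female, weight_kg 56.4 +/- 12.2

Dose contrast (experimental - standard): 0.52 ng/ml [-2.78, 3.82], p = 0.757
Subgroup dose contrasts (Bonferroni-adjusted CIs):
                      stratum_label cutoff  n estimate ci_low ci_high p_value
 insufficient (baseline < 30 ng/ml)     30 17    -2.40 -10.81    6.00   0.521
  sufficient (baseline >= 30 ng/ml)     30 43     2.67  -1.25    6.59   0.126

Individualized net-gain fit (experimental minus standard dose)
  final week: 12 ; n = 30 + 30 participants
  net-gain line: -16.69 + 0.4679 * baseline (ng/ml)
  benefit threshold (95% band excludes zero): 42.53 ng/ml and above
```

Reading the output: averaged over everyone, the two doses are
indistinguishable (dose contrast 0.52 ng/ml, p = 0.76) — yet the fitted
net-gain line rises with baseline, and for participants starting above
about 42.5 ng/ml the 95% band excludes zero, i.e. only the higher dose
promises a further clear increase for them. `plot(rep$fit)` draws the
curve with its band and the semi-parametric overlays;
`plot(rep$fit, which = "change")` shows the two per-arm predicted
change-from-baseline lines whose crossing drives the effect.

`predict(rep$fit, newdata = c(25, 35, 45))` evaluates the net gain with
its interval at chosen baselines; `coef(rep$fit)` tabulates the per-arm
coefficients and their differences.

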