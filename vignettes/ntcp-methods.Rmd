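---
title: "Methods: actuarial NTCP modelling of temporal lobe injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actuarial NTCP modelling of temporal lobe injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlintcp)
```

## Scope and analysis unit

`tlintcp` estimates tolerance doses for radiation-induced temporal lobe
injury (TLI) from a bilateral cohort: one record per temporal lobe, with
dose-volume-histogram (DVH) metrics, clinical covariates, the months
from IMRT completion to either first MRI appearance of injury (event) or
censoring, and the censoring reason (death, repeat irradiation, or end
of MRI follow-up). Both lobes of a patient are treated as independently
at risk given their own dose — the standard working assumption for this
endpoint; a patient-clustered sandwich standard error is available in
`fit_cox(cluster = TRUE)` as a sensitivity analysis but is off by
default, so the headline analysis matches the independence assumption
exactly.

## DVH metrics

A cumulative DVH gives the absolute volume (cc) receiving at least each
dose (Gy); differential DVHs are not accepted. `dvh_metrics()` computes
the 15 standard scalars. Conventions:

* `d_max` is the largest dose coordinate of the curve — a maximum point
  dose at the curve's own resolution, not a percentile surrogate such as
  D2%.
* `d_xcc` (inverse lookup) and `v_x` (forward lookup) interpolate
  linearly between curve points. On a flat (tied-volume) segment the
  inverse lookup returns the largest dose of the segment, so that
  `d_xcc` remains the *highest* dose received by the hottest x cc.
  `dose_at_volume(curve, 0)` returns `d_max`.
* `v_x` is reported in absolute cc, not percent of structure volume.
* mean dose is the trapezoid integral of the cumulative curve divided by
  the structure volume; median dose is the inverse lookup at half the
  volume.
* All doses are physical; no fractionation (LQ/EQD2) correction is
  applied anywhere, so tolerance doses are tied to the fractionation of
  the underlying cohort (≈ 33 fractions for the reference conditions).
* A structure smaller than a probe volume (e.g. `d_20cc` of an 18-cc
  structure) yields `NA` with a warning; a zero-volume structure is an
  error.

## Elastic-net Cox screening

With 15 DVH metrics plus age, sex, dichotomized T stage (T1-2 vs T3-4)
and chemotherapy (19 candidates), the hot-spot metrics are mutually
rank-correlated above 0.8 (`spearman_matrix()`), making unpenalized
multivariable selection meaningless. `coxnet_path()` fits the
elastic-net-penalized Cox partial likelihood

$$\min_\beta \; -\tfrac{1}{n}\,l(\beta) \;+\;
  \lambda\left(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right)$$

by cyclic coordinate descent on the weighted-least-squares quadratic
approximation to the Breslow partial likelihood, with warm starts along
a geometric λ path from the smallest all-zero λ. The mixing weight
defaults to α = 0.5, which buys the grouping behaviour needed for
correlated predictors (exact duplicates receive near-equal
coefficients). Binary covariates are standardized like continuous ones
for penalization; coefficients are reported on the original scale.

Cross-validation (`coxnet_cv()`) uses the partial-likelihood deviance by
the difference method, `-2[l_{all}(\hat\beta_{-k}) -
l_{train}(\hat\beta_{-k})]`. Deviance is the statistically meaningful
loss for a Cox model; a "mean squared error" label seen in some software
for the same CV curve is a UI artifact, not a different loss. Two design
choices were genuinely open and are resolved as follows:

* **Folds are assigned at the patient level**, stratified by patient
  event status, so both lobes of a patient always share a fold. This is
  the conservative choice under within-patient dependence; lobe-level
  folds would leak the patient's shared dose geometry across folds.
* **λ is chosen by the one-standard-error rule by default** (largest λ
  whose mean CV deviance is within one SE of the minimum), with
  `rule = "min"` available. The 1-SE set is never larger than the
  minimum-rule set.

A fold layout that leaves a training set without events is re-drawn
with a new sub-seed (warning); if impossible (e.g. a single event
patient), selection stops with an explanatory error.

### Numerical choices

Coordinate descent runs in covariance form (each coordinate update is
O(p) after one O(np) weighted cross-product per reweighting) with an
active-set strategy. Convergence is declared when the largest weighted
squared update, $\max_j A_{jj}(\Delta\beta_j)^2$ on the standardized
scale, falls below `thresh` (default 1e-9), applied to both the inner
sweeps and the outer reweighting steps. An absolute
max-$|\Delta\beta|$ criterion is *not* used: with near-collinear
predictor blocks (exactly the situation this screen exists for) the
iterates crawl along near-null directions of the quadratic and such a
criterion effectively never triggers, while the objective and fitted
risk scores are long converged. A step-halving safeguard keeps the
penalized objective non-increasing across reweighting iterations; the
per-iteration objective trace is stored in the fitted object and
asserted monotone in the test suite. Karush-Kuhn-Tucker conditions can
be checked post hoc with `coxnet_kkt()`. At λ = 0 with tight `thresh`
the solver reproduces unpenalized Newton-Raphson coefficients to 1e-6;
along a path it agrees with an independent penalized solver to ~1e-5.

Ties in event time use the Breslow approximation inside the penalized
fit (standard for coordinate descent) and the Efron approximation in
the definitive univariate fit below; with monthly-grained times the
difference is negligible but both are exposed.

## Cox dose-response and tolerance doses

`fit_cox()` fits the univariate proportional-hazards model on the
selected dose metric (Newton-Raphson via `survival::coxph`, Efron
ties), with a Wald test, the global Schoenfeld-residual PH diagnostic
(`ph_test()`, Kaplan-Meier time transform by default), and the Breslow
baseline cumulative hazard at covariate zero. The failure function at
horizon t (default 60 months, configurable) is

$$F(t \mid D) = 1 - \exp\{-H_0(t)\, e^{\beta D}\},$$

with `H_0` held at its value at the largest event time ≤ t, and its
inverse is the closed-form tolerance dose
$\mathrm{TD}_p = [\ln(-\ln(1-p)) - \ln H_0(t^*)]/\beta$. Evaluation
beyond the observed follow-up span is refused rather than extrapolated.
A delta-method standard error on $(\beta, \ln H_0(t^*))$ using the
Breslow estimator's variance (including its covariance with β) is
provided; it is labelled approximate — the definitive SEs in this
package come from the logistic route, which has a clean ML covariance.
Degenerate inputs are flagged rather than fitted: a constant dose
metric returns β = 0 with infinite SE; β ≤ 0 makes a tolerance dose
undefined and errors.

`kaplan_meier()` reports actuarial injury-free survival at the patient
level (a patient fails at the earlier injured lobe's time) with
Greenwood standard errors.

## Logistic dose-response

The binary-endpoint route first applies the adequate-follow-up rule
(`eligibility_filter()`): injured lobes are always analysable; an
uninjured lobe counts as normal only if observed injury-free beyond the
window. The window defaults to 50 months because almost all injuries
(16/17 in the reference cohort, 19/20 in an earlier series) manifest
within 50 months; it is a plain parameter. Two edge policies were open:

* An injured lobe whose patient is *later* censored (e.g. dies at 30
  months after injury at 19) is retained — the injury was observed
  before censoring. A `strict = TRUE` toggle drops both lobes of such
  patients instead.
* The model covariance is the inverse *observed* Fisher information at
  the optimum (what IRLS/`glm` returns); observed and expected coincide
  for the canonical logit link.

`fit_logistic()` is maximum likelihood by IRLS with complete-separation
detection (a perfect dose threshold between classes is reported, never
silently diverged). Tolerance doses are
$\mathrm{TD}_p = (\mathrm{logit}(p) - b_0)/b_1$ with delta-method SE
from gradient $(-1/b_1, -\mathrm{TD}_p/b_1)$; the SE pattern widens
toward extreme p, and the delta-method SEs agree with a parametric
bootstrap within 10% at interior p. Dose-response curves are emitted
with *horizontal* (dose-direction) ±1 SE bands at fixed probability —
the natural rendering when the quantity of interest is a dose — with a
vertical (probability-direction) variant also available. Crude
incidence is binned into half-open 2.5-Gy intervals anchored at 0 Gy,
with lobes as denominators.

The two-parameter logistic in dose (no volume parameter) is the model
family used throughout: published tolerance-dose tables of this form
are cross-row self-consistent (any two rows determine the rest), which
the test suite exploits by calibrating to two anchors and reproducing
the other rows to one decimal. Lyman-style models with a volume
parameter are out of scope.

## Cohort comparison statistics

`compare_categorical()` uses the Pearson chi-square without continuity
correction when all expected counts are ≥ 5 and Fisher's exact test
otherwise — the switch that reproduces published baseline-table
P values (uncorrected Pearson for the T-category comparison, Fisher for
sex and chemotherapy). `compare_continuous()` is a two-sided Welch
t-test by default, with Student and Wilcoxon variants. All tests are
two-sided at α = 0.05. No multiplicity correction is applied.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the analysis assumes,
with known ground truth for every stage:

* **DVH shape.** Each lobe's cumulative DVH is the power-tail curve
  $V(d) = \mathrm{TLV}\,(1 - d/D_{max})^g$ on a 0.1-Gy grid (bin width
  configurable). With $D_{max} \sim N(70.5, 4.3^2)$ truncated to
  [56.1, 83.1] Gy, shoulder $g \sim \mathrm{logN}(\log 1.8, 0.12)$, and
  TLV ~ N(100, 12²) cc truncated to [67, 138], the per-metric means of
  a generated cohort fall inside the min-max envelopes reported for
  real bilateral NPC cohorts, and the hot-spot metrics exhibit the
  Spearman correlations (> 0.8) that motivate the elastic net. Left and
  right lobe doses share a patient-level factor with correlation 0.7
  (configurable, empirically recoverable ±0.1).
* **Outcome model.** Injury latency follows the Cox-type hazard
  $H(t|D) = e^{\log h_0}\,(t/60)^{k}\,e^{\beta D}$ with the true
  log-hazard β = 0.16/Gy and $\log h_0 = -13.16$ at 60 months on the
  1-cc dose — the parameters implied by the reference actuarial
  dose-response — and Weibull shape k = 1.5, chosen so the median
  latency among injured lobes is ≈ 43 months under the reference
  follow-up distribution. Latency is drawn from this conditional
  distribution (inverse-transform), which couples latency and dose
  exactly as the Cox model assumes, rather than independently.
* **Follow-up and censoring.** Administrative follow-up is uniform on
  11-106 months (configurable, including a fixed-horizon variant);
  injury is never observed after follow-up ends. Death (probability
  0.17) and repeat irradiation (0.06) censor both lobes of a patient at
  a shared time. The resulting crude patient rate is ~12%, and the
  cohort passes the 50-month eligibility rule with realistic exclusion
  counts.
* **Clinical covariates** are drawn from marginal frequencies (male
  0.727, T3-4 0.606, chemotherapy 0.856, age ~ N(47, 13²) truncated to
  12-77) with no dose confounding by default; a `t34_dose_shift` knob
  ties T stage to dose for sensitivity studies.
* **Reproducibility.** One seeded stream yields deterministic
  per-patient sub-seeds, so cohorts regenerate identically.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: MRI ascertainment error and
interval-censored detection (latency is the true biological time, not
the first scan after it), dose-confounded censoring, heterogeneous
fractionation, spatial dose information beyond the DVH, and any real
joint distribution of the 15 metrics beyond the power-tail family. The
`td_true(p, t)` element of the returned truth makes the generative
tolerance dose available to recovery experiments.

### Recovery experiments and problem sizes

The test suite verifies, among others: β recovery within 3 SE on
500-patient cohorts (20 replicates); TD50 recovery to < 1 Gy mean bias
on 2000-patient cohorts (10 replicates) in a designed experiment with a
fixed 60-month follow-up, no competing censoring, and a dose
distribution spanning the response range — with the reference dose
range (almost all lobes below 30% risk) the logistic/complementary-log-log
link mismatch alone shifts TD50 by ~1.2 Gy, so dose coverage of the
target quantile, not sample size, is the binding requirement;
selection of a single true predictor among 18 noise variables in ≥ 95%
of 50 replicates; ~5% size of the PH diagnostic over 200 null
replicates and > 80% power against a reversing time-varying effect; and
type-I control of the dose effect under a null generator. Replicate
counts are sized for a single-CPU run of the whole suite in a few
minutes; tolerances are the scientifically motivated ones stated above.

## Known limitations

* The delta-method SE on the Cox-route tolerance dose treats the
  Breslow baseline as log-normal and ignores the uncertainty of the
  time horizon; it is reported but the logistic-route SEs are the
  definitive ones.
* The penalized path reports no post-selection inference; selected-set
  P values from a subsequent univariate fit are conditional on
  selection.
* Competing risks are handled as plain censoring (no Fine-Gray model),
  matching the reference analysis.
* The logistic and actuarial tolerance doses answer slightly different
  questions (risk by end of follow-up vs risk by exactly t*); they are
  expected to agree within joint uncertainty, not exactly.
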