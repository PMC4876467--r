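# tlintcp

Actuarial normal-tissue complication probability (NTCP) modelling of
radiation-induced temporal lobe injury (TLI) after intensity-modulated
radiotherapy (IMRT) of nasopharyngeal carcinoma.

## The problem

After high-dose IMRT of skull-base tumours, parts of the temporal lobes
receive doses near their tolerance, and injury (contrast-enhancing
lesions or cysts on MRI) appears with a latency of years. Radiation
oncologists need *tolerance doses* — the dose at which the probability
of injury reaches a given level — to set planning constraints. Two
complications make this a non-trivial statistical problem:

1. **Censoring.** Injury is only observable while a patient is under
   MRI follow-up; deaths and re-irradiation censor the endpoint, so
   crude rates understate risk. Tolerance doses should come from
   actuarial (time-to-event) models.
2. **Multicollinearity.** The candidate dose-volume-histogram (DVH)
   metrics — maximum point dose `D_max`, hot-spot doses `D_0.1cc`,
   `D_1cc`, ..., volumes `V_40` ... `V_75` — are strongly rank-correlated,
   so ordinary multivariable selection is unstable.

`tlintcp` implements the full analysis pipeline for a bilateral cohort
(each patient contributes two lobes, assumed independently at risk):

* **DVH metrics** — cumulative DVH parsing and the 15 standard scalars
  (`dvh_metrics()`): TLV, `D_max`, mean/median dose, `D_xcc` for
  x ∈ {0.1, 1, 5, 10, 20} cc, `V_x` for x ∈ {40, ..., 75} Gy (absolute cc).
* **Elastic-net Cox screening** (`screen_predictors()`, `coxnet_cv()`)
  — the penalized partial likelihood
  `-l(β)/n + λ(α‖β‖₁ + (1-α)/2 ‖β‖₂²)` with α = 0.5, fitted by cyclic
  coordinate descent with warm starts, 10-fold cross-validation with
  patient-level folds, and the 1-SE selection rule.
* **Cox dose-response** (`fit_cox()`) — univariate proportional-hazards
  fit with Efron ties, Schoenfeld PH diagnostic (`ph_test()`), Breslow
  baseline hazard, and tolerance-dose inversion of the 60-month failure
  function `F(t|D) = 1 − exp(−H₀(t) e^{βD})`:
  `TD_p = [ln(−ln(1−p)) − ln H₀(t*)]/β` (`cox_tolerance_dose()`).
* **Logistic dose-response** (`fit_logistic()`) — binary endpoint after
  the 50-month adequate-follow-up rule (`eligibility_filter()`),
  `TD_p = (logit(p) − b₀)/b₁` with delta-method standard errors
  (`tolerance_dose()`), dose-response curves with horizontal SE bands
  and binned crude incidence (2.5-Gy intervals).
* **Actuarial incidence and cohort statistics** — patient-level
  Kaplan-Meier TLI-free survival with Greenwood errors
  (`kaplan_meier()`), crude rates, χ²/Fisher and Welch comparisons
  (`compare_categorical()`, `compare_continuous()`).
* **Synthetic cohorts with ground truth** (`generate_cohort()`) — a
  bilateral cohort generator with correlated left/right lobe doses,
  power-tail DVHs, a Weibull-baseline Cox generative hazard, and
  death/re-irradiation censoring, returning the true β and tolerance
  doses so every stage is testable without patient data.
* **Pipeline** (`run_ntcp_pipeline()`) — simulate or load a cohort,
  screen, fit both models, and write all tables as CSV/JSON artifacts;
  a thin CLI wrapper lives in `inst/scripts/ntcp_pipeline.R`.

## Worked example

```r
library(tlintcp)

sim   <- generate_cohort(cohort_config(n_patients = 400, seed = 7))
lobes <- sim$lobes

fit <- fit_cox(lobes, "d_1cc")
print(fit)
#> Cox dose-response model for d_1cc
#>   beta = 0.1368 /Gy (se 0.0298, z = 4.59, P = 4.45e-06)
#>   n = 800 lobes, 63 events

ph_test(fit)                      # PH global chisq = 1.76, P = 0.18

cox_tolerance_dose(fit, c(0.05, 0.1, 0.2, 0.5), t = 60)
#>      p   td   se
#> 1 0.05 62.6 1.54
#> 2 0.10 67.9 1.20
#> 3 0.20 73.4 1.81
#> 4 0.50 81.7 3.38

kaplan_meier(lobes)
#> Kaplan-Meier injury-free survival: 400 patients, 57 events
#>   S(36 months) = 0.922 (se 0.015)
#>   S(60 months) = 0.852 (se 0.023)

eligible <- eligibility_filter(lobes, window = 50)
tolerance_dose(fit_logistic(eligible, "d_1cc"), c(0.05, 0.2, 0.5))
#> Tolerance doses (Gy)
#>   TD5   =   58.2 +/- 1.9
#>   TD20  =   67.5 +/- 0.9
#>   TD50  =   75.8 +/- 2.1
```

The per-Gy log hazard (here 0.137 ± 0.030 against a generative value of
0.16) and the dose at 50% five-year failure probability (81.7 Gy against
a generative 80.0 Gy) are recovered from the simulated cohort; the Cox
(actuarial) and logistic (binary) routes give consistent tolerance
doses, with the logistic route slightly lower because its endpoint
accumulates risk over the whole follow-up rather than exactly 60 months.

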