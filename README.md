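# rppdecay

Bayesian modelling of **residual pneumoperitoneum (RPP)** — the CO₂ left in
the abdomen after laparoscopic surgery — as it resorbs over the first
post-operative week.

CT is the standard work-up for post-operative abdominal pain and is
exquisitely sensitive to free air; but free air after laparoscopy is usually
leftover insufflation gas, not a perforation. The clinically useful question
is therefore *how much gas is still expected on day d for a patient like this
one*. rppdecay answers it with a hierarchical censored log-linear decay
model fitted to serial CT volumetry (post-operative days — PODs — 3, 5, 7),
and turns the fit into a reference table of posterior-predictive 95%
intervals by BMI group and day.

## The model

With `y = log(V + 1)` (an exact 0 mL maps to 0) and `x_day = POD − 3`:

```
y_i  ~  N( α_{j[i]} + β_{j[i]} x_day,i + γ·normal + δ·overweight + η·obese , σ_y² )

(α_j, β_j)  ~  N( (μ_α, μ_β),  Σ ),   Σ_12 = ρ σ_α σ_β
```

Patient-specific intercepts α_j (log volume at the first scan) and slopes
β_j (decay rate per day) are correlated bivariate-normal; BMI-group dummies
shift the level (reference coding: γ ≡ 0). Recorded zeros are treated as
**left-censored** below the volumetric detection limit, not as exact values.
Sampling is MCMC via JAGS with a split-chain R-hat < 1.01 convergence gate;
equivalence testing of estimates uses the ROPE rule (95% HDI vs ±0.1
reference SD).

Because the underlying 31-patient cohort is not deposited, the package
includes a synthetic-cohort generator whose defaults are calibrated to the
published summary statistics (POD-3 mean 37.6 mL / median 9.58 mL, POD-5
mean 19.85 mL, POD-7 zero fraction 32.3%, BMI mean 26.59), including the
conditional follow-up design (a POD-5/7 scan only happens while gas was
still seen at the previous scan). Real data in the same CSV schema drop in
via `read_cohort()`. The vignette
(`vignettes/rpp-decay-modelling.Rmd`) documents the model, the calibration,
and the two published summaries that no model of this class can reproduce.

## Worked example

```r
library(rppdecay)

cohort <- simulate_cohort(generator_config(n_patients = 150, seed = 42))
summarize_cohort(cohort)
#>    variable             n  mean     sd median iqr_low iqr_high
#>  1 age                150  65.9   6.79  65.7   61.3      70.1
#>  4 bmi                150  26.0   3.84  25.9   23.0      29.0
#>  8 rpp_pod3_mL        150  36.0  89.4   11.1    2.88     39.1
#>  9 rpp_pod5_mL        150  13.3  19.4   4.96    0.922    16.7
#> 10 rpp_pod7_mL        150  13.0  38.5   1.26    0         8.58   (abridged)

anova_rpp(cohort)           # F = 12.9 on (2, 406) df, p = 3.6e-06
zero_rpp_fraction(cohort, 7)  # 0.313

fit <- fit_rpp_model(cohort, seed = 42)   # converged: TRUE
tidy(fit)
#>   parameter     mean    sd hdi_low hdi_high  rhat   ess
#> 1 mu_alpha     2.61  0.191   2.26     3.00   1.00  8309
#> 2 mu_beta     -0.343 0.037  -0.413  -0.267   1.00  3665
#> 8 sigma_y      0.839 0.062   0.721   0.959   1.00   640   (abridged)
```

The mean shifted-log volume at POD 3 is 2.61 (≈ 12.6 mL for a typical
normal-weight patient) and falls by 0.343 per day; the obese effect
η = −0.97 means obese patients carry roughly 60% less gas at equal days.
The clinician-facing output is the predictive table:

```r
make_credible_table(fit, seed = 42)
#>    bmi_group    pod lower_mL upper_mL
#>  1 normal         3        0    335
#>  5 normal         7        0    114
#> 11 obese          3        0    124
#> 15 obese          7        0     45.9   (abridged; 15 rows)
```

A volume above the upper limit for the patient's group and day is larger
than the model expects for an uncomplicated course. ROPE decisions on the
same fit: the decay slope and the obese effect are practically significant
(`reject_null`), the overweight contrast stays `undecided` at this sample
size.

`run_full_pipeline(run_config(), out_dir)` chains
simulate → descriptives → fit → predictive table → ROPE report and writes
every artifact plus a manifest (seeds, versions, config hash);
`recovery_experiment()` validates the sampler by refitting cohorts simulated
at known parameters. A thin CLI ships at `inst/cli/rpp.R`
(`simulate | report | fit | predict-table | recover | all`).

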