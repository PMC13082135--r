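# initsurv

Time-varying survival and causal models of adolescent substance-use
initiation.

`initsurv` is for epidemiologists and biostatisticians analyzing
longitudinal youth cohorts (ABCD-style designs: annual interviews plus
mid-year phone contacts over ~4 years) who want to move from visit-level
endorsement data to (1) time-varying Cox models of time to first substance
use and (2) marginal structural models for modifiable exposures. Because
such cohort data are access-controlled, the package also ships a synthetic
cohort generator with known causal ground truth, so the whole pipeline is
testable and demonstrable without any data access.

## What it implements

**Outcome derivation.** Harmonizes annual and phone endorsement sources by
an explicit visit-order key, coerces responses to {0,1} (invalid codes →
missing), masks endorsements flagged as exclusively religious-context,
takes the first affirmative visit as the initiation event (in months since
baseline), censors at the 4-year visit, and requires 3-year-visit
observation for control status.

**Counting-process intervals.** Converts visit records to start–stop rows
(`start_1 = 0`, `stop_i = t_{i+1}`, event on the final interval,
zero-length rows dropped, baseline row copied when the first visit is
late), with leakage-free forward fill (LOCF, never backward) and
value + availability encoding (`X_obs` indicator + median imputation) for
intermittently missing predictors.

**Time-varying Cox models.** For predictor X(t) and forced covariates C:

    h_i(t | X_i(t), C_i) = h_0(t) exp(β X_i(t) + γᵀ C_i)

fitted on `Surv(start, stop, event)` with Breslow ties and cluster-robust
(sandwich) standard errors by participant; univariate screens with BH-FDR
and Bonferroni control, coverage/evidence pre-selection, cross-validated
LASSO screening with participant-grouped folds, and a final site-stratified
multivariable model.

**MSM with stabilized IPTW.** Per exposure A (median-split if continuous),
stabilized weights

    SW_ik = ∏_{m≤k} P(A_im | A_i,m−1, Z_i, t_im) / P(A_im | A_i,m−1, Z_i, t_im, L_im)

with probability clipping and upper-quantile truncation, prevalence / mean
weight / effective-sample-size diagnostics, and a weighted pooled logistic
outcome model `logit P(Y_ik = 1) = α(t) + ψ A_ik + ηᵀ Z_i` (spline α(t),
participant-clustered robust SEs, BH across retained exposures).

## Worked example

```r
library(initsurv)

co <- generate_cohort(sim_config(n_participants = 1000, seed = 42))
co
#> synthetic_cohort: 1000 participants, 8221 visit rows, 9 visits scheduled
#> latent cumulative incidence:
#>   alcohol   0.3580
#>   nicotine  0.0430
#>   cannabis  0.0270
#>   other     0.0130
#> counterfactual marginal OR (alcohol): 2.844 (psi_true = 0.693)
```

The generator's event rates are calibrated to a large ABCD-like cohort
(~36.5% alcohol-like initiation over 4 years, ~5% nicotine-like). The
counterfactual OR is the total effect of sustained exposure — larger than
`exp(psi_true) = 2` because exposure also feeds back through the
time-varying confounder.

```r
outs <- derive_outcomes(harmonize_sources(co$long))
table(outs$alcohol$status)
#>    case control missing
#>     354     566      80
```

354 of 1,000 initiate; 80 non-initiators lack the 3-year observation
required for control status. Build intervals and screen predictors:

```r
long <- forward_fill(co$long, c("conf_ar", "par_monitor", "beh_x1"))
iv <- build_interval_table(long, outs$alcohol,
                           covariate_cols = c("conf_ar", "par_monitor", "beh_x1"))
iv <- attach_baseline(iv, co$baseline)
iv <- encode_value_availability(iv, c("conf_ar", "par_monitor", "beh_x1"))
scr <- screen_univariate(iv, c("conf_ar", "par_monitor", "beh_x1", "prs_1"),
                         forced_cols = c("sex", "baseline_age_months"))
scr[, c("predictor", "HR", "ci_low", "ci_high", "p", "q", "p_bonf")]
#>     predictor    HR ci_low ci_high        p        q   p_bonf
#> 1     conf_ar 1.365  1.265   1.472 1.08e-15 4.33e-15 4.33e-15
#> 2 par_monitor 0.827  0.756   0.905 3.52e-05 4.69e-05 1.41e-04
#> 3      beh_x1 0.983  0.901   1.072 6.99e-01 6.99e-01 1.00e+00
#> 4       prs_1 1.368  1.229   1.522 9.34e-09 1.87e-08 3.74e-08
```

The confounder and the PRS raise the hazard (HR ≈ 1.37), the
monitoring-like score is protective (HR ≈ 0.83), and the pure-noise
predictor is null — matching how the cohort was simulated. Causal analysis
on the reference feedback scenario (true exposure OR = 2):

```r
ivr <- simulate_msm_intervals(3000, psi_true = log(2), seed = 1)
msm <- run_msm_exposure(ivr, "A", z_cols = c("sex", "agez", "prs"),
                        l_cols = "L", type = "binary")
msm[, c("exposure", "OR", "ci_low", "ci_high", "p", "mean_w", "ess_ratio", "retained")]
#>   exposure   OR ci_low ci_high        p mean_w ess_ratio retained
#> 1        A 1.91   1.36    2.66 0.000159  0.964     0.604     TRUE
```

The IPTW estimate (OR 1.91, CI 1.36–2.66) covers the true value 2; the
mean stabilized weight near 1 and ESS ratio 0.60 indicate well-behaved
weights, so the exposure is retained for FDR control. An unweighted pooled
logistic adjusted only for baseline covariates is biased upward (≈ 2.9 on
average) in this scenario because the confounder both responds to and
drives exposure.

`run_pipeline(run_config(...))` chains all stages (simulate → outcomes →
intervals → QC → screen → LASSO → multivariable Cox → MSM) and writes TSV
result tables, a QC report, a log and a checksummed JSON manifest.

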