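---
title: "Time-varying survival and causal models of substance-use initiation: methods"
author: "initsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying survival and causal models of substance-use initiation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(initsurv)
```

# The analysis problem

Adolescent cohorts such as the ABCD Study follow children from about age 9–10
with annual in-person interviews and mid-year phone contacts, recording both
substance-use endorsements ("have you ever sipped alcohol?", "used an
e-cigarette?") and a large panel of time-varying environmental measures
(parenting, peers, sleep, mental health, ...) plus time-invariant covariates
(sex, baseline age, site, ancestry principal components, polygenic risk
scores). Two questions drive the analysis this package implements:

1. **Association.** Which time-varying and polygenic predictors are
   associated with the *hazard* of first substance use, treating initiation
   as a time-to-event outcome with covariates that change across visits?
2. **Causal exploration.** For modifiable exposures, what is the effect of
   the exposure on initiation risk once *treatment–confounder feedback* is
   accounted for — i.e. when a confounder (say, low parental monitoring)
   both influences and is influenced by earlier exposure?

Real cohort data of this kind are access-controlled. The package therefore
ships a synthetic cohort generator with known causal structure; every
modeling stage is exercised and validated against that ground truth.

# Outcome derivation

Per substance, initiation is the **first visit with any affirmative
endorsement** among a prespecified item set, after harmonizing the annual
and phone instruments into one table ordered by an explicit visit key
(baseline < 6-month phone < FU1 < ... < FU4). Responses are coerced to
{0, 1}; any other code (refuse, don't know) becomes missing. Alcohol and
nicotine endorsements flagged as occurring exclusively in religious or
ceremonial contexts are set to missing *before* aggregation so that, e.g.,
communion wine does not count as initiation.

Follow-up is censored at the 4-year visit (FU4). Event time is months since
baseline at the first affirmative visit; non-initiators are censored at
their last observed visit on or before FU4 and are *controls* only if they
were observed at the 3-year visit (FU3) — otherwise their case–control
status is *missing*, since "no endorsement" with little recent observation
is weak evidence of non-use.

Three decisions here were genuinely open:

* **Baseline endorsements** get event time 0.5 months rather than 0, because
  a zero-length follow-up contributes an empty risk interval. The offset is
  configurable (`baseline_event_time`).
* **Missing endorsements are skipped**, never treated as 0, when scanning
  for the first affirmative.
* A phone endorsement after the last annual visit but before a missing FU4
  is still counted if it is on or before FU4 in the visit order; censoring
  otherwise falls at the last observed contact.

# Counting-process intervals

Time-varying Cox models need start–stop ("counting process") rows: each row
is an interval [start, stop) with covariates frozen at its start and events
possible only at its end. For ordered visit times $t_1 < \dots < t_n$ and
follow-up time $T$:

$$\text{start}_i = \begin{cases}0 & i = 1\\ t_i & i > 1\end{cases}
\qquad
\text{stop}_i = \begin{cases}t_{i+1} & i < n\\ T & i = n\end{cases}$$

with the event indicator set on the final interval only, rows with
stop ≤ start removed, and — when the first observed visit falls after
month 0 — a baseline row at time 0 copying the earliest observation so all
participants share a common origin.

Covariate handling is designed to be *leakage-free*:

* **Forward fill (LOCF)** propagates observed values to later rows only;
  the package's metamorphic test perturbs single cells and asserts that no
  interval with an earlier start changes.
* **Value + availability encoding**: each intermittently missing predictor
  $X$ is split into an indicator $X_{\text{obs}}$ and an imputed value where
  missing cells receive the median of observed values. The median is pooled
  over all rows (the natural reading when no grouping level is specified);
  per-visit medians are available behind `per_visit = TRUE`. Imputation
  runs *after* forward fill, so the indicator marks cells no earlier
  observation could fill.
* Ties between an event time and a visit time resolve to the earlier
  visit's covariates (no look-ahead); times are kept as floating months.

# Predictor quality control

Minimal filtering, mirroring what one would do before a high-dimensional
screen: drop entirely missing columns, near-constant numeric columns
(modal frequency ≥ 0.99 — the threshold is a package default, there is no
canonical value), and one member of each pair with |Pearson r| > 0.9
(pairwise-complete). Collinear pruning is a single greedy pass over pairs
sorted by |r| descending, keeping the earlier column in input order — a
deterministic tie-break; permuting column order can change *which* member
survives but never *how many*. Forced covariates (sex, age, site, PCs) and
PRS columns are exempt from all filters. The pipeline is idempotent.

# Time-varying Cox models

## Univariate screen

For each candidate $X_i(t)$, the hazard is modeled as
$h_i(t) = h_0(t)\exp(\beta X_i(t) + \gamma^T C_i)$ with forced adjustment
covariates $C_i$. Fitting uses the counting-process partial likelihood with
**Breslow tie handling** and **cluster-robust (sandwich) variance**
aggregating score residuals within participant — repeated intervals from
one child are not independent. Breslow was chosen because ties are sparse
on a months scale and it matches a simple explicit oracle: the test suite
maximizes the hand-written Breslow partial likelihood numerically and
requires agreement with the fitted log-HR to 1e-6 on every small dataset it
generates.

Across the screen, Benjamini–Hochberg q-values and Bonferroni-adjusted
p-values are computed over the *converged* family; non-converging
predictors are reported with `converged = FALSE` and a logged count rather
than silently dropped. Site enters univariate models as an adjustment
covariate and the multivariable model as a stratum (both are available).

## Selection and the multivariable model

Dimensionality is reduced in three steps, each with explicit defaults:

1. **Pre-screen**: univariate p ≤ 0.05 (`p_enter`, configurable — no
   canonical threshold exists) *and* observed at least once in ≥ 50% of
   participants (baseline-only measures therefore survive).
2. **Cross-validated LASSO** (Cox family) as a screening device. Because
   coordinate-descent LASSO implementations do not handle late entry, the
   default treats each interval's *stop* as an independent right-censored
   time — an acknowledged approximation; exact (start, stop] risk sets are
   available via `use_start_stop = TRUE`. Folds are assigned to whole
   participants (10 folds, seeded) so clustering is respected; forced
   covariates are unpenalized; the penalty minimizing cross-validated
   deviance is used (1-SE rule behind `one_se = TRUE`).
3. **Final model**: one site-stratified counting-process fit containing the
   selected predictors, their availability indicators, the forced
   covariates and all PRS, with cluster-robust SEs and BH/Bonferroni over
   the selected set. Constant columns (e.g. an all-ones availability
   indicator) are dropped with a warning, never returned as NaN.

# Marginal structural models with stabilized IPTW

For a binary time-varying exposure $A_{ik}$ (continuous exposures are
median-split among observed values, ties to 0), the stabilized weight is

$$SW_{ik} = \prod_{m=1}^{k}
\frac{P(A_{im} \mid A_{i,m-1}, Z_i, t_{im})}
     {P(A_{im} \mid A_{i,m-1}, Z_i, t_{im}, L_{im})},$$

estimated by two logistic regressions per exposure (prior treatment is 0 at
each participant's first interval). Fitted probabilities are clipped to
[0.01, 0.99] and weights truncated at the 0.99 quantile by default — the
mechanisms are standard positivity safeguards; the numbers are package
defaults, configurable and logged, not field constants. The outcome model
is a weighted pooled logistic regression

$$\text{logit}\,P(Y_{ik} = 1) = \alpha(t_{ik}) + \psi A_{ik} + \eta^T Z_i$$

with participant-clustered robust SEs; with rare per-interval events the
exposure odds ratio approximates a hazard ratio. $\alpha(t)$ is a
restricted cubic spline with 4 knots at the 5/35/65/95 percentiles of
interval end times, degrading to a linear term when the time grid is too
coarse. The current exposure value enters the outcome model
(cumulative-exposure MSMs are out of scope), the denominator uses the same
leakage-free forward-filled confounder values as the Cox stage, and
exposures failing any of the predefined diagnostics — person-interval
prevalence outside [0.05, 0.95], mean weight outside [0.9, 1.1], ESS ratio
$(\sum w)^2 / (n \sum w^2) < 0.5$ — are excluded from outcome modeling and
from the BH family.

# The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws, per participant: sex, site, baseline age
$\sim N(118.9, 7.4)$ months (12 × (9.91 ± 0.62) years), 20 PCs and 4 PRS
(standard normal); a confounder following
$L_k = \rho L_{k-1} + \kappa A_{k-1} + \varepsilon_k$ (AR(1) with exposure
feedback, $\rho = 0.6$, $\kappa = 0.4$); a binary exposure
$A_k \sim \text{Bern}(\text{expit}(a_0 + a_1 L_k + a_2 A_{k-1} + a_3^T Z))$;
auxiliary AR(1) predictors and a monitoring-like score negatively tied to
$L$; and per-substance discrete-time events with logit
$\alpha_0 + \alpha_1 t + \psi A_k + \delta L_k + \eta^T Z$. Visits run
every 6 months from 0 to 48 (annual + mid-year contacts). Endorsement
items switch on at the event visit and persist; a small fraction of first
alcohol/nicotine endorsements (5%) carry a religious-context flag.
Missingness is MCAR — per-cell (10%) and per-visit dropout (10%, baseline
always retained; monotone dropout behind a flag) — because the emulated
design reports no missingness mechanism.

The per-outcome intercepts were calibrated once by Monte Carlo (n = 2×10⁵)
so that cumulative incidence over the 8 intervals is ≈ 36.5% for the
alcohol-like outcome, 5.44% nicotine-like, 3.42% cannabis-like and ≈ 1%
for other substances, matching the emulated cohort's event rates; the
solved values are frozen in `default_base_hazard()`.

The ground-truth object reports $\psi$ and a counterfactual marginal odds
ratio computed by re-simulating 10⁵ participants (seed offset +1) under
sustained do(A = 1) versus do(A = 0). Note that this is the *total* effect
of a sustained regime: with feedback ($\kappa \ne 0$) it includes the path
through $L$ and exceeds $e^\psi$; only with $\kappa = 0$ and rare events
does it converge to $e^\psi$ (odds ratios are non-collapsible otherwise,
which is why default per-interval probabilities are kept small).

**The reference feedback scenario** (`simulate_msm_intervals()`) is the
testbed for causal recovery: $a_1 = 0.7$, $a_2 = 0.2$, $\kappa = 0.2$,
$\delta = 0.4$, per-interval event logit −5. These values were chosen so
that (i) confounding is strong enough that the naive baseline-adjusted
pooled logistic is visibly biased (≈ +0.35 on the log-OR), while (ii) the
exposure-history effect mediated through $L$ ($\kappa\delta$) is small
enough that the current-exposure-only MSM is essentially correctly
specified and IPTW recovers $\psi$ (residual bias ≈ +0.01), and (iii)
weights stay well-behaved (ESS ratio ≥ 0.51 across clip ∈ {0.001, 0.01}
and truncation quantile ∈ {0.99, 0.995}). A scenario with large
$\kappa\delta$ would need a treatment-history MSM, which is deliberately
out of scope.

What the generator does **not** emulate: real instrument item content,
genotype/LD structure (PRS are plain normals), informative missingness,
site-level heterogeneity in event rates, and measurement error. Passing
tests therefore demonstrate that the *engines* are correct under known
structure, not that any particular real-data finding would replicate.

# Numerical choices

* Cox fits: Breslow ties, convergence tolerance 1e-10, 50 iterations max;
  non-convergence and infinite-coefficient warnings surface in the result.
* Normal-quantile 95% CIs throughout (1.959964).
* Weight products are computed on the log scale and re-exponentiated.
* The BH step-up and Bonferroni adjustments use the standard closed forms;
  tests verify them against an independently coded step-up.
* All simulations are seeded; the pipeline fans a single seed out to stages
  by fixed offsets, so a run is reproducible end to end (the manifest
  records output checksums).

# Problem sizes used in validation

The shipped validation suite uses cohorts of 60–6,000 participants,
50-replicate recovery studies at n = 2,000 (Cox, HR = 1.5), 100 replicates
at n = 3,000 (IPTW recovery, OR = 2), 200 replicates at n = 1,000 (causal
null calibration), and 500 permutation refits at n = 2,000 — sizes chosen
to keep Monte-Carlo error well below the assertion tolerances while
remaining fast on a single core.

# Known limitations

* The LASSO screening step ignores late entry by default (documented
  approximation; exact mode available but slower and not the default used
  in validation).
* IPCW for informative censoring, doubly robust estimators, g-computation,
  continuous-treatment MSMs, time-varying coefficients and
  proportional-hazards diagnostics are out of scope.
* Cluster-robust inference is asymptotic in the number of participants;
  with very few participants (or very few events per stratum) the robust
  SEs and the pooled-logistic approximation both degrade.
* The median-split exposure definition discards within-person dose
  information; availability indicators capture missingness structure but
  not informative missingness.
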