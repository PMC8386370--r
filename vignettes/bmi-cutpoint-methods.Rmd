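---
title: "Methods: BMI cut points for comorbidity incidence in EHR data"
author: "bmicutpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BMI cut points for comorbidity incidence in EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmicutpoints)
```

## The question

Obesity-related comorbidities — type 2 diabetes, hypertension,
obstructive sleep apnea and others — become more frequent as BMI rises,
but screening guidelines need a *threshold*: a BMI beyond which the
near-term risk of developing the disease is high enough that screening
is worthwhile. This package operationalizes that question for
longitudinal EHR data. BMI at an index visit is treated as a screening
test for one-year disease incidence, and the cut point is the BMI value
that best separates patients who developed the disease within a year
from those who did not, provided BMI discriminates at all.

## The estimator

For a comorbidity with incident indicator $y_i \in \{0,1\}$ and baseline
BMI $b_i$, the screening rule "positive when $b \ge t$" has, at each
threshold $t$,

$$\mathrm{Se}(t) = P(b \ge t \mid y = 1), \qquad
  \mathrm{Sp}(t) = P(b < t \mid y = 0).$$

The ROC curve is swept over the *observed* BMI values (plus
$\pm\infty$ sentinels); the AUROC is the trapezoidal area, which equals
the Mann–Whitney concordance $P(b_{case} > b_{ref}) + \tfrac12 P(tie)$ —
an identity the test suite verifies exactly against an $O(n^2)$
pairwise count. A cut point is *defined* only when AUROC strictly
exceeds a discrimination gate, 0.6 by default; otherwise the result is
reported as "not defined" rather than dropped. When defined, the cut
point is the observed BMI maximizing the Youden index
$J = \mathrm{Se} + \mathrm{Sp} - 1$, with ties broken toward the
*smaller* BMI (the conservative choice for screening: it flags more
patients).

Design choices worth making explicit, since any of them could be made
otherwise:

* **Orientation.** The test is one-sided in BMI (positive means
  *at or above* the threshold). This is the screening direction for
  obesity-related disease.
* **Threshold set.** Only observed BMI values are candidates. The
  estimand "the BMI value that maximized the Youden index" is then
  always an attained value, and the estimator needs no grid.
* **Strict gate.** `defined` is exactly `auroc > gate`; a comorbidity at
  the gate is not defined. The gate is configurable
  (`pipeline_config(gate = ...)`).

## Cohort and case definitions

Eligibility requires a BMI-bearing index visit with another visit at
least 365 days before and at least 365 days after it. The look-back
window identifies prevalent disease (any matching code dated at or
before the index visit — a closed boundary); the follow-up window
defines incidence (first matching code in the half-open interval
(index, index + 365 d]). Each at-risk patient contributes exactly one
person-year, because the design guarantees observation through the
follow-up year; the rate per 100 person-years is therefore
100·incident/at-risk, i.e. the one-year cumulative incidence scaled.
There is no censoring model — nothing in the fixed-window design
supports one.

"One year" is read as *at least* 365 days on both sides. The text this
design follows is ambiguous between "exactly" and "at least"; the
at-least reading is the one under which the follow-up visit guarantees
the full incidence window is observed.

Patients with several candidate index visits have one selected uniformly
at random from a stream keyed on (seed, patient id) — a deterministic
hash, not the global RNG — so cohort membership is invariant to the
order in which rows arrive and reproducible across runs. Code matching
is prefix-based over normalized (uppercased, dot-stripped) ICD strings;
`"E11"` matches `"E11.9"` and `"e119"` alike. Exact-list matching is a
switch (`match_codes(..., exact = TRUE)`).

## Anthropometric cleaning

Cleaning is per patient and single pass, in the spirit of longitudinal
plausibility cleaning of adult EHR anthropometrics:

1. absolute bounds: heights outside (44, 90) in, weights outside
   (55, 1000) lb;
2. on the survivors of step 1, computed once per patient: heights more
   than 1 SD from the mean when SD > 2.5% of the mean; weights more than
   70% of the range from the mean when range ≥ 50 lb, and more than 1 SD
   from the mean when SD > 20% of the mean.

Conventions the source text leaves open, fixed here and tested:

* statistics are computed *within* each patient's series, not over the
  whole EHR — the rules are meant to find entries inconsistent with the
  patient's own history;
* sample SD (n − 1); a single-measurement series has SD 0, so the
  conditional rules never fire;
* strict inequalities: a value exactly 1 SD from the mean, or exactly at
  70% of the range, is kept;
* no iteration: the dispersion statistics are not recomputed after
  removals. The map is therefore idempotent on its own output only when
  the rule triggers are stable — re-cleaning can in principle remove
  more once a gross outlier no longer inflates the SD. The single-pass
  convention is deterministic and matches the rule order as stated.

Missing heights are filled from the most recent previous valid height,
then any still-missing from the next subsequent valid height; weights
are never imputed. Cleaning removes measurements, never patients.

On the generator's default corruption model (unit confusions: heights
entered in cm, weights in kg; first-two-digit transpositions), the rules
remove over 90% of injected errors while flagging under 2% of
uncorrupted values — a property of these rules on this corruption model,
asserted in the tests, not a clinical claim.

## Median regression

Differences in median baseline BMI between incident and reference
patients are estimated by quantile regression at τ = 0.5, minimizing the
check loss $\sum_i \rho_{0.5}(y_i - x_i^\top\beta)$. The solver is
iteratively reweighted least squares on $1/\max(|r|, \varepsilon)$
weights, followed for small problems by exact vertex polishing: an
optimum of the check loss is attained at a coefficient vector
interpolating $p$ observations, so the best subsets among the smallest
IRLS residuals are solved exactly and the loss-minimizing vertex is
returned. Correctness is defined by loss agreement with a brute-force
enumeration oracle (tested to 1e−6), not by solver identity. In the
two-group unadjusted model the estimate is computed as the difference of
group medians — an algebraic identity of that model, asserted exactly.

The adjusted model enters age linearly and sex, race/ethnicity and
smoking as reference-coded indicators (references: female, White
non-Hispanic, non-smoker — fixed so results are reproducible). The 95%
CI is a seeded percentile bootstrap over patients (1000 resamples by
default). The source analysis does not state its CI construction; the
bootstrap is this package's declared choice, kept uniform with the
cut-point comparisons.

## Bootstrap comparison of cut points

Two cut points (by sex, by race/ethnicity, or incidence vs prevalence)
are compared by resampling patients with replacement within each sample,
recomputing both cut points per resample, and forming
$\Delta_b = \hat t_a^{(b)} - \hat t_b^{(b)}$. The two-sided p-value uses
the add-one correction
$p = 2\min\{\#(\Delta \le 0) + 1,\ \#(\Delta \ge 0) + 1\}/(B + 1)$,
clamped at 1. Resamples in which a side fails the AUROC gate or loses a
class are redrawn up to a cap (20) and then counted as missing with a
warning. Resampling is unstratified by default — the source does not say
whether its resampling preserved class counts — with a stratified switch
(`stratified = TRUE`). The prevalence-based analysis takes prevalent
patients as positives against *all* non-prevalent cohort members
(including later incident cases); the alternative (excluding incident
cases) is a stricter contrast the source does not specify.

Calibration is checked by simulation (see *Simulation sizes*): under
identical generators the rejection rate at α = 0.05 stays within
[0.01, 0.10], and a 6 kg/m² true separation at 10,000 patients per group
is detected with power above 0.8.

## The synthetic generator

`simulate_ehr()` emulates roughly a decade of adult primary care:

* **Visits.** Per-patient Poisson counts (1.5/patient-year by default)
  at uniform dates strictly inside the window.
* **Anthropometrics.** Constant true height (sex-specific normal), and a
  latent BMI trajectory: lognormal intercept (mean ≈ 29, SD ≈ 7 kg/m²,
  matching a contemporary US adult case mix), slow linear drift
  (SD 0.15 kg/m²/yr), and visit-level noise (SD 0.5 kg/m²). Recorded
  weights derive from latent BMI; heights and weights are rounded to
  0.5 in and 0.1 lb.
* **Corruption.** Heights go missing (30% by default — heights are
  recorded far less often than weights); heights and weights receive
  gross entry errors (0.5% each): unit confusion (cm as inches, kg as
  pounds) or transposition of the leading digits.
* **Disease.** Baseline prevalence is logistic in BMI and age. One-year
  incidence among disease-free patients follows
  $\mathrm{logit}(p) = \mathrm{logit}(p_0) + \delta\,[b \ge \theta]
  + \beta_{age}(age - 45)$, simulated year by year on the latent BMI —
  a *hard step*, so a true cut point exists by construction (a smoothed
  logistic ramp is a config switch). Diagnosis codes are emitted at or
  shortly after onset; prevalent disease emits a code early in the
  window, before any possible index date.
* **Exclusions.** Configurable fractions of pregnancy codes (among
  female patients), cancer codes, and registry membership.

The defaults (demographic mixture, age distribution, base rates,
thresholds between 28.5 and 31 kg/m²) describe a plausible adult
US-health-system population; they are the generator's study conditions,
not fitting targets. What the generator does **not** emulate — and what
passing tests therefore cannot certify about real data: correlated
comorbidities, realistic ICD ontologies and coding error, visit patterns
that depend on health status, secular BMI trends, enrollment gaps, or
differential missingness. Recovery results on synthetic data bound the
estimator's behavior under the stated model only.

A consequence worth knowing: the step sits in *latent* BMI, while the
analysis sees measured BMI (noise + rounding + cleaning). Recovered cut
points are therefore slightly attenuated toward the bulk of the data —
a few tenths of a kg/m² at the default noise levels — which is exactly
the behavior one should expect with real measurement error.

## Simulation sizes and numerical choices

The verification suite uses problem sizes chosen to make the checks
sharp at desk scale: 20 end-to-end generator replicates of 20,000
patients for threshold recovery (median absolute error ≤ 0.5 kg/m² at
δ = 3, θ = 30); 20 replicates of 20,000 for gate rejection under δ = 0;
200 replicates × 200 resamples at 2,000 patients per group for the
type-I error of the bootstrap comparison, and 40 replicates at 10,000
per group for its power. The oracle checks (pairwise-concordance AUROC,
check-loss enumeration) run on instances of at most 200 and 50 points
respectively, where brute force is exact and fast.

Other numerical conventions: BMI is 703·lb/in² to double precision;
Youden ties break to the smaller BMI; `which.max` on the threshold sweep
implements that tie rule because thresholds ascend; the IRLS smoothing
floor is 1e−8 with convergence at 1e−10 on coefficients; degenerate
inputs (single-class outcomes, empty at-risk sets, all-missing heights)
return typed "undefined" markers or errors as documented per function,
never silent NA propagation.

## Limitations

The cut-point estimator inherits the known fragilities of
Youden-maximizing thresholds: it is a non-smooth argmax, so individual
estimates carry more sampling noise than the AUROC itself, and bootstrap
inference for it is approximate. The fixed one-person-year convention is
only as good as the design guarantee behind it; data without an assured
follow-up visit would need person-time and censoring handling this
package deliberately does not provide. Prefix-based code matching is as
good as the supplied code sets; the bundled sets are deliberately small
toy defaults for the synthetic generator, not a curated phenotype
library.
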