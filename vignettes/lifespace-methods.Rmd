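---
title: "Methods: GPS life-space excursions, falls, and visual-field staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS life-space excursions, falls, and visual-field staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lifespacer)
library(dplyr)
```

`lifespacer` implements a complete analysis pipeline for prospective
cohort studies that ask whether falling changes how much older adults —
here, adults with glaucoma or suspected glaucoma — travel away from home.
The pipeline has four scientific stages, each usable on its own: (1)
quantification of away-from-home excursions from minute-epoch GPS traces,
(2) prospective fall-status classification from monthly falls calendars,
(3) binocular (integrated) visual-field staging from paired-eye 24-2
sensitivities, and (4) negative binomial and GEE regression linking fall
status to the excursion parameters. A synthetic cohort generator with
known latent truth makes all of it testable without access to any
participant data.

## Excursion quantification

Participants wear a GPS logger for 7 consecutive days at two visits
(baseline and one year later); the device records latitude/longitude once
per minute. The stage proceeds:

* **Deduplication.** Timestamps are truncated (never rounded) to the
  whole minute; if a minute carries several fixes the first is kept with
  a warning. All timestamps live in one fixed study-site clock with no
  DST handling.
* **Home anchoring.** The home anchor is the componentwise median of all
  fixes recorded between 02:00 and 04:00 (half-open window), pooled over
  the week. The median is robust to GPS jitter and a night or two spent
  away; a trace with no night-window fixes is rejected by name rather
  than guessed at. Pooling across the week (rather than anchoring each
  night separately) was an open choice; pooling was selected because a
  single household location is the estimand and pooling maximises the
  sample behind the median.
* **Home margin.** A fix is *home* iff its great-circle distance to the
  anchor is ≤ `radius_m` (default 50 m). The boundary is inclusive: a fix
  at exactly 50 m is home. Distance is haversine on a sphere of radius
  6,371,000 m, adequate at these scales (sub-millimetre error over tens
  of meters).
* **Valid-day QC.** A calendar day is *valid* when fixes cover at least
  80% of the 960 minutes between 06:00 and 22:00 (half-open; the
  threshold is inclusive, so 768 minutes qualify). Participants need at
  least 2 valid days per week to enter the analysis.
* **Segmentation.** Within each calendar day, each maximal run of
  away-labeled minutes is one excursion. Unobserved minutes carry no
  label and contribute no away time; by default any unobserved minute
  breaks a run (`gap_bridge_min = 0`), because the source protocol
  states no imputation. A configurable bridge may merge away runs
  separated only by ≤ `gap_bridge_min` missing minutes — to tolerate
  GPS dropout inside buildings — in which case the bridged minutes count
  toward the duration. Excursions in progress at midnight are split at
  the day boundary: the weekly parameters are day-normalised and the QC
  filter is day-based, so this only affects rare overnight trips. A
  minimum duration (default 1 minute) filters jitter-length episodes.
* **The three parameters**, averaged over valid days only: average
  number of daily excursions; average daily time away from home (hours);
  average time per excursion (hours, undefined when the week has no
  excursions). Away minutes outside 06:00–22:00 on a valid day still
  count — the window defines validity, not the measurement. The identity
  `daily time away = daily excursions x time per excursion` holds by
  construction whenever excursions exist.

## Falls ascertainment

Participants return monthly calendars marking each day fallen/not;
calendars not returned within the collectibility horizon are *missing*
months. Injury information comes from a per-fall follow-up interview, so
the injury flag lives on the fall event, not the calendar. Classification
over the follow-up year: *faller* (≥ 1 fall), *recurrent faller* (> 1),
*injurious faller* (≥ 1 injurious fall), *recurrent injurious faller*
(> 1 injurious fall). Status is computed from observed months only and
participants are retained regardless of how many months are missing (no
exclusion rule is stated in the source protocol); `n_missing_months` is
reported so sensitivity analyses remain possible. Cohort percentages are
rounded half-up to one decimal.

## Integrated visual field

Per-eye 24-2 fields (54 locations; the two blind-spot points at
(15, ±3)° are excluded) are combined into a binocular *integrated visual
field*: the left-eye field is mirrored to right-eye orientation
(x → −x), spatially corresponding points are matched, and the maximum
sensitivity of each pair is taken — the better eye dominates each
location, approximating binocular viewing. Mean sensitivity averages on
the linear (1/Lambert) scale, `10^(dB/10)`, and transforms back:
`MS = 10 log10(mean(10^(dB/10)))`; by Jensen's inequality this is never
below the arithmetic dB mean. Severity uses
Hodapp–Parrish–Anderson-derived cuts on integrated mean sensitivity:
none-to-mild ≥ 28 dB, severe ≤ 23 dB, moderate strictly between. The
`10^(dB/10)` convention and blind-spot exclusion are declared choices
(the source describes the procedure without printing formulas); both are
configurable. Monocular records are an error by default — the cohort
design tests both eyes.

## Statistical models

The published analysis treats the three weekly averages as continuous
outcomes in negative binomial models. A coherent NB likelihood needs
integer counts with exposures, so each outcome is encoded as a total
with a log-exposure offset:

| outcome | total | offset |
|---|---|---|
| daily excursions | excursions over valid days | log(valid days) |
| daily time away | away minutes over valid days | log(valid days) |
| time per excursion | away minutes | log(total excursions) |

Zero-excursion weeks contribute no time-per-excursion row (the quantity
is undefined for them). This encoding keeps the incidence-rate-ratio
reading of `exp(coef)` while the likelihood stays well-defined; the
original encoding is unstated, so this one is declared, not inferred.

* **NB IRR models** (`fit_excursion_nb`): log-link NB2 via
  `MASS::glm.nb`, dispersion by maximum likelihood, one binary
  fall-status exposure at a time, Wald 95% CIs and two-sided p-values.
  Multivariable models adjust for age (years), sex, race (Black vs
  other), IVF mean sensitivity, comorbidity (> 1 illnesses) and
  polypharmacy (≥ 5 prescribed medicines) — the adjustment set named by
  the published model footnote. There is no multiplicity adjustment,
  mirroring the "multiple independent models" design.
* **Severity interaction** (`fit_excursion_nb_interaction`): adds
  exposure × severity terms and reports a joint Wald chi-square p-value
  (2 df) for whether the fall-status IRR varies across the severity
  spectrum.
* **GEE over visits** (`fit_excursion_gee`): marginal log-link count
  model over both visits, clustered by participant. No GEE
  implementation ships in this environment's R stack, and the marginal
  model is the inferential core of the repeated-visits question, so the
  Liang–Zeger estimator is implemented in the package: exchangeable
  working correlation estimated by moments from Pearson residuals,
  NB2 variance with the dispersion fixed at the pooled ML estimate, and
  robust (sandwich) standard errors. Convergence: maximum coefficient
  step < 1e-8, at most 200 iterations; the working correlation is
  clamped to its feasible range. With one observation per cluster the
  estimating equations collapse onto the GLM score — the test suite
  exploits this independence limit as an exact oracle. The
  visit × fall-status interaction (visits coded 1 and 2) tests whether
  the baseline-to-year-1 change differs by fall status.

## The synthetic cohort generator

`cohort_scenario()` fixes the study conditions; `simulate_cohort()`
draws a cohort with a latent-truth side channel that never feeds the
pipeline. Defaults emulate the cohort the pipeline was built for:

* 192 participants, two 7-day GPS weeks, 12 calendar months.
* Fallers: 45.3% of participants; fallers' extra falls are Poisson with
  mean 0.575, giving P(> 1 fall | faller) ≈ 0.44 (the published
  recurrent fraction); each fall is injurious with probability 0.552
  (the published per-fall injury share).
* Excursions: daily counts Poisson with mean 2.5 × a mean-1 gamma
  frailty per participant (shape 2.5). The frailty makes weekly counts
  negative binomial — between-person heterogeneity is what justifies NB
  regression, and without it the NB dispersion estimate diverges.
  Durations are log-normal with median 90 minutes (log-sd 0.8), placed
  without overlap inside 06:00–22:00 with at least one home minute
  between episodes. Away positions follow a random walk around a point
  300–1,500 m out, radially clamped to stay > 200 m from home, so
  planted labels are unambiguous relative to the 50-m margin —
  margin-straddling behaviour is tested with crafted fixtures instead.
  The 02:00–04:00 night window is always generated at home, keeping the
  home anchor identifiable.
* Fall effect: fallers' year-1 rate is multiplied by
  `irr_fall_on_excursions` (default 1 — the null the study reported),
  giving exact parameter-recovery targets for the inference stage.
* Missingness: whole days unrecorded with probability 0.12 (matching
  ~5.7 valid days per week); individual *home* minutes dropped with
  probability 0.05. Minute dropout is modelled at home because its real
  mechanisms — non-wear while sleeping or bathing, indoor signal loss —
  happen there, while a device out on an excursion is outdoors and keeps
  its fix. Away-minute dropout is still fully handled by the analysis
  (gap bridging) and exercised by the label-string oracle suites.
* Vision: latent per-eye sensitivity N(24, 3.2²) dB; the pointwise-max
  integration adds about +3.6 dB, centring integrated mean sensitivity
  near 28 dB with a study-like spread.
* Covariates drawn to the published margins (age 70.1 ± 7, 50.5% male,
  28.1% Black, 63% with > 1 comorbidity, 30.7% polypharmacy).

What the generator does **not** emulate: street networks or destination
structure, accelerometry, bursty or spatially correlated GPS error,
seasonal behaviour, fear-of-falling feedback on mobility, or informative
missingness. Passing tests therefore certify the *algorithms* —
segmentation equals its oracle, planted parameters are recovered
exactly, model estimates are calibrated — not that real GPS data are
this clean.

`simulate_analysis_rows()` draws model-ready rows directly (gamma
frailty shared across visits, so the two visits are exchangeably
correlated) for Monte-Carlo calibration of the inference stage without
paying for GPS simulation.

## Numerical choices and degenerate inputs

* Intervals: night window [02:00, 04:00), day window [06:00, 22:00);
  coverage compares `n/960 >= 0.8` exactly.
* Quantiles for medians/IQRs: type 7 (linear interpolation).
* Percentages: round half away from zero, one decimal.
* Model convergence: `glm.nb` and the GEE both use epsilon 1e-8 and 200
  iterations; GEE sandwich variances are reported regardless of the
  working-correlation estimate.
* Errors, not guesses: constant exposures, all-zero outcomes,
  single-level severity, monocular fields, missing grid locations,
  unmatched identifiers and home-less traces all abort with the
  offending records named. A GEE asked for exchangeable correlation with
  no repeated observations warns and reduces to independence.
* Determinism: a scenario plus seed reproduces a byte-identical bundle;
  the pipeline is deterministic given its inputs.

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to balance Monte-Carlo
error against runtime on a single CPU: segmentation is compared with a
brute-force run-length oracle on 10,000 random label strings (lengths up
to 2,000 minutes, spanning midnight); planted-truth recovery uses 500
noiseless participant-weeks; NB calibration uses 500 null replicates of
n = 500 and recovery 200 replicates per planted IRR ∈ {0.5, 1.5, 2}; the
GEE interaction recovery uses 200 replicates of 500 participants × 2
visits. Tighter Monte-Carlo bounds simply need larger replicate counts.

## Known limitations

* The excursion definition is purely geometric; trips that stay within
  50 m of home (e.g. gardening) are invisible, and two distinct
  destinations visited without returning home form one excursion.
* Exchangeable working correlation is the only GEE structure provided —
  with two visits per participant it is also fully general.
* The NB encoding of the time outcomes treats minutes as counts;
  alternative encodings (e.g. gamma models) would answer slightly
  different questions and are out of scope.
* Covariates are carried, never imputed; participants missing any model
  variable drop out of the affected models.
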