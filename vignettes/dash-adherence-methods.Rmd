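---
title: "Methods: the DASH adherence index, feedback engine, and trial analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DASH adherence index, feedback engine, and trial analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dashtrack)
```

## Overview

`dashtrack` implements the computational core of an mHealth intervention
built around app-based diet tracking and the DASH (Dietary Approaches to
Stop Hypertension) dietary pattern: scoring daily nutrient intakes against
DASH standards, composing and scheduling tailored feedback text messages,
summarizing self-monitoring engagement, filtering 24-hour dietary recalls by
protocol validity, and analyzing a two-arm randomized trial of such an
intervention. A synthetic-cohort simulator generates data under known
parameter values so that every analysis path can be validated by parameter
recovery rather than against undeposited participant data.

## The nutrient-based DASH adherence index

The index scores one day of intake on nine nutrients. Because nutrient needs
scale with energy intake, raw amounts are first standardized to
calorie-relative bases:

* **Percent of energy** for total fat, saturated fat, and protein, using
  Atwater conversion factors of 9 kcal/g (fat) and 4 kcal/g (protein).
  The reported total energy is used as the denominator as printed by the
  tracking instrument; no attempt is made to re-derive energy from
  macronutrients (alcohol and rounding make the reported total the more
  faithful base).
* **Density per 1000 kcal** for cholesterol, fiber, magnesium, calcium and
  potassium: `amount x 1000 / energy`.
* **Absolute mg/day** for sodium, matching how the DASH sodium standard is
  expressed (< 2400 mg per day) even though the other minerals are scored
  as densities.

Each standardized value earns a credit of 1 (full target met), 0.5
(intermediate threshold met), or 0, and the nine credits sum to the 0-9
daily total; 9 is full adherence. The full targets are the published DASH
nutrient standards:

```{r}
dash_targets()
```

Two numerical choices deserve mention:

* **Intermediate thresholds.** The half-credit cutoffs used by the original
  deployment are not published. The package defaults to 2/3 of the target
  for "more is better" nutrients and 1.5 times the target for "less is
  better" nutrients: a simple, monotone, direction-consistent rule. Every
  threshold can be overridden per nutrient through the targets file, and the
  shipped default file reproduces the table above at full double precision
  (it round-trips bit-exactly, which the test suite asserts).
* **Boundary ties.** The standards are printed as strict inequalities
  ("<27%", ">14.8 g/1000 kcal"), which leaves the boundary value undefined;
  scoring must be total, so ties resolve toward the better credit (a fiber
  density of exactly 14.8 earns 1). Totals are sums of halves and are never
  rounded.

Days with incomplete nutrient data are never scored. The original platform
had dietitians back-fill missing database nutrients by hand; an automated
re-implementation cannot reproduce that, so incomplete records are flagged
with a per-field validation report and excluded, and the feedback engine
receives an explicit "no score" token rather than a zero.

## Feedback messages and cadence

Feedback follows the study cadence: a daily message at 12:00 study time
(America/New_York, DST-aware) for study days 1-14, then one weekly message
for the remainder, plus a topic message with a video link every Sunday
afternoon (15:00 by default; no clock time is published for the topic
messages, so it is configurable). Weekly messages are sent on the
enrollment weekday and summarize the mean score over the preceding seven
days' valid tracked days — whether the live system reported a single day or
an aggregate is not documented, and an aggregate is the more defensible
summary of a week. Under a 90-day study this yields 14 daily and 10 weekly
messages, the first weekly send falling on study day 22 (the first
enrollment-anniversary weekday after the daily period, covering days
15-21).

A message body contains a personalized greeting, the previous day's score
to one decimal, a sentence naming up to two "best" components (full-credit,
closest call to the target first) and up to two "struggle" components
(zero-credit, furthest from the target first, with half-credit components
backfilling unfilled slots — struggle picks first so the lists never
overlap), and one behavioral tip aimed at the top struggle component.
"Distance" is relative: `|value - target| / target`, which makes
percent-of-energy and density components comparable. Tips and topics ship
as editable YAML banks and are selected by deterministic cycling on the
study day, never randomly, so message fixtures are stable. Untracked days
get a tracked-nothing prompt instead of a score. Inbound texts from
enrolled participants receive a single fixed auto-reply pointing to staff
email; auto-replies are never themselves answered, and unknown senders are
logged and dropped.

## Engagement and recall validity

A **valid tracked day** is a day with any submitted log and at least 600
kcal of reported energy; day blocks are anchored at each participant's
randomization date (calendar-week anchoring is the alternative, but the
protocol describes per-participant follow-up windows, so
randomization-anchored 7-day blocks are used). Partial terminal weeks are
excluded from the per-participant mean. Engagement trends are fit with a
random-intercept linear mixed model (`lme4`) of weekly valid-day counts on
continuous time in weeks, arm, and their interaction. The published model
specifies an unstructured residual covariance; `lme4` supports only
independent residuals around a random intercept, which the design allows as
a documented fallback — the `diagnostics` element of the fit records
`residual_structure = "independent"`, and the contract is the fixed-effect
estimates and their Wald confidence intervals. For degenerate zero-variance
panels the mixed-model covariance is singular and the OLS covariance of the
same fixed-effect structure is substituted (flagged as `vcov_fallback`).

A **valid recall set** contains at least two recalls covering one weekend
day and one weekday, collected no more than 14 days apart, with mean energy
in [600, 3500] kcal. When more than two recalls exist the earliest weekend
and earliest weekday recall form the assessed pair (the protocol is silent
here; earliest-first is deterministic and favors the recalls closest to the
scheduled window), and the energy rule applies to the recalls used, not all
submitted. All five rules are always evaluated and failures accumulate as
named reasons rather than errors.

## Trial analysis

Within-arm change from baseline to three months is the paired
repeated-measures estimate (with two timepoints the repeated-measures ANOVA
contrast is the paired t statistic). Between-arm effects are ANCOVA-style:
the three-month outcome regressed on arm plus its baseline value, with
t-based Wald intervals on residual degrees of freedom and alpha = 0.05
two-sided throughout (no multiplicity correction, matching the source
analysis). The DASH-blood-pressure association is the least-squares slope
of BP change on DASH-score change together with the Pearson correlation,
overall and per arm; improvement is coded positive and a beneficial
association is a negative slope, reported alongside `decrease_per_unit`
(the negated slope) for readability. The identity
`r = slope x sd(dDASH) / sd(dBP)` is asserted on every fit in the test
suite. Missing three-month measurements are handled as available-case
likelihood estimation under a missing-at-random assumption — all randomized
participants with data contribute; multiple imputation is out of scope, and
sensitivity analyses re-run the same models with protocol-invalid records
restored (each fit captured independently so a per-protocol failure does
not mask a successful sensitivity fit).

## The synthetic-cohort simulator

The simulator is first-class, tested code. Its defaults are the study
conditions, not tuning knobs: 59 participants, permuted blocks of sizes
{4, 6, 8} (a two-arm balanced block must be even, so "sizes 4 to 8"
restricts to even values), baseline latent adherence Normal(2.3, 1.3)
censored to [0, 9], a +0.8-point mean 3-month change in both arms (SD 1.0),
tracking starting at 4.6 valid days/week with the intervention arm
declining 0.23 days/week per week against a flat comparator, baseline blood
pressure Normal(122.9, 14.2) systolic and Normal(80.2, 8.8) diastolic, and
follow-up blood pressure coupled to the measured DASH change at -2.5
(systolic) and -1.6 (diastolic) mmHg per score unit.

Parameters without a published value were fixed once at field-plausible
levels: daily energy Normal(2000, 350) censored to [1200, 3200] kcal (a
typical range for adult women, and safely inside the 600-3500 recall
validity window); BP residual SDs of 6.9/5.7 mmHg, chosen so the implied
change-score correlations reproduce the study-scale associations (about
-0.34 systolic, -0.27 diastolic) at the default coupling; a 10% missing
rate for the 3-month visit (the study retained 90%); enrollment staggered
uniformly over six weeks; contamination rates for invalid tracking days and
invalid recall pairs defaulting to 0 so the calibrated engagement and
adherence processes are observed exactly, with knobs available for
robustness exercises.

Two design choices matter for calibration:

* **Censoring, not rejection.** "Truncated to [0, 9]" is implemented by
  clamping draws at the bounds. Rejection sampling of Normal(2.3, 1.3) at
  zero would shift the cohort mean up to about 2.41 — no longer the
  configured baseline level — whereas censoring keeps it at about 2.32.
  These are closed-form properties of the truncated versus censored normal,
  decided at design time.
* **Coupling to the measured change.** Follow-up BP couples to the
  scored-recall DASH change rather than the latent change, because the
  association of interest is between observed quantities; coupling to the
  latent would attenuate the recoverable slope by the ratio of latent to
  measured change variance.

The intake generator inverts the scorer: a latent total L in [0, 9] is
converted to 2L half-credits (the fractional part resolved by a Bernoulli
draw, so the expected total is exactly L), spread evenly across the nine
components with the remainder assigned to a seeded random subset, and each
component's standardized value is then drawn uniformly inside its credit's
band — bounded by the two thresholds, by twice the target on the favorable
side, and by fixed physiologic limits (e.g. sodium at most 8000 mg/day) on
the unfavorable side. Saturated fat is drawn after total fat and capped by
it. Scoring the emitted intake with the same target set reproduces the
drawn credits exactly, a property the suite asserts over random latents.
Each participant's data come from a private stream seeded by
(master seed, participant index), so cohorts are reproducible row for row
regardless of generation order.

What the simulator does **not** emulate: food-item-level structure,
weekday/weekend or seasonal eating patterns, energy-adherence correlation,
self-report measurement error beyond the contamination knobs, or dropout
mechanisms other than missing-at-random. Passing recovery tests therefore
demonstrates the correctness of the scoring and analysis pipeline under the
stated generative model, not robustness to real-world reporting biases.

## Validation scales and determinism

The recovery checks use the scales a single CPU handles comfortably while
keeping Monte-Carlo intervals tight: 2000 participants for the baseline
score round trip (the replicate standard error of the mean is about 0.036
score points, well inside the +/-0.1 tolerance), and 20 replicates of 500
participants per arm for the engagement-decline and BP-coupling recoveries,
judged by whether the replicate 95% interval covers the generating value.
All stochastic tests fix their seeds; every generator accepts one, and the
acceptance script derives all of its streams from a single `--seed`
argument.

## Known limitations

* The intermediate scoring thresholds are package defaults, not the
  (unpublished) deployed values; analyses sensitive to half-credit
  boundaries should supply their own targets file.
* The mixed model's residual structure is a documented simplification of
  the published unstructured covariance.
* One satisfaction-survey item refers to a 1-10 score scale; the methods
  definition (0-9) is what the package implements.
* The CLI `feedback` subcommand recomputes scores from the intake file
  rather than consuming a pre-scored file, because ranking best/struggle
  components needs the standardized values, not only the credits.
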