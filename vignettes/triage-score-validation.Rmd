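---
title: "Validating a three-point triage disposition score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a three-point triage disposition score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(khds)
```

## The scientific problem

Emergency triage in low-resource settings must sort large volumes of
presenting patients quickly, with little equipment and often little
training. The Kitovu Hospital Disposition Score (KHDS) is a deliberately
minimal instrument: one point for altered mental status, one point for
impaired mobility, and one point for a deranged respiratory measurement —
either a low oxygen saturation or a fast respiratory rate, never both.
This package implements the score in its three variants, the South
African Triage Scale (SATS) presentation-urgency ranking it is compared
against, the discrimination statistics used to validate such scores, and
a calibrated synthetic-cohort generator, so the whole validation pipeline
is reproducible and testable without access to patient data.

## The score and its variants

Every variant awards 0–3 points as a sum of three binary components.

* **Mobility** (all variants): one point for any lack of a stable
  independent gait. The cohort model keeps five gait categories
  (`stable_independent`, `unsteady`, `uses_aid`, `needs_help`,
  `bedridden`) and collapses them to the binary point at scoring time, so
  richer source data survives I/O.
* **Mental status**: the default (`"sat"`) and respiratory-rate
  (`"resp"`) variants use the subjective assessment — normal only if the
  patient is alert, attentive, calm **and** coherent. The `"months"`
  variant uses the objective months-backwards test (reciting the months
  in reverse from December to July); failing — or being unable to
  attempt it, e.g. in coma — scores the point. We treat "unable" as a
  fail deliberately: the alternative (excluding such patients) would
  drop exactly the sickest patients from the objective variant.
* **Respiratory**: variants `"sat"` and `"months"` award the point for
  SpO2 strictly below 94%; variant `"resp"` for a respiratory rate
  strictly above 23 breaths/min. The boundary values (94, 23) score
  zero. The score never uses both measurements at once — the variant
  selects exactly one.

Records missing a component required by a variant are excluded from that
variant's analysis set (complete-case per variant); nothing is imputed.
This mirrors practice, where the assessments started on different dates
and each variant therefore has its own, smaller, denominator.

## SATS urgency ranking

SATS assigns presentations to ordinal urgency levels: non-urgent (0) <
urgent (1) < very urgent (2) < emergent (3). The taxonomy shipped here is
the one observable in the study setting — 20 labelled presentations
(3 emergent, 11 very urgent, 6 urgent), with reduced level of
consciousness re-defined as coma. A patient with several ranked
complaints takes the highest ranking; a patient with none is non-urgent.
Unknown codes raise an error rather than mapping silently to non-urgent,
so fixture data stays honest. The pseudo-code `non_urgent` is accepted
(and ignored by the ranking) to distinguish "assessed, nothing urgent
found" from "never assessed" (`NA`) within one CSV column.

## Discrimination statistics

The c statistic is the probability that a randomly chosen
outcome-positive patient scores higher than a randomly chosen
outcome-negative one, with ties counting one half. With a 4-level score,
ties are ubiquitous, so the tie convention is load-bearing: we compute
the statistic from mid-ranks, which is algebraically identical to the
all-pairs count with half-weighted ties, and the test suite checks that
identity against a brute-force enumeration oracle and against an
independent ROC implementation.

Its standard error uses the Hanley–McNeil closed form, with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$:

$$SE(A) = \sqrt{\frac{A(1-A) + (n_+-1)(Q_1 - A^2) + (n_--1)(Q_2 - A^2)}{n_+ n_-}}$$

Two c statistics are compared by
$z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2 - 2 r\, SE_1 SE_2}$ with a
**one-tailed** upper tail probability $P(Z \ge |z|)$ and $r = 0$ by
default. The tail convention deserves a note: the comparisons in this
design are made on overlapping patients, so an uncorrelated z test is
conservative on the variance, and the one-tailed tail is what reproduces
the published comparison p-values from their printed AUC/SE pairs (0.39,
0.44, 0.44, ≈0.07, ≈0.003); we verified that before freezing the
convention into tests. A `method = "paired"` option takes a
user-supplied correlation for genuinely paired comparisons. Equal
estimates give $z = 0$, $p = 0.5$ — a one-tailed test cannot exceed 0.5.

Association tests follow standard practice: Yates' continuity correction
for 2×2 tables only (clamped at zero when the correction exceeds
$|ad-bc|$), the uncorrected Pearson statistic for wider tables, and the
pooled-variance Student t for numeric comparisons. These wrap the base R
implementations; the package's own contributions are the score, the
c-statistic machinery, the concordance layer and the generator.

## Concordance and discordance

The concordance analysis cross-tabulates score points (0–3) against SATS
urgency over patients with both. **Higher-acuity discordance** is the
share of SATS-non-urgent patients whom the score flags at or above the
high-score cut; **lower-acuity discordance** is the share of
urgent-or-very-urgent patients the score leaves below the cut.

The high-score cut defaults to **2 points**. The published narrative
says "three or more points" in one sentence, but the published cross-tab
arithmetic only reproduces the printed 768 higher-acuity patients
(11.1% of 6,926) as the sum of the 2-point and 3-point non-urgent cells
(689 + 79); the cut of 2 is the only mapping consistent with the table
and with every downstream count, so it is the default, and it is
configurable. The lower-discordance denominator defaults to urgent +
very urgent (551 = 156 + 395, matching the printed "of 551"); including
emergent is a flag and changes nothing on the reference cross-tab, where
no emergent patient scored below 2.

The packaged reference cross-tab (16 cells, grand total 7,500) ships as
plain CSV and anchors exact tests: row/column totals, the 768/11.1% and
7/1.3% discordance values, and the structural zeros (no zero-point
patient ranked above non-urgent).

## Reporting conventions

Percentages are displayed to one decimal place, rounded **half-up**
(base R's round-half-to-even would drift from printed clinical tables);
p-values to two decimals, `"<.0001"` below $10^{-4}$. Quartiles use
linear-interpolation (type-7) percentiles. Every displayed percentage
recomputes exactly from its numerator and denominator counts, and tests
enforce this for the published worked ratios (2.2%, 5.3%, 95%, 6.1%,
53.0%).

## The synthetic-cohort generator

No patient-level data accompanies the study, so the generator emulates
the cohort's published statistical structure. It generates **score class
first** — the published material reports score-level prevalences and
outcome rates, so component correlation is implied rather than
quantified — then fills in components, vitals, outcomes and urgency
conditionally:

1. Score class from the published prevalences (72.93%, 10.22%, 12.38%,
   4.48% for 0–3 points over 14,585 patients).
2. Admission with probability conditional on score; 24-hour death with
   probability (0, 0, 2/1805, 37/653), forcing admission (every death is
   an admission); late in-hospital death among the admitted, with the
   day of late death geometric, calibrated so about 69% fall within 5
   days.
3. Components uniform over the subsets consistent with the point total,
   except that 24-hour deaths at two points always carry the mental +
   mobility components — this reproduces the observed structural zero
   (no patient with a stable gait or normal mental status died within
   24 h) and makes the share of early deaths with SpO2 < 94% come out
   near the published 95%.
4. Vitals uniform within range-faithful integer bands: SpO2 88–93 when
   the respiratory component is positive, 94–99 otherwise; respiratory
   rate 24–40 vs 12–23. Saturation and rate derangement co-occur by
   construction, so the two vital-based variants agree wherever both are
   measured.
5. The months-backwards result tracks the subjective assessment with a
   5% disagreement rate, so the objective variant differs from the
   default without a modelled mechanism.
6. SATS urgency drawn conditionally on points from the published joint
   distribution of the ranked sub-population; a presentation code is
   then drawn within the level, weighted by the published
   per-presentation totals.
7. Demographics: age from a normal (mean 44.0, SD 19.9) truncated at 12
   by redraw (the truncation raises the realised mean to about 46 —
   accepted, since the published mean describes the untruncated fit);
   male fraction 0.392; arrival dates uniform over the 343-day study
   window with the day-time loading observed in the study (2% of
   arrivals between midnight and 6 am).

Later-starting assessments are blanked for patients arriving before
their start dates (months-backwards from February, SATS from May,
respiratory rate from late June of the study year), which reproduces the
shrinking per-variant analysis sets.

Several parameters are genuinely under-determined by the published
marginals and are fixed here as documented free choices: the
admission-probability split between scores 2 and 3 (0.95 at three
points, the two-point value solved to give 1,708 expected admissions at
two-or-more points), the uniform admission rate below two points
(96/12127), the uniform late-death rate (134/1804), and the gait
severity mix among the mobility-impaired. All live in the configuration
returned by `default_config()` and can be overridden.

Randomness uses one root seed from which independent per-stage streams
are derived, so adding a stage never reshuffles earlier draws, and the
same seed yields a byte-identical cohort.

### What the generator does and does not show

Passing tests on synthetic cohorts demonstrate that the pipeline
recovers the calibration it was given (marginals within three binomial
standard deviations at full cohort size; c statistics above 0.9 for both
outcomes) and that the analysis code is internally consistent. They do
**not** validate the score on real patients: the generator has no
vital-sign physiology, no case-mix or seasonal structure, no repeat
attendances, and its component correlations beyond the enforced
structural zero are an assumption. The published cohort-level c
statistics (0.975, 0.965) are not identifiable from printed marginals
and are therefore covered qualitatively (> 0.9), not numerically.

## Degenerate inputs and numerical choices

All-positive or all-negative outcomes make discrimination undefined and
raise an error, as do zero-margin contingency tables, zero pooled
variance, and empty discordance denominators. The SE formula clamps tiny
negative variances from floating-point cancellation at zero (and is
exactly zero at A ∈ {0, 1}). The z comparison refuses a zero variance
rather than returning infinity.

## Problem sizes

The test suite exercises full-size cohorts (n = 14,585) for marginal
recovery, 10 × 2,000–3,000 for structural properties, 200 random
cohorts of size ≤ 50 against the brute-force oracle, and the whole suite
runs in a few seconds. The analysis scripts under `analysis/` use the
full published cohort size throughout.
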