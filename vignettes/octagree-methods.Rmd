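---
title: "Methods: rater agreement and treatment-adequacy adjudication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rater agreement and treatment-adequacy adjudication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octagree)
```

## Setting

Under a pro-re-nata anti-VEGF regimen for macular oedema (diabetic, DME,
or secondary to retinal vein occlusion, RVO), the retreatment decision at
each visit rests on the treating physician's interpretation of an SD-OCT
scan. Reading centres (RCs) re-grading the same scans under standardized
protocols act as the reference evaluation. `octagree` analyses visit-level
cohorts carrying both gradings: how well do physicians agree with the RC,
and — combining the RC's fluid call with the visit's treatment record,
visual acuity course and documented reasons — which visits look like
possible under- or overtreatment?

The unit of analysis is one (patient, eye, visit) row; the full column
dictionary is `cohort_columns()`. All analyses are descriptive: rates with
explicit integer numerators and denominators, no confidence intervals.

## Grading model

Raters grade each OCT parameter on a four-option scale (`yes`, `no`,
`questionable`, `cannot grade`). For analysis these collapse to binary
presence (`harmonize_grade()`): only `yes` counts as present, because
neither `questionable` nor `cannot grade` confirms presence. A fifth
state — the rater supplied no evaluation at all — is kept distinct as
`NA` and is *excluded* from denominators, never counted as absent. This
distinction matters because the two kinds of missingness enter
denominators differently: an RC-graded cohort can be much larger than its
dual-graded subset, and agreement statistics must use the latter.

Two composites are exposed and deliberately kept apart:

* **Foveal fluid** (`foveal_fluid()`): harmonized foveal IRF OR foveal
  SRF. This is the consensus-table composite; diffuse foveal thickening
  is not part of it.
* **Disease activity** (`foveal_activity()`): foveal fluid OR diffuse
  foveal thickening. This is the activity definition the
  treatment-adequacy adjudication uses.

A composite is `NA` only when *all* its components are ungraded; a
partially graded visit treats ungraded components as absent, which is the
harmonization rule applied component-wise.

## Agreement statistics

`foveal_fluid_crosstab()` tabulates physician (rows) against RC (columns)
over dual-graded visits. `agreement_rates()` derives overall agreement,
positive confirmation P(physician present | RC present) and negative
confirmation P(physician absent | RC absent) — the physician's
sensitivity and specificity against the RC reference — plus both
prevalences. Two conditioning conventions coexist in this literature and
both are first-class here: the consensus table conditions on the RC
(bracketed column percentages), while the whole-scan compartment
comparison (`compartment_confirmation()`) conditions on the physician's
call. Neither is ever inferred from context; the output names the
direction.

`cohens_kappa()` is provided as the standard chance-corrected companion
statistic (the study itself reports raw percentages only, so kappa is not
part of any reproduction).

Thickness agreement (`thickness_comparison()`) uses per-visit differences
with the stated sign convention (physician minus RC) and a paired
two-sided t test; with fewer than two pairs, or a degenerate difference
distribution, the p-value is `NA` rather than a fabricated number.

Percentages are rounded half-up to one decimal (`round_half_up()`):
half-up is the convention under which every published percentage in the
packaged fixtures reproduces exactly from its printed counts (base R's
half-to-even does not).

## Longitudinal criteria

**Change concordance.** Raters also report the fluid change versus the
previous visit (increased / stable / decreased). `change_concordance()`
cross-tabulates the two reports and conditions agreement on the
physician's category. Change categories are taken as reported, never
recomputed, for real data — the raters' internal change criterion is not
observable.

**Stability.** A no-treatment decision is justifiable when BCVA *or*
retinal thickness were stable over three prior visits. `is_stable()`
implements this as a window of `n_prior_visits` (default 3) visits ending
at the decision visit: stable when the BCVA range is at most 5 ETDRS
letters OR the physician CSRT range is at most 25 µm. Design choices,
both configurable:

* *Window placement.* "Stable in 3 prior visits" is ambiguous between a
  window including the decision visit and one strictly before it. The
  default includes it, because the decision uses the information available
  at the visit; `include_index = FALSE` selects the other reading.
* *Thickness window.* No numeric thickness criterion is published; 25 µm
  sits near reported OCT test-retest variability for central subfield
  thickness and is therefore used as the default.
* *Missingness.* A missing value inside the window makes that basis
  non-assessable (not stable by that basis); if neither basis is
  assessable, or the window does not fit, stability is non-assessable
  altogether, which the adjudication treats conservatively (below).

**BCVA outcome categories** (`bcva_delta_categories()`) follow the
printed boundary conventions exactly: stable iff |Δ| ≤ 5; deterioration
iff Δ < −5; gain at ≥ +15 inclusive; loss strictly beyond −15. The
15-letter flags deliberately overlap the three-way partition.

## The adjudication tree

`adjudicate_visit()` classifies each RC-gradable visit, in fixed order.
With RC-confirmed foveal activity: treated → `TREATED_ACTIVE`; stable →
`WW_JUSTIFIED_STABLE`; documented reason, non-assessable stability, or
missing treatment information → `WW_JUSTIFIED_DOCUMENTED`; otherwise
undertreatment, split into `UNDERTREAT_FALSE_NEGATIVE` (physician
reported no activity; the result records whether the RC flagged the
missed fluid as strongly visible) and `UNDERTREAT_UNCLEAR`. Without
RC-confirmed activity: untreated → `UNTREATED_INACTIVE`; an injection is
justified by a > 5-letter BCVA decline versus the previous visit or by
being part of an injection series; otherwise suspected overtreatment,
split by whether the physician reported foveal fluid.

Three choices deserve comment:

* *Conservative missingness rule.* Any missing information at the
  justification step (no documented-reason field, non-assessable
  stability, missing injection record) resolves to
  `WW_JUSTIFIED_DOCUMENTED`, never to undertreatment. Only an explicit
  "no reason" (`"none"`) together with assessable instability counts as
  possible undertreatment. This gives the monotonicity property the test
  suite checks: adding missingness can only move visits *out of* the
  undertreatment categories.
* *Branch order.* Stability is tested before documented reasons because
  stability is quantified as the dominant justification; the order only
  affects the sub-labels within "justified", not the justified vs
  undertreatment split.
* *Series derivation.* "Injection within a series" uses the recorded
  flag when present; otherwise it is derived as "previous visit of the
  same eye was injected at most 42 days earlier" (configurable), since no
  formal definition of a series is published.

The ten categories partition the adjudicable visits exactly, split by RC
fluid status; `patient_rollup()` reduces to per-patient any-visit flags.
One study eye per patient is the expected case; data with both eyes are
still handled per (patient, eye), and the rollup flags a patient if any
eye qualifies.

## The synthetic cohort generator

No raw visit data are public, so `generate_cohort()` provides cohorts
with the statistical structure the pipeline assumes; the packaged count
fixtures (`load_fixture()`) carry the actual published integers. The
generator draws, per visit, a latent foveal-activity state at the
configured per-diagnosis prevalence. The RC reports that state without
error — the analysis frames the RC as the reference, so only the
physician-vs-RC channel needs noise — while the physician is a binary
channel with configured sensitivity 0.852 and specificity 0.358, emitting
`questionable`/`cannot grade` among its negative calls at configured
rates. IRF/SRF compartments are drawn conditional on activity (at least
one foveal compartment carries the fluid), CSRT comes from an active or
quiet normal distribution with independent per-rater measurement noise
(15 µm, chosen so paired physician−RC differences have a spread near the
published ≈21 µm), per-rater change categories derive from that rater's
CSRT differences with a 25 µm threshold, BCVA is baseline plus cumulative
drift (−1.5 letters per untreated active visit) plus noise, and
injections follow the two-probability policy (0.356 with RC fluid, 0.394
without — both published marginals). Defaults are the study scale: 77 DME
and 56 RVO patients, 8–16 visits each at 21–42 day intervals, 34.6% of
visits missing the physician grading.

What the generator does **not** emulate: temporal autocorrelation of
fluid (latent states are independent across visits), eye-level
correlation or fellow eyes, treatment pharmacodynamics (injections do not
clear fluid at the next visit), rater drift or learning, and any
anatomical realism. BCVA is a drift-plus-noise process, not a disease
model — only Δ-letter categories feed the analysis. Consequently, tests
passing on generated cohorts demonstrate the *bookkeeping* (denominators,
conditioning, tree walking, partitions) and parameter recovery, not
clinical realism; the published whole-cohort percentages are reproduced
only from the packaged count fixtures.

## Numerical and degenerate-input conventions

* Rates always travel with integer numerator and denominator; a zero
  denominator yields `NA`, never 0/0.
* Visit ordering within an eye is by date, ties broken by input order
  (reproducibility); validation is a projection.
* Duplicate (patient, eye, visit index) keys are fatal; other invariant
  breaches are structured, non-fatal issues.
* Empty cohorts and empty strata produce valid all-zero outputs.
* Determinism: one seed in the config drives all sampling
  (`withr::with_seed`), and cohort CSV / summary JSON serialization is
  byte-stable.

## Problem sizes in the test suite

The suite checks parameter recovery on a 2000-patient generated cohort
(≈24,000 visits), oracle equivalence against independent brute-force
tallies and a literal tree-walk on 200 randomized mini-cohorts,
missingness-monotonicity on 100 seeded cohorts, and exact reproduction of
all published percentages from the count fixtures. These sizes give
3-standard-error bands of about ±1–2 percentage points for the recovery
checks while keeping the whole suite around a minute on one CPU.

## Known limitations

* The adjudication reconstructs decisions from recorded fields only; it
  cannot model physician intent, and visits without an RC grading are
  excluded rather than imputed.
* Published whole-cohort results that lack printed denominators (the
  whole-scan confirmation percentages, the follow-up outcome
  distributions) cannot be reproduced without the raw data; they are
  covered qualitatively by the property tests instead.
* Some published fraction annotations are internally inconsistent (e.g. a
  printed 23.7% beside 170/820, which is 20.7%); the fixtures store the
  integer counts and the package reports count-derived percentages only.
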