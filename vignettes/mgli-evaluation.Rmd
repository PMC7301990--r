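---
title: "Evaluating service quality with multi-granularity linguistic information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating service quality with multi-granularity linguistic information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgliqual)
```

## Why linguistic scales, and why several at once

Survey respondents and expert panels rarely produce defensible exact
numbers. They are much better at verbal judgements — "good", "slightly
poor" — and different raters are comfortable with scales of different
lengths: a coarse 5-term scale forces clear commitments, a 7-term scale
lets a careful rater be precise. A rater may also hesitate between two
adjacent terms and want to answer with the interval `[S_4, S_5]` rather
than either endpoint. `mgliqual` takes such *multi-granularity linguistic
information* as its raw material and carries the uncertainty through the
whole analysis instead of forcing early numeric conversion.

The package grew out of a teleconsultation service-quality study — the
raters are the regional doctors who actually operate the platform — and the
study's summary tables are bundled as fixtures, but nothing in the method
is specific to that setting.

## The model

### Encoding

A term set `S = {S_0, …, S_T}` is strictly ordered, with negation
`Neg(S_t) = S_{T−t}` and max/min given by the index order. An answer
`[S_m, S_n]` (point answers have `m = n`) on a granularity-`(T+1)` scale
becomes the normalized trapezoidal fuzzy number

```
A = ( max{(2m−1)/(2T+1), 0},  2m/(2T+1),  (2n+1)/(2T+1),  min{(2n+2)/(2T+1), 1} ).
```

The plateau `[b, c]` covers the chosen terms; the ramps extend half a term
either way; the clamps keep the extremes inside [0, 1]. The denominator
`2T+1` is taken as given by the source method; note it makes the scale very
slightly asymmetric about ½ (the defuzzified midpoint of `S_0`/`S_T` pairs
is constant but not exactly ½), which is why the test suite asserts
*stability* of the pairwise sums rather than exact mirror symmetry.

The key property is that each value is encoded with its **own** scale's
`T`. That is the entire multi-granularity mechanism: there is no explicit
granularity-transformation function; once encoded onto [0, 1], a 5-term
answer and a 7-term answer average componentwise without further ado.

### Algebra and defuzzification

Addition, multiplication and non-negative scaling are componentwise and
preserve the trapezoid ordering (for positive operands). Subtraction and
division are also componentwise but do **not** preserve ordering; the
package returns them as `signed_tuple` objects with an honest `ordered`
flag and never silently re-sorts. This matters in exactly one place: the
literal fuzzy-weighted expert average (`expert_mean_linguistic()`) divides
by a fuzzy weight sum and can produce unordered tuples, which is why that
path is a separate, warning-carrying function while the recommended crisp
path (`expert_mean()`) is a weighted componentwise mean that stays ordered.

Crisp summaries use the segmentation-integral defuzzification
`P(A) = (a + 2b + 2c + d)/6`. It is linear, so "defuzzify then subtract"
and "subtract then defuzzify" agree exactly — the gap analysis exploits
this and reports crisp gaps.

### Screening

Let `M_0, …, M_T` be the encodings of the reference importance terms. For
an aggregated indicator trapezoid `f*`, the similarity degree to term θ is

```
Y(f*, M_θ) = 1 − ¼ Σ_{h=1..4} |f*_h − M_θ^h| ,
```

i.e. one minus the mean componentwise absolute difference. The difference
is taken componentwise over the 4-tuple: that reading reproduces the
bundled published similarity table, whereas a scalar (defuzzified) reading
does not (0.9231 vs the printed 0.9641 for the first row). `1 − Y` is a
scaled L1 metric, so similarity is symmetric and maximal only at identity —
both property-tested.

The indicator's decision is the zone of its most similar term. For the
7-term importance scale the default is remove = {S_0, S_1, S_2}, review =
{S_3} ("middle"), keep = {S_4, S_5, S_6}; for other granularities the
default generalizes as lower third / middle / upper third, with the exact
midpoint as the review zone for odd granularity. A tie at the maximum
(within 1e−9) always forces "review": zone boundaries decided by
floating-point noise should go to a human. Integrations of reviewed
indicators are deliberately *declarative* (`merge_plan()`): which
indicators merge into what is expert judgement, not computation, so it
enters as configuration and is validated (sources must exist, be disjoint,
and not be removed indicators). The optimized hierarchy places each merge
target at its first source's position, which reproduces the case study's
row order exactly.

### Gap analysis

Per indicator, `P = defuzzify(AP)`, `E = defuzzify(AE)` and
`gap = P − E ∈ [−1, 1]`; a negative gap means perception falls short of
expectation. Dimension-level AP/AE are unweighted componentwise means of
the dimension's sub-indicator tuples — the roll-up rule is not dictated by
the algebra, but it reproduces the case study's first two dimension rows to
three decimals, so it is adopted as the default (see "Known
inconsistencies" for the other two).

Key factors are ranked by ascending **reported** gap (3 decimals, half
away from zero), ties broken by indicator id. Ranking on reported rather
than raw gaps is a deliberate choice: two of the case study's gaps are
−0.0310 and −0.0305, indistinguishable at the reported precision, and the
published key-factor order lists them id-first — the raw-value order would
swap them. Magnitude-based ranking was rejected because positive gaps are
strengths, not problems.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| term sets | 5-, 7-term presets | granularity `T+1`, labels; dimensionless |
| `zones` | 3/1/3 split on 7 terms | remove/review/keep partition of reference indices |
| `missing` | `"strict"` | survey missing-data policy; `"drop"` removes a respondent per indicator and logs the effective `l` |
| report digits | 3 (gaps), 4 (similarities) | half-away-from-zero rounding of report columns |
| `top_k` | 5 | key-factor ranking depth |

## The synthetic-data generator

`simulation_spec()` fixes the study conditions: 15 equally weighted experts
alternating between the 7- and 5-term scales (raters choosing granularities
is the phenomenon of interest), 434 respondents all on the 7-term scale (as
in the case survey), planted true levels per indicator on the canonical
7-term scale, ordinal noise probability 0.1, and hesitant-interval
probability 0.05. Cross-granularity planting maps indices proportionally
with half-up rounding (`map_term()`); noise moves a cell one term up or
down with equal probability and clips to the scale; an interval answer
widens `t` to `[t, t+1]` (downward at the scale top). The 691-collected /
434-valid questionnaire counts enter only as reported constants
(`case_study_profile()`), because validity screening happens upstream of
the method.

What the generator emulates: granularity mixing, hesitant answers,
symmetric ordinal noise around a true level, and planted
perception–expectation orderings. What it does not emulate: respondent
covariates, systematic response styles (acquiescence, extreme-response
bias), item non-response patterns, or correlated errors across indicators.
Passing recovery tests therefore shows the pipeline is consistent under
well-behaved ordinal noise, not that it is robust to structured biases in
real survey data.

Recovery behaviour under the defaults (asserted in the test suite):
screening recovers the planted importance zone for ≥95% of indicators
across 200 simulated panels, and gap signs match the planted
perception–expectation ordering for ≥99% of indicators across 50 simulated
surveys of 434 respondents. At zero noise, recovery is exact (the average
trapezoid equals the planted term's encoding to machine precision).

## Numerical choices

* **Rounding.** Reports round half away from zero (0.7225 → 0.723,
  −0.0255 → −0.026), matching the bundled tables; base R's half-to-even is
  not used. A 1e−9 boundary tolerance absorbs binary-float representation
  of exact halves (0.675 − 0.7055 lands a few ulps below −0.0305).
  Internal computation is always full precision.
* **Degenerate ramps.** The membership function's `(x−a)/(b−a)` ramp is a
  step when `a = b` (membership 1 at the plateau edge); likewise on the
  right.
* **Extended scales.** A set may declare `extended_T > T` to admit
  out-of-scale judgements; their encodings clamp all four components into
  [0, 1] (identical to the standard formula for indices ≤ T). A `clamp`
  mode on `linguistic_value()` instead snaps wild indices into `[0, T]`.
* **Ties.** Similarity argmax ties within 1e−9 force "review"; ranking
  ties at the reported precision break by id for determinism.
* **Degenerate inputs.** Empty panels/surveys, zero total weight,
  incomplete grids, division by zero-component tuples, and empty
  dimensions are all hard errors with specific messages.

## Known inconsistencies in the bundled tables

The fixture tables transcribe a published case study, and the test suite
recomputes each table from the previous one. Three discrepancies are in
the source material itself, and the corresponding acceptance checks fail
honestly rather than being loosened:

* Recomputing all 168 similarity cells from the 3-decimal averaged
  trapezoids matches the printed table within ±0.0005 for 162 cells; six
  cells differ by up to 0.0007 (the printed table was evidently computed
  from unrounded averages). Every row's most-similar term matches.
* One sub-indicator row (C14) prints P = 0.715 while its own printed AP
  tuple defuzzifies to 0.7025; all other 45 derived cells agree within
  0.0005.
* The dimension table's C3 and C4 rows do not equal the componentwise
  means of their sub-indicators (C4 is off by 0.037 on AP, and its printed
  gap −0.006 contradicts its sub-indicators' uniformly positive gaps);
  C1 and C2 agree to three decimals.

Two further rows (the two indicators rated uniformly at the scale top)
share identical trapezoids `(0.810, 0.905, 1, 1)`; this is taken as
genuine identical panels, not an error. Two printing typos in the averaged
trapezoids ("0301", "0.864.0.932") are corrected in the fixture and noted
in its `note` column.

## Problem sizes

The bundled analyses are desk-scale (24 indicators × 7 terms, 19-row gap
tables) and run in well under a second. The recovery studies simulate 200
panels of 15 × 24 ratings and 50 surveys of 434 × 24 paired answers —
a few seconds in total — which is ample for the binomial margins the
assertions need.

## Limitations

* The method ranks and localizes quality shortfalls; it attaches no
  inferential uncertainty to gaps (no tests, no intervals), so small gap
  differences should not be over-read.
* The componentwise fuzzy division used by the literal linguistic-weight
  average is not the extension-principle quotient; treat
  `expert_mean_linguistic()` as a fidelity path, not a recommendation.
* Dimension roll-up weights all sub-indicators equally; if indicators
  within a dimension differ greatly in importance, a weighted roll-up
  (not provided) may be preferable.
* Cross-sectional by design: nothing here models change over time.
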