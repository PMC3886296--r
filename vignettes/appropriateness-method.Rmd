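---
title: "The RUAM classification pipeline: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RUAM classification pipeline: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruam)
```

## The procedure

The RAND/UCLA Appropriateness Method combines a literature review with
structured expert ratings.  The statistical core that this package
implements is purely rule-based — nothing is estimated:

1. **Scenario space.** Each patient population carries a set of clinical
   variables with ordered levels; scenarios are the full Cartesian
   product of those levels, and each scenario is paired with every
   applicable treatment to form *indications*.  The shipped
   `round2-default` space (iron deficiency in IBD) enumerates to
   28 NAID + 168 IDA = 196 scenarios and 28·5 + 168·6 = 1148
   indications.
2. **Ratings.** P panellists each rate every indication once on the
   integer 1–9 scale.  The package treats the rating table as complete
   by contract: consensus methodology defines no missing-data rule, so
   a gap is a validation error, never silently imputed.
3. **Classification.** Per indication: *agreement* iff at least A
   ratings share one section of the scale (1–3, 4–6, 7–9);
   *disagreement* iff at least D ratings sit in 1–3 *and* at least D in
   7–9; category from the median band (7–9 appropriate, 1–3
   inappropriate, both only without disagreement; everything else
   uncertain).

```{r}
cfg <- panel_config(16)
classify(c(rep(2L, 5), rep(5L, 6), rep(8L, 5)), cfg)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `panel_size` P | 16 | voting panellists (dimensionless) |
| `agreement_min` A | ⌈0.75·P⌉ (12 at P=16) | ratings in one section needed for agreement |
| `disagreement_min` D | max(2, round(0.3125·P)) (5 at P=16) | ratings in *each* extreme section for disagreement |
| `bands` | 1–3 / 4–6 / 7–9 | the scale sections; any partition of 1..9 |
| `sigma` | 0.5 | rater noise SD, in scale points |
| `split_fraction` | 5/16 | opposed raters on split indications |
| `mix` | .5/.3/.15/.05 | planted appropriate/uncertain/inappropriate/split |

The canonical thresholds 12-of-16 and 5-of-16 are stated only for a
16-member panel; for other P the defaults keep the same fractions.  That
scaling is an extrapolation of ours, documented as such and overridable —
at P = 6 it gives A = 5, D = 2, which is the configuration the exhaustive
rule-equivalence test sweeps.

## Numerical conventions

* **Even-panel medians.** The median is the midpoint of the two central
  order statistics, so half-integer values (3.5, 6.5) occur.  They lie in
  no section and therefore classify as uncertain; the inclusive band
  check makes this explicit rather than an accident of rounding.
* **Disagreement counts raw ratings**, never the median's band.
* **Display rounding.** Distribution tables print whole percentages, as
  such tables are conventionally reported, but every computed value is
  kept unrounded; row sums equal 100 exactly before rounding.
* **Ties.** The preferred-option rules never break ties silently:
  scenarios whose best appropriate options tie are counted and reported
  separately.
* **Degenerate inputs.** Empty rating vectors, empty result sets,
  single-level variables (no discriminativeness pairs) and incomplete
  tables are hard errors or explicit `NA`s, not defaults.
* **Generator rounding** uses R's `round()` (round-half-to-even); with
  the integer category centres and continuous noise the half-way case
  has probability zero, and the noise-free limit is exact.

## The synthetic panel model

Raw ratings from real RUAM studies are essentially never public, so the
generator plants a ground truth and emulates a complete round: each
indication draws a category from `mix`; its latent score sits at the band
midpoint (8 / 5 / 2); each rater reports
`clamp(round(theta + bias + N(0, sigma^2)))`.  *Split* indications model
a genuinely divided panel: `round(split_fraction * P)` raters (a fixed
count, so the noise-free behaviour is exact) rate from an opposed centre
8 while the rest rate from 2, which triggers the disagreement rule and
makes the intended category uncertain.  One seeded RNG stream per round
makes tables byte-reproducible.

What this emulates — complete integer tables, unimodal consensus noise,
bimodal disagreement, reproducibility — is what the downstream rules are
sensitive to.  What it does not emulate: systematic rater styles
(bias defaults to 0), correlated ratings across related scenarios,
ordinal-scale distortions (a cumulative-logit model would slot into the
same interface), or panellists revising between rounds.  Passing
recovery tests therefore validates the *pipeline arithmetic*, not any
claim about real panel behaviour.

## Design choices where the ground was open

* **Default space structure.** Published RUAM reports typically print
  only variable names and totals.  The default space uses previous
  treatment = 7 levels ({none} ∪ {oral, low-dose IV, high-dose IV} ×
  {success, failure}), conditions = 2, activity = 2, plus for IDA
  haemoglobin bands <8, 8–<10, 10–<12 g/dL (the clinically cited
  cut-points, upper-exclusive) and symptoms = 2.  This is the unique
  small factorisation consistent with the printed totals
  (28·5 + 168·6 = 1148 with 28 + 168 = 196); any other structure can be
  expressed in the YAML/JSON config, and no first-round default is
  shipped because its structure is unpublished.
* **"No treatment" is an ordinary treatment option**, so its row appears
  in the distribution table like any other.
* **Preferred option** is not a defined RUAM term.  Default rule:
  appropriate option with the strictly highest median;
  `unique_appropriate` (exactly one appropriate option) is the
  alternative reading.  Both are exposed because summary statements like
  "preferred in x% of scenarios" are compatible with either.
* **Discriminativeness** operationalises "cross-tabulation" screening as
  the fraction of matched scenario-pair × treatment comparisons (pairs
  differing in exactly one variable) whose categories differ.  It is
  symmetric, scale-free, exactly computable, and reduces to 1 for a
  variable that alone determines the outcome and 0 for an inert one.
* **Transcribed guidance fixture.** The packaged recommendation set for
  iron deficiency in IBD is a transcription of published *summary*
  statements, stored at their granularity (NAID: previous treatment ×
  activity; IDA: previous treatment × Hb band).  Cells the summary does
  not pin down are graded `optional`; cells it states as negative
  findings (oral iron after oral success at Hb < 10 g/dL; transfusion at
  Hb ≥ 8 g/dL) are graded inappropriate.  Its provenance tag
  `transcribed-fixture` keeps it distinct from computed sets, and it is
  synthetic in the sense that the underlying raw ratings are not public.
* **Scenario ids** are the diff-friendly string
  `POP|var=level|...` with variables in configuration order, so ids are
  stable across runs and readable in exports.

## Verification strategy and problem sizes

The test suite checks the classification against an independent literal
transcription of the three rules exhaustively over all 9^6 = 531 441
vectors at P = 6 (A = 5, D = 2), and by random sampling at P = 16; the
scenario enumeration against a brute-force odometer oracle on random
small configs; and the whole pipeline end-to-end on synthetic rounds of
the full 1148-indication default space.  Recovery checks use σ = 0
(exact) and σ = 0.5 (≥ 95% required); monotone degradation is asserted
on seed-averaged recovery over σ ∈ {0, 0.5, 1, 2, 3} on a small space,
sizes chosen to keep the suite quick while leaving the binomial noise
well below the asserted margins.  Mutual exclusivity of agreement and
disagreement at 12/5-of-16 (a pigeonhole consequence: 12 + 5 > 16) is
asserted over 10^5 random vectors.

## Limitations

* The package computes panel statistics; it has no opinion on clinical
  correctness, and the fixture transcribes summary guidance rather than
  recomputing it from (unavailable) raw ratings.
* Only the printed agreement/disagreement definitions are implemented —
  no IPRAS or other alternative disagreement statistics, no rater
  weighting, no Bayesian consensus models.
* Rounds are classified independently; merging across structurally
  different rating rounds is deliberately undefined.
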