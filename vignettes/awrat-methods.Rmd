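---
title: "Methods behind the AWRAT scoring, completeness and reliability analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the AWRAT scoring, completeness and reliability analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awrat)
```

## The instrument and its weights

The AWRAT asks an assessor to rate observational risk-factor statements
on a 0–100 visual-analogue scale; statements are phrased positively, so
100 is the favourable end. Factors belong to four topic areas — farm,
animals, treatment, nutrition — and each topic carries a topic-risk
rating (TRR) on a 100-point budget expressing its judged impact on
welfare outcomes. The shipped defaults are farm 30, animals 30,
treatment 20, nutrition 20. These weights are a subjective expert
calibration, not an estimate from data, which is why they are plain
configuration in this package (`default_instrument()` arguments or a
YAML file): recalibration is expected as evidence accumulates, and an
equal-impact reference point is available as `equal_weight_trr(4) = 25`.

The published factor statements live in the tool's standard operating
procedure, which is distributed as supplementary material rather than in
the main text; the scoring arithmetic depends only on factor *counts*
per topic and the weights. The default configuration therefore uses
placeholder labels with a 5/5/4/4 split of the 18 factors across topics.
Users running the real instrument should load their own YAML with the
genuine wording and split; every computation downstream is unchanged.

## Risk rating and completeness

Field visits rarely allow all 18 factors to be observed, so the score is
built from rated factors only. Within a topic, ratings of exactly 0 are
first replaced by 0.01 — a zero is information (the statement is
entirely untrue), and the substitution keeps it from being
indistinguishable from "not rated" in spreadsheet-style summation while
leaving the score essentially unchanged (a fully rated all-zero
assessment scores 0.01 rather than 0). The substitution is applied
*only* to exact zeros; small positive ratings are taken at face value.
Ratings are handled as continuous numbers throughout, since a
visual-analogue slider produces continuous output.

The topic's mean substituted rating (sum divided by 100 times the rated
count) is scaled by its TRR, and topics add up to the AWRAT-RR. Because
each topic is averaged before weighting, an unrated factor neither
penalises nor credits its topic; what it does do is reduce the
**measure of completeness**. Each factor carries a factor value
`TRR/n_factors`, and the MOC subtracts the factor values of unrated
factors from the budget. The subtraction form and the equivalent
additive form (rated count × factor value) are both implemented in the
test oracles and checked to agree to 1e-9 under random instruments and
missingness patterns.

A topic with *no* rated factors is the one genuinely open design point:
the verbal recipe is silent, and the validity rule (at least one rating
per topic, MOC ≥ 70) puts the case out of contract. We let such a topic
contribute 0 and flag the result invalid rather than renormalising the
remaining TRRs: renormalisation would silently re-weight the instrument,
and an explicit invalid flag is the safer behaviour for an enforcement
context. The MOC threshold of 70 is the anticipated validity bound, kept
configurable (`moc_threshold`).

## Cleaning and stratified validation

The validation pipeline compares the composite against the assessor's
single overall welfare rating (WR, 0 = very poor, 100 = very good),
given before the detailed assessment. Cleaning applies, in order:
records with no factor ratings; records without a WR; non-key species
(default cattle/sheep/goats); records entered more than `recency_days`
after the visit; and same-day duplicates per farm. "Within one month" is
implemented as a fixed 31-day bound because calendar months vary and a
fixed bound is testable. For same-day duplicates the last-entered record
(file order) is retained, on the reasoning that the latest entry most
plausibly reflects the completed assessment. Every rule reports its
removal count, and the counts are required to reconcile with the input
size, so alternative orderings can be audited.

OLS is then fitted with WR as response and AWRAT-RR as the single
predictor — the tool is being asked to predict the holistic judgement —
within MOC strata `all, ≥70, ≥80, ≥90, =100`. "Adjusted R" is
interpreted and reported as adjusted R², the standard
variance-explained summary, computed as `1 − (1 − R²)(n − 1)/(n − 2)`
for the single-predictor model. Strata with fewer than three records or
a constant predictor are reported as undefined rows rather than errors,
since small high-MOC strata are common.

## Reliability via ANOVA-based ICC

The observation study has raters score the same photograph/statement
items twice, at least ten days apart. Both reliability analyses reduce
to a complete items × raters matrix and a two-way ANOVA without
replication: row (item), column (rater/session) and residual sums of
squares are computed directly from the balanced-layout means, with the
partition identity asserted in tests against brute-force summation and
against `lm()` fits.

The default coefficient is ICC(2,1) — two-way random effects, single
rater, absolute agreement:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

Absolute agreement is the right notion when assessors must be
interchangeable, as rater bias then counts against reliability.
ICC(3,1) (consistency) and ICC(1,1) (one-way) are selectable for
sensitivity analysis; ICC(3,1) ≥ ICC(2,1) whenever the rater mean
square exceeds the residual, which the tests assert. Negative estimates
are reported as computed, not truncated at zero, so estimator behaviour
on weak data stays visible.

Missing-value policy mirrors the study design: for the test–retest
analysis, an item missing in either session is dropped for that
observer; for the inter-observer analysis, each observer contributes
their first (or only) session and observers with any missing value are
removed, leaving a complete matrix. An observer appearing with more
than two sessions is an error (ambiguous pairing) rather than a silent
choice. The ten-day gap is enforced only when timestamps are present.

## The synthetic generator

Real field data from instrument trials of this kind cannot generally be
redistributed, so the package carries a generator whose defaults define
its study conditions. Assessment cohorts share a farm-level latent
welfare quality $q \sim 100\,\mathrm{Beta}(2,2)$ (centred, mildly
dispersed, as expected of a mixed visit stream). WR is $q$ plus
$N(0, \sigma_{wr})$ noise; each topic draws a per-farm offset
$N(0, \sigma_{topic})$, reflecting that farms are systematically better
in some areas than others; each factor adds $N(0, \sigma_{factor})$.
Defaults $\sigma_{wr} = 10$, $\sigma_{topic} = 5$,
$\sigma_{factor} = 10$ (rating points) represent an assessor able to
place a farm within about ±10 points — a realistic precision for a
100-point VAS — and `p_missing = 0.15` reflects that skipped factors
were common but a minority. Values clamp to [0, 100], mirroring the
slider's hard stops, rather than resampling from a truncated normal;
with central latent means and these SDs, fewer than 1% of draws clamp
(asserted empirically). Missingness is MCAR by default, with an
optional quality-dependent mode (poorer farms harder to assess) for
stressing the MOC analysis.

Observer tables follow an additive variance-component model
$rating = \mu_i + b_o + e$, with item true scores $N(50, 20)$, rater
bias SD 5, retest noise SD 5 and residual SD 5, giving a population
absolute-agreement ICC of $400/475 \approx 0.84$ and a test–retest ICC
of $400/450 \approx 0.89$ — the "good reliability" regime the
instrument is meant to operate in.

What passing tests on these cohorts shows is that the algorithms
recover known structure: they do not show that real farm visits satisfy
the latent-state model. In particular the generator has no seasonal
drift, no assessor learning effects, no informative missingness by
default, and its WR and factor ratings come from one latent variable —
a stronger coupling than two human judgements would share.

## Numerical choices and problem sizes

Tolerances: exact identities (score decomposition, MOC dual forms, OLS
versus normal equations) are checked at 1e-9; the ANOVA partition at
1e-6 relative. Monte-Carlo checks use fixed seeds: 1,000 random
instrument/record draws for the scoring and MOC oracles; 200 replicates
of 500 × 3 matrices for ICC variance-component recovery (tolerance
±0.03 on the mean); 100 null-cohort replicates of 60 farms for the
mean-zero adjusted-R² check; cohorts of 60–200 farms elsewhere. These
sizes give comfortably stable estimates at sub-minute runtimes; scaling
any of them up is a matter of changing one constant in the tests.

## Known limitations

* The default instrument's per-topic factor split is a placeholder; load
  the real configuration for field use.
* TRR weights are expert judgement; the package deliberately provides no
  machinery to re-derive them from outcome data.
* Prior-offence history is carried as metadata only and never enters the
  score: composite-plus-recidivism models are out of scope here, as
  a dominant binary predictor swamps the observational factors.
* The regression validates the composite against a judgement from the
  same assessor, not an external gold standard; a high adjusted R² is
  evidence of coherence, not of field validity.
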