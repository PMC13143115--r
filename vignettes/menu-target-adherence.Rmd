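---
title: "Auditing menu nutrition against the UK reduction targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing menu nutrition against the UK reduction targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menutargets)
```

## The problem

The UK Government operates three voluntary reformulation programmes for
food: sugar reduction targets (set per 100 g), calorie reduction targets
(set per serving), and salt reduction targets (set per 100 g or per
serving, with separate target sets for the out-of-home sector and for
retailers/manufacturers). Auditing a restaurant menu against these
targets sounds mechanical but is riddled with data problems: restaurants
disclose nutrition on inconsistent bases (per 100 g, per serving, or
both), often without serving sizes, sometimes with energy only in kJ or
salt only as sodium; the programmes' category systems overlap and carry
precedence rules; and pizzas come with their own serving-count
conventions.

`menutargets` implements that audit as a deterministic, provenance-tracked
pipeline, together with a seeded synthetic menu-corpus generator whose
ground truth makes every downstream number checkable. The package is
organised as an analysis workflow: the numbered scripts under `analysis/`
run the steps in order on a simulated corpus, and every computation they
perform lives in exported package functions.

## Data model

A menu corpus is a tibble with one row per menu item. Ten nutrient fields
(kcal, kJ, fat, saturated fat, carbohydrate, sugar, protein, fibre, salt
in grams, sodium in milligrams) exist on two bases — `_100g` and `_serv`
columns — plus a `serving_size` in grams. Every field is optional, and an
empty cell means *missing*, never zero: the exclusion rule and the
completion formulas all key on missingness, so the distinction is load-
bearing. Each value column has a parallel `src_` provenance column taking
`reported`, `derived` (filled by a formula), or `subcategory_imputed`.
Reported values are never overwritten by any later stage.

Items carry a subcategory from a fixed 12-label vocabulary (Pizzas …
Sauces) used for cross-restaurant summaries and serving-size imputation;
restaurants map to one of five types (Burger, Chicken, Pizza, Sandwich,
Other Main) via a group map.

## Completion

An item is excluded only when all three nutrients of interest — kcal,
salt, sugar — are missing on both bases and underivable: kJ counts as
kcal-derivable, a complete macronutrient panel counts as kcal-derivable,
and sodium counts as salt-derivable.

The completion formulas are:

* energy unit conversion: kcal = kJ / 4.184 (and the inverse);
* macronutrient fallback, used only when neither energy field is
  present: kcal = 4·protein + 9·fat + 3.75·carbohydrate;
* salt/sodium conversion: sodium (mg) = salt (g) × 1000 / 2.5 (and the
  inverse);
* basis scaling: per 100 g = per serving / (serving size / 100), per
  serving = (serving size / 100) × per 100 g, and serving size =
  100 / per-100g × per-serving when a nutrient is present on both bases.

The engine applies unit conversions before basis scaling so that, for
example, a kJ-only per-serving panel can seed serving-size derivation,
and repeats the sequence to a fixpoint (at most a handful of passes).
That ordering maximises the number of completions; it also makes the
pipeline idempotent, which the tests assert directly. Serving-size
derivation tries nutrients in the fixed order kcal, salt, sugar,
carbohydrate, fat, protein — kcal first because it is the most
consistently reported field. When a nutrient is reported on both bases
but disagrees with the serving-size scaling by more than 5% (relative),
the engine warns and keeps the reported values: disagreement is a data-
quality signal, not a license to edit data. The macronutrient rule is
applied on whichever basis carries all three macros.

Items still lacking a serving size after completion receive their
subcategory's mean serving size (the primary strategy) with provenance
`subcategory_imputed`. The subcategory statistics — mean, median, and
quartiles by linear interpolation between order statistics (R's default
quantile type 7; the convention is configurable in principle and recorded
here) — are computed only over reported or derived serving sizes, never
over imputed ones, so imputation cannot feed back into its own inputs.

## Target assignment

Category membership for each programme is configuration, not code: a
category map is an ordered rule list matching on subcategory and/or an
explicit per-item label, because assigning foods to the government's
category system is a judgement call that belongs in reviewable config.
The hierarchy, however, is mechanical and fixed:

1. sugar rules are evaluated first; calorie rules only for items with no
   sugar match — no item ever holds both a sugar and a calorie target;
2. salt rules are evaluated OOH-sector first, then
   retailer/manufacturer for the remainder, and the matched sector is
   recorded;
3. the salt comparison basis travels with the matched target row (OOH
   rows typically per serving, retailer/manufacturer rows per 100 g).

This yields exactly four eligibility states per item: ineligible for
all programmes, eligible for one, salt-and-calorie, or salt-and-sugar.

Pizzas get special handling. A *sharing* pizza is large-or-above or at
least 11.5 inches in diameter — either condition suffices. For the
calorie comparison, whole-pizza energy is divided by a serving count:
the restaurant's declared count when present; else 1 for Italian-style
pizzas; else a size-label rule (small 1, medium 2, large 3, extra-large
4); else diameter breakpoints at 10.5/12.5/14.5 inches. The
small-1/medium-2 and diameter completions extend the published
large-3/extra-large-4 assumptions to the remaining sizes in the same
spirit (a medium is conventionally shared between two). A takeaway pizza
with none of these clues is flagged unassignable and leaves the calorie
denominator only, with an audit entry.

## Adherence

A target is met when the compared value is less than or equal to the
target value — boundary inclusive, so the tests assert that perturbing a
value at equality by +ε flips the call and by −ε does not. Sugar is
compared per 100 g, calories per serving, salt on the matched target's
basis. An item whose required basis value is still missing after
completion is dropped from that programme's denominator only (with an
audit note) and remains in the others — the all-applicable judgement is
then over its remaining eligible programmes.

Counts are carried as exact integers; percentages are rounded only at
report time (default whole percents), so a 1271/2951 never silently
becomes ambiguous between 43% and 43.07%.

Aggregation produces, per grouping (overall, restaurant, subcategory,
restaurant type), counts and proportions for each programme and for
all-applicable, whose denominator is the set of items eligible for at
least one programme. Denominator conservation — each grouping's eligible
and met counts summing to the overall counts — is asserted on every
pipeline run, not just in tests.

## Descriptive summaries

Nutrient summaries (mean, median, SD) are computed for kcal, salt,
sugar, and fat on three bases: per 100 g, per reported serving (for
pizzas, the serving as the restaurant declared it), and per
subcategory-average serving, in which *every* item's per-100g value is
rescaled by its subcategory's mean serving size as a parallel column
family — not merely a fill-in for missing values. SD is the sample
standard deviation (n − 1), reported as 0 for single-item groups; the
choice is recorded in output metadata. Distribution exports provide the
five-number summaries (min, quartiles, max) behind box-plot figures,
using the same quantile convention as the serving statistics.

## Sensitivity analyses

Two perturbations re-run the identical pipeline:

* `exclude_lto`: limited-time-offer items are removed before any stage;
  denominators shrink by exactly the excluded eligible counts.
* `serving_lq` / `serving_uq`: missing serving sizes are imputed with the
  subcategory lower/upper quartile instead of the mean. The quartiles
  come from the primary run's serving statistics, so the strategies
  perturb imputation only, never the statistics themselves — and
  provenance tracing lets the tests assert that all resulting changes
  flow through `subcategory_imputed` items.

The three-strategy comparison tables (average / lower quartile / upper
quartile) cover six nutrient-basis rows and the four adherence rows.
A smaller imputed serving size mechanically raises per-100g values for
per-serving-only items and lowers per-serving values for per-100g-only
items, which is the direction the comparison tables show.

## The synthetic corpus

No real menu corpus ships with the package, so the generator is a
first-class module. Its defaults describe the study conditions the
pipeline is designed for: 21 restaurants in a 3/2/5/6/5 mix over the
five types, a mean of 148 items per restaurant clipped to 40–330 (drawn
log-normally; the −0.10 meanlog offset keeps the post-clipping mean on
target), stylised subcategory menu profiles per type, and per-subcategory
log-normal macronutrient densities from which energy is computed exactly
as 4·protein + 9·fat + 3.75·carbohydrate — so macro-implied energy is
consistent by construction. Sugar is a Beta-distributed share of
carbohydrate (high for Desserts), salt log-normal (highest for Sauces),
serving sizes truncated-normal per subcategory, with pizza size labels,
diameters, declared serving counts, and an Italian-style fraction of
0.15.

Missingness is the observed pattern: 32% of items report per-100g only
and 28% per-serving only; serving size is withheld at rate 0.88, so
about 53% of items ((0.32 + 0.28) × 0.88) are single-basis with no
serving size and require subcategory imputation — the share the study
design reports. kJ-only energy and sodium-only salt each occur at rate
0.10, a small unusable fraction (0.005) exercises the exclusion rule,
and 1.2% of items are limited-time offers.

Targets are placed at order statistics of the generated compared-value
distributions: for a designed met fraction f and n eligible items in a
category, the target sits midway between the k-th and (k+1)-th order
statistics with k = round(f·n), so exactly k items meet it, robustly to
the ~1-ulp floating error a per-100g/per-serving round trip can
introduce. The designed fractions default to 61% calorie, 58% salt, 36%
sugar. This makes adherence a sharp ground truth: with restorable
missingness (serving sizes present or derivable) the pipeline must
recover the designed met counts *exactly*, and under subcategory-mean
imputation any deviating met flag must belong to a provenance-traced
imputed item. Both properties are asserted in the acceptance tests at
full scale (~3,000 items).

What the generator does not emulate: real restaurants' actual nutrient
values or brand-level idiosyncrasies, sales weighting, menu churn over
time, or correlated missingness (a restaurant that hides serving sizes
for all its items). Passing tests therefore demonstrate that the
*pipeline logic* is exact and well-behaved under realistic data shapes —
not that any particular real-world adherence percentage is correct.

## Numerical choices and degenerate inputs

* Quartiles: linear interpolation (type 7) everywhere, verified against
  a brute-force oracle on {10, 20, 30, 40} → 17.5/32.5.
* Unit-pair invariants after completion: kJ = 4.184 × kcal and sodium =
  400 × salt at 1e-6 relative tolerance wherever both are present.
* A derived serving size that is not positive is discarded and the item
  flagged rather than propagated.
* Empty groups are omitted from summaries with a warning; single-item
  groups report SD 0.
* Duplicated (restaurant, item) pairs warn but are kept: de-duplication
  is an explicit upstream decision, not silent behaviour.
* Zero compared values meet any positive target (0 ≤ target).

## Problem sizes

The test suite exercises unit fixtures of up to 50 items, property
suites over seeded 20–40-item corpora, and full-scale synthetic corpora
of roughly 2,500–3,500 items for the end-to-end recovery and invariant
checks; the acceptance script runs the complete analysis twice at full
scale. These sizes were chosen to match the corpus scale the analysis is
designed for while keeping the whole suite comfortably interactive.

## Known limitations

* Category assignment quality is only as good as the supplied category
  map; the package validates referential integrity and first-match
  shadowing but cannot judge whether a mapping is nutritionally sensible.
* The engine trusts reported values even when internally inconsistent
  (it warns at >5% cross-basis disagreement but never corrects), so
  systematic under-reporting passes through unchanged.
* Salt targets of kind "average" and "maximum" are both representable,
  but the pipeline applies whichever value the target table carries; it
  does not model fleet-average compliance, only item-level comparison.
* Proportions are unweighted item counts; sales weighting is out of
  scope.
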