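---
title: "Methods: the updated Nutri-Score algorithm and the snapshot comparison pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the updated Nutri-Score algorithm and the snapshot comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscoreR)
```

## Scope and model

`nutriscoreR` computes Nutri-Score classifications of branded foods with
the updated algorithm (solid-food revision of 2022, beverage revision of
2023) and compares two market snapshots — one table of products per year —
to quantify how class distributions shifted, and whether shifts came from
reformulation of products sold in both years or from the turnover of the
assortment.

The scoring model is a pure function of a product's per-100 g (per-100 mL
for beverages) composition. Unfavourable components (energy in kJ, sugars,
saturated fatty acids, salt, all in g) earn *negative points* `N`;
favourable components (protein, fibre in g; fruits/vegetables/legumes, FVL,
in percent) earn *positive points*. Each component is scored by a grid of
ascending cutoffs: the points are the number of cutoffs the value reaches,
capped at the grid maximum. FVL uses a sparse band mapping instead (solids:
0/1/2/5 points at 40/60/80 %; beverages 0/2/4/6). The final sum is
`N − P_applied` where `P_applied` drops protein points in some situations
(below), and maps to the letters A–E by category-specific intervals.

Special rules, all parameters of the scheme file rather than code:

* *Protein counting.* For general solids, protein points are not counted
  when `N ≥ 11`, unless the product is a cheese. The updated solid-food
  algorithm keeps only the cheese exemption (the older
  high-FVL exemption no longer exists). For fats/oils/nuts/seeds the
  threshold is `N ≥ 7`; beverages always count protein.
* *Red meat.* Products flagged as red meat have protein points capped at 2.
  Flagging is a case-insensitive, diacritic-folded keyword search over
  product name plus ingredient list (Dutch and English default terms,
  editable in the scheme file), since branded-food databases carry no
  red-meat flag.
* *Sweetened beverages.* Beverages whose label text matches the
  non-nutritive sweetener keyword list receive 4 additional negative
  points.
* *Water rule.* Only mineral waters (an input flag, `is_water`) receive
  class A among beverages; the numeric beverage bounds therefore start at
  B, making A unreachable for any other beverage no matter how it
  reformulates.
* *Fat category.* Fats, oils, nuts and seeds score saturated fat as the
  SFA/total-fat ratio (percent) and use an energy grid in 120 kJ steps;
  `total_fat_g` is mandatory for these records.

## The cutoff boundary convention

Official grid tables are printed as intervals of the form "> x to ≤ y". Read
literally, a value exactly on a cutoff does *not* earn the point
("strict"). The package supports both this and the "inclusive" convention
(value ≥ cutoff earns the point) as a one-line scheme switch, because the
two differ in a documented, consequential place: lowering sugars from 17 to
13.5 g/100 g on the general-solid grid (cutoffs ... 10, 14, **17**, 20 ...)
removes *two* points under the inclusive convention but only *one* under
the strict one, since 17 sits exactly on a cutoff. The shipped default is
`inclusive`, which reproduces the two-point worked example used in
reformulation-headroom reasoning for breakfast cereals; the grids
themselves are identical under both conventions, and for continuously
distributed composition data the two conventions almost surely agree. The
active convention is part of the scheme, printed with it, and recorded in
every pipeline run log.

## Data preparation

The preparation pipeline applies, in a fixed and logged order:

1. keep processed foods only (`is_processed` is input data; "processed" is
   not inferred from composition);
2. exclude records missing any of the five mandatory components (energy,
   salt, SFA, sugars, protein) — fibre or FVL missingness never excludes;
3. impute missing fibre with the arithmetic mean of observed fibre in the
   same food group *and year* (fibre declaration is optional on labels, so
   missingness is common and structural); a group-year with no observed
   fibre at all is an error, not a silent zero;
4. fill missing FVL with the taxonomy's per-group estimate (branded-food
   databases do not carry FVL; the estimates are editable configuration);
5. drop group-years with fewer than 10 products.

Imputation runs after the mandatory-component filter so the means are
computed over the records that actually enter the analysis, per year. The
report object reconciles exactly: input = excluded + retained, and the
imputed count equals the missing-fibre count among surviving records.

## Comparison statistics

Per food group and year the pipeline reports medians and interquartile
ranges of energy and each nutrient, the class distribution in percent, the
integer histogram of the final sum, and the mean final sum. The median uses
the midpoint convention for even group sizes and percentiles use linear
interpolation (`stats::quantile()` type 7); both choices are deliberate,
documented, and tested against sort-based oracles, since no single
percentile definition is canonical.

Change between years is expressed per class in percentage points
(`pp_change`, later minus earlier; sums to zero within a group). The
per-group *overall change* aggregates these as Σ|Δpp|/2 — the
total-variation distance, i.e. the share of the group's products that moved
between classes, which makes thresholds like "≥ 7 percentage points"
interpretable as mass moved. The raw Σ|Δpp| variant is available
(`metric = "abs_sum"`); the choice is recorded in the run log. The top-k
(default 5) groups by overall change are selected for in-depth output
(per-class nutrient medians, final-sum histograms); ties break by group-key
order so selection is deterministic.

The EAN-matched sensitivity analysis inner-joins the two years on the
product identifier and reports, per group, the share of matched products
whose class *letter* changed; a final-sum change within the same letter
counts as no change. Duplicated EANs within a year are an error because the
join would silently multiply rows.

## The synthetic market generator

Real branded-food databases are proprietary, so the generator emulates
their structure at reduced scale: per-group product counts in the hundreds,
right-skewed nutrient distributions, structural fibre missingness, absent
FVL, partial EAN carry-over between years, reformulation of carried-over
products and diversification (new products from a shifted distribution),
plus keyword-flag injection (red meat, sweeteners) and a mineral-water
fraction in beverage groups.

Each nutrient is drawn log-normally, parameterised *analytically* from a
target median `m` and IQR `w`: `meanlog = log m` and
`sdlog = asinh(w / 2m) / Φ⁻¹(0.75)`, so configured medians and IQRs are
matched exactly in distribution, not by calibration. Nutrients are drawn
independently — adequate for testing a componentwise scoring engine, but a
simplification of real composition data, where sugars, energy and fat are
correlated; recovery results on synthetic data therefore validate the
pipeline's arithmetic, and say nothing about covariance-sensitive questions
(which the pipeline does not compute). Values are truncated at 0 and sugars
at 100 g. All randomness derives from one master seed; generation is run
twice reproducibly in the test suite.

Default conditions (`synthetic_config()`): six food groups of 300–500
products per year with market-plausible medians (e.g. breakfast-cereal
sugars 17 g median, 12 g IQR; dairy/plant beverage sugars 6.9 g), 60 % EAN
carry-over, 30 % fibre missingness, FVL always estimated, sugar
reformulation injected into breakfast cereals (−3.5 g) and dairy/plant
beverages (−2 g). These defaults keep every test in seconds while
exercising all three scoring categories and all special rules.

## The parameter-recovery benchmark

`recovery_config()` fixes a larger experiment used by the acceptance
checks: five groups × 2000 products per year, 50 % carry-over, sugar shifts
(−4 g cereals, −2.5 g dairy/plant beverages) applied to carried-over
products and to new-product draws. Two design rules are part of the
benchmark, both chosen so that its checks can only fail for the reason they
test:

* *Dispersion cap.* Each configured IQR is capped at 0.8 × median, which
  keeps the sampling error of an empirical median at n = 2000 below ~1.7 %,
  so the 5 % recovery band is at least three standard errors wide for every
  nutrient. Without the cap, a highly skewed nutrient can miss a 5 % band
  by pure sampling fluctuation even when the generator and pipeline are
  exact.
* *No fibre missingness, FVL fully estimated.* Group-mean fibre imputation
  is year-dependent: an unshifted product sold in both years would receive
  two different imputed fibre values and could change class without any
  reformulation. Setting fibre fully observed (and FVL to the constant
  per-group estimate) makes carried-over products bit-identical across
  years unless reformulated, so the matched-EAN class-change shares must
  agree *exactly* with shares derived from the generator's truth record.

Under these conditions the benchmark checks: recovered group medians within
5 % of targets; the two shifted groups ranked top-2 by overall change; and
exact matched-share agreement. Problem sizes (2000 per group-year, ~10⁴
scored products per run) keep a full run under a few seconds.

## Numerical and degenerate-input choices

* All points are integers by construction, so final sums are integers;
  `classify_sum()` rejects non-integers rather than rounding.
* Class intervals are validated on scheme load: contiguous on integers,
  non-overlapping, covering all attainable sums (beverage bounds cover
  everything below B's upper end since A is water-only).
* Grid cutoffs are validated strictly ascending; `component_points()`
  rejects negative or missing values instead of scoring them.
* Missing data sentinel is the empty CSV cell; 0 is always a legal value.
  Sodium-declaring sources are converted once at ingest (salt = sodium ×
  2.5) with a message.
* Energy is stored in kJ (4.184 kJ/kcal if converting at ingest).
* A fats/oils product with zero total fat has an undefined SFA ratio; it is
  scored as ratio 0 (no saturated fat present either, since SFA ≤ total
  fat is a record invariant).
* Percentages are kept at full precision internally; rounding is left to
  display.

## Known limitations

* The FVL content and the taxonomy's per-group estimates are configuration,
  not measurement; classifications of FVL-sensitive groups (preserves,
  legumes) are only as good as those estimates.
* Keyword flagging of red meat and sweeteners is substring-based; it is
  deterministic and auditable but can miss paraphrases or hit false
  positives in unusual label text. The lists ship as editable defaults.
* The generator's independence across nutrients and log-normal family are
  modelling choices for testability, not claims about real label data;
  passing recovery tests demonstrates correct pipeline arithmetic, not
  market realism.
* No inferential statistics are produced (no tests or confidence
  intervals): the pipeline describes distribution changes.
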