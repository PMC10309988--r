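---
title: "Methods: farm-system economics of cattle tick control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: farm-system economics of cattle tick control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acarecon)
```

## The problem

Ticks (*Rhipicephalus microplus* above all) burden subtropical dairy herds
twice over: directly, through parasitism and tick-borne disease, and
indirectly, through the money farms spend on acaricide control — money that
buys less and less as acaricide resistance spreads. Measuring that burden
farm by farm requires a full accounting exercise: every input cost and every
revenue of the production year, with the acaricide-treatment outlay placed
in the context of the whole budget. `acarecon` implements such a
farm-system evaluation as a reusable pipeline: annual cost accounting,
larval-packet-test resistance classification, a k-means farm typology,
contingency analysis of resistance against infestation, and decision-tree
models of acaricide-treatment cost shares selected by a repeated
train/test-split procedure.

The surveyed population that motivates the defaults — 105 dairy farms in
two subtropical Andean foothill zones, evaluated for the 2020–2021 fiscal
year in USD — was never deposited as a public dataset. The package
therefore ships a first-class synthetic-cohort generator that reproduces
the published statistical structure of that population, so every stage of
the pipeline can be exercised and tested end to end.

## The cost-accounting model

Annual expenses are coded E1–E18 and classified as variable or fixed:

* **Variable costs**: `VC = E1 + E2 + E3 + E4 + E5 + E6 + E7 + E8 + E10 +
  E11 + E12 + E17` (feeding, labour, veterinary services and drugs, pasture
  management, insemination, equipment maintenance, transport, pasture rent,
  animal replacement).
* **Fixed costs**: `FC = E9 + E13 + E14 + E15 + E16 + E18` (infrastructure
  depreciation, taxes, mortality, theft, basic services).
* **Total cost**: `TC = VC + FC`, under two veterinary-service scenarios.
  Scenario A uses the veterinary fees actually paid (`e5_real`); scenario B
  values state-subsidised veterinary services at the average private-visit
  price (`e5_opportunity`). The scenarios differ exactly by that E5 gap.
* **Milk production cost**: `TCM = TC_A − E2 − E14 − E15 − E16` (calf
  feeding, mortality and theft are excluded because replacement-animal
  purchases are costed instead), and the cost per litre
  `CPM = TCM / AMP` with `AMP` the annual litres produced.
* **Revenues**: `TR = R1 + R2 + R3` (milk delivered, on-farm consumption at
  opportunity cost, cattle sales) and **profit** `P = TR − TC`.

Supporting rules, each with its default and unit:

| Rule | Default | Notes |
|---|---|---|
| Straight-line depreciation | infrastructure 20 y, equipment 11 y | residual value 0 |
| Animal useful life | cows 9 y, bulls 5 y | drives E17 per animal |
| Milking labour | 18 cows/worker manual, 25 mechanical | requirement is the ceiling of the ratio, since partial workers are impossible |
| Mortality cap | 3% of the herd per year | capped deaths are costed cheapest-first |
| Price deflation | 2.56%/yr, one multiplicative period | drug prices collected a year late |

Two conventions deserve a note. The E8 insemination outlay merges into E5
when a professional performs the insemination: the per-farm flag
`insemination_by_professional` moves the amount once, so it is never
counted twice. And the mortality cap is applied to the *count* of deaths
(floored to whole animals); when it binds, the cheapest deaths are costed
first — a deliberate, conservative tie-break.

The four tree responses are ratios of the acaricide-treatment cost
(drugs + application labour): model 1 as % of total cost, model 2 in USD
per adult animal, model 3 as the tick-drug share of the E6 drug ledger, and
model 4 as % of the sanitary cost (E6 + E5 + sanitary labour). Sanitary
labour beyond the application labour is a configurable fraction of E3+E4,
default 0, because task-level labour data are rarely collected. Model
denominators use scenario A unless scenario B is requested, keeping the
metrics consistent with the milk-cost calculation.

## Resistance classification

The larval packet test exposes ~100 larvae per packet to discriminating
concentrations (amitraz 0.1%, alpha-cypermethrin 0.02%, ivermectin 0.1%
w/v), two replicates plus a control, read at 24 h. Survival is
`100 −` mean replicate mortality, classified as:

| Category | Survival |
|---|---|
| susceptible | [0, 10) |
| low (susceptible with restriction) | [10, 20) |
| medium (emerging resistant) | [20, 50] |
| high (resistant) | (50, 100] |

The published band edges overlap ("10–20", "20–50"); we close them on the
left at 10 and 20 and close the medium band at 50, since ">50%" is printed
strictly. A farm counts as *resistant* when the category is medium or high
— equivalently, survival ≥ 20%.

Abbott control correction (`100(m − c)/(100 − c)`) is available but **off**
by default: a control group was run in the field protocol, but no
correction is stated, so the default reproduces the uncorrected reading.
Control mortality above 10% invalidates an assay (strictly above: a control
of exactly 10% is still usable with the correction). The farm-level
high-infestation flag follows an external field methodology whose
thresholds are not published here; `infestation_status()` therefore takes
both thresholds (per-animal count, farm fraction) as explicit arguments
with no hidden defaults.

## The synthetic cohort

`generate_cohort()` draws 105 farms in five latent groups of sizes
21/17/27/23/17, matching the published typology:

* **Attributes** follow the per-group templates (farm-size class, external
  paddocks, technification, veterinary control, labour, crops,
  supplementation, grass cut, milk price/destination, education, owner
  hours), each categorical attribute flipped to another level with
  probability 0.05 to mimic within-group heterogeneity.
* **Costs** are drawn from normals truncated at zero (resampling until
  non-negative) with the published per-group mean/SD of each grouped
  component. Truncation is mandatory: several published SDs exceed their
  means. Grouped amounts are split into constituent E-codes with fixed
  shares (feed 85/15 between cows and calves; labour by the published
  per-group paid/unpaid shares; infrastructure 70/30 between depreciation
  and maintenance; animal entry/departure 30/20/10/40 across E14–E17).
  The group-5 SD row of the source table duplicates group 4 verbatim — an
  apparent typesetting artefact kept as printed and flagged in
  `default_cost_params()`.
* **Resistance** flags are independent Bernoulli draws at prevalences
  0.4952 / 0.5333 / 0.3714 (amitraz / alpha-cypermethrin / ivermectin),
  drawn independently of the infestation flag — matching the published
  non-significant contingency tests. Assay replicates are scattered around
  the implied mortality with an SD of 3 percentage points (no dispersion
  was published; 3 points keeps replicate pairs as tight as routine larval
  packet tests) and redrawn if observation noise would cross the 20%
  decision boundary, so derived flags equal latent flags.
* **Infestation** probability depends on technology only: 0.48 / 0.55 /
  0.25 for non-/semi-/technified farms, giving an overall prevalence of
  ≈45.7% with technified farms near 25%, the published pattern.
* **Treatment cost** per adult animal is drawn by technology level (means
  23 / 14 / 8.5 USD, SD 7), the published gradient from non-technified to
  technified farms; labour takes 15–30% of it. The E6 drug ledger is
  floored at 1.25× the tick-drug cost so the model-3 share stays a true
  percentage.
* **Herds and production** (herd size, yields, zone mix, cattle sales) are
  not tabulated in the source; the defaults are chosen once so per-group
  annual milk production and total revenue land on the published scale
  (e.g. ≈120,000 L/yr and ≈64,000 USD revenue for the large technified
  group).

One master seed spawns a per-farm substream (a per-farm seed drawn up
front), so cohorts are reproducible farm by farm; within a farm the
component draws are sequential. What the generator does **not** emulate:
correlations among cost components within a farm, measurement error in the
ledgers, spatial structure, multi-year dynamics, or any genuine
resistance–infestation dependence. Passing recovery tests therefore shows
the pipeline recovers planted structure of this kind — not that the
published field estimates are correct.

## Typology

The twelve typology variables are recoded to small ordinal integers
(`default_ordinal_map()`): three-level variables as 0/1/2 in their natural
order, booleans as 0/1, farm area binned at 20 and 45 ha (the published
small/medium/large classes), owner hours at 2 and 4 h/day, and milk price
at 0.42 USD/L — the regulatory reference price separating ordinary from
premium remuneration. Features are used unscaled by default: all codes
share comparable ranges, and z-scoring is available by flag.

k-means is run as the best of 25 restarts (Hartigan–Wong updates,
`iter.max` 100). The number of clusters comes from the elbow of the
within-cluster sum-of-squares curve. We formalise the elbow as the maximum
discrete second difference of **log** WSS — the ratio of successive
proportional drops. The raw-WSS second difference (available as
`method = "raw"`) is scale-dependent and collapses to k = 2 whenever one
group is much farther from the rest than the others are from each other,
which is exactly the geometry here: the large technified group is several
times more distant than any other pair. The log rule is scale-invariant,
picks the planted k = 5 on default cohorts, and still gives k = 2 on
curves with a single dominant bend. A near-linear curve (maximum
successive-drop ratio below 1.1) is flagged low-confidence.

## Decision trees and model selection

Trees are grown by greedy binary recursive partitioning (variance reduction
for regression, Gini for classification) with defaults `min_split = 20`,
`min_leaf = 7`, `max_depth = 5`, `complexity = 0.01` — sized to produce the
5–7 terminal nodes that are interpretable at n ≈ 105. Categorical splits
search all binary partitions (every predictor here has ≤ 3 levels).
Prediction routes rows down the fitted partition; an unseen categorical
level at a split is routed to the majority side with a warning.

The selection procedure formalises "run it many times and keep the
concordant models": 100 random 75/25 splits; per run, fit on the training
split and screen the **test** predictions — ordinary least squares of
observed on predicted must give a 95% CI for the slope containing 1 and for
the intercept containing 0, and a Bland–Altman one-sample t-test of the
differences must not reject zero mean at α = 0.05. Among passing runs the
one with minimum test MSE is kept, with a full run log either way. "Close
enough to one/zero" had no published tolerance; CI coverage is our
formalisation, as is the t-test for "did not differ significantly". The
screens are applied to the held-out split because that is what "testing the
model" tests. Degenerate cases have fixed conventions: constant predictions
fail the screen (flagged degenerate); zero-variance differences give
Bland–Altman p = 1 at zero mean and p = 0 otherwise; an exact linear
relation yields zero-width intervals.

The infestation classifier (technology + three resistance flags) is fitted
on the full cohort and summarised by AUC-ROC — the Mann–Whitney
concordance probability with ties counted ½ — with a DeLong 95% interval
(bootstrap available by flag). Terminal nodes are profiled with their size,
share, mean response ("Avg") with a 95% interval (t-based for regression,
exact binomial for classification), and attribute composition.

## Contingency analysis

2×2 tables of infestation against each single and combined resistance flag
are tested with the two-sided Fisher exact test under the probability-mass
rule (sum over tables with the observed margins that are no more probable
than the one observed) — the convention of standard statistical software;
the source does not state its two-sided rule. Zero-margin tables return
p = 1 with a degenerate-table warning. Prevalences carry exact
Clopper–Pearson intervals. P-values are rounded to 2 decimals only at the
reporting layer.

## Test problem sizes

The suite exercises: 1,000-ledger accounting identities; full-enumeration
Fisher oracles for tables up to n = 50; a 10,000-farm cohort for the
prevalence calibration; 1,000 generated cohorts for the
resistance–infestation independence rate; 20 master seeds for the typology
(elbow k and adjusted Rand index) and tree-recovery properties; and 1,000
null replicates for the Bland–Altman type-I error. These sizes give the
binomial checks ~3σ margins while keeping the default run comfortably
interactive.

## Known limitations

* The undeposited farm-level dataset means published farm-level results
  (per-group cost tables, the AUC of 0.64, node averages, selected-model
  R²/MSE) are scale references, not reproduction targets; recovery
  properties on synthetic cohorts stand in for them.
* The infestation field rule is parameterised, not reproduced; cohorts
  carry the flag directly.
* Costs are single-year USD; no discounting, currency conversion, panels
  or loan amortisation.
* Cluster identities are recoverable only up to relabelling: the published
  ordinal codes and any scaling are unstated, so the shipped map is a
  documented choice.
* Trees use complete cases by design (validation enforces completeness);
  there are no surrogate splits, and no ensemble methods.
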