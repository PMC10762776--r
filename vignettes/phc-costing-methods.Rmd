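---
title: "Methods: activity-based and normative costing of a PHC network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-based and normative costing of a PHC network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phccost)
```

## The problem

Planning and budgeting for universal health coverage needs two numbers that
are rarely both available: what a primary health care (PHC) network —
health posts, health centers, and primary hospitals — *actually* spends per
person per year, and what delivering a defined benefit package to everyone
in need at target coverage *would* cost (the normative cost). The
difference is the resource gap. `phccost` implements this comparison as a
reusable pipeline: activity-based costing of a facility sample, three
extrapolation estimators to a regional network, protocol-based normative
costing with an overhead uplift, and one-way/scenario sensitivity analysis.
A synthetic-data generator with known ground truth replaces confidential
facility survey microdata, so every stage is testable.

## Actual costing of one facility

A facility record holds a staff roster with annual remuneration (salary,
allowances, duties, summed), clinical time-use fractions over the five
clinical departments — outpatient (OPD), HIV/AIDS, maternal and child
health (MCH), delivery (DEL), and inpatient/operating room (IPD/OR) — plus
other-service, administrative, and unspecified activity; drug, medical
supply, and operational line items; and annual patient counts per
department. Allocation rules:

* **Clinical labor.** Each clinical staff member's remuneration is split
  across departments in proportion to their time-use fractions. Time on
  administration and unspecified activity is pooled into a single
  administrative bucket, because both end up in indirect administration and
  the reporting convention has a single administration row. Time on
  services outside the five departments (laboratory, environmental health)
  forms a separate *other service* bucket that is never distributed.
* **Drugs and supplies.** Items tagged with a department go there wholly;
  untagged items are split in proportion to department clinical labor cost
  (shares over the five departments only — administrative labor is not an
  allocation basis).
* **Indirect costs.** Administration = non-clinical remuneration plus
  clinical administrative/unspecified labor; other indirect = untagged
  operational spending (utilities, maintenance).
* **Health posts** are costed in totals only: time-use data are not
  collected at that level and their indirect costs sit with the associated
  health center, so no department allocation is attempted and their
  overhead rate is zero by convention.

Department unit costs add the department's labor, its drugs and supplies,
and a share of *other indirect* costs allocated by labor; they exclude
administration and other-service costs, which the overall unit cost (total
cost over total patients) does include. A department with cost but no
patients is flagged and reported as undefined, never infinite. Money is
conserved by construction: the five department costs plus other-service,
administration, and other-indirect buckets equal total remuneration plus
total line items, and the test suite asserts this at 1e-6 relative
tolerance on every generated facility (observed error is at machine
precision). Amounts are carried as doubles with a currency label —
conversion from local currency to US$ happens exactly once, and converting
an already-converted amount is an error; we rely on tolerance-based
conservation checks rather than a decimal type.

## Extrapolation to the network

Three estimators scale the sample to the regional network:

* **A1 (catchment norms):** each facility's total cost is divided by the
  midpoint of the reference catchment-population norm for its level; the
  level value is the *simple unweighted mean* of these per-capita costs,
  multiplied by the pooled regional population.
* **A2 (reported catchments):** identical, but dividing by the
  facility-reported catchment. Facilities without one are dropped with a
  warning. Because facilities tend to report catchments larger than the
  norms, A2 generally sits below A1.
* **B (utilization expansion):** department service counts are weighted by
  the sample's mean department unit costs (computed per level, since unit
  costs differ strongly by level; health posts use their overall unit cost
  as a single uniform weight). The expansion factor for each region × level
  is total weighted region-wide utilization over total weighted sampled
  utilization in that region; sampled costs are multiplied by these
  factors. The estimator is invariant to rescaling all weights, which the
  tests assert; a display-normalized weight column (OPD = 1) is provided.

Estimators A1/A2 yield only a per-capita scalar per level, so their
component split (clinical labor / drugs & supplies / indirect) applies the
sample's level-wise component shares — the only reading consistent with
reporting components for a catchment-based estimate.

When a region has utilization at a level but no sampled facility there, a
pooled factor is borrowed: the level's total weighted regional utilization
over total weighted sample utilization across sampled regions. Since no
sampled cost exists in such a region, the implementation applies the
pooled *cost per weighted utilization unit* to the region's weighted
utilization — algebraically the borrowed-factor rule applied to a
proportional cost share. A warning reports every borrow.

## Normative costing

Each benefit-package service carries a standard treatment protocol (STP):
the eligible population fraction, an episode rate (incidence or
prevalence, episodes per eligible person-year), a coverage target,
encounters per episode, consumable quantities and unit prices, and labor
minutes per cadre with per-minute wages. Then, per service:

* population in need = population × eligible fraction × rate;
* episode direct cost = Σ quantity × price + encounters × Σ minutes × wage;
* annual cost = population in need × coverage target × episode cost,

aggregated by facility level and department. Labor minutes are read as
*per encounter* by default (`stp_minutes_per` switches to per-episode):
protocols that state encounters per episode alongside minutes per service
most naturally price each encounter's staff time.

STPs cover direct costs only. The overhead rate *r* per level is taken from
the actual sample as indirect over **total** cost; the uplift is therefore
`total = direct / (1 − r)`, which is the only form that preserves
`indirect / total = r` exactly (a `direct × (1 + r)` markup would not, and
the published normative indirect-to-total ratios match the sample's
indirect shares only under the reciprocal form). Health posts get r = 0.
The department view allocates a level's normative indirect cost in
proportion to department direct costs; department rows in the gap report
carry direct cost only, with indirect as its own row, matching how the
actual side is reported.

## Gap and sensitivity

The resource gap per level (and overall) is normative minus actual
per-capita cost; the percent gap is that difference over the normative
value, computed unrounded and displayed as a half-up integer (per-capita
values display at one decimal, ties away from zero — base `round()`'s
banker's rounding would misprint ties). Negative gaps are reported as
negative and flagged as excess funding rather than clipped.

Sensitivity scenarios apply relative adjustments to cost components and the
population denominator. Defaults: actual costs vary clinical labor by
±10% and drugs, supplies, and indirect costs by ±20% (expenditure data are
noisier than payroll); normative costs vary labor, drugs, and supplies by
±10% and indirect by ±20% (the normative overhead is itself derived from
actual data); population varies by ±5%. The worst case raises all costs
and shrinks the population; the best case mirrors it. When drugs and
medical supplies arrive merged — as network component tables report them —
the drug and supply adjustments must be equal and are applied once to the
merged value; unequal adjustments require the split input, and the code
refuses to guess. The one-way table adds each single-parameter adjustment
in both directions for tornado-style reporting.

## The synthetic-data generator

`generator_spec()` encodes the study conditions as defaults: 20 health
posts, 25 health centers, and 8 primary hospitals allocated across nine
regions (populations summing to 92.4 million) following the sample's
regional layout; log-normal cost components per level with locations at
the observed sample medians and scales reproducing the observed
mean/median skew (costs are strongly right-skewed — e.g. health-post mean
total about 11.5k US$ against a 6.6k median); staffing counts and service
volumes within the observed ranges; service-output mixes per level with
essentially no delivery/HIV output and no inpatient care at health posts;
and sample-capture fractions of 0.1%, 2.3%, and 10.4% of network
utilization. One calibration subtlety: the indirect target distribution
describes *total* indirect cost, so the expected clinical
administrative-time labor is netted out before drawing non-clinical
payroll and operational items, avoiding double counting. Under these
defaults the generated health-center mean total cost sits near US$ 254k
and component shares land within a few points of the observed 36/39/25
(health centers) and 48/19/33 (primary hospitals) splits.

Region utilization is built as sampled counts scaled by `1/capture`, with
non-negative log-normal jitter on the scale-up part only — so region
utilization never falls below sampled utilization and expansion factors
are ≥ 1 by construction. `generate_known_truth()` switches the jitter off
and omits unsampled region-levels, making network totals, expansion
factors (exactly `1/capture`), and capture percentages known exactly;
per-facility truth components are computed by direct summation over the
generated micro-records, independently of the costing code path. The
end-to-end recovery test demands agreement to 1e-6 relative.

A single pseudo-random stream drives generation in a documented draw
order (facilities in level order; within a facility: cost targets,
staffing, remuneration weights, time-use fractions, items, outputs,
catchment; then utilization jitter; then the protocol tables), so a seed
pins every byte of the emitted CSV bundle.

What the generator does **not** emulate: within-facility correlation
between staffing and output (assumed independent — the data offer no
estimate), regional heterogeneity in disease burden, reporting gaps and
errors in routine utilization data, or the real 1,018-service benefit
package (the generated STP bundle is a small illustrative package).
Passing recovery tests therefore demonstrate the pipeline's arithmetic
fidelity under the stated construction, not robustness to real-world data
quality.

## Parameters, sizes, and numerical choices

* Exchange rate: 28.44 local currency units per US$ (2018/19), config.
* Catchment norm midpoints: 5,000 / 25,000 / 100,000 persons — editable
  placeholders for the official reference norms, which are not shipped.
* `working_days_per_year` = 365; the observed productivity tables do not
  state their divisor, so it is configurable rather than hard-coded.
* Time-use fractions must sum to 1 within 1e-9; conservation is asserted
  at 1e-6 relative; expansion-factor oracles at 1e-12.
* Medians use the midpoint-of-two-central-values convention (`median()`).
* Test and acceptance problem sizes: 53-facility samples, seed sweeps of
  10 for calibration and oracle checks, single known-truth runs for
  recovery — the full suite runs in under two minutes on one CPU, the
  acceptance script in well under one.

## Known limitations

The overhead uplift assumes indirect costs scale linearly with direct
costs — no economies of scale. Estimators A1/A2 inherit the unreliability
of catchment populations; estimator B inherits completeness issues of
routine utilization data. No variance or interval estimation accompanies
the point estimates; uncertainty is explored only through the scenario
analysis. Out-of-pocket spending, capital, and above-facility costs are
out of scope.
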