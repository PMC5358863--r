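---
title: "Age-threshold issuing in a two-bank RBC supply model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-threshold issuing in a two-bank RBC supply model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcflow)
```

## The model

`rbcflow` simulates a national red blood cell (RBC) supply chain as a
stock-and-flow system with two aggregate banks. Donations enter the
**Collector**; the **Hospital** transfuses patients and is resupplied by
the Collector. Stock is an integer inventory stratified by the eight
ABO/Rh phenotypes and by storage age in days (1 to the shelf life, 42
days by default). Unmet demand is lost, not backordered — a unit not
transfused today is not owed tomorrow.

Recipients are split into mutually exclusive classes: one or more
**high-risk groups** (HRGs — intensive care, cardiac surgery, coronary
care and trauma patients, whose transfusion shares come from a packaged
table of mutually exclusive group combinations) and the **baseline blood
recipients** (BBRs, everyone else). Baseline recipients are served
oldest-compatible-first (the `LO` policy, standard practice since it
minimises outdating). High-risk classes are served by the **Threshold
Method** (`TM7`, `TM14`, `TM28`): each demanded unit is filled by

1. an exact-phenotype unit stored at most the threshold age, oldest
   qualifying unit first;
2. failing that, a *compatible* unit within the threshold, donors in
   preference order within each age step;
3. failing that, the freshest available compatible unit of any age
   (last-in-first-out fallback).

Units issued by stage 3, plus demand not filled at all, are counted as
**unmet by age** — demanded units the system could not provide at or
below the required age. The percent unmet by age divides that count by
the class's total demand; **efficiency** is its complement
(100 − % unmet).

### Within-day event order

The daily cycle is: (a) donations enter the Collector at age 1; (b) the
Hospital transfuses the high-risk classes (Threshold Method, "practical"
compatibility rules); (c) the Hospital transfuses the baseline class;
(d) the Collector ships to the Hospital — first *young* units to cover
the next day's expected high-risk demand, then units of any age, oldest
first, until the Hospital holds six days of expected demand ("standard"
compatibility rules); (e) both banks age one day and units past the
shelf life expire. This order makes shipments serve the *next* day's
threshold demand, and it is the single point of truth for the engine
(`run_day()`).

Two timing subtleties are worth spelling out. First, a unit collected on
day *d* is usable the same day at age 1 (the alternative, next-day
availability, is a configuration switch; the model gives no reason to
prefer a lag and the same-day convention is the simplest). Second, the
young-unit shipment anticipates overnight aging: a unit shipped today at
age τ would be age τ+1 when transfused tomorrow, so only units of age at
most τ−1 are shipped against a threshold of τ, and the Hospital's
qualifying stock is counted the same way. Ignoring this off-by-one makes
the threshold unreachable by construction — shipped units arrive one day
too old — which is easy to verify in a single-phenotype toy world.

### Donor preference order

When a compatible (non-exact) unit must be chosen, donors are ordered:
exact phenotype first, then ABO-compatible donors of identical Rh sign,
then Rh-crossing donors, canonical phenotype order within each tier.
Preserving Rh conserves the scarce Rh-negative stock. Both
compatibility matrices default to textbook red-cell rules and can be
replaced from CSV; the inter-bank ("standard") matrix can optionally be
restricted to identical-phenotype transfers.

### Overlapping groups and the youngest-threshold rule

The group shares ship as a table of *mutually exclusive* combinations
(ICU only, CS ∩ ICU, ...), so unions are sums of rows. When a scenario
assigns different thresholds to overlapping groups, each row takes the
youngest (minimum) threshold among the selected groups it intersects:
a patient in two groups gets the stricter freshness requirement. Rows
are then pooled by threshold into `TM<k>` classes and the residual share
becomes the BBR class. Summing the packaged table's trauma rows gives
5.33%, while coarser summaries of the same source print 5.2% — an
intermediate-rounding artifact of the source data; the packaged table
is kept as printed at row level, so the trauma union is reported as
5.3.

## Synthetic calibration

The original model was calibrated to proprietary national donation and
billing extracts that are not public. The package therefore generates
synthetic daily streams:

* **Day totals** for donations and demand are negative binomial with
  configurable means and dispersion (`size`); the default dispersion 400
  gives roughly 5% day-to-day coefficient of variation at national
  scale, and `Inf` recovers the Poisson limit. Optional weekday
  multipliers (averaging 1) add within-week seasonality; they default to
  flat.
* **Phenotype composition**: each day total is thinned to the eight
  phenotypes by a multinomial draw with the replicate's prevalence
  vector. Prevalence itself is drawn once per replicate from a Dirichlet
  distribution with shape `baseline × concentration` (concentration
  1,000 by default; 10,000 for tighter uncertainty), centred on standard
  US frequencies (O+ 37.4%, A+ 35.7%, ... shipped as an editable CSV).
  Drawing once per replicate treats the Dirichlet as between-run
  uncertainty about prevalence; a flag redraws daily instead. The shape
  parameters multiply the probability-scale baseline (not percentages),
  so concentration is interpretable as a prior sample size.
* **Collection surplus.** Mean donations default to 8% above mean
  demand. This is not a free dial: US collections exceed transfusions
  (on the order of 14–16 million collected versus 13–14 million
  transfused annually), and the surplus is precisely the stock that ages
  in storage and eventually outdates. In a lost-sales system with equal
  means, standing inventory cannot accumulate beyond the start-up
  transient: every unit is transfused within days of donation, nothing
  ever expires, and the expiry–supply trade-off the model exists to
  study vanishes identically. The 8% default keeps the system in the
  regime the model describes — baseline expiries a few percent of
  throughput, old stock available for oldest-first issuing.

What the generator does *not* emulate: long-run seasonality and shocks
(holiday droughts, recalls), hospital-level heterogeneity, per-unit
attributes (irradiation, CMV status), and any correlation between
donation and demand streams. Passing tests therefore demonstrate the
mechanics and internal consistency of the allocation system under a
plausible national-scale regime, not a forecast for the real US supply;
absolute supply levels depend on the unpublished calibration and are out
of scope.

## Experiments

A scenario experiment (`run_experiment()`) runs every scenario over the
same replicates with **common random numbers**: shared initial banks,
and within each replicate the same prevalence draw and the same daily
donation/demand series; the demand-partition stream is re-seeded
identically per replicate so scenarios with the same class structure see
identical partitions. Cross-scenario contrasts are therefore paired.

Initial banks are the cell-wise average (rounded) of the final states of
independent burn-in runs under the baseline scenario, started from empty
banks. The package default burn-in is 200 days; the package's own
acceptance experiment uses 600 days because, with an 8% collection
surplus, the Collector's age backlog fills at the surplus rate and needs
roughly 500 days to stabilise. Scenarios with a shorter shelf life
truncate the shared initial banks to their own shelf life (units already
older than it are discarded at initialization).

Daily demand is split across recipient classes by a multinomial draw
with the class shares as probabilities — the shares are annual averages,
so daily composition fluctuates; a deterministic largest-remainder split
is available for exactness tests. Class totals always sum to the day's
demand.

### Problem sizes

The packaged experiments are desk-scale by design: 20 replicates of 365
days, mean daily demand 2,000 units (donations 2,160), 20 burn-in runs
of 600 days, across up to 14 scenarios. These sizes give stable
orderings of the reported measures (the qualitative contrasts are large)
while a full experiment finishes in minutes on one CPU. All sizes are
configuration values; nothing in the package depends on them.

## Measures

All measures are annual-average-daily (AAD) statistics over the horizon,
aggregated across replicates with normal-approximation 95% confidence
intervals (replicate-level, since replicates are the independent unit; a
percentile bootstrap would be a drop-in alternative). The weighted age
of transfused units pools unit-days over the whole horizon rather than
averaging daily means — identical under constant demand, and the pooled
version weights days by how much was actually transfused. Scenario
comparisons report percent reduction in AAD total supply against the
baseline scenario, sorted in descending supply order.

## Numerical and degenerate-case conventions

* Inventories are integer cohort counts; all allocation is exact integer
  arithmetic, so conservation (initial + donations = transfused +
  expired + final) holds exactly, and is asserted, on every run.
* Ties across phenotypes at equal preference break by canonical
  phenotype order (O−, O+, A−, A+, B−, B+, AB−, AB+); within the
  threshold, stages 1–2 issue the *oldest* qualifying units first, which
  conserves the freshest stock (switchable in principle; the oldest-first
  choice dominates in stock terms and is the documented default).
* Stage 3 scans ages from freshest upward with the donor-preference
  order within each age, so the fallback is always the freshest unit and
  prefers an exact match among equally fresh units.
* A class with zero demand has undefined percent-unmet and transfused
  age; both are reported as missing rather than zero.
* Shortfalls anywhere (transfusion or shipment) are recorded in the
  ledger, never raised as errors; the Collector ships what exists.
* With a threshold equal to the shelf life, stage 3 can never trigger
  and unmet-by-age equals plain unmet demand — a useful identity test.

## Limitations

The model is non-adaptive: shipment targets use the configured expected
demand, not forecasts from observed history, and no reservation or
lookahead policy is attempted. There is one collector and one hospital;
network effects and inter-hospital transfers are out of scope, as are
platelets and plasma, extended antigen matching, and emergency-release
policies beyond the compatibility matrices. Absolute magnitudes of
supply, expiry and unmet demand depend on the proprietary calibration of
the original study and are intentionally not reproduced; the package's
claims are about the direction and ordering of effects, which are
asserted by its test suite.
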