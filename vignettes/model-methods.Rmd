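---
title: "Model structure, assumptions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbtcea)
```

This vignette is the package's account of its science: the decision model,
the choices the published base-case table does not pin down, how each open
choice was fixed, and what the validation machinery does and does not
establish.

## The decision problem

University students with mild depressive symptoms (PHQ-9 5–9) can be
offered low-intensity CBT either in person or through a therapist-guided
internet platform. The two delivery modes differ in four places only:
acceptance (75.3% internet vs 63.3% in person), compliance (80.8% vs
83.9%), a relative-effectiveness multiplier on the recovery branch
(base 1.00), and the program cost ($41.44 vs $189 per participant).
Everything downstream — relapse, remission, mortality, care costs,
utilities, school dropout — is shared, so every incremental result is
driven by the small difference in the state distribution with which the
two cohorts leave the program window.

## Decision tree

The tree is resolved instantaneously at time zero. Non-accepters and
non-compliers both receive the no-intervention response probabilities
(spontaneous recovery 25%, deterioration 9.1%); the treated fraction
(acceptance × compliance) receives the low-intensity-CBT probabilities
(recovery 63.9%, deterioration 5.3%). The relative-effectiveness
multiplier applies only to the recovery branch of the internet arm, capped
so probabilities stay valid; deterioration is left untouched because a
single relative difference in effectiveness is all that is specified.
Program cost is charged to *accepters* by default — resources are
committed at enrollment whether or not a student later adheres
(`cea_settings(program_cost_payers = "compliers")` switches to the
alternative; with compliers paying, the extended platform-cost threshold
moves outside the explored range, which is one reason the accepters
convention is also the better-calibrated one).

## Markov model

Five occupancy states: well/remission, mild, moderate and severe
depressive symptoms, and death (absorbing). The defining structural choice
is that severity within the symptomatic pool is a **proportional split,
not a persistent attribute**: each month the staying symptomatic mass is
redistributed across mild/moderate/severe by the relapse severity mix
(24.3% mild; the moderate–severe remainder split 50/50). Equivalently, the
chain is a three-macro-state model (well, symptomatic, dead) whose
symptomatic pool carries a fixed severity composition for costing and
utility weighting.

This choice was made deliberately. A five-state chain with persistent
severity (no lateral moves, relapse mix applied only to new relapses)
keeps the large initial mild mass mild for years — its only exits are
remission at 0.54%/month and death — and produces five-year QALY totals
near 2.9 per arm and an incremental QALY gain near 0.006. The
proportional-severity model produces totals near 2.52 and a gain near
0.0225, which is what the published base case reports (≈2.55 and 0.0211).
The package's acceptance suite verifies this quantitatively; the
transition matrix itself remains a genuine row-stochastic 5×5 object
(`build_transition_model()`), so all standard cohort-model invariants
still apply and are property-tested.

Other fixed modelling commitments:

* **Mortality** uses a single age-specific monthly probability
  (2.5×10⁻⁵; the printed "0.0025" under a percent header is read as a
  percentage, consistent with all-cause mortality at age 21) times a
  relative risk of 1.81 while symptomatic. Ages 21–26 mortality is nearly
  flat, so no life-table ingestion.
* **Hospitalization** is a cost event, not a state: severe occupancy
  incurs 1.78% × $1500 per month in expectation. The microsimulation
  samples the event; the cohort engine prices its expectation.
* **School dropout** is a parallel hazard (0.124%/month well,
  0.193%/month symptomatic), never a health state, and never feeds back
  into the transitions.

## Structural switches and their calibration

Four questions the base-case table does not answer are exposed as explicit
switches in `cea_settings()`, and were fixed once by calibrating *only
these switches* (never the input values) against the published base case:

1. **Which symptomatic states incur outpatient care?**
   Default `"symptomatic"` (all of mild/moderate/severe): stepped-up care
   applies to everyone who has not achieved remission. Restricting to
   moderate–severe leaves both arms' five-year costs ~7% low.
2. **Is the high-intensity CBT course charged separately?**
   Default `"none"`: the $231 patient-month outpatient figure comes from
   ambulatory psychiatric care reimbursement claims, which already include
   therapy, so adding a separate $972 course charge double-counts (and
   overshoots the published costs by 9–12%). `"initial"` and `"entries"`
   remain available.
3. **Does school dropout truncate accrual?**
   Default `TRUE`: under the service-provider perspective a student who
   has permanently left the university stops generating program costs and
   counted QALYs. With truncation all four published cost/QALY levels are
   matched within ~2%; without it costs run ~7% high. The switch applies
   to the cohort and microsimulation engines simultaneously, so the oracle
   property is preserved under either convention.
4. **When in a cycle is occupancy rewarded?**
   Default `"end"` (post-transition occupancy, discounted at the cycle's
   start index): the decision-tree phase ends at cycle 0 and rewards
   accrue as students live through each subsequent month. `"start"` and
   `"half"` (half-cycle correction) are available; the three differ by
   under 1% on levels and the end-of-cycle convention sits closest to the
   published incremental cost.

The well/remission state uses the remission utility 0.80 by default; the
age-specific population utility 0.92 is retained as a documented
alternative (`well_utility = "age"`) since it is listed among the inputs
without a sensitivity range and without a stated role.

## Probabilistic sensitivity analysis

Non-fixed parameters are sampled per draw: triangular distributions as
printed (min = low, mode = base, max = high); beta and gamma by method of
moments with mean = base and sd = (high − low)/3.92, i.e. the printed
range — including the interquartile range of the outpatient cost — is
treated as an approximate 95% interval. The construction is isolated in
`make_sampler()` so it can be swapped.

The acceptance pair and the compliance pair are each drawn with a **common
quantile** (comonotone) by default. Each pair comes from a single source
study, so their uncertainties move together; sampled independently, the
between-arm sampling noise dominates the incremental QALY
(SD ≈ 0.016 instead of ≈ 0.008), roughly doubling the spread of the
cost-effectiveness plane and dropping the accepted fraction to ~95%,
which is far from the published 99.7% with its ±$2 confidence interval on
the mean saving. `correlated_pairs = FALSE` restores independence.

Both strategies are always evaluated on the same draw (paired design).
Seeds: one master seed spawns a deterministic per-draw substream
(`(seed + i·982451653) mod (2³¹−19)`), so enlarging `n` extends the draw
sequence without reshuffling earlier draws.

## Numerical choices

* Row sums of the transition matrix and the initial tree masses are
  enforced to 1 within 10⁻¹²; cohort occupancy is monitored within 10⁻⁹
  per cycle.
* ICER is reported as `NA` when ΔQALY is exactly zero — an explicit
  sentinel, never a division error — and negative ICERs are reported as
  computed with the dominance flag alongside.
* The acceptance rule's south-west quadrant (cheaper, less effective) is
  decided by the net-monetary-benefit sign so that every PSA draw has a
  verdict; exact ties go to the comparator (in-person), as do two-way grid
  ties.
* Threshold search bisects to $1 for money-scale parameters and 0.1
  percentage point for shares, after a 41-point scan that reports every
  verdict crossing if the flip is not unique.
* The two-way grid defaults to a 0.005 step (101×101); because each arm's
  outcome depends only on its own compliance rate, the grid costs one
  model run per axis value, not per cell.
* Degenerate inputs are handled explicitly: a zero-month horizon accrues
  program cost only; fixed distributions yield degenerate samplers; a
  single-individual microsimulation flags its standard errors as `NA`.

## The microsimulation oracle

`simulate_cohort()` and `simulate.cea_model()` run the identical model at
the individual level: tree branch, monthly transitions (severity redrawn
from the mix each symptomatic month, matching the memoryless cohort
chain), Bernoulli hospitalization while severe, and a state-dependent
dropout time, under the same accrual switches. It is the package's
synthetic-data generator and its brute-force validator: cohort totals must
match microsimulation means within Monte Carlo error — the test suite
checks both strategies at 200,000 individuals, a panel of non-default
switch combinations, and random perturbed parameter sets with a two-sided
z-score panel that would reveal any systematic one-sided bias.

What passing these checks shows: the cohort engine correctly computes the
expectations of the stochastic model it claims to implement. What it does
not show: that the model matches real students — the generator emulates
the model's own assumptions (memoryless severity, monthly homogeneous
hazards, independence of dropout and symptom course given state), not
empirical trajectories.

## Known limitations and discrepancies

* The published one-way sensitivity narrative for the two compliance rates
  is not reproducible as printed. In any model of this structure the
  incremental cost and QALYs are affine in each compliance rate, so the
  printed pairing — the ICER growing in magnitude as internet compliance
  rises — would require the QALY advantage to *shrink* when more students
  receive the more effective program, which is impossible with treated
  recovery (63.9%) above untreated (25%). This package's endpoint ICERs
  match the published *values* within ~2% but with the pairing reversed:
  the large-magnitude ICER occurs at the *low* internet-compliance end,
  where the arms nearly coincide and the fixed program-cost saving is
  divided by a near-zero ΔQALY. The acceptance suite documents the
  mismatch honestly rather than emulating it.
* The published PSA mean saving ($244) is reproduced to ~8%, inside the
  base-case reproduction tolerance but far outside ±3 Monte Carlo standard
  errors (±$4 at 10,000 draws); the corresponding acceptance expectations
  are left failing, since Monte Carlo precision cannot absorb a structural
  base-case difference.
* Indirect costs, productivity losses and the quality-of-life impact of
  dropping out are outside the model; mild-state outpatient costing does
  not vary by severity within the symptomatic mix.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own trade-off between Monte Carlo precision and
turnaround: sampler checks at 10⁵–10⁶ draws; oracle agreement at 200,000
individuals (base case) and 15,000–40,000 (panels); the PSA at the full
10,000 draws in the acceptance suite and 40–400 in unit tests; the two-way
grid at steps 0.01–0.025 in tests and 0.005 in reports.
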