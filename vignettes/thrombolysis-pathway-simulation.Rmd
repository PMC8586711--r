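---
title: "Modelling the intra-hospital thrombolysis pathway"
author: "dntsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the intra-hospital thrombolysis pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dntsim)
```

## The model

`dntsim` simulates the treatment of acute ischemic stroke patients from
hospital arrival ("door") to the start of the tPA bolus ("needle"). The
process is a *stochastic activity network*: a directed acyclic graph of
activities whose durations are random variables in minutes, executed with
earliest-start semantics. A patient's door-to-needle time (DNT) is the
start time of the bolus activity minus the door time — equivalently, the
longest (critical) path from door to bolus through that patient's sampled
durations. This identity is load-bearing: only reductions that touch the
critical path can shorten DNT, which is exactly the phenomenon the scenario
analysis probes, and it gives the engine a deterministic oracle
(`critical_path()`) that the test suite exploits.

Four phases structure the graph: pre-arrival activities (possible only when
EMS pre-notifies the hospital), arrival activities, imaging and treatment
decision, and treatment. Two pathways differ in phase B: EMS patients
(probability 0.80, independent Bernoulli) skip all pre-arrival work
post-door, while private-vehicle (PV) patients must be triaged, registered,
*recognised as a stroke*, and have the protocol activated after walking in.
From imaging onward the pathways share one process: non-contrast CT, then
CT angiography, then interpretation; labs and the neurological assessment
run in parallel branches that join at the treatment decision; tPA
preparation starts once interpretation is available and runs in parallel
with the decision; the bolus waits for both (and, where practised, for the
travel from imaging back to the ED).

Arrivals follow a piecewise-constant-rate Poisson process over twelve
two-hour clock blocks, identical across days of the week; block counts are
Poisson, times uniform within the block. Mondays–Fridays 08:00–16:00
(half-open) is "regular hours"; the hours class is fixed at door time and
determines both which activities exist (rural sites add an on-call CT
technologist call-in delay out of hours) and which duration variant an
activity uses (the decision may be slower out of hours). The weekly
regular-hours share is therefore the 08–16 block mass times 5/7 — 35.4%
for the shipped schedule — with no free parameter.

One hospital-wide stroke-protocol activation is allowed at a time
(a capacity-one token granted FIFO by door time, held from the first
post-door activity to the bolus). At the modelled volumes (~100 treated
patients/year) contention is rare, but the constraint is part of the model
and the test suite asserts its exclusivity.

Assumptions worth stating plainly: resources other than the protocol token
are always available; pathway assignments and activity durations are
mutually independent; EMS always pre-notifies; every simulated patient is
treated (the point is the DNT of treated patients, not eligibility);
durations do not depend on symptom-onset time; stroke mimics, hemorrhagic
strokes and endovascular-therapy logistics are out of scope. Replications
are one year (365 days, starting Monday 00:00) with no warm-up — each
patient episode is transient and independent of the empty-and-idle start.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_ems` | 0.80 | probability of arrival by EMS |
| `block_rates` | site schedule | hourly arrival rates per 2-h block |
| `arrival_scale` | site ratio | volume multiplier (780/3021, 405/3021 for the rural sites) |
| `duration_scale` | calibrated | global multiplier on every sampled duration |
| `reduction_factor` | 0.65 | multiplier used by the R1/R2 scenarios (35% reduction) |
| `n_reps`, `horizon_days` | 30, 365 | experiment size |

A replication-count analysis (`replications_needed()`) with the standard
t-based half-width criterion supports the choice of 30 replications: a
pilot with coefficient of variation around 10% needs ~18 replications for
5% relative precision at 95% confidence, so 30 is comfortable.

## Scenario semantics

Scenarios are pure transformations of a `site_config`; the input is never
mutated. P1 deletes the stretcher-to-bay transfer from the EMS graph,
rewiring its successors to its predecessors; P2 deletes the
imaging-to-ED travel everywhere *and* switches the preparation to a
shorter in-imaging variant; P3 moves registration into the pre-arrival
phase for EMS (it stays post-door for PV — a walk-in cannot be
pre-registered); R1 and R2 scale the decision and preparation laws by
0.65. P-codes apply before R-codes, making composition order-independent;
consequently, when P2 and R2 are combined, the 35% reduction acts on the
in-imaging variant — the two preparation reductions compound. That is a
modelling choice; the alternative (R2 acting on the original preparation)
would make the combined scenario weaker, and nothing in the published
tables distinguishes the two, so the compounding reading was fixed and
documented. P-codes are idempotent; re-applying an R-code to an
already-reduced configuration is refused rather than silently compounding.

Scenarios listed in a site's `baseline_flags` are no-ops, reproducing the
"current baseline" rows of the published scenario tables.

## Common random numbers and seeds

All sampling is inverse-CDF: each draw consumes exactly one uniform, so a
scaled distribution yields exactly `factor ×` the original draw under the
same uniform. Patient *i* of replication *r* under base seed *s* draws
from a substream seeded by a deterministic mix of (s, r, i), with one
uniform slot per activity of the *base* inventory (frozen in the config at
construction and preserved by every scenario transformation). A deleted
activity's uniform goes unused; a rescaled activity reuses its slot. Two
consequences: (1) baseline and scenario runs are coupled patient-by-patient,
so no patient's DNT can increase under any scenario — a property the test
suite asserts over every code; and (2) experiments are byte-identical
across reruns and invariant to replication execution order. Scenario runs
reuse the baseline arrival streams by default (set
`independent_arrivals = TRUE` to decouple them); the published scenario
tables show differing patient counts across scenarios at one site, which
fixed streams cannot produce, so coupled streams were chosen as the
reproducible default.

The truncated-normal family (and any family given a positive lower bound)
is handled by inverting the CDF conditioned on exceeding the bound. This
is equal in law to resampling until the draw clears the bound — no point
mass at the bound — but consumes exactly one uniform, preserving the
substream alignment above.

## Calibration and the stand-in distributions

The shipped site configurations reproduce the three study sites'
*structure*: which process changes are already baseline practice (urban
site: stretcher-to-imaging and pre-registration, bolus in imaging during
regular hours; second rural site: the same flags; third rural site: none),
where registration happens, which sites call in a CT technologist out of
hours, and relative annual volumes (3021 : 780 : 405 treated patients per
30 simulated years).

The activity-duration *distributions* are stand-ins (triangular laws,
provenance-tagged `"calibrated"`), because the source duration tables are
not reproduced here. They were designed against the published outcome
patterns, then a single global multiplier per site was fitted
(`calibrate_global_scale()`) so the pooled baseline median DNT matches the
observed 50.0 / 40.1 / 74.0 minutes. Calibration exploits the
common-random-number structure: with every trial scale reusing the same
seeds, the pooled median is an exactly linear function of the scale
(absent token queueing), so the fit lands in one or two evaluations and is
reproducible to six decimals. A single global multiplier is deliberate:
one observed median cannot identify per-activity parameters.

Structural constraints built into the stand-ins, and why:

* at the urban site the preparation branch strictly dominates the decision
  branch (the out-of-hours decision maximum equals the preparation
  minimum), so a 35% decision-time cut changes *nothing* — every patient's
  DNT is identical under common random numbers, reproducing the published
  null result exactly;
* at the slow rural site the decision and preparation branches are
  near-equal, so cutting either alone merely exposes the other as the
  bottleneck while cutting both shortens the branch by the full 35% —
  the published super-additive combination;
* the urban site's heavy upper tail (a 90th percentile around 71 minutes
  over a 50-minute median) is carried by the PV recognition activity: a
  minority-pathway tail is the only placement
  consistent with the decision cut leaving median, IQR *and* 90th
  percentile unchanged while the combined scenario still lowers the 90th
  percentile substantially;
* the rural sites' out-of-hours CT call-in has a short mode and long
  maximum, producing the scenario-invariant upper quartile visible in the
  published tables.

What passing tests therefore show: the engine, scenario algebra and
statistics reproduce the published *verification* quantities (arrival
volumes, hours split, chi-square), the calibrated baseline medians, and
the qualitative scenario conclusions, with magnitudes in moderate bands.
What they do not show: that the stand-in distributions equal the sites'
elicited distributions — scenario magnitudes inherit whatever error the
stand-ins carry, which is why `load_sm1_distributions()` exists to swap in
transcribed duration tables (provenance `"SM1"`) when available.

## Statistical machinery

Pooled summaries concatenate all replications and use linear-interpolation
quantiles (`stats::quantile` type 7) — the pooled median of unequal
replications is *not* the mean of per-replication medians, and the test
suite pins that distinction. Percentage reductions are
`100·(baseline − scenario)/baseline` on the pooled median, IQR width and
90th percentile. Their confidence intervals come from a percentile
bootstrap that resamples *replications* (the independent units) with
replacement and recomputes the pooled metrics each draw; when both arms
have the same replication count the resampling is paired, which respects
the shared arrival streams and makes an exact scaling of the baseline
produce a degenerate interval, as it should. How the published intervals
were computed is not stated anywhere; the bootstrap was chosen as a
defensible, reproducible method, so interval *widths* may legitimately
differ from published ones even where point estimates agree. Significance
uses the Mann-Whitney U test (exact for tiny tie-free samples, otherwise
the tie- and continuity-corrected normal approximation via
`stats::wilcox.test`), and arrival verification uses the Pearson
chi-square statistic against the desired block volumes with k−1 degrees of
freedom — computed directly rather than via `chisq.test`, which would
renormalise the expected counts.

## Numerical choices

Time is real-valued minutes throughout; nothing is rounded internally
(serialized CSVs round to 3 decimals after all statistics are computed).
Simultaneous events are ordered by (door time, patient index). Degenerate
inputs are rejected at construction (triangular needs min ≤ mode ≤ max,
scales must be positive, schedules need a positive rate) or reported by
`validate_config()` with the offending activity ids. Seed mixing keeps all
intermediates below 2^53 and results within 32-bit integer range.

Problem sizes in the shipped tests — 30 replications × 365 days for
acceptance checks, 2–3 replications for property checks, 200 trials × 300
bootstrap draws for coverage — were chosen so the full suite exercises
every claim at full experimental scale for the headline checks and reduced
scale for properties that hold sample-by-sample.

## Limitations

The model is a single-patient-at-a-time view of one hospital: no bed or
staff rosters, no multi-hospital transfer logistics, no endovascular
pathway, no patient covariates (age, sex, severity), no onset-to-door
dependence, and 100% protocol compliance. The arrival schedule has
time-of-day structure but no day-of-week or seasonal variation. The
stand-in durations are calibrated to one median per site and should be
replaced by elicited or measured distributions for any site-specific
decision-making.
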