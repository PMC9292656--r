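---
title: "Modelling donor flow in a whole-blood collection centre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling donor flow in a whole-blood collection centre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(donorflow)
```

## The system and the model

`donorflow` simulates one working day of a fixed-site whole-blood
collection centre fed by a period-structured appointment schedule. The
day is divided into `K = 3` two-hour periods (7:30–9:30, 9:30–11:30,
11:30–13:30); an upstream appointment scheduler supplies, per period, the
number of already-booked donors, the number of pre-allocated (not yet
booked) slots, and the expected number of walk-ins, plus a period weight
that the scheduler uses to penalize queue build-up. The scarce resource
is physician time: each period carries a nominal capacity of 450
physician-minutes (3.75 physician-equivalents over two hours) and the
scheduler prices each donor at a standard consultation time of
`r` = 20 min.

Donors pass through four stages: registration with a clerk, a medical
consultation with a physician (including haemoglobin measurement, which
three layout variants place *within* the consultation (`W`), or at a
separate dedicated-nurse station *before* (`B`) or *after* (`A`) it),
phlebotomy on a donation bed, and rest plus an unconstrained canteen
refreshment. A nurse is seized only for the pre-setup (venipuncture) and
post-setup (disconnection); during the draw itself nurses are free to
serve other donors. The bed is held from pre-setup until the donor
leaves for the canteen. Cycle time is arrival-to-exit *including* the
refreshment, because it is part of the donor's perceived time in the
system.

The engine is event-driven: state changes only at arrival and
end-of-service instants, with no fixed tick. All times are decimal
minutes; clock instants are minutes from midnight.

### Arrival and gate model

Each pre-allocated slot converts to a booking with probability
`pfill = 0.9`; every booked donor (original or converted) then no-shows
with probability `pns = 0.05`. Walk-ins arrive in deterministic count
`round(n_walkin_expected)`. Arrival instants are uniform within the
donor's period — the scheduler assigns periods, not appointment times,
and no intra-period arrival pattern is assumed.

Deferral gates are Bernoulli: at the consultation, 5.03×10⁻³ for booked
donors and 4.523×10⁻² for walk-ins (who are not pre-screened during
reservation), and 5×10⁻³ at the haemoglobin test for both. Combined,
these give total acceptance rates of 99% (booked) and 95% (unbooked).
Both gate outcomes are fixed per donor when the arrival set is realized,
*before* the layout is applied — this is what makes common random
numbers exact across layouts (see below). Under placement `B` a donor
failing the haemoglobin test leaves without seeing a physician; under
`A` the test (and its deferral) follows the consultation; under `W` the
consultation service time is the sum of the consultation and
haemoglobin draws and either gate may trigger at its end.

### Service-time distributions

All nine process times come with literature-derived defaults
(`process_time_catalog()`): normal registration for booked donors
(1.77 ± 0.612 min) and lognormal for walk-ins (mean 2.4, sd 0.82 min,
their records must be created at the desk); triangular consultation
(16.5, 20, 18.33 min) and uniform haemoglobin test (1.34–2 min), jointly
calibrated so their expected sum equals the 20-min standard; normal
pre-setup (1.6 ± 0.284), three-parameter Weibull phlebotomy (scale 4.23,
shape 1.82, location 9.5 — every draw is at least 9.5 min); uniform
post-setup (1–2); triangular rest (4, 10, 5); lognormal refreshment
(mean 14.22, sd 7.11). Lognormal parameters are interpreted as the mean
and standard deviation *of the distribution itself* and converted to
log-scale parameters internally; the sources state them without log
qualifiers and the converted moments are what the cited observations
measured. Normal draws at or below zero are resampled rather than
clamped: service times must be strictly positive, and at these
parameter values the truncation probability (≈2×10⁻³ for the
registration time) biases the mean negligibly.

### Physician timetable and the after-hours rule

The 3.75 physician-equivalents are realized as three physicians working
the full period plus a fourth working 90 minutes, placed at the start
(timetable 1) or the end (timetable 2) of every period.
`physicians_on_duty()` reports 0 outside opening hours, and a
consultation may start only if the number in progress is below the
on-duty count at that instant; a consultation running across a shift
boundary is completed by its physician as overtime. After the last
period ends, the three full-period physicians keep starting
consultations until the queue drains — without this rule donors still
queueing at 13:30 would never be served, and the last-donor exit time
(one of the management KPIs, observed well past closing) would be
undefined. Utilization, however, counts only busy minutes inside
opening hours against the scheduled 1350 physician-minutes.

### Queue disciplines and nurse contention

Registration and the haemoglobin station are always FIFO. The
consultation queue is FIFO in the baseline and booked-priority (`PRTY`)
in the variants: any waiting booked donor is called before any waiting
walk-in, FIFO within class, ties broken by donor id. In the donation
room, the first free nurse accompanies the longest-waiting donor to the
first free bed (FIFO). When a nurse frees while donors are waiting both
to be connected and to be disconnected, disconnection (post-setup) is
served first: the waiting donor is attached to a collection bag, and
neither the upstream description nor the factor definitions specify
this tie — the clinically natural priority was chosen once and is fixed.

## The synthetic schedule generator

The real scheduler solution that fed the motivating study is not
public, so `synth_day()` generates synthetic days. In calibrated mode
each period's expected consultation workload matches nominal capacity:
`(n_booked + pfill·n_preallocated + n_walkin_expected)·r ≈ ct_k`, about
22.5 expected consultations per period, with the booked /
pre-allocated / walk-in composition jittered around realistic shares
(walk-ins ≈ 20% of arrivals, pre-allocated ≈ 30% of booked-type slots).
The `load` argument scales each period's workload relative to capacity.

A fully loaded day, however, is *not* the operating point the study
observed: its printed per-period used physician capacities (≈368, 364,
364 of 450 min) put the real day at roughly 81% loading, which is what
produces ≈70% physician saturation, mean queue times of a few minutes
and last consultation exits shortly after each period. `baseline_day()`
therefore fixes `load = c(0.82, 0.81, 0.81)` — calibrated once to those
printed values — and is the default day for `run_plan()` and the
shipped study scripts. Period weights default to (3, 2, 1): decreasing,
so the original schedule penalizes early-period queues most, matching
the observation that the first period ran undercharged. The generator
does *not* emulate blood-type balancing, day-to-day demand dynamics, or
empirical intra-period arrival patterns; conclusions from synthetic
days are therefore about the centre's queueing behaviour, not about any
specific real schedule.

## Experiments, CRN and validation

`enumerate_layouts()` crosses queue policy (2) × physician timetable
(2) × haemoglobin placement (3) × resource combinations (12: 2–3
nurses, 1–2 clerks, 5–7 beds) into 144 layouts; the study design runs
each 30 times (4,320 runs). For replication *j*, `run_plan()` realizes
one arrival set and one complete set of per-donor service times and
gate outcomes from seed `seed + j`, and feeds that identical input to
every layout. Because draws are keyed to donors rather than to event
order, common random numbers survive layout changes that reorder
events, and paired layout contrasts have far lower variance than
independent runs (this is asserted by a test).

`validate_baseline()` reproduces the validation statistics: a
one-sample two-sided t-test of replication mean cycle times against a
reference mean, the sample critical difference
`δ̂ = |x̄ − μ| / s`, and the type-II error `β(δ̂)` from the noncentral-t
distribution with noncentrality `δ̂√n`. The replication count required
for `β ≤ 0.05` is found by numerical inversion of that power function
rather than by reading an operating-characteristic chart, so the
computed requirement (n ≈ 19 at δ̂ = 0.89) can differ from chart-derived
values (the study settled on n = 30, which is conservative); both are
reported, neither is forced to match the other.

## Analysis choices

For each KPI (cycle and queue times overall and by donor type, four
utilizations, per-period used capacity and last consultation exit) the
factorial results are analysed by a univariate ANOVA with the six
factors as categorical main effects plus all 15 two-factor
interactions — one linear model per KPI, which is how the multi-KPI
analysis is reported, rather than a single MANOVA statistic.
Cost-efficiency is excluded from the ANOVA (it is a function of cycle
time and cost) and analysed separately by OLS of throughput rate
(1/mean cycle time) on layout cost, with isocost winners per cost
level. On the balanced full factorial the sum-of-squares convention is
immaterial; unbalanced input triggers a warning naming the sequential
(Type I) convention used. Normality of per-replication KPIs is
inspected by q-q correlation (`qq_normality()`).

The study states best layouts per stakeholder but not the ranking rule;
it is formalized here as: donors minimize mean cycle time (cost is
ignored); resources maximize the mean utilization of nurses, clerks and
beds *minus* physician utilization; management maximizes throughput per
cost unit. Selection is lexicographic with a one-standard-error
tolerance on the leading layout, ties broken by lower cost then name.

Costs are in non-monetary cost units (CU, ≈20 euros in the motivating
case): clerk 5, nurse 10, bed 1 per workday, plus one nurse salary for
the dedicated haemoglobin station under placements `A`/`B` — that
station is staffed in addition to the 2–3 donation-room nurses, since
the factor levels for nurses are unchanged across placements.
Physicians and structural costs are fixed across layouts and excluded.

## The feedback loop

Two re-calibrations feed back from simulation output to the scheduler's
parameters. First, when haemoglobin testing leaves the consultation
room (placements `A`/`B`), the scheduler's standard consultation time
drops from 20 to 18.33 min — the *modal* value of the consultation
triangular, which is the figure the upstream calibration quotes for the
consultation alone (the analytic mean `(16.5 + 20 + 18.33)/3 = 18.28`
differs slightly; 18.33 is used deliberately, as quoted). Second, the
period weights are reversed, penalizing queue formation most in the
last period, so the under-used first period fills.

The true scheduler is out of scope, so `rebalance_day()` is a
deliberately simple surrogate: each period's target allocation is its
current allocation re-weighted by the penalty ratio `w_old/w_new` and
renormalized to conserve the daily total (and each slot category)
exactly; targets are integerized by largest remainder and clipped at
the period capacity in donor units (`ct_k/r'`), excess moving to the
earliest period with slack. This construction makes an unchanged
adjustment a no-op and the operation idempotent, keeps every period
within nominal capacity, and shifts workload monotonically in the
weight ratio — the properties the comparison relies on. Its outputs are
compared with pre-feedback runs on *direction* only (first-period used
capacity up, maximum cycle time down, on CRN-paired replications),
never on magnitudes, which depend on the unpublished real schedule. One
feedback iteration is applied, as in the study; iterating is possible
by re-invoking the same functions.

## Numerical conventions and degenerate inputs

* Ties in event time are processed in deterministic insertion order;
  queue ties break by enqueue time, then donor id.
* Degenerate triangular distributions (`a = b = c`) are point masses;
  the test-suite oracles are built from them.
* Empty KPI strata are reported as `NA` ("undefined"), never zero; an
  all-deferred day leaves cycle statistics undefined.
* The per-donor identity `cycle = Σ service + Σ wait` holds to 10⁻⁹
  min by construction and is asserted in tests.
* Period capacity is attributed by the donor's *arrival* period by
  default (it measures how the scheduler's period loading lands);
  attribution by consultation-start period is available and the two
  agree in total exactly.
* Zero-variance validation samples flag the t statistic as undefined
  and fail to reject.

## Problem sizes

The shipped tests run small configurations: single-digit donor counts
for the exact oracles, 10–30 replications for directional and
calibration checks, and 500 pure-noise syntheses (at 3 replications per
cell) for the ANOVA type-I calibration. The acceptance script runs the
full 144 × 30 plan — about 295,000 simulated donor paths — in well
under a minute on one core, plus the ANOVA, cost-efficiency and
feedback comparisons.

## Known limitations

Staff breaks, differentiated shifts, apheresis, donor reneging and
mobile collection are out of scope by design. The engine models one day
in isolation (no multi-day ramp-up). The haemoglobin-station nurse is
always additional, and low-haemoglobin donors under placement `B` leave
without a consultation; centres that consult deferred donors anyway
would need a different routing. Synthetic days share none of the
blood-type structure of real scheduler output, so blood-group-level
questions cannot be asked of this package.
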