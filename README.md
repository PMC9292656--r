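# donorflow

Discrete-event simulation of a fixed-site whole-blood collection centre,
for analysts and managers who need to dimension such a centre — how many
clerks, nurses and beds; where to place the haemoglobin test; how to
staff physicians; whether to prioritize booked donors — and to check
whether the appointment schedules produced by an upstream scheduler are
actually workable on the floor.

## The model

One working day is split into *K* = 3 two-hour periods (7:30–13:30). A
period-structured schedule supplies, per period *k*, already-booked
donors, pre-allocated slots (each fills with probability
*p*<sub>fill</sub> = 0.9) and expected walk-ins; booked donors no-show
with probability *p*<sub>ns</sub> = 0.05, and arrival instants are
uniform within the period. Donors flow through

> registration (clerk) → \[haemoglobin station\] → consultation
> (physician) → \[haemoglobin station\] → pre-setup (nurse + bed) →
> phlebotomy (bed only) → post-setup (nurse) → rest (bed) → refreshment,

with the haemoglobin test either inside the consultation (layout `W`)
or at a separate dedicated-nurse station before (`B`) or after (`A`)
it. Bernoulli deferral gates at the haemoglobin test (5×10⁻³) and the
consultation (5.03×10⁻³ booked, 4.523×10⁻² walk-in) give 99% / 95%
total acceptance. Physician capacity is 450 min per period — 3.75
physician-equivalents, realized as 3 full-period physicians plus one
working 90 min at the period start or end. Service times are drawn from
a nine-activity catalogue (normal, lognormal, triangular, uniform and
three-parameter Weibull families) whose consultation + haemoglobin
expectation equals the scheduler's 20-min standard consultation time.

The package implements the full study pipeline around the engine: a
synthetic schedule generator, Table-style KPIs (cycle/queue time
stratified by donor type, resource utilizations, per-period used
physician capacity and last consultation exit, layout cost in cost
units, throughput rate), the 144-layout factorial experiment under
common random numbers with 30 replications (4,320 runs), one-sample
t-validation with noncentral-t power analysis (δ̂ = |x̄−μ|/s), per-KPI
ANOVA with all two-factor interactions, cost-efficiency regression with
isocost winners, stakeholder-based layout ranking, and the feedback
loop that re-calibrates the scheduler's consultation time (20 →
18.33 min when the haemoglobin test leaves the consultation) and
reverses the period queue-penalty weights.

## Worked example

```r
library(donorflow)
set.seed(7)
day <- baseline_day()          # synthetic stand-in for a scheduler day
day
#> <day_schedule> K=3 periods, ct=450 min, r=20 min
#>   k=1 07:30-09:30 booked=10 preallocated=5 walkins=4 w=3
#>   k=2 09:30-11:30 booked=12 preallocated=4 walkins=3 w=2
#>   k=3 11:30-13:30 booked=10 preallocated=6 walkins=3 w=1
#>   total slots: 57 (expected workload 1140 min vs capacity 1350 min)

arrivals <- realize_arrivals(day)            # no-shows, slot fills, times
donors   <- draw_donor_attributes(arrivals)  # service times + gates
log      <- run_day(layout_config("FIFO", 1, "W", 2, 1, 5), donors)
kpi_report(log)
#> <kpi_report> FIFO-1-W-01  (cost 30 CU, throughput 0.0153 donors/min)
#>   cycle           min   50.9  avg   65.2  max   92.9
#>   cycle_booked    min   50.9  avg   66.0  max   92.9
#>   cycle_unbooked  min   55.7  avg   61.8  max   69.2
#>   queue           min    0.0  avg    5.9  max   23.3
#>   queue_booked    min    0.0  avg    6.5  max   23.3
#>   queue_unbooked  min    0.0  avg    3.0  max   11.6
#>   utilization: physician 0.77, nurse 0.21, clerk 0.32, bed 0.63, hb_nurse NA
#>   k=1 used capacity 360.1 min, last exit 09:51
#>   k=2 used capacity 379.9 min, last exit 11:54
#>   k=3 used capacity 358.9 min, last exit 13:57
```

Donors spent 65 min in the centre on average (about 6 of them queueing),
physicians ran at 77% of their scheduled 1350 min while the cheaper
resources stayed far from saturation, and the last consultation of each
period ended 21–27 min after the period — the day's 30-cost-unit layout
handles this schedule with moderate congestion. A factorial comparison
is one call (`run_plan(experiment_plan(...))`), and
`anova_kpis()` / `best_layouts()` / `cost_efficiency()` summarize it;
`rebalance_day()` + `compare_pre_post()` close the loop back to the
scheduler. See the vignette `vignettes/donor-flow-simulation.Rmd` for
the modelling choices.

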