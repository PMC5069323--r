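---
title: "Simulating pre-hospital mass-casualty response"
author: "mcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pre-hospital mass-casualty response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcisim)
```

## The modelling problem

In a mass casualty incident the medical needs temporarily exceed response
capacity, and mortality among survivors is driven less by medicine than by
logistics: how fast victims are extracted, in what order scarce providers
treat them, where ambulances take them and who rides along. `mcisim`
implements a discrete-event simulation of that pre-hospital chain — from
the wreck to hospital admission — so that operational doctrines can be
compared under identical, repeatable conditions.

The simulator is *victim-centred*: each casualty is one entity whose
clinical state and logistic state evolve in parallel and interact only
through two triggers — the passage of time and the completion of a
treatment. Internally each victim is duplicated into a clinical facet
(driving the health-state machine) and a logistics facet (moving through
queues and vehicles); both are handles over one shared state, so a trigger
raised through either side is seen exactly once by the other.

## The victim model

A victim profile is a directed graph of *clinical conditions*. Each
condition carries vital signs, the RPM severity score (the sum of coded
respiratory rate, pulse rate and best motor response, 0 worst to 12 best)
and a triage category. Transitions are either **time-triggered** (a dwell
in the source condition, the untreated pathway) or **treatment-triggered**
(a provider skill plus a treatment-effect delay). End conditions — dead or
stabilized — are absorbing.

Survival over time is taken from a deterioration grid: survival percent
indexed by RPM (0–12) and elapsed time in 30-minute bins, loaded from
`inst/extdata/deterioration_rpm.csv` and validated at load time (all
entries in [0, 100], non-increasing in time, non-decreasing in RPM).
Lookup is a left-continuous step function — the row of the largest
tabulated time not exceeding *t* — because the source is a discrete table;
no interpolation is invented. Beyond the last row the last row applies.

**Deterministic death rule.** The simulator draws no survival lotteries.
A profile's untreated pathway enters its dead state at the first grid bin
where the survival probability of the victim's current RPM reaches zero.
This keeps between-run variance down to what the operational factors and
the seeded arrival order produce, which is exactly what a factor
comparison wants.

### The synthetic profile library

The clinical source data behind the original airport case study are not
published, so the package ships a *synthetic, documented* library
(`build_default_profiles()`): three profiles per triage category, each
defined by an initial RPM and a per-bin decrement.

| category | initial RPM | decrement / 30 min | untreated death |
|---|---|---|---|
| T1 | 6, 5, 7 | 2 | 60–90 min |
| T2 | 9, 10, 11 | 1 | 150–180 min |
| T3 | 12, 11, 12 | 0 (stabilizes) | never |
| T4 | 2, 1, 3 | 1, 1, 2 | 30–60 min |

These were chosen once, on clinical plausibility: T1 victims need
intervention within the first hour; T2 victims destabilize over 2–6 hours;
T3 walking wounded need first aid only; T4 expectant victims have little
salvageable margin. Treatment transitions attach to every live untreated
state: an EMT holds the current RPM on a slowed pathway (60-minute
dwells), a PIT improves RPM by 1 (stabilizing outright when the improved
score reaches 11), an MMT improves RPM by 2 and stabilizes after 30
minutes. Slowed-pathway states keep an oblique MMT escalation. A
higher-skill provider may fire a lower-skill transition when no dedicated
one exists (MMT ⊇ PIT ⊇ EMT): escalation is modelled, blocked care by
over-qualification is not.

What the generator does *not* emulate: per-victim diagnoses, body-region
injuries, secondary-survey parameters, or empirically calibrated
deterioration trajectories. Tests passing on this library show the
*mechanics* (ordering, conservation, capacity laws, directional effects)
are right; they do not validate absolute mortality against any real
incident.

## The response model

Default choreography (the printed anchors of the source intervention plan
are fixed; the remaining durations are documented stand-ins chosen once):

* Ambulatory victims (T3 and the uninjured) clear the wreck within
  **3 minutes** and walk to the casualty collection point (CCP).
  Non-ambulatory extraction starts at **minute 5**, in seeded random
  order, at the configured per-10-minute rate; two additional fuselage
  openings at **minute 21** triple the throughput. Rates (low 3, medium
  5, high 8 victims per 10 minutes) are stand-ins spanning slow to fast
  extraction.
* The initial dispatch wave is fixed: **5 BLS ambulances, 4 MMTs, 2 Red
  Cross teams**. The first MMT is the incident commander and never treats
  or transports; the second performs primary triage at the CCP (joined by
  the airport's own physician–nurse team from minute 2) and moves on when
  triage is done; the third and fourth set up the forward medical post
  (FMP) — treatment can start exactly **8 minutes** after their arrival.
  The CCP→FMP leg is **1 minute**.
* With triage on, urgent victims queue by priority code
  (category·100000 + RPM·1000 + arrival minute; ties broken
  first-in-first-out by queue entry, then victim id). The code is
  snapshotted at queue entry — the encoded arrival minute makes
  re-coding in place ill-defined. With triage off, every queue is
  first-in-first-out and the triage service step is skipped.
* Stay-and-play: the five initial ambulances shuttle urgent victims
  CCP→FMP; MMTs stabilize them (delivery 10 min for T1, 5 for T2);
  loading for evacuation starts only after the delivery time expires.
  Scoop-and-run: urgent victims go straight from the CCP to hospital,
  with care en route delivered at the supervising crew's skill level.
  T4 victims are not evacuated by ambulance: they receive supportive care
  at the FMP (stay-and-play) or where they lie (scoop-and-run).
* Supervision levels: `emt` (no extra crew), `nurse` (nurse required for
  T1; a PIT-type ambulance satisfies it), `physician` (physician–nurse
  team for T1), `physician_all` (team for T1 and T2). A missing crew
  delays departure — reproducing the mechanism by which strict
  supervision can cost lives while victims wait.
* Hospitals: six on a distance ring (8–40 km; the nearest also a trauma
  centre, one with a burn unit). `nearest_first` fills the closest
  capable hospital's surge then moves outward; `round_robin` rotates
  proportionally to capacity. Admissions are immediate within the
  initial surge, then spaced by 60/rate minutes. The ambulance is
  released on arrival (the source is silent on ambulance blocking; this
  choice is configurable in principle and documented here).
* The non-urgent branch: airport buses (capacity 20) move walking wounded
  to the non-urgent care area; after 30 minutes of care they are
  discharged home or to a non-urgent facility. A victim whose clinical
  facet deteriorates to an urgent category while there is re-examined and
  transferred to the FMP.
* Resource levels set the committed fleet (10/14/19/24 ambulances — 19
  being half of the regional fleet of 38, the rest covering day-to-day
  calls — and 4/5/6/8 MMTs of the regional 10). The high level fields 7
  working MMTs in the first wave (arrivals inside 3–15 minutes); lower
  levels send reinforcements at minute 30/20/10.

### Numerical and engine choices

Time is continuous (real minutes); only deterioration lookups are binned.
Events execute in (time, scheduling-sequence) order, so simultaneous
events fire deterministically in the order they were scheduled. Each
victim has at most one pending time transition; a completed treatment
cancels it and schedules the pathway switch after the treatment-effect
delay. An interrupted lower-skill treatment is restarted, not credited,
on escalation (the source does not specify; restarting is the
conservative choice). Matching of providers, vehicles and victims is
work-conserving: after every event the simulator re-matches until no
idle compatible resource faces a non-empty queue, and the test suite
runs an auditor that asserts this plus single-queue membership after
every event.

All randomness — profile mapping, attribute draws, extraction order —
flows through explicitly seeded generators that never touch the global
RNG stream. Identical scenario and seed give byte-identical event logs.

## The experiment harness

`build_factorial()` crosses the seven factors (1152 designs);
`run_replications()` derives one seed per (design, replication) from a
stable integer hash, so sweeps are reproducible and any run can be
re-executed in isolation; failures are recorded per-run without aborting
a sweep. Reporting uses standard machinery: per-level descriptive
tables, one-way ANOVA (via `stats::aov`) with explained variance
SS_factor/SS_total, Scheffé pairwise contrasts, and the per-matched-design
policy difference. ANOVA treats individual runs, not design means, as
observations (the alternative is not stated in the source; this is the
documented default). Reproduction of the original study's absolute
mortality tables is deliberately not attempted — it would require the
unpublished appendix inputs — so the shipped checks are structural
(counts, encodings, choreography anchors) and directional (triage lowers
mean mortality; faster extraction lowers mean mortality) on the default
configuration.

## Problem sizes used by the shipped checks

The test suite exercises the full 205-victim default scenario for
determinism, conservation, capacity-law and choreography checks, a
reduced 38-victim incident for the flow invariants, a three-victim
micro-scenario against a hand-derived golden event log, and the
directional mortality comparisons on 30 seeded replications per arm of
the default scenario. The 34,560-row replication-bookkeeping check runs
the harness against a constant stub simulator, which verifies the
counting independently of simulation cost.

## Known limitations

* Absolute mortality depends on the synthetic profile library and the
  stand-in durations; only comparisons between factor levels under
  identical conditions are meaningful.
* Hospitals are admission sinks: in-hospital care beyond the emergency
  department door is out of scope.
* Red Cross teams provide logistics and non-urgent care only; whether
  they should deliver field treatment is left to configuration.
* The NATO T1–T4 categorization is the only triage system modelled.
* Geometry is a distance ring with straight-line legs; there is no road
  network or congestion model.
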