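# mcisim

A victim-centred discrete-event simulator for the **pre-hospital phase of a
mass casualty incident (MCI)**, built for disaster-medicine researchers and
emergency planners who want to compare operational doctrines — scoop-and-run
versus stay-and-play, triage on or off, extraction rates, resource and
supervision levels, hospital distribution rules and surge capacities — by
their effect on mortality, in a controlled and fully reproducible virtual
incident.

## The model

Every victim carries a **clinical-condition state machine**. A clinical
condition holds vital signs, a triage category (NATO T1 immediate, T2
delayed, T3 minimal, T4 expectant) and an **RPM injury severity score**:

```
RPM = code(respiratory rate) + code(pulse rate) + code(best motor response)
```

each component coded 0–4, so RPM runs from 0 (worst) to 12 (best).
Untreated victims walk a time-triggered pathway of worsening conditions; a
tabulated deterioration grid (survival percent by RPM and 30-minute elapsed
time bin) fixes, deterministically, the bin at which an untreated pathway
reaches a dead end state. Treatment by providers of increasing skill —
basic EMTs, paramedic teams (PIT), physician–nurse mobile medical teams
(MMT) — switches the victim onto a treated pathway that holds or improves
the RPM score, after a treatment-effect delay; a higher skill arriving
mid-pathway escalates obliquely.

The **medical response model** moves victims from the wreck through a
casualty collection point (CCP), a forward medical post (FMP) and a
non-urgent care area (NUCA) to hospitals. Urgent victims queue by a
priority code

```
code = category * 100000 + RPM * 1000 + arrival minute
```

(lowest code first: a T1 with RPM 6 arriving at minute 45 codes to
`106045`), or first-in-first-out when triage is off. Hospitals admit
immediately up to an initial surge, then at a configured hourly rate. A
simulated victim's run ends at hospital admission, NUCA discharge, or
death.

A **full-factorial harness** crosses the seven interventional factors
(2 × 2 × 3 × 4 × 4 × 2 × 3 = 1152 designs), manages seeded replications,
and reports per-factor descriptive tables, one-way ANOVA with explained
variance, Scheffé post-hoc contrasts and matched-design policy
differences.

## Worked example

```r
library(mcisim)

scn <- make_scenario()                      # default airport crash scenario
run <- simulate_mci(scn, default_factors(), seed = 7)
run
#> MCI simulation run (seed 7)
#>   factors: policy=stay_and_play, triage=TRUE, sar=medium, resources=normal,
#>            supervision=physician, distribution=nearest_first, hcf_capacity=medium
#>   injured victims: 205
#>   total deaths: 14
#>   deaths by location: fmp=9, scene=5
#>   dispositions: admitted=78, dead=14, discharged=113
```

The default scenario is an airliner crash with 250 occupants: 205 injured
(26 T1, 62 T2, 113 T3, 4 T4), 5 immediate fatalities and 40 uninjured.
Here 14 of the 205 injured died (9 at the forward medical post, 5 at the
scene before or during collection), 78 urgent victims were admitted to
hospital and the 113 walking wounded were discharged through the
non-urgent branch — every injured victim is accounted for.

Comparing triage against no triage over a small sweep:

```r
designs <- build_factorial(list(triage = c(TRUE, FALSE)))
res <- run_replications(designs, n_reps = 5, base_seed = 7, scenario = scn)
summarize_by_factor(res, "triage")
#>  factor level n mean median        sd min max
#>  triage  TRUE 5 13.6     14 0.8944272  12  14
#>  triage FALSE 5 20.4     20 1.1401754  19  22
```

With priority-coded queues the scarce physician teams reach the most
severe salvageable victims first; under first-in-first-out they are spent
on whoever arrived earliest, and mean mortality rises.

A command-line front end wraps the same functions
(`system.file("cli", "mcisim.R", package = "mcisim")`) with subcommands
`simulate`, `sweep`, `report`, `make-fixtures` and `validate`.

## Limitations

The victim profile library is a synthetic, documented stand-in (the
clinical source data behind the original case study are not published);
absolute mortality levels therefore depend on the shipped defaults, and
the simulator's value lies in *comparisons across factor levels* under
identical conditions. In-hospital care beyond admission is out of scope.
See the methods vignette (`vignettes/mci-response-simulation.Rmd`) for the
model's assumptions, parameters and design decisions.
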