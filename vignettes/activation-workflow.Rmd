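---
title: "Modelling the clinical-trial activation workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the clinical-trial activation workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialflow)
```

## The process and its model

The administrative work that opens an industry-sponsored clinical trial is
modelled as a fork-join queueing network over six sub-processes: Initial
Preparation (itself a series of four timed activities), the parallel
Contract and Budget Negotiations, and the PI, sponsored-research-division
and sponsor approvals. Trials arrive as a Poisson stream; every
sub-process is a first-in-first-out station with a finite number of
parallel "servers" (the number of trials the responsible participants can
progress at once). At the fork a trial's contract and budget documents
proceed concurrently; the join releases the trial only when both are
done, so the earlier-finishing document idles — the *batching* delay that
practitioners recognise as documents sitting in a pile waiting for their
sibling.

Assumptions worth stating explicitly:

* time is continuous in calendar days, with 24/7 arrivals and service —
  the historical duration data the distributions are fitted to are
  themselves calendar-day spans, so weekends and holidays are folded into
  the fitted service times;
* service times are independent across trials and stations;
* all trials traverse both negotiation branches. The observed logs have
  contract data for more trials than budget data, but that is data
  availability, not routing; per-branch traversal probabilities are
  exposed (`branch_traversal`) and default to 1;
* no preemption, priorities, reneging, staff rosters or costs.

## Parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| arrival rate | trials/day | 147/365 | 147 trials observed per year; the commonly quoted "14 per month" rounds the same stream |
| Initial Preparation | days | U(0.5,1) + Tri(1,8,21) + Tri(1,2,3) + U(0.5,1) | the four fitted activity distributions, in series (mean 13.5 d) |
| Contract / Budget | days | Exp(28.5) / Exp(25.0) | fitted service families |
| PI / DSR / Sponsor | days | LogN(5.0,8.3) / LogN(2.5,2.8) / LogN(6.5,15.9) | fitted; lognormal parameters are the mean and SD of the variate (the simulation-software convention), converted internally via σ² = log(1+(sd/mean)²), μ = log(mean) − σ²/2 |
| capacities | trials | 9, 12, 11, 5, 3, 7 | see calibration below |
| warm-up / horizon | days | 1460 / 365 | four simulated years discarded, one measured |
| replications | – | 38 | sized so the activation-time CI is a few percent of the mean; `replications_needed()` recomputes the requirement from a pilot |

## Capacity calibration

The data behind this model do not record how many trials each participant
can progress simultaneously, but they do record time-average queue
lengths at the two negotiation stations (18.5 and 15.2 trials).
`calibrate_capacities()` therefore searches integer capacities upward
from the smallest stable value (capacity strictly above the offered load
λ·E[S]) and keeps the capacity whose simulated queue length is closest to
the target, stopping once the queue drops below it (queue length is
monotone in capacity; a larger capacity is accepted only if it improves
the fit by more than 0.05 trials, so a zero target yields the minimal
stable capacity). For the default arrival rate this gives Contract = 12
and Budget = 11 — for Contract, both simulation and the Erlang-C closed
form put the steady-state queue within a fraction of a trial of the 18.5
target; for Budget no stable capacity reaches 15.2 (capacity 11 queues
about 7–8 trials, capacity 10 is unstable), so 11 is the closest stable
choice. The four non-negotiation capacities (9, 5, 3, 7) were chosen once
so that each of those stages contributes well under half a day of
expected waiting (M/G/c heavy-traffic estimate); they exist so that
capacity scenarios touching them are meaningful, not because the data
identify them.

## What the simulator measures

Statistics cover trials *arriving* in the measurement window
`[warmup, warmup + horizon)`. The arrival stream stops at the horizon but
every admitted trial is followed to completion, so activation times are
never censored — without this, heavily overloaded scenarios would have no
completed post-warm-up trials to average. The `status` flag and the
number-out / work-in-process counts still use the horizon cut, and queue
lengths are time averages over the window (all queued trials counted,
whenever they arrived).

Per trial, *idle time* is activation time minus the service-time critical
path through the routing graph — the parallel section contributes the
larger branch service sum — which guarantees idle ≥ 0 and
idle + value-added = activation. The *batch wait* is the gap between the
two branch completions. The engine itself is not an event calendar: each
station is processed in topological order with the exact multi-server
FIFO recursion (a vector of server-free times; trials taken in ready-time
order), which is equivalent for this network class and fast in plain R.
Correctness is pinned by three oracles: single-stage M/M/c instances
reproduce the Erlang-C waiting time (the acceptance suite holds a 3 %
band at 24 replications of a 100-year horizon, sized so Monte-Carlo noise
is well inside the band), all-constant models reproduce the closed-form
critical path exactly, and arrivals = completions + work-in-process in
every replication.

## Distribution fitting

`fit_distribution()` compares method-of-moments fits by the sum of
squared errors between the relative-frequency histogram (Sturges' rule)
and the fitted density. The fitted density is *bin-averaged* (the fitted
probability of the bin divided by its width) rather than evaluated at the
bin midpoint: for strongly skewed families such as the lognormal the
density varies by orders of magnitude inside the first Sturges bin, and
midpoint evaluation systematically favours flatter families —
bin-averaging makes family recovery reliable across all four families.
Near-ties (SSE within 1e-6) go to the family with fewer parameters.
Absolute SSE values are a function of the binning rule and are not
comparable across tools; only the arg-min family is meaningful.
Zero-variance samples are returned as a flagged degenerate constant fit.

## Communication networks

Centralities are computed on the binarised digraph (tie weights are
interaction counts, not distances): in/out degree counts distinct alters,
betweenness is directed geodesic betweenness, and closeness defaults to
the harmonic form (sum of reciprocal distances, unreachable pairs
contributing zero) because empirical communication networks are rarely
strongly connected; classic Freeman closeness is available as an option.
Bonacich power is computed on the symmetrised binary adjacency,
c(β) = α(I − βA)⁻¹A·1 with α scaled so Σc² = n, with β defaulting to
−0.75/λ_max — negative, so that being connected to otherwise unconnected
participants confers power. All four measures are verified against
brute-force oracles (matrix-power geodesic counting; series expansion for
the power index) on small digraphs. Published centrality tables for this
process use a network tool's own normalisation (e.g. degree 6.0 in a
six-participant network) that standard definitions cannot reproduce; this
package does not imitate it.

## The synthetic-data generator

`generate_dataset()` emulates one year (by default) of office
operations: Poisson arrivals, per-sub-process durations drawn directly
from the model's fitted distributions and laid out back-to-back (parallel
branches share a start and join at the later finish), statuses drawn from
the observed 78:16:52:1 mix of complete / missing-data / in-process /
terminated trials, and communication events whose per-direction annual
totals match the observed initiation counts (contract: 507
office-initiated vs 346 sponsor-initiated; budget: 153 sponsor vs 69
office and 70 PI vs 13 office — the budget reading of the printed counts
is ambiguous and this allocation is flagged as an interpretation).
Interaction totals are allocated across trials proportionally to the
sub-process duration — longer negotiations plausibly generate more
messages — and scattered uniformly within the interval; that is a
modelling convenience, not an empirical claim.

Because the generator writes durations without queueing (the fitted
distributions already absorb waiting and rework in the source data),
analyser round trips are exact in expectation: `duration_stats()` and
`fit_distribution()` on generated logs recover the generating families
and means, which is the generator's core acceptance property. What the
generator does **not** emulate: correlated durations, rework loops,
calendar effects, message content, or any participant behaviour beyond
the eight named roles — so passing round-trip tests demonstrates internal
consistency of the toolkit, not fidelity to any particular institution.

## Known limitations

The printed operational figures this model is calibrated against are not
jointly attainable by *any* fixed-capacity queueing network at the stated
arrival rate, and users should expect the same tension on their own data
if they calibrate to queue lengths and validate on flow times. Little's
law ties the two: a queue of 18.5 trials at 147 arrivals/year *implies*
about 46 days of contract waiting (≈74 days of flow), not the ~52 days of
flow reported alongside it; conversely the reported scenario responses
(finite activation times at doubled arrival rates) require so much
negotiation capacity that the baseline queues would be near zero. The
published figures come from a far more granular model — some thirty
activities with decision points and rework loops, where elapsed
negotiation time is mostly *not* resource occupation — and that model is
deliberately out of scope here. Calibrating the aggregated model to the
queue-length targets therefore puts the baseline near its stability
limit: the simulated entire-process mean runs ~12 days above the reported
82, and arrival-scaling scenarios overload the network rather than
degrade it gracefully. The relative effect of capacity scenarios is far
more robust than absolute levels (doubling negotiation capacity cuts
activation by ~28 % here, matching the reported relative reduction).
These divergences are asserted honestly in `test-acceptance.R` rather
than papered over with tolerances.

Problem sizes used by the test suite — one-year horizons with four-year
warm-ups at 38 replications for workflow experiments, 10⁴-sample fits,
10⁵–10⁶-draw moment checks, 100-year single-queue runs for the Erlang-C
band, 1200–1500 resamples for the t-test size — keep the full suite in
the tens of seconds on a single CPU while leaving Monte-Carlo noise well
inside each asserted band.
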