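# trialflow

Opening ("activating") an industry-sponsored clinical trial at an academic
medical centre is an administrative marathon: documents are prepared,
contracts and budgets are negotiated in parallel with the sponsor, and a
chain of approvals follows — typically 2–6 months before the first patient
can be enrolled. `trialflow` is a toolkit for clinical-research
administrators and operations researchers who want to understand and
improve that process. It combines three analytic lenses:

* **Value-stream timing analysis** of activity-timestamp logs — per
  sub-process duration statistics, inclusion filtering, and pooled-variance
  group comparisons;
* **Social network analysis** of participant communication logs — directed
  weighted networks with degree, closeness, betweenness and Bonacich power
  centralities;
* **Discrete-event simulation** of the activation workflow — a fork-join
  queueing network with finite-capacity FIFO stations, batch
  synchronization of the parallel contract/budget branches, warm-up
  truncation, replications with Student-t confidence intervals, and
  declarative what-if scenarios.

## The model

Trials arrive to the research office as a Poisson stream with rate
λ (default 147/365 per day) and traverse

```
Initial Preparation ──┬── Contract Negotiation ──┐
                      │                          ├──(AND-join)── PI ── DSR ── Sponsor ── activated
                      └── Budget Negotiation ────┘
```

Each sub-process *i* is a FIFO station with `c_i` parallel servers and
service times drawn from a fitted family (`uniform`, `triangular`,
`exponential`, `lognormal(mean, sd)` in the simulation-software
convention, or `constant`; all in calendar days). At the AND-split a
trial's contract and budget documents proceed concurrently; at the
AND-join the first-finished document waits ("batching") for its sibling.
Per trial, **activation time** is receipt-to-activation, **idle time** is
activation time minus the service-time critical path (queueing, signature
and batching delays), and **queue length** is the time-average number of
trials waiting at a station. Negotiation capacities are calibrated by
integer search so simulated queue lengths match observed targets
(18.5 and 15.2 trials → capacities 12 and 11); single-stage instances are
validated against the Erlang-C closed form to within 3 %.

Distribution fitting selects, among candidate families, the
method-of-moments fit minimising the sum of squared errors between the
relative-frequency histogram (Sturges bins) and the fitted bin-averaged
density.

## Worked example

```r
library(trialflow)

model <- default_ocr_model()
exp <- simulate_trials(model, sim_config(seed = 1))   # 38 replications
glance(exp)
#>   activation_time activation_ci idle_time batch_wait n_replications
#> 1            94.1          8.14      26.6       38.3             38

obs <- readr::read_csv(system.file("extdata", "observed_performance.csv",
                                   package = "trialflow"))
format_comparison(comparison_table(exp, setNames(obs$actual, obs$measure)))
#> Measure               Actual  Simulated (95% CI)
#> Initial Preparation   11.0    13.8 (0.1)
#> Contract Negotiation  54.9    56.4 (9.4)
#> Budget Negotiation    46.3    37.4 (4.2)
#> PI Approval           4.8     5.1 (0.2)
#> DSR Approval          2.5     2.6 (0.1)
#> Sponsor Approval      5.5     6.6 (0.5)
#> Entire Process        76.6    94.1 (8.1)
#> Number in             147.0   146.5 (4.1)
#> Number out            78.0    108.2 (3.4)
#> Still in process      52.0    38.2 (4.5)
```

Mean activation is 94.1 days with a 95 % CI half-width of 8.1; the two
negotiation stations carry nearly all the queueing. The five bundled
what-if studies:

```r
cmp <- run_scenarios(model, ocr_scenarios(), sim_config(seed = 1))
dplyr::filter(cmp, measure == "activation_time")
#>   scenario                      mean ci_halfwidth delta_pct ci_separated
#> 1 workload_16_14               225.         22.0    139.    TRUE
#> 2 double_negotiation_capacity   68.1         1.01   -27.7   TRUE
#> 3 double_workload             1539.         32.0   1535.    TRUE
#> 4 double_other_capacity         93.8         8.09    -0.384 FALSE
#> 5 reduced_variability           74.8         7.28    -20.6   TRUE
```

Doubling the contract/budget capacity cuts mean activation by 27.7 %
(the study this model is calibrated against reported a 28 % reduction),
while adding capacity anywhere else changes nothing — the negotiation
stations are the bottleneck. The calibrated baseline sits close to its
stability limit, so arrival-rate increases blow queues up dramatically.

The synthetic-data generator produces seeded, analysable operational
datasets (timestamp logs plus communication logs) for testing every
analysis without institutional data:

```r
ds <- generate_dataset(generator_spec(seed = 7))
duration_stats(filter_included_trials(ds$timestamps)$data)
centrality_report(build_network(ds$communications,
                                subprocess = "Contract Negotiation"))
```

A thin command-line front end covers the same workflow
(`inst/scripts/trialflow generate | fit | vsm | sna | simulate |
scenarios | calibrate`).

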