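Package: trialflow
Title: Discrete-Event Simulation and Network Analytics for Clinical
    Trial Activation Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the administrative process that opens
    ("activates") industry-sponsored clinical trials at an academic
    research office. Provides a discrete-event simulator of the
    activation workflow -- a fork-join queueing network in which contract
    and budget negotiation run in parallel and must both finish before
    final approvals -- together with duration-distribution fitting by
    histogram sum-of-squared-errors, value-stream timing statistics over
    activity-timestamp logs, centrality analysis of participant
    communication networks (degree, closeness, betweenness, Bonacich
    power), declarative what-if scenarios on arrival rates, capacities
    and processing-time variability, and a seeded synthetic operational
    data generator so every analysis is testable without institutional
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
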