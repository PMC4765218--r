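test_that("generation is deterministic in the seed", {
  s <- generator_spec(n_years = 0.5, seed = 7)
  d1 <- generate_dataset(s)
  d2 <- generate_dataset(s)
  expect_identical(d1$timestamps, d2$timestamps)
  expect_identical(d1$communications, d2$communications)
  d3 <- generate_dataset(generator_spec(n_years = 0.5, seed = 8))
  expect_false(identical(d1$timestamps, d3$timestamps))
})

test_that("a default year contains about 147 trials", {
  ds <- generate_dataset(generator_spec(seed = 3))
  n <- dplyr::n_distinct(ds$timestamps$trial_id)
  expect_lt(abs(n - 147), 3 * sqrt(147))
})

test_that("the status mix follows the requested proportions", {
  ds <- generate_dataset(generator_spec(n_years = 3, seed = 5))
  st <- ds$timestamps |>
    dplyr::distinct(trial_id, status) |>
    dplyr::count(status)
  n <- sum(st$n)
  probs <- c(complete = 78, missing_data = 16, in_process = 52,
             terminated = 1) / 147
  for (nm in names(probs)) {
    got <- sum(st$n[st$status == nm])
    expect_lt(abs(got - n * probs[[nm]]),
              3 * sqrt(n * probs[[nm]] * (1 - probs[[nm]])) + 1)
  }
})

test_that("analyzers recover the generating distributions (round trip)", {
  ds <- generate_dataset(generator_spec(n_years = 5, seed = 11))
  log <- filter_included_trials(ds$timestamps)$data
  contract <- dplyr::filter(log, subprocess == "Contract Negotiation")
  dur <- contract$end - contract$start
  fit <- fit_distribution(dur, c("exponential", "uniform", "triangular"))
  expect_equal(fit$family, "exponential")
  expect_lt(abs(fit$distribution$params[["mean"]] - 28.5),
            3 * 28.5 / sqrt(length(dur)))
  # duration_stats agrees on the mean for budget too
  st <- duration_stats(log)
  budget <- st[st$subprocess == "Budget Negotiation", ]
  expect_lt(abs(budget$mean - 25), 3 * 25 / sqrt(budget$n))
  # and the entire process is receipt-to-activation per trial
  entire <- st[st$subprocess == "Entire Process", ]
  init <- st[st$subprocess == "Initial Preparation", ]
  expect_gt(entire$mean, init$mean)
})

test_that("interaction volumes hit the annual targets per direction", {
  ds <- generate_dataset(generator_spec(seed = 13))
  got <- ds$communications |>
    dplyr::count(subprocess, source, target)
  targets <- default_interaction_targets()
  for (i in seq_len(nrow(targets))) {
    row <- targets[i, ]
    g <- got |>
      dplyr::filter(subprocess == row$subprocess, source == row$source,
                    target == row$target)
    expect_equal(g$n, row$count)
  }
  # the contract network reproduces the initiation asymmetry
  net <- build_network(ds$communications,
                       subprocess = "Contract Negotiation")
  dw <- degree_centrality(net, weighted = TRUE)
  expect_equal(dw$out_degree[dw$participant == "OCR"], 507)
  expect_equal(dw$out_degree[dw$participant == "Sponsor"], 346)
})

test_that("interaction events fall inside their sub-process interval", {
  ds <- generate_dataset(generator_spec(n_years = 0.5, seed = 17))
  joined <- ds$communications |>
    dplyr::left_join(ds$timestamps, by = c("trial_id", "subprocess"))
  expect_true(all(joined$timestamp >= joined$start - 1e-9))
  expect_true(all(joined$timestamp <= joined$end + 1e-9))
})

test_that("datasets round trip through CSV", {
  ds <- generate_dataset(generator_spec(n_years = 0.25, seed = 19))
  dir <- tempfile(); on.exit(unlink(dir, recursive = TRUE))
  paths <- write_ops_dataset(ds, dir)
  back <- read_timestamp_log(file.path(dir, "timestamps.csv"))
  expect_equal(nrow(back), nrow(ds$timestamps))
  comm <- read_communication_log(file.path(dir, "communications.csv"))
  expect_equal(nrow(comm), nrow(ds$communications))
  expect_error(read_timestamp_log(file.path(dir, "nope.csv")),
               class = "trialflow_error_io")
})

test_that("the bundled synthetic fixture is analysable end to end", {
  tsp <- system.file("extdata", "synthetic_ops", "timestamps.csv",
                     package = "trialflow")
  log <- filter_included_trials(read_timestamp_log(tsp))$data
  st <- duration_stats(log)
  expect_true("Entire Process" %in% st$subprocess)
  cmp <- system.file("extdata", "synthetic_ops", "communications.csv",
                     package = "trialflow")
  rep <- centrality_report(build_network(read_communication_log(cmp)))
  expect_true(all(c("OCR", "Sponsor", "PI") %in% rep$participant))
  expect_true(all(rep$betweenness >= 0))
})
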