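test_that("deterministic durations reproduce the critical path exactly", {
  m <- constant_forkjoin_model(init = 2, contract = 5, budget = 3,
                               pi = 1, dsr = 1, sponsor = 1, lambda = 0.05)
  rep <- run_replication(m, sim_config(horizon = 200, warmup = 50,
                                       replications = 2), seed = 3)
  w <- rep$trials$in_window
  expect_true(all(abs(rep$trials$activation_time[w] -
                        (2 + max(5, 3) + 1 + 1 + 1)) < 1e-9))
  expect_true(all(abs(rep$trials$batch_wait[w] - (5 - 3)) < 1e-9))
  expect_true(all(abs(rep$trials$idle_time[w]) < 1e-9))
})

test_that("timestamps are coherent along each trajectory", {
  m <- default_ocr_model()
  rep <- run_replication(m, sim_config(horizon = 120, warmup = 60,
                                       replications = 2), seed = 8)
  ev <- rep$events
  expect_true(all(ev$service_start >= ev$queue_entry - 1e-9))
  expect_true(all(ev$service_end >= ev$service_start))
  expect_true(all(rep$trials$idle_time >= -1e-9))
  expect_true(all(rep$trials$activation_time >=
                    rep$trials$experienced_service - 1e-9))
  # FIFO at a capacity-1 station: completion order equals entry order
  m1 <- single_stage_model(dist_exponential(2), capacity = 1, lambda = 0.3)
  r1 <- run_replication(m1, sim_config(horizon = 100, warmup = 0,
                                       replications = 2), seed = 5)
  e1 <- dplyr::arrange(r1$events, queue_entry)
  expect_true(!is.unsorted(e1$service_end))
})

test_that("single-stage M/M/c matches the Erlang-C closed form", {
  lam <- 2.4; c <- 3
  m <- single_stage_model(dist_exponential(1), capacity = c, lambda = lam)
  exp <- simulate_trials(m, sim_config(horizon = 3650, warmup = 365,
                                       replications = 10, seed = 11))
  # modest experiment: the bound reflects its Monte-Carlo noise; the
  # acceptance suite holds the tighter 3% bound at a far larger size
  wq_sim <- summary_value(exp, "flow_time.S") - 1
  wq_th <- erlang_c_wq(lam, 1, c)
  expect_lt(abs(wq_sim - wq_th) / wq_th, 0.10)
  lq_sim <- summary_value(exp, "queue_length.S")
  expect_lt(abs(lq_sim - erlang_c_lq(lam, 1, c)) / erlang_c_lq(lam, 1, c),
            0.05)
})

test_that("flow is conserved in every replication", {
  m <- default_ocr_model()
  for (seed in c(1, 2, 3)) {
    rep <- run_replication(m, sim_config(), seed = seed)
    s <- setNames(rep$stats$value, rep$stats$measure)
    expect_equal(s[["n_in"]], s[["n_out"]] + s[["wip"]])
    w <- rep$trials$in_window
    expect_equal(s[["n_in"]], sum(w))
    expect_equal(s[["n_out"]],
                 sum(w & rep$trials$status == "completed"))
  }
})

test_that("experiments are reproducible given the master seed", {
  m <- constant_forkjoin_model()
  cfg <- sim_config(horizon = 100, warmup = 20, replications = 2, seed = 99)
  e1 <- simulate_trials(m, cfg)
  e2 <- simulate_trials(m, cfg)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$seeds, e2$seeds)
})

test_that("more capacity never slows activation; more arrivals never speed it", {
  m <- default_ocr_model()
  cfg <- sim_config(replications = 8, seed = 21)
  base <- simulate_trials(m, cfg)
  up <- apply_scenario(m, scenario("cap+", capacity_multipliers =
                                    c("Contract Negotiation" = 2,
                                      "Budget Negotiation" = 2)))
  faster <- simulate_trials(up, cfg)
  ci <- summary_ci(base, "activation_time") +
    summary_ci(faster, "activation_time")
  expect_lt(summary_value(faster, "activation_time"),
            summary_value(base, "activation_time") + ci)
  busier <- simulate_trials(apply_scenario(m, scenario("arr+",
                                                       arrival_scale = 1.5)),
                            cfg)
  expect_gt(summary_value(busier, "activation_time"),
            summary_value(base, "activation_time") - ci)
})

test_that("replication sizing matches a brute-force scan", {
  m <- constant_forkjoin_model()
  pilot <- simulate_trials(m, sim_config(horizon = 100, warmup = 20,
                                         replications = 5, seed = 7))
  # constant durations, ample capacity: no variance across replications
  expect_identical(replications_needed(pilot), 2L)

  noisy <- simulate_trials(default_ocr_model(),
                           sim_config(replications = 6, seed = 13))
  n_pkg <- replications_needed(noisy, rel_error = 0.05)
  row <- noisy$summary[noisy$summary$measure == "activation_time", ]
  scan <- 2
  while (qt(0.975, scan - 1) * row$sd / (sqrt(scan) * row$mean) > 0.05)
    scan <- scan + 1
  expect_equal(n_pkg, scan)
  expect_error(replications_needed(noisy, rel_error = 2),
               class = "trialflow_error_bad_config")
})

test_that("sizing the default experiment lands near the design point", {
  pilot <- simulate_trials(default_ocr_model(),
                           sim_config(replications = 10, seed = 31))
  n <- replications_needed(pilot, rel_error = 0.05)
  # the case-study design used 38 replications for 5% error; same order
  expect_gt(n, 5)
  expect_lt(n, 400)
})

test_that("capacity calibration recovers a known M/M/c configuration", {
  lam <- 2.4
  target <- erlang_c_lq(lam, 1, 3)  # Lq at capacity 3
  m <- single_stage_model(dist_exponential(1), capacity = 1, lambda = lam)
  cal <- calibrate_capacities(
    m, targets = c(S = target),
    config = sim_config(horizon = 2000, warmup = 200, replications = 6,
                        seed = 17))
  expect_equal(cal$subprocesses[["S"]]$capacity, 3)
  # an unloaded stage with a near-zero target needs no extra servers
  m2 <- single_stage_model(dist_exponential(1), capacity = 1, lambda = 0.1)
  cal2 <- calibrate_capacities(
    m2, targets = c(S = 0),
    config = sim_config(horizon = 500, warmup = 50, replications = 4,
                        seed = 19))
  expect_equal(cal2$subprocesses[["S"]]$capacity, 1)
})

test_that("branch-skip probabilities thin a branch without breaking the join", {
  m <- constant_forkjoin_model(lambda = 0.1)
  m$branch_traversal[["Budget"]] <- 0.5
  rep <- run_replication(m, sim_config(horizon = 400, warmup = 0,
                                       replications = 2), seed = 23)
  sk <- rep$events$skipped[rep$events$subprocess == "Budget"]
  expect_gt(mean(sk), 0.3); expect_lt(mean(sk), 0.7)
  # trials that skipped budget wait only for contract and batch nothing
  skipped_ids <- rep$events$trial_id[rep$events$subprocess == "Budget" & sk]
  expect_true(all(rep$trials$batch_wait[skipped_ids] == 0))
  expect_true(all(abs(rep$trials$activation_time[skipped_ids] -
                        (2 + 5 + 1 + 1 + 1)) < 1e-9))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(replications = 1),
               class = "trialflow_error_bad_config")
  expect_error(sim_config(horizon = 0), class = "trialflow_error_bad_config")
  expect_error(sim_config(warmup = -1), class = "trialflow_error_bad_config")
})
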