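#' Simulation run configuration
#'
#' @param horizon Measurement window length in days (default one year).
#' @param warmup Warm-up span discarded before measurement, in days
#'   (default four years). Statistics cover trials arriving in
#'   `[warmup, warmup + horizon)`; queue-length time averages are taken
#'   over the same window.
#' @param replications Number of independent replications (>= 2).
#' @param seed Master seed; every replication draws its own substream
#'   seed from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(horizon = 365, warmup = 1460, replications = 38,
                       seed = 1L) {
  if (!is.numeric(horizon) || horizon <= 0)
    abort("`horizon` must be > 0.", class = "trialflow_error_bad_config")
  if (!is.numeric(warmup) || warmup < 0)
    abort("`warmup` must be >= 0.", class = "trialflow_error_bad_config")
  if (!is.numeric(replications) || replications < 2)
    abort("`replications` must be >= 2.", class = "trialflow_error_bad_config")
  structure(list(horizon = horizon, warmup = warmup,
                 replications = as.integer(replications),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Exact multi-server FIFO: trials are taken in ready-time order; each joins
# the earliest-free server. Returns service-start times.
serve_fifo <- function(ready, svc, capacity) {
  if (is.infinite(capacity)) return(ready)
  n <- length(ready)
  start <- numeric(n)
  free <- numeric(capacity)
  for (i in order(ready, seq_len(n))) {
    k <- which.min(free)
    s <- max(ready[i], free[k])
    start[i] <- s
    free[k] <- s + svc[i]
  }
  start
}

#' Run one replication of the activation workflow
#'
#' Poisson arrivals feed the routing graph; each sub-process is a
#' finite-capacity FIFO station; at an AND-split a trial's documents
#' proceed down all branches concurrently and at the AND-join the
#' first-finished document waits for its siblings. Arrivals stop at
#' `warmup + horizon` but every trial is followed to completion, so
#' activation times are uncensored; the `status` field still records
#' whether a trial was finished by the horizon.
#'
#' Per-trial idle time is activation time minus the service-time critical
#' path through the graph (the parallel section contributes the larger
#' branch service sum), so idle + value-added = activation and idle >= 0.
#'
#' @param model A [process_model].
#' @param config A [sim_config].
#' @param seed Integer seed for this replication.
#' @return A list with `trials` (one row per trial: arrival, activation,
#'   idle, batch wait, status, ...), `events` (one row per trial x
#'   sub-process with queue-entry/service-start/service-end times) and
#'   `stats` (a long tibble of replication summary measures).
#' @export
run_replication <- function(model, config = sim_config(), seed = 1L) {
  stopifnot(inherits(model, "process_model"), inherits(config, "sim_config"))
  set.seed(seed)
  t_end <- config$warmup + config$horizon
  lam <- model$arrival_rate * model$arrival_scale

  # arrival stream on [0, t_end)
  n_guess <- ceiling(lam * t_end + 4 * sqrt(lam * t_end) + 10)
  arr <- cumsum(rexp(n_guess, rate = lam))
  while (arr[length(arr)] <= t_end)
    arr <- c(arr, arr[length(arr)] + cumsum(rexp(n_guess, rate = lam)))
  arr <- arr[arr < t_end]
  n <- length(arr)
  if (n == 0)
    abort("No arrivals generated; horizon too short for the arrival rate.",
          class = "trialflow_error_bad_config")

  nodes <- model$topo
  pred <- split(model$routing$from, factor(model$routing$to, levels = nodes))
  ready <- start <- end <- svc <- list()
  skipped <- list()
  cpath <- list()  # service-time critical path up to and including node
  batch_first <- rep(NA_real_, n)
  batch_release <- rep(NA_real_, n)
  batch_wait <- numeric(n)

  for (nd in nodes) {
    sp <- model$subprocesses[[nd]]
    pr <- pred[[nd]]
    if (length(pr) == 0) {
      rdy <- arr
      cp_in <- numeric(n)
    } else if (length(pr) == 1) {
      rdy <- end[[pr]]
      cp_in <- cpath[[pr]]
    } else {
      rdy <- do.call(pmax, end[pr])
      first <- do.call(pmin, end[pr])
      # batching: only meaningful where >= 2 branches actually traversed
      trav_n <- Reduce(`+`, purrr::map(pr, ~ !skipped[[.x]]))
      bw <- ifelse(trav_n >= 2, rdy - first, 0)
      batch_wait <- batch_wait + bw
      batch_first <- ifelse(is.na(batch_first), first, batch_first)
      batch_release <- ifelse(is.na(batch_release), rdy, batch_release)
      cp_in <- do.call(pmax, cpath[pr])
    }

    p_trav <- model$branch_traversal[[nd]]
    skip <- if (p_trav < 1) runif(n) >= p_trav else rep(FALSE, n)
    s <- subprocess_sample(sp, n)
    s[skip] <- 0

    st <- rdy
    if (any(!skip)) {
      st[!skip] <- serve_fifo(rdy[!skip], s[!skip], sp$capacity)
    }
    en <- st + s

    ready[[nd]] <- rdy; start[[nd]] <- st; end[[nd]] <- en
    svc[[nd]] <- s; skipped[[nd]] <- skip
    cpath[[nd]] <- cp_in + s
  }

  done <- end[[model$sink]]
  activation <- done - arr
  experienced <- cpath[[model$sink]]
  idle <- activation - experienced
  status <- ifelse(done <= t_end, "completed", "in_process_at_horizon")

  trials <- tibble(
    trial_id = seq_len(n),
    arrival_time = arr,
    activation_time = activation,
    experienced_service = experienced,
    idle_time = idle,
    batch_wait = batch_wait,
    batch_release_time = batch_release,
    completion_time = done,
    status = status,
    in_window = arr >= config$warmup
  )

  events <- purrr::map_dfr(nodes, function(nd) {
    tibble(trial_id = seq_len(n), subprocess = nd,
           queue_entry = ready[[nd]], service_start = start[[nd]],
           service_end = end[[nd]], skipped = skipped[[nd]])
  })

  # --- replication statistics ---------------------------------------------
  w <- trials$in_window
  t0 <- config$warmup; t1 <- t_end
  overlap <- function(a, b) pmax(0, pmin(b, t1) - pmax(a, t0))

  flow <- purrr::map_dbl(nodes, function(nd) {
    keep <- w & !skipped[[nd]]
    if (!any(keep)) return(NA_real_)
    mean(end[[nd]][keep] - ready[[nd]][keep])
  })
  qlen <- purrr::map_dbl(nodes, function(nd) {
    sum(overlap(ready[[nd]][!skipped[[nd]]], start[[nd]][!skipped[[nd]]])) /
      config$horizon
  })
  q_batch <- if (all(is.na(batch_first))) NA_real_ else
    sum(overlap(batch_first[!is.na(batch_first)],
                batch_release[!is.na(batch_release)])) / config$horizon

  n_in <- sum(w)
  n_out <- sum(w & trials$status == "completed")

  stats <- dplyr::bind_rows(
    tibble(measure = c("activation_time", "idle_time", "batch_wait"),
           value = c(mean(activation[w]), mean(idle[w]),
                     mean(batch_wait[w]))),
    tibble(measure = paste0("flow_time.", nodes), value = flow),
    tibble(measure = paste0("queue_length.", nodes), value = qlen),
    tibble(measure = "queue_length.batch_join", value = q_batch),
    tibble(measure = c("n_in", "n_out", "wip"),
           value = c(n_in, n_out, n_in - n_out))
  )

  list(trials = trials, events = events, stats = stats)
}

#' Run a replicated simulation experiment
#'
#' Runs `config$replications` independent replications (each on its own
#' seed substream drawn from the master seed) and aggregates every
#' replication measure into a cross-replication mean with a 95 %
#' Student-t confidence half-width.
#'
#' @param model A [process_model].
#' @param config A [sim_config].
#' @return An `activation_experiment`: `summary` tibble (measure, mean,
#'   sd, ci_halfwidth, n_reps), the per-replication `reps` tibble, the
#'   seeds used, and the config. [tidy()], [glance()] and [autoplot()]
#'   methods are provided.
#' @examples
#' \donttest{
#' exp <- simulate_trials(default_ocr_model(),
#'                        sim_config(replications = 4, seed = 42))
#' glance(exp)
#' }
#' @export
simulate_trials <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "process_model"), inherits(config, "sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$replications)
  reps <- purrr::map_dfr(seq_len(config$replications), function(r) {
    dplyr::mutate(run_replication(model, config, seed = seeds[r])$stats,
                  rep = r)
  })
  summary <- reps |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      n_reps = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      ci_halfwidth = ifelse(.data$n_reps >= 2,
                            qt(0.975, pmax(.data$n_reps - 1, 1)) * .data$sd /
                              sqrt(pmax(.data$n_reps, 1)), NA_real_)) |>
    dplyr::select("measure", "mean", "sd", "ci_halfwidth", "n_reps")
  structure(list(summary = summary, reps = reps, seeds = seeds,
                 config = config),
            class = "activation_experiment")
}

experiment_value <- function(exp, measure) {
  i <- match(measure, exp$summary$measure)
  if (is.na(i)) abort(paste0("No such measure: ", measure),
                      class = "trialflow_error_bad_measure")
  exp$summary[i, ]
}

#' Replications needed for a target relative precision
#'
#' Smallest n such that the 95 % Student-t half-width of the mean
#' activation time, estimated from a pilot experiment's between-replication
#' variance, is at most `rel_error` of the mean:
#' `t_{n-1, 0.975} * s / (sqrt(n) * mean) <= rel_error`.
#'
#' @param pilot An `activation_experiment` with >= 2 replications.
#' @param rel_error Target relative error in `(0, 1)`.
#' @param measure Which measure to size for (default activation time).
#' @return An integer >= 2.
#' @export
replications_needed <- function(pilot, rel_error = 0.05,
                                measure = "activation_time") {
  stopifnot(inherits(pilot, "activation_experiment"))
  if (!is.numeric(rel_error) || rel_error <= 0 || rel_error >= 1)
    abort("`rel_error` must be in (0, 1).", class = "trialflow_error_bad_config")
  row <- experiment_value(pilot, measure)
  if (!is.finite(row$mean) || row$mean == 0)
    abort("Pilot mean is zero; relative precision undefined.",
          class = "trialflow_error_zero_mean")
  s <- row$sd
  if (s == 0) return(2L)
  for (n in 2:1e6) {
    if (qt(0.975, n - 1) * s / (sqrt(n) * abs(row$mean)) <= rel_error)
      return(as.integer(n))
  }
  abort("No n up to 1e6 reaches the requested precision.",
        class = "trialflow_error_bad_config")
}

#' Calibrate sub-process capacities to target queue lengths
#'
#' For each named target, searches integer capacities upward from the
#' smallest stable value (capacity strictly greater than the offered load
#' `arrival rate x mean service`) and picks the capacity whose simulated
#' baseline time-average queue length is closest to the target. Queue
#' length is monotone decreasing in capacity, so the search stops as soon
#' as the simulated queue drops below the target.
#'
#' @param model A [process_model].
#' @param targets Named numeric vector of target time-average queue
#'   lengths (trials), e.g. `c("Contract Negotiation" = 18.5)`.
#' @param config A [sim_config] for the calibration runs (a modest number
#'   of replications is enough).
#' @param max_extra Upper search bound above the stability minimum.
#' @return The model with calibrated capacities; the chosen values and
#'   their simulated queue lengths are attached as attribute
#'   `"calibration"`.
#' @export
calibrate_capacities <- function(model, targets = c("Contract Negotiation" = 18.5,
                                                    "Budget Negotiation" = 15.2),
                                 config = sim_config(replications = 10),
                                 max_extra = 12L) {
  stopifnot(inherits(model, "process_model"))
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    abort("`targets` must be a named vector.", class = "trialflow_error_bad_config")
  unknown <- setdiff(names(targets), names(model$subprocesses))
  if (length(unknown))
    abort(paste0("Unknown sub-processes in targets: ",
                 paste(unknown, collapse = ", ")),
          class = "trialflow_error_bad_config")
  if (any(targets < 0))
    abort("Queue-length targets must be nonnegative.",
          class = "trialflow_error_bad_config")

  lam <- model$arrival_rate * model$arrival_scale
  log <- list()
  for (nd in names(targets)) {
    sp <- model$subprocesses[[nd]]
    a <- lam * model$branch_traversal[[nd]] * subprocess_mean(sp)
    c_min <- floor(a) + 1L
    best <- NULL
    for (cap in c_min:(c_min + max_extra)) {
      model$subprocesses[[nd]]$capacity <- cap
      exp <- simulate_trials(model, config)
      lq <- experiment_value(exp, paste0("queue_length.", nd))$mean
      err <- abs(lq - targets[[nd]])
      if (is.null(best) || err < best$err - 0.05) {
        best <- list(cap = cap, lq = lq, err = err)
      } else break  # queue length is monotone in capacity: gains stalled
      if (lq < targets[[nd]]) break  # larger capacities only move further away
    }
    if (is.null(best))
      abort(paste0("No stable capacity found for ", nd, " within bound."),
            class = "trialflow_error_unstable")
    model$subprocesses[[nd]]$capacity <- best$cap
    log[[nd]] <- tibble(subprocess = nd, capacity = best$cap,
                        queue_length = best$lq, target = targets[[nd]])
  }
  attr(model, "calibration") <- dplyr::bind_rows(log)
  model
}
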