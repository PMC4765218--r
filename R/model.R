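#' Define a sub-process of the activation workflow
#'
#' A sub-process is a service station: trials queue FIFO and at most
#' `capacity` of them are in service at once. Its service time is either a
#' single [duration_dist] or an ordered list of named activities executed
#' in series within the same capacity slot (used for Initial Preparation,
#' whose four activities are timed separately).
#'
#' @param name Unique sub-process name.
#' @param duration A [duration_dist], or a named list of them (activities
#'   in series).
#' @param capacity Positive integer, or `Inf` for unbounded.
#' @return A `subprocess` object.
#' @export
subprocess <- function(name, duration, capacity = Inf) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    abort("`name` must be a non-empty string.",
          class = "trialflow_error_bad_subprocess")
  if (inherits(duration, "duration_dist")) {
    activities <- NULL
  } else if (is.list(duration) && length(duration) > 0 &&
             all(purrr::map_lgl(duration, inherits, "duration_dist"))) {
    activities <- duration
    if (is.null(names(activities)))
      names(activities) <- paste0("activity_", seq_along(activities))
  } else {
    abort("`duration` must be a duration_dist or a non-empty list of them.",
          class = "trialflow_error_bad_subprocess")
  }
  if (!(is.infinite(capacity) || (is.numeric(capacity) && capacity >= 1 &&
                                  capacity == floor(capacity))))
    abort("`capacity` must be a positive integer or Inf.",
          class = "trialflow_error_bad_subprocess")
  structure(list(name = name,
                 duration = if (is.null(activities)) duration else NULL,
                 activities = activities,
                 capacity = capacity),
            class = "subprocess")
}

#' Theoretical mean service time of a sub-process
#'
#' Sum of the activity means for a series sub-process, otherwise the
#' distribution mean, in days.
#'
#' @param sp A [subprocess].
#' @return A single number.
#' @export
subprocess_mean <- function(sp) {
  if (!is.null(sp$activities))
    sum(purrr::map_dbl(sp$activities, dist_mean))
  else dist_mean(sp$duration)
}

subprocess_sample <- function(sp, n) {
  if (!is.null(sp$activities)) {
    draws <- purrr::map(sp$activities, dist_sample, n = n)
    Reduce(`+`, draws)
  } else dist_sample(sp$duration, n)
}

#' Assemble and validate an activation process model
#'
#' The workflow is a directed acyclic routing graph over sub-process names.
#' A node with several successors is an AND-split (the trial's documents
#' proceed down every branch concurrently); a node with several
#' predecessors is an AND-join (the first-finished document waits --
#' "batching" -- until all siblings arrive). The graph must have exactly
#' one source and one sink, with every node reachable from the source and
#' reaching the sink.
#'
#' @param subprocesses List of [subprocess] objects.
#' @param routing Two-column data frame (`from`, `to`) of directed edges
#'   over sub-process names.
#' @param arrival_rate Trials per calendar day (Poisson arrivals,
#'   exponential interarrival times).
#' @param arrival_scale Positive scenario multiplier on the arrival rate.
#' @param branch_traversal Optional named numeric vector of traversal
#'   probabilities in `(0, 1]` per sub-process; a trial skips a sub-process
#'   (passing through with zero service) with one minus this probability.
#'   Defaults to 1 for every sub-process.
#' @return A validated `process_model`.
#' @export
process_model <- function(subprocesses, routing, arrival_rate,
                          arrival_scale = 1, branch_traversal = NULL) {
  if (!all(purrr::map_lgl(subprocesses, inherits, "subprocess")))
    abort("`subprocesses` must be a list of subprocess objects.",
          class = "trialflow_error_bad_subprocess")
  nm <- purrr::map_chr(subprocesses, "name")
  if (anyDuplicated(nm))
    abort("Sub-process names must be unique.",
          class = "trialflow_error_bad_subprocess")
  names(subprocesses) <- nm

  routing <- as_tibble(routing)
  if (!all(c("from", "to") %in% names(routing)))
    abort("`routing` needs columns `from` and `to`.",
          class = "trialflow_error_bad_routing")
  unknown <- setdiff(unique(c(routing$from, routing$to)), nm)
  if (length(unknown))
    abort(paste0("Routing references unknown sub-processes: ",
                 paste(unknown, collapse = ", ")),
          class = "trialflow_error_bad_routing")

  if (!is.numeric(arrival_rate) || arrival_rate <= 0)
    abort("`arrival_rate` must be > 0.", class = "trialflow_error_bad_arrival")
  if (!is.numeric(arrival_scale) || arrival_scale <= 0)
    abort("`arrival_scale` must be > 0.", class = "trialflow_error_bad_arrival")

  trav <- setNames(rep(1, length(nm)), nm)
  if (!is.null(branch_traversal)) {
    bad <- setdiff(names(branch_traversal), nm)
    if (length(bad))
      abort(paste0("branch_traversal names unknown sub-processes: ",
                   paste(bad, collapse = ", ")),
            class = "trialflow_error_bad_routing")
    if (any(branch_traversal <= 0 | branch_traversal > 1))
      abort("branch_traversal probabilities must lie in (0, 1].",
            class = "trialflow_error_bad_routing")
    trav[names(branch_traversal)] <- branch_traversal
  }

  model <- structure(list(subprocesses = subprocesses, routing = routing,
                          arrival_rate = arrival_rate,
                          arrival_scale = arrival_scale,
                          branch_traversal = trav),
                     class = "process_model")
  validate_process_model(model)
}

#' @rdname process_model
#' @param model A `process_model` to re-validate (after manual edits).
#' @export
validate_process_model <- function(model) {
  nm <- names(model$subprocesses)
  routing <- model$routing
  indeg <- table(factor(routing$to, levels = nm))
  outdeg <- table(factor(routing$from, levels = nm))
  sources <- nm[indeg == 0]
  sinks <- nm[outdeg == 0]
  if (length(sources) != 1)
    abort(paste0("Routing must have exactly one source; found ",
                 length(sources), "."),
          class = "trialflow_error_missing_source")
  if (length(sinks) != 1)
    abort(paste0("Routing must have exactly one sink; found ",
                 length(sinks), "."),
          class = "trialflow_error_missing_sink")

  topo <- topo_sort(nm, routing)  # aborts on cycles
  # reachability from source / to sink
  succ <- split(routing$to, factor(routing$from, levels = nm))
  pred <- split(routing$from, factor(routing$to, levels = nm))
  reach_fwd <- reach_from(sources, succ)
  reach_bwd <- reach_from(sinks, pred)
  stranded <- setdiff(nm, intersect(reach_fwd, reach_bwd))
  if (length(stranded))
    abort(paste0("Sub-processes not on a source-to-sink path: ",
                 paste(stranded, collapse = ", ")),
          class = "trialflow_error_bad_routing")

  model$source <- sources
  model$sink <- sinks
  model$topo <- topo
  model
}

topo_sort <- function(nodes, routing) {
  indeg <- setNames(as.integer(table(factor(routing$to, levels = nodes))),
                    nodes)
  succ <- split(routing$to, factor(routing$from, levels = nodes))
  queue <- nodes[indeg == 0]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in succ[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes))
    abort("Routing graph contains a cycle.",
          class = "trialflow_error_cyclic_routing")
  out
}

reach_from <- function(start, adj) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' The bundled clinical-trials-office baseline model
#'
#' Encodes the case-study workflow: Initial Preparation (four timed
#' activities in series), then Contract Negotiation and Budget Negotiation
#' in parallel, an AND-join, and the three final approvals (PI, sponsored
#' research division, sponsor) in sequence. Arrivals are Poisson at
#' 147 trials per 365 days. Contract and Budget capacities (12 and 11)
#' come from calibrating the simulated time-average queue lengths to the
#' observed 18.5 and 15.2 trials (see [calibrate_capacities()]); the
#' remaining capacities are set so those stages add well under a day of
#' expected waiting.
#'
#' @return A validated [process_model].
#' @examples
#' m <- default_ocr_model()
#' dist_mean(m$subprocesses[["Contract Negotiation"]]$duration) # 28.5
#' @export
default_ocr_model <- function() {
  sps <- list(
    subprocess("Initial Preparation",
               list("OCR sends documents" = dist_uniform(0.5, 1.0),
                    "P&L reviews"         = dist_triangular(1.0, 8.0, 21.0),
                    "PI prepares documents" = dist_triangular(1.0, 2.0, 3.0),
                    "P&L reviews (2nd)"   = dist_uniform(0.5, 1.0)),
               capacity = 9),
    subprocess("Contract Negotiation", dist_exponential(28.5), capacity = 12),
    subprocess("Budget Negotiation",   dist_exponential(25.0), capacity = 11),
    subprocess("PI Approval",      dist_lognormal(5.0, 8.3),  capacity = 5),
    subprocess("DSR Approval",     dist_lognormal(2.5, 2.8),  capacity = 3),
    subprocess("Sponsor Approval", dist_lognormal(6.5, 15.9), capacity = 7)
  )
  routing <- tibble(
    from = c("Initial Preparation", "Initial Preparation",
             "Contract Negotiation", "Budget Negotiation",
             "PI Approval", "DSR Approval"),
    to = c("Contract Negotiation", "Budget Negotiation",
           "PI Approval", "PI Approval",
           "DSR Approval", "Sponsor Approval")
  )
  process_model(sps, routing, arrival_rate = 147 / 365)
}

#' @export
print.process_model <- function(x, ...) {
  cat("<process_model> ", length(x$subprocesses), " sub-processes, arrivals ",
      signif(x$arrival_rate * x$arrival_scale, 4), "/day\n", sep = "")
  for (sp in x$subprocesses) {
    dur <- if (!is.null(sp$activities))
      paste0("series of ", length(sp$activities), " activities (mean ",
             signif(subprocess_mean(sp), 4), " d)")
    else format(sp$duration)
    cat("  ", format(sp$name, width = 22), dur,
        "  capacity ", sp$capacity, "\n", sep = "")
  }
  cat("  routing: ",
      paste(paste(x$routing$from, "->", x$routing$to), collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' Read or write a process model configuration
#'
#' Models are stored as YAML with nested sections: `arrival` (base rate and
#' scale), `subprocesses` (name, capacity, and either a `duration` or an
#' `activities` list of `{family, params}` entries), `routing` (a list of
#' `[from, to]` pairs), and optional `branch_traversal`. The export/import
#' round trip is lossless.
#'
#' @param path File path.
#' @return `read_process_model()` a validated [process_model];
#'   `write_process_model()` returns `path` invisibly.
#' @export
read_process_model <- function(path) {
  if (!file.exists(path))
    abort(paste0("No such config file: ", path),
          class = "trialflow_error_io")
  cfg <- yaml::read_yaml(path)
  process_model_from_config(cfg)
}

process_model_from_config <- function(cfg) {
  if (is.null(cfg$subprocesses) || is.null(cfg$routing) ||
      is.null(cfg$arrival))
    abort("Config must contain `arrival`, `subprocesses` and `routing`.",
          class = "trialflow_error_bad_config")
  sps <- purrr::map(cfg$subprocesses, function(s) {
    cap <- s$capacity %||% Inf
    if (identical(cap, "unbounded")) cap <- Inf
    dur <- if (!is.null(s$activities)) {
      acts <- purrr::map(s$activities, as_duration_dist)
      names(acts) <- purrr::map_chr(s$activities, ~ .x$name %||% "activity")
      acts
    } else as_duration_dist(s$duration)
    subprocess(s$name, dur, capacity = cap)
  })
  routing <- tibble(
    from = purrr::map_chr(cfg$routing, 1),
    to = purrr::map_chr(cfg$routing, 2)
  )
  trav <- if (!is.null(cfg$branch_traversal))
    unlist(cfg$branch_traversal) else NULL
  process_model(sps, routing,
                arrival_rate = cfg$arrival$base_rate,
                arrival_scale = cfg$arrival$scale_factor %||% 1,
                branch_traversal = trav)
}

#' @rdname read_process_model
#' @param model A [process_model].
#' @export
write_process_model <- function(model, path) {
  stopifnot(inherits(model, "process_model"))
  cfg <- list(
    arrival = list(base_rate = model$arrival_rate,
                   scale_factor = model$arrival_scale),
    subprocesses = purrr::map(model$subprocesses, function(sp) {
      out <- list(name = sp$name,
                  capacity = if (is.infinite(sp$capacity)) "unbounded"
                             else sp$capacity)
      if (!is.null(sp$activities)) {
        out$activities <- purrr::imap(unname(sp$activities), function(d, i) {
          c(list(name = names(sp$activities)[i]), dist_to_list(d))
        })
      } else out$duration <- dist_to_list(sp$duration)
      out
    }),
    routing = purrr::map2(model$routing$from, model$routing$to, c),
    branch_traversal = as.list(model$branch_traversal)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
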