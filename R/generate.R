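#' Specification for the synthetic operational data generator
#'
#' Describes a synthetic year (or years) of office operations: trials
#' arrive as a Poisson stream, traverse the workflow with durations drawn
#' from the model's distributions (laid out back-to-back, parallel
#' branches sharing a start and joining at the later finish -- the
#' generator emulates the observed activity log, in which the fitted
#' distributions already absorb queueing and rework), receive a status
#' from the given mix, and emit communication events whose per-direction
#' annual totals hit the interaction targets, allocated across trials
#' proportionally to the sub-process duration and scattered uniformly
#' within it.
#'
#' @param model A [process_model] (distributions and routing are used;
#'   capacities are not, see above).
#' @param n_years Years of operations to generate.
#' @param status_mix Named proportions over
#'   `complete`/`missing_data`/`in_process`/`terminated`; must sum to 1.
#'   The default mirrors a 78:16:52:1 split of 147 trials.
#' @param interaction_targets Tibble with columns `subprocess`, `source`,
#'   `target`, `count`: annual interaction totals per initiating
#'   direction. See [default_interaction_targets()].
#' @param seed Master seed; a fixed seed reproduces the dataset
#'   byte-for-byte.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(model = default_ocr_model(), n_years = 1,
                           status_mix = c(complete = 78, missing_data = 16,
                                          in_process = 52,
                                          terminated = 1) / 147,
                           interaction_targets = default_interaction_targets(),
                           seed = 1L) {
  stopifnot(inherits(model, "process_model"))
  if (abs(sum(status_mix) - 1) > 1e-8 || any(status_mix < 0))
    abort("`status_mix` must be nonnegative proportions summing to 1.",
          class = "trialflow_error_bad_config")
  need <- c("subprocess", "source", "target", "count")
  interaction_targets <- as_tibble(interaction_targets)
  if (!all(need %in% names(interaction_targets)) ||
      any(interaction_targets$count < 0))
    abort("`interaction_targets` needs subprocess/source/target/count >= 0.",
          class = "trialflow_error_bad_config")
  structure(list(model = model, n_years = n_years, status_mix = status_mix,
                 interaction_targets = interaction_targets,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Default annual interaction-volume targets
#'
#' Contract negotiation is dominated by office <-> sponsor traffic
#' (507 office-initiated vs 346 sponsor-initiated interactions per year);
#' during budget negotiation the sponsor and the PI out-initiate the
#' office (153 vs 69 and 70 vs 13).
#'
#' @return A tibble: `subprocess`, `source`, `target`, `count`.
#' @export
default_interaction_targets <- function() {
  tibble(
    subprocess = c(rep("Contract Negotiation", 2),
                   rep("Budget Negotiation", 4)),
    source = c("OCR", "Sponsor", "Sponsor", "OCR", "PI", "OCR"),
    target = c("Sponsor", "OCR", "OCR", "Sponsor", "OCR", "PI"),
    count = c(507, 346, 153, 69, 70, 13)
  )
}

#' Generate a synthetic operational dataset
#'
#' @param spec A [generator_spec].
#' @return An `ops_dataset` list: `timestamps` (one row per trial x
#'   sub-process: `trial_id`, `subprocess`, `start`, `end`, `status`, day
#'   offsets from study start) and `communications` (one row per
#'   interaction: `timestamp`, `source`, `target`, `subprocess`,
#'   `trial_id`), both ordered deterministically.
#' @examples
#' ds <- generate_dataset(generator_spec(seed = 7))
#' dplyr::count(ds$timestamps, status)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  model <- spec$model
  t_total <- 365 * spec$n_years
  lam <- model$arrival_rate * model$arrival_scale

  n_guess <- ceiling(lam * t_total + 4 * sqrt(lam * t_total) + 10)
  arr <- cumsum(rexp(n_guess, rate = lam))
  while (arr[length(arr)] <= t_total)
    arr <- c(arr, arr[length(arr)] + cumsum(rexp(n_guess, rate = lam)))
  arr <- arr[arr < t_total]
  n <- length(arr)

  nodes <- model$topo
  pred <- split(model$routing$from, factor(model$routing$to, levels = nodes))
  start <- end <- list()
  for (nd in nodes) {
    pr <- pred[[nd]]
    st <- if (length(pr) == 0) arr else do.call(pmax, end[pr])
    dur <- subprocess_sample(model$subprocesses[[nd]], n)
    start[[nd]] <- st
    end[[nd]] <- st + dur
  }

  statuses <- sample(names(spec$status_mix), n, replace = TRUE,
                     prob = spec$status_mix)

  rows <- purrr::map_dfr(nodes, function(nd) {
    tibble(trial_id = seq_len(n), subprocess = nd,
           start = start[[nd]], end = end[[nd]])
  }) |>
    dplyr::mutate(status = statuses[.data$trial_id]) |>
    dplyr::arrange(.data$trial_id, .data$start)

  # status-driven truncation of the visible log
  done <- end[[model$sink]]
  cut <- arr + runif(n) * (done - arr)
  keep <- rep(TRUE, nrow(rows))
  trunc <- statuses[rows$trial_id] %in% c("in_process", "terminated")
  keep[trunc & rows$end > cut[rows$trial_id]] <- FALSE
  drop_one <- which(statuses == "missing_data")
  if (length(drop_one)) {
    # drop one uniformly chosen sub-process row per missing-data trial
    pick <- vapply(drop_one, function(i) sample(length(nodes), 1), 1L)
    key <- paste(rows$trial_id, rows$subprocess)
    keep[match(paste(drop_one, nodes[pick]), key)] <- FALSE
  }
  timestamps <- rows[keep, ]

  # communications: totals allocated across visible sub-process intervals
  comms <- purrr::pmap_dfr(spec$interaction_targets, function(subprocess,
                                                              source, target,
                                                              count) {
    iv <- dplyr::filter(timestamps, .data$subprocess == !!subprocess)
    total <- round(count * spec$n_years)
    if (nrow(iv) == 0 || total == 0)
      return(tibble(timestamp = numeric(), source = character(),
                    target = character(), subprocess = character(),
                    trial_id = integer()))
    dur <- iv$end - iv$start
    w <- if (sum(dur) > 0) dur / sum(dur) else rep(1 / nrow(iv), nrow(iv))
    alloc <- as.vector(rmultinom(1, total, w))
    idx <- rep(seq_len(nrow(iv)), alloc)
    tibble(timestamp = iv$start[idx] +
             runif(length(idx)) * (iv$end[idx] - iv$start[idx]),
           source = source, target = target,
           subprocess = subprocess, trial_id = iv$trial_id[idx])
  }) |>
    dplyr::arrange(.data$timestamp)

  structure(list(timestamps = timestamps, communications = comms,
                 spec = spec),
            class = "ops_dataset")
}

#' Write or read a synthetic dataset as CSV
#'
#' Writes `timestamps.csv` and `communications.csv` into `dir` -- the same
#' dialects the analysis functions read.
#'
#' @param ds An `ops_dataset`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_ops_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ops_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "timestamps.csv")
  p2 <- file.path(dir, "communications.csv")
  readr::write_csv(ds$timestamps, p1)
  readr::write_csv(ds$communications, p2)
  invisible(c(p1, p2))
}

#' @rdname write_ops_dataset
#' @param path Path to a timestamps CSV.
#' @export
read_timestamp_log <- function(path) {
  if (!file.exists(path))
    abort(paste0("No such file: ", path), class = "trialflow_error_io")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @export
print.ops_dataset <- function(x, ...) {
  cat("<ops_dataset> ", dplyr::n_distinct(x$timestamps$trial_id),
      " trials, ", nrow(x$timestamps), " timestamp rows, ",
      nrow(x$communications), " interactions\n", sep = "")
  invisible(x)
}
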