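#' Declare a what-if scenario
#'
#' A scenario is a declarative transform of a baseline model: scale the
#' arrival rate, multiply selected capacities (rounded half-up to an
#' integer, never below 1), and/or swap a sub-process's service
#' distribution for a mean-preserving lower-variance family.
#'
#' The variability swap replaces the service distribution with one of the
#' same theoretical mean \eqn{\mu}: `"triangular"` gives
#' \eqn{Tri((1-r)\mu, \mu, (1+r)\mu)} with range factor `r = swap_range`
#' (default 0.5, cutting the variance of an exponential from
#' \eqn{\mu^2} to \eqn{\mu^2 r^2/6}), `"constant"` gives a degenerate
#' \eqn{\mu}, and `"exponential"` an exponential with mean \eqn{\mu}.
#'
#' @param name Scenario label.
#' @param arrival_scale Positive multiplier on the arrival rate.
#' @param capacity_multipliers Named positive numeric vector,
#'   sub-process -> multiplier.
#' @param variability_swap Named character vector, sub-process ->
#'   replacement family.
#' @param swap_range Range factor for the triangular swap.
#' @param description Free-text note.
#' @return A `scenario` object.
#' @export
scenario <- function(name, arrival_scale = 1, capacity_multipliers = NULL,
                     variability_swap = NULL, swap_range = 0.5,
                     description = "") {
  if (!is.numeric(arrival_scale) || arrival_scale <= 0)
    abort("`arrival_scale` must be > 0.", class = "trialflow_error_bad_scenario")
  if (!is.null(capacity_multipliers) &&
      (is.null(names(capacity_multipliers)) || any(capacity_multipliers <= 0)))
    abort("`capacity_multipliers` must be a named vector of positives.",
          class = "trialflow_error_bad_scenario")
  if (!is.null(variability_swap) && is.null(names(variability_swap)))
    abort("`variability_swap` must be a named character vector.",
          class = "trialflow_error_bad_scenario")
  structure(list(name = name, arrival_scale = arrival_scale,
                 capacity_multipliers = capacity_multipliers,
                 variability_swap = variability_swap,
                 swap_range = swap_range, description = description),
            class = "scenario")
}

mean_preserving_swap <- function(dist, family, range_factor = 0.5) {
  mu <- dist_mean(dist)
  switch(family,
    triangular = dist_triangular((1 - range_factor) * mu, mu,
                                 (1 + range_factor) * mu),
    constant = dist_constant(mu),
    exponential = dist_exponential(mu),
    abort(paste0("Unsupported swap family: ", family),
          class = "trialflow_error_unknown_family")
  )
}

#' Apply a scenario to a baseline model
#'
#' Returns a transformed copy; the baseline is untouched. Swapped
#' distributions preserve the theoretical mean exactly.
#'
#' @param model A [process_model].
#' @param scn A [scenario].
#' @return A validated [process_model].
#' @export
apply_scenario <- function(model, scn) {
  stopifnot(inherits(model, "process_model"), inherits(scn, "scenario"))
  out <- model
  out$arrival_scale <- model$arrival_scale * scn$arrival_scale
  for (nd in names(scn$capacity_multipliers)) {
    if (!nd %in% names(out$subprocesses))
      abort(paste0("Unknown sub-process: ", nd),
            class = "trialflow_error_bad_scenario")
    cap <- out$subprocesses[[nd]]$capacity
    if (is.finite(cap))
      out$subprocesses[[nd]]$capacity <-
        max(1, floor(cap * scn$capacity_multipliers[[nd]] + 0.5))
  }
  for (nd in names(scn$variability_swap)) {
    if (!nd %in% names(out$subprocesses))
      abort(paste0("Unknown sub-process: ", nd),
            class = "trialflow_error_bad_scenario")
    sp <- out$subprocesses[[nd]]
    if (is.null(sp$duration))
      abort("Variability swap is only defined for single-distribution sub-processes.",
            class = "trialflow_error_bad_scenario")
    out$subprocesses[[nd]]$duration <-
      mean_preserving_swap(sp$duration, scn$variability_swap[[nd]],
                           scn$swap_range)
  }
  validate_process_model(out)
}

#' Run a comparative scenario suite
#'
#' Simulates the baseline and every scenario under the same configuration
#' and reports, per scenario and measure, the mean, its 95 % CI
#' half-width, the absolute and percentage change against baseline, and
#' whether the two 95 % confidence intervals separate (the working
#' definition of a significant change).
#'
#' @param model Baseline [process_model] (already calibrated).
#' @param scenarios A list of [scenario] objects.
#' @param config A [sim_config].
#' @param measures Which measures to tabulate (default: the headline ones).
#' @return A `scenario_comparison` tibble.
#' @export
run_scenarios <- function(model, scenarios, config = sim_config(),
                          measures = c("activation_time", "idle_time",
                                       "batch_wait")) {
  stopifnot(inherits(model, "process_model"))
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  base <- simulate_trials(model, config)
  rows <- purrr::map_dfr(scenarios, function(scn) {
    exp <- simulate_trials(apply_scenario(model, scn), config)
    dplyr::mutate(exp$summary, scenario = scn$name, .before = 1)
  })
  base_tab <- dplyr::select(base$summary, "measure",
                            baseline_mean = "mean",
                            baseline_ci = "ci_halfwidth")
  out <- rows |>
    dplyr::filter(.data$measure %in% measures) |>
    dplyr::left_join(base_tab, by = "measure") |>
    dplyr::mutate(
      delta = .data$mean - .data$baseline_mean,
      delta_pct = 100 * .data$delta / .data$baseline_mean,
      ci_separated = abs(.data$delta) >
        (.data$ci_halfwidth + .data$baseline_ci)) |>
    dplyr::select("scenario", "measure", "mean", "ci_halfwidth",
                  "baseline_mean", "baseline_ci", "delta", "delta_pct",
                  "ci_separated")
  structure(out, class = c("scenario_comparison", class(out)),
            baseline = base)
}

#' The five bundled case-study scenarios
#'
#' The numerical studies shipped with the baseline model: a 14 % workload
#' increase (16/14 arrival scaling), doubling the two negotiation
#' capacities, doubling the workload, doubling every non-negotiation
#' capacity, and swapping the exponential negotiation times for
#' mean-preserving triangular ones.
#'
#' @return A named list of [scenario] objects.
#' @export
ocr_scenarios <- function() {
  list(
    workload_16_14 = scenario(
      "workload_16_14", arrival_scale = 16 / 14,
      description = "arrival rate scaled from 14 to 16 trials/month"),
    double_negotiation_capacity = scenario(
      "double_negotiation_capacity",
      capacity_multipliers = c("Contract Negotiation" = 2,
                               "Budget Negotiation" = 2),
      description = "double contract and budget negotiation capacity"),
    double_workload = scenario(
      "double_workload", arrival_scale = 2,
      description = "arrival rate doubled at baseline capacities"),
    double_other_capacity = scenario(
      "double_other_capacity",
      capacity_multipliers = c("Initial Preparation" = 2, "PI Approval" = 2,
                               "DSR Approval" = 2, "Sponsor Approval" = 2),
      description = "double every non-negotiation capacity"),
    reduced_variability = scenario(
      "reduced_variability",
      variability_swap = c("Contract Negotiation" = "triangular",
                           "Budget Negotiation" = "triangular"),
      description = "mean-preserving triangular negotiation times")
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n", sep = "")
  if (x$arrival_scale != 1) cat("  arrival x", signif(x$arrival_scale, 4), "\n")
  if (!is.null(x$capacity_multipliers))
    cat("  capacity:",
        paste(names(x$capacity_multipliers), "x",
              x$capacity_multipliers, collapse = "; "), "\n")
  if (!is.null(x$variability_swap))
    cat("  swap:", paste(names(x$variability_swap), "->",
                         x$variability_swap, collapse = "; "), "\n")
  invisible(x)
}
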