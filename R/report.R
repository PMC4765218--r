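#' @export
print.activation_experiment <- function(x, ...) {
  cat("<activation_experiment> ", x$config$replications,
      " replications, warm-up ", x$config$warmup, " d + horizon ",
      x$config$horizon, " d\n", sep = "")
  act <- experiment_value(x, "activation_time")
  cat("  mean activation time ", round(act$mean, 1), " d (95% CI half-width ",
      round(act$ci_halfwidth, 1), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.activation_experiment <- function(x, ...) x$summary

#' @export
glance.activation_experiment <- function(x, ...) {
  act <- experiment_value(x, "activation_time")
  idle <- experiment_value(x, "idle_time")
  bw <- experiment_value(x, "batch_wait")
  tibble(activation_time = act$mean, activation_ci = act$ci_halfwidth,
         idle_time = idle$mean, batch_wait = bw$mean,
         n_replications = x$config$replications)
}

#' Side-by-side simulated-vs-observed performance table
#'
#' Lays an experiment's per-sub-process flow times, entire-process
#' activation time and yearly counts out as an aligned table, optionally
#' next to observed values for validation.
#'
#' @param exp An `activation_experiment`.
#' @param observed Optional named numeric vector of observed values keyed
#'   by measure label (e.g. `"Contract Negotiation"`, `"Entire Process"`,
#'   `"Number in"`).
#' @return A tibble: `measure`, `simulated`, `ci_halfwidth` and, when
#'   supplied, `actual`.
#' @export
comparison_table <- function(exp, observed = NULL) {
  stopifnot(inherits(exp, "activation_experiment"))
  s <- exp$summary
  flows <- s[startsWith(s$measure, "flow_time."), ]
  # present sub-processes in workflow order (as simulated), not sorted
  topo <- unique(exp$reps$measure[startsWith(exp$reps$measure, "flow_time.")])
  flows <- flows[match(topo, flows$measure), ]
  out <- dplyr::bind_rows(
    tibble(measure = sub("^flow_time\\.", "", flows$measure),
           simulated = flows$mean, ci_halfwidth = flows$ci_halfwidth),
    tibble(measure = "Entire Process",
           simulated = experiment_value(exp, "activation_time")$mean,
           ci_halfwidth = experiment_value(exp, "activation_time")$ci_halfwidth),
    tibble(measure = c("Number in", "Number out", "Still in process"),
           simulated = c(experiment_value(exp, "n_in")$mean,
                         experiment_value(exp, "n_out")$mean,
                         experiment_value(exp, "wip")$mean),
           ci_halfwidth = c(experiment_value(exp, "n_in")$ci_halfwidth,
                            experiment_value(exp, "n_out")$ci_halfwidth,
                            experiment_value(exp, "wip")$ci_halfwidth)))
  if (!is.null(observed))
    out$actual <- unname(observed[out$measure])
  out
}

#' Render a comparison table as aligned text
#'
#' @param tab Output of [comparison_table()].
#' @param digits Rounding.
#' @return A character vector of lines, invisibly; also printed.
#' @export
format_comparison <- function(tab, digits = 1) {
  sim <- paste0(format(round(tab$simulated, digits), trim = TRUE),
                " (", format(round(tab$ci_halfwidth, digits), trim = TRUE),
                ")")
  cols <- list(Measure = tab$measure)
  if ("actual" %in% names(tab))
    cols$Actual <- ifelse(is.na(tab$actual), "-",
                          format(round(tab$actual, digits), trim = TRUE))
  cols$`Simulated (95% CI)` <- sim
  widths <- purrr::imap_int(cols, ~ max(nchar(c(.y, .x))))
  line <- function(vals) paste(purrr::imap_chr(vals, function(v, nm)
    formatC(v, width = widths[[nm]], flag = "-")), collapse = "  ")
  lines <- c(line(setNames(as.list(names(cols)), names(cols))),
             purrr::map_chr(seq_len(nrow(tab)), function(i)
               line(purrr::map(cols, i))))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write an experiment summary as JSON
#'
#' @param exp An `activation_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_json <- function(exp, path) {
  stopifnot(inherits(exp, "activation_experiment"))
  jsonlite::write_json(list(
    config = unclass(exp$config),
    seeds = exp$seeds,
    summary = exp$summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
autoplot.activation_experiment <- function(object, ...) {
  s <- object$summary
  flows <- s[startsWith(s$measure, "flow_time."), ] |>
    dplyr::mutate(measure = sub("^flow_time\\.", "", .data$measure))
  ggplot2::ggplot(flows,
                  ggplot2::aes(x = stats::reorder(.data$measure, .data$mean),
                               y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci_halfwidth,
                                        ymax = .data$mean + .data$ci_halfwidth),
                           width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean flow time (days, 95% CI)")
}

#' @export
autoplot.scenario_comparison <- function(object, ...,
                                         measure = "activation_time") {
  base <- attr(object, "baseline")
  df <- object |>
    dplyr::filter(.data$measure == !!measure) |>
    dplyr::bind_rows(tibble(
      scenario = "baseline",
      mean = experiment_value(base, measure)$mean,
      ci_halfwidth = experiment_value(base, measure)$ci_halfwidth))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci_halfwidth,
                                        ymax = .data$mean + .data$ci_halfwidth),
                           width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("mean ", measure, " (days, 95% CI)"))
}

#' Write a scenario comparison as CSV and JSON
#'
#' @param cmp A [run_scenarios()] result.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The paths written, invisibly.
#' @export
write_scenario_comparison <- function(cmp, csv_path = NULL,
                                      json_path = NULL) {
  stopifnot(inherits(cmp, "scenario_comparison"))
  if (!is.null(csv_path)) readr::write_csv(as_tibble(cmp), csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(as_tibble(cmp), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(c(csv_path, json_path))
}
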