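#' Descriptive timing statistics over an activity-timestamp log
#'
#' Computes, per sub-process and for the entire process, the sample size,
#' mean, median, standard deviation and interquartile range (with Q1/Q3)
#' of durations in calendar days. Quartiles use linear interpolation
#' (quantile type 7). If a `status` column is present only complete
#' trials contribute. The entire-process duration per trial is the span
#' from its earliest start to its latest end. A single-observation group
#' reports `sd = 0` (flagged by `n = 1`).
#'
#' @param data Tibble with columns `trial_id`, `subprocess`, `start`,
#'   `end` (day offsets or anything subtractable) and optionally `status`.
#' @return A tibble: `subprocess`, `n`, `mean`, `median`, `sd`, `q1`,
#'   `q3`, `iqr`; the last row is `"Entire Process"`.
#' @export
duration_stats <- function(data) {
  data <- as_tibble(data)
  need <- c("trial_id", "subprocess", "start", "end")
  if (!all(need %in% names(data)))
    abort(paste0("`data` needs columns: ", paste(need, collapse = ", ")),
          class = "trialflow_error_bad_log")
  if ("status" %in% names(data))
    data <- dplyr::filter(data, .data$status == "complete")
  if (nrow(data) == 0)
    abort("No complete trials in the dataset.",
          class = "trialflow_error_empty_dataset")
  if (any(unclass(data$end) < unclass(data$start)))
    abort("Found end < start.", class = "trialflow_error_bad_log")

  summarise_durations <- function(d, label) {
    tibble(subprocess = label, n = length(d),
           mean = mean(d), median = median(d),
           sd = if (length(d) > 1) sd(d) else 0,
           q1 = unname(quantile(d, 0.25, type = 7)),
           q3 = unname(quantile(d, 0.75, type = 7))) |>
      dplyr::mutate(iqr = .data$q3 - .data$q1)
  }

  per_sp <- data |>
    dplyr::mutate(duration = as.numeric(.data$end) - as.numeric(.data$start),
                  subprocess = factor(.data$subprocess,
                                      levels = unique(.data$subprocess))) |>
    dplyr::group_by(.data$subprocess) |>
    dplyr::group_map(~ summarise_durations(.x$duration,
                                           as.character(.y$subprocess))) |>
    dplyr::bind_rows()

  entire <- data |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(duration = max(as.numeric(.data$end)) -
                       min(as.numeric(.data$start)), .groups = "drop")
  dplyr::bind_rows(per_sp, summarise_durations(entire$duration,
                                               "Entire Process"))
}

#' Render duration statistics in the report layout
#'
#' Formats a [duration_stats()] table into the two classic columns
#' "Average (Median, SD)" and "IQR (Q1, Q3)".
#'
#' @param stats Output of [duration_stats()].
#' @param digits Rounding for display.
#' @return A tibble of character columns.
#' @export
format_duration_stats <- function(stats, digits = 1) {
  r <- function(x) format(round(x, digits), trim = TRUE)
  tibble(
    subprocess = stats$subprocess,
    n = stats$n,
    `Average (Median, SD)` = paste0(r(stats$mean), " (", r(stats$median),
                                    ", ", r(stats$sd), ")"),
    `IQR (Q1, Q3)` = paste0(r(stats$iqr), " (", r(stats$q1), ", ",
                            r(stats$q3), ")"))
}

#' Keep analysable trials and tally exclusions
#'
#' Retains trials whose status is `"complete"` and reports how many were
#' excluded for each reason (missing data, still in process, terminated).
#'
#' @param data Tibble with `trial_id` and `status` columns.
#' @return A list: `data` (the complete-trial rows) and `tally` (a tibble
#'   of per-status trial counts, including `complete`).
#' @export
filter_included_trials <- function(data) {
  data <- as_tibble(data)
  if (!all(c("trial_id", "status") %in% names(data)))
    abort("`data` needs columns trial_id and status.",
          class = "trialflow_error_bad_log")
  statuses <- data |>
    dplyr::distinct(.data$trial_id, .data$status)
  lv <- c("complete", "missing_data", "in_process", "terminated")
  tally <- statuses |>
    dplyr::count(status = factor(.data$status, levels = lv),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(status = as.character(.data$status))
  list(data = dplyr::filter(data, .data$status == "complete"),
       tally = tally)
}

#' Pooled-variance two-sample t test
#'
#' The independent-samples t test assuming equal variances (pooled
#' variance, `n_x + n_y - 2` degrees of freedom), as used for comparing
#' sub-process durations between trial groups.
#'
#' @param x,y Numeric vectors of durations, each with >= 2 values.
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `mean_x`,
#'   `mean_y`.
#' @examples
#' t_test_equal_var(c(1, 2, 3), c(2, 3, 4))
#' @export
t_test_equal_var <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    abort("Each sample needs at least 2 observations.",
          class = "trialflow_error_too_few_samples")
  nx <- length(x); ny <- length(y)
  pooled <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (pooled == 0)
    abort("Zero pooled variance; the t statistic is undefined.",
          class = "trialflow_error_degenerate")
  ht <- t.test(x, y, var.equal = TRUE)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), mean_x = mean(x), mean_y = mean(y))
}
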