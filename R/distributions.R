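#' Duration distributions for processing times
#'
#' Processing times in the activation workflow are expressed in calendar
#' days and modelled with a small parametric family: constant, uniform,
#' triangular, exponential, and lognormal. The lognormal is parameterised
#' by the mean and standard deviation of the variate itself (the
#' convention used by mainstream simulation software), not by the
#' underlying normal; the conversion is
#' \eqn{\sigma^2 = \log(1 + (sd/mean)^2)}, \eqn{\mu = \log(mean) - \sigma^2/2}.
#'
#' @param value,min,max,mode,mean,sd Family parameters, in days.
#' @return An object of class `duration_dist`.
#' @examples
#' d <- dist_triangular(1, 8, 21)
#' dist_mean(d) # 10
#' dist_sample(dist_exponential(28.5), 3)
#' @name duration_dist
NULL

new_duration_dist <- function(family, params) {
  structure(list(family = family, params = params), class = "duration_dist")
}

#' @rdname duration_dist
#' @export
dist_constant <- function(value) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value < 0)
    abort("`value` must be a single nonnegative number.",
          class = "trialflow_error_bad_params")
  new_duration_dist("constant", c(value = value))
}

#' @rdname duration_dist
#' @export
dist_uniform <- function(min, max) {
  if (!is.numeric(min) || !is.numeric(max) || is.na(min) || is.na(max) ||
      min >= max)
    abort("uniform requires min < max.", class = "trialflow_error_bad_params")
  new_duration_dist("uniform", c(min = min, max = max))
}

#' @rdname duration_dist
#' @export
dist_triangular <- function(min, mode, max) {
  ok <- is.numeric(c(min, mode, max)) && !anyNA(c(min, mode, max)) &&
    min <= mode && mode <= max && min < max
  if (!ok)
    abort("triangular requires min <= mode <= max (and min < max).",
          class = "trialflow_error_bad_params")
  new_duration_dist("triangular", c(min = min, mode = mode, max = max))
}

#' @rdname duration_dist
#' @export
dist_exponential <- function(mean) {
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) || mean <= 0)
    abort("exponential requires mean > 0.", class = "trialflow_error_bad_params")
  new_duration_dist("exponential", c(mean = mean))
}

#' @rdname duration_dist
#' @export
dist_lognormal <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || is.na(mean) || is.na(sd) ||
      mean <= 0 || sd <= 0)
    abort("lognormal requires mean > 0 and sd > 0.",
          class = "trialflow_error_bad_params")
  new_duration_dist("lognormal", c(mean = mean, sd = sd))
}

#' Coerce a plain list to a duration distribution
#'
#' Used when reading model configurations: a distribution is written as a
#' list with a `family` string and an ordered `params` vector.
#'
#' @param x A `duration_dist`, or a list with elements `family` and `params`.
#' @return A `duration_dist`.
#' @export
as_duration_dist <- function(x) {
  if (inherits(x, "duration_dist")) return(x)
  if (!is.list(x) || is.null(x$family))
    abort("Cannot interpret `x` as a duration distribution.",
          class = "trialflow_error_unknown_family")
  fam <- as.character(x$family)
  p <- as.numeric(unlist(x$params))
  switch(fam,
    constant    = dist_constant(p[1]),
    uniform     = dist_uniform(p[1], p[2]),
    triangular  = dist_triangular(p[1], p[2], p[3]),
    exponential = dist_exponential(p[1]),
    lognormal   = dist_lognormal(p[1], p[2]),
    abort(paste0("Unknown distribution family: '", fam, "'."),
          class = "trialflow_error_unknown_family")
  )
}

lnorm_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample from a duration distribution
#'
#' @param dist A `duration_dist`.
#' @param n Number of draws.
#' @return Numeric vector of `n` nonnegative durations (days).
#' @export
dist_sample <- function(dist, n = 1) {
  stopifnot(inherits(dist, "duration_dist"))
  p <- dist$params
  switch(dist$family,
    constant = rep(p[["value"]], n),
    uniform = runif(n, p[["min"]], p[["max"]]),
    triangular = {
      # inverse-CDF sampling
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      u <- runif(n)
      fc <- (m - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (m - a)),
             b - sqrt((1 - u) * (b - a) * (b - m)))
    },
    exponential = rexp(n, rate = 1 / p[["mean"]]),
    lognormal = {
      lp <- lnorm_pars(p[["mean"]], p[["sd"]])
      rlnorm(n, lp$meanlog, lp$sdlog)
    }
  )
}

#' Theoretical moments of a duration distribution
#'
#' Closed-form mean and standard deviation, in days.
#'
#' @param dist A `duration_dist`.
#' @return A single number.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "duration_dist"))
  p <- dist$params
  switch(dist$family,
    constant = p[["value"]],
    uniform = (p[["min"]] + p[["max"]]) / 2,
    triangular = (p[["min"]] + p[["mode"]] + p[["max"]]) / 3,
    exponential = p[["mean"]],
    lognormal = p[["mean"]]
  )
}

#' @rdname dist_mean
#' @export
dist_sd <- function(dist) {
  stopifnot(inherits(dist, "duration_dist"))
  p <- dist$params
  switch(dist$family,
    constant = 0,
    uniform = (p[["max"]] - p[["min"]]) / sqrt(12),
    triangular = {
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      sqrt((a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18)
    },
    exponential = p[["mean"]],
    lognormal = p[["sd"]]
  )
}

#' Density of a duration distribution
#'
#' @param dist A `duration_dist`.
#' @param x Numeric vector of evaluation points (days).
#' @return Density values. The constant family has no density and errors.
#' @export
dist_density <- function(dist, x) {
  stopifnot(inherits(dist, "duration_dist"))
  p <- dist$params
  switch(dist$family,
    constant = abort("The constant family has no density.",
                     class = "trialflow_error_degenerate"),
    uniform = dunif(x, p[["min"]], p[["max"]]),
    triangular = {
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      d <- numeric(length(x))
      up <- x >= a & x <= m
      dn <- x > m & x <= b
      if (m > a) d[up] <- 2 * (x[up] - a) / ((b - a) * (m - a))
      else d[x == a] <- 2 / (b - a)
      d[dn] <- 2 * (b - x[dn]) / ((b - a) * (b - m))
      d
    },
    exponential = dexp(x, rate = 1 / p[["mean"]]),
    lognormal = {
      lp <- lnorm_pars(p[["mean"]], p[["sd"]])
      dlnorm(x, lp$meanlog, lp$sdlog)
    }
  )
}

#' Cumulative distribution function of a duration distribution
#'
#' @param dist A `duration_dist`.
#' @param x Numeric vector of evaluation points (days).
#' @return CDF values in `[0, 1]`.
#' @export
dist_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "duration_dist"))
  p <- dist$params
  switch(dist$family,
    constant = as.numeric(x >= p[["value"]]),
    uniform = stats::punif(x, p[["min"]], p[["max"]]),
    triangular = {
      a <- p[["min"]]; m <- p[["mode"]]; b <- p[["max"]]
      out <- numeric(length(x))
      out[x >= b] <- 1
      up <- x > a & x <= m
      dn <- x > m & x < b
      if (m > a) out[up] <- (x[up] - a)^2 / ((b - a) * (m - a))
      out[dn] <- 1 - (b - x[dn])^2 / ((b - a) * (b - m))
      out
    },
    exponential = stats::pexp(x, rate = 1 / p[["mean"]]),
    lognormal = {
      lp <- lnorm_pars(p[["mean"]], p[["sd"]])
      stats::plnorm(x, lp$meanlog, lp$sdlog)
    }
  )
}

#' @export
format.duration_dist <- function(x, ...) {
  paste0(x$family, "(", paste(signif(x$params, 6), collapse = ", "), ")")
}

#' @export
print.duration_dist <- function(x, ...) {
  cat("<duration_dist> ", format(x), "  mean = ", signif(dist_mean(x), 6),
      " d\n", sep = "")
  invisible(x)
}

dist_to_list <- function(dist) {
  list(family = dist$family, params = as.numeric(dist$params))
}
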