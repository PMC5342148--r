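as_event <- function(events) {
  if (is.logical(events)) return(events)
  if (is.numeric(events)) {
    if (!all(events %in% c(0, 1))) {
      abort("Numeric event indicators must be 0/1.")
    }
    return(events == 1)
  }
  check_enum(events, c("event", "death", "censored"), "event indicator")
  events %in% c("event", "death")
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival is estimated as the product over event times of
#' `1 - d_i / n_i`, with `d_i` events among `n_i` at risk. At tied times,
#' events precede censorings (the censored subjects are still at risk for
#' the event at that time). Times at which only censoring occurs reduce the
#' risk set without a step in the curve. Follow-up of exactly zero is
#' rejected.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators: logical, 0/1, or
#'   `"event"`/`"death"`/`"censored"`.
#' @return An object of class `ragc_km`; [tidy()] gives the per-time table
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `survival`), [glance()] the
#'   sample size, event count and median survival.
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
#' tidy(km)$survival  # 0.75 0.50 0.25 0.00
#' @export
km_estimate <- function(times, events) {
  events <- as_event(events)
  if (length(times) == 0) abort("Empty survival input.")
  if (length(times) != length(events)) {
    abort("`times` and `events` must have equal length.")
  }
  if (anyNA(times) || anyNA(events)) abort("Missing survival data.")
  if (any(times <= 0)) {
    abort("Follow-up times must be positive; subjects lost at time 0 are not supported.",
          class = "ragc_validation_error")
  }
  n <- length(times)
  tab <- tibble(time = times, event = events) |>
    group_by(.data$time) |>
    summarise(n_event = sum(.data$event), n_censor = sum(!.data$event),
              .groups = "drop") |>
    arrange(.data$time)
  tab$n_risk <- n - cumsum(dplyr::lag(tab$n_event + tab$n_censor, default = 0L))
  tab$survival <- cumprod(1 - tab$n_event / tab$n_risk)
  structure(
    list(data = tab[c("time", "n_risk", "n_event", "n_censor", "survival")],
         n = n, n_events = sum(events)),
    class = "ragc_km"
  )
}

#' @export
print.ragc_km <- function(x, ...) {
  cat(sprintf("<ragc_km> n = %d, events = %d\n", x$n, x$n_events))
  print(x$data, n = 6)
  invisible(x)
}

#' @export
tidy.ragc_km <- function(x, ...) x$data

#' @importFrom generics glance
#' @export
glance.ragc_km <- function(x, ...) {
  below <- x$data$time[x$data$survival <= 0.5 + 1e-12]
  tibble(n = x$n, n_events = x$n_events,
         median_survival = if (length(below)) min(below) else NA_real_)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.ragc_km <- function(object, ...) {
  d <- object$data
  d0 <- dplyr::bind_rows(tibble(time = 0, survival = 1), d)
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*%
    diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' K-group log-rank test
#'
#' The standard log-rank statistic: at each distinct event time the
#' observed events per group are compared with the expectation under equal
#' hazards given the risk sets, and the quadratic form of the summed
#' observed-minus-expected vector in its hypergeometric covariance is
#' referred to a chi-square with `k - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param groups Group labels, one per subject (>= 2 non-empty groups).
#' @return An object of class `ragc_logrank`; [glance()] gives
#'   `statistic`, `df`, `p_value`; [tidy()] the per-group observed and
#'   expected event counts.
#' @export
log_rank <- function(times, events, groups) {
  events <- as_event(events)
  groups <- as.character(groups)
  if (!(length(times) == length(events) && length(times) == length(groups))) {
    abort("`times`, `events` and `groups` must have equal length.")
  }
  if (anyNA(times) || anyNA(events) || anyNA(groups)) {
    abort("Missing survival data.")
  }
  if (any(times <= 0)) {
    abort("Follow-up times must be positive.",
          class = "ragc_validation_error")
  }
  labs <- unique(groups)
  k <- length(labs)
  if (k < 2) abort("Need at least 2 groups with subjects.")

  event_times <- sort(unique(times[events]))
  O <- setNames(numeric(k), labs)
  E <- setNames(numeric(k), labs)
  V <- matrix(0, k, k, dimnames = list(labs, labs))
  for (t in event_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    d_j <- sum(events & times == t)
    n_ij <- vapply(labs, function(g) sum(at_risk & groups == g), numeric(1))
    d_ij <- vapply(labs, function(g) sum(events & times == t & groups == g),
                   numeric(1))
    O <- O + d_ij
    E <- E + d_j * n_ij / n_j
    if (n_j > 1) {
      p <- n_ij / n_j
      V <- V + d_j * (n_j - d_j) / (n_j - 1) * (diag(p, k) - outer(p, p))
    }
  }
  z <- (O - E)[-k]
  statistic <- drop(t(z) %*% pseudo_inverse(V[-k, -k, drop = FALSE]) %*% z)
  df <- k - 1L
  structure(
    list(statistic = statistic, df = df,
         p_value = pchisq(statistic, df, lower.tail = FALSE),
         summary = tibble(
           group = labs,
           n = vapply(labs, function(g) sum(groups == g), numeric(1)),
           observed = unname(O), expected = unname(E)
         )),
    class = "ragc_logrank"
  )
}

#' @export
print.ragc_logrank <- function(x, ...) {
  cat(sprintf("<ragc_logrank> chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ragc_logrank <- function(x, ...) x$summary

#' @export
glance.ragc_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Log-rank test restricted to two named groups
#'
#' @inheritParams log_rank
#' @param pair Character vector of length 2 naming the groups to compare.
#' @return An `ragc_logrank` object.
#' @export
pairwise_log_rank <- function(times, events, groups, pair) {
  groups <- as.character(groups)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must name two distinct groups.")
  }
  missing_grp <- setdiff(pair, unique(groups))
  if (length(missing_grp) > 0) {
    abort(sprintf("Group label(s) not present: %s",
                  paste(missing_grp, collapse = ", ")))
  }
  keep <- groups %in% pair
  log_rank(times[keep], events[keep], groups[keep])
}

#' Kaplan-Meier comparison across groups
#'
#' Convenience wrapper producing per-group product-limit curves together
#' with the k-group log-rank test, directly from a per-case tibble.
#'
#' @param data Per-case tibble.
#' @param time_col,event_col,group_col Column names (strings).
#' @return Object of class `ragc_survcmp` with `curves` (one row per group
#'   per distinct time) and `logrank`. Cases with missing follow-up are
#'   dropped with a message via the returned `n_excluded`.
#' @export
compare_survival <- function(data, time_col, event_col, group_col) {
  for (v in c(time_col, event_col, group_col)) {
    if (!v %in% names(data)) {
      abort(sprintf("Variable `%s` not found.", v))
    }
  }
  keep <- !is.na(data[[time_col]]) & !is.na(data[[event_col]]) &
    !is.na(data[[group_col]])
  d <- data[keep, ]
  groups <- as.character(d[[group_col]])
  curves <- purrr::map_dfr(unique(groups), function(g) {
    km <- km_estimate(d[[time_col]][groups == g], d[[event_col]][groups == g])
    mutate(km$data, group = g, .before = 1)
  })
  structure(
    list(curves = curves,
         logrank = log_rank(d[[time_col]], as_event(d[[event_col]]), groups),
         n_excluded = sum(!keep)),
    class = "ragc_survcmp"
  )
}

#' @export
print.ragc_survcmp <- function(x, ...) {
  cat(sprintf("<ragc_survcmp> %d groups, %d excluded\n",
              length(unique(x$curves$group)), x$n_excluded))
  print(x$logrank)
  invisible(x)
}

#' @export
tidy.ragc_survcmp <- function(x, ...) x$curves

#' @export
glance.ragc_survcmp <- function(x, ...) glance(x$logrank)

#' @export
autoplot.ragc_survcmp <- function(object, ...) {
  d0 <- object$curves |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, survival = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (months)", y = "Survival probability", colour = NULL,
      subtitle = sprintf("log-rank p = %.3f", object$logrank$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Cox proportional-hazards adapter
#'
#' Thin wrapper over [survival::coxph()] for multivariate follow-up
#' modeling of an annotated cohort. The fit is delegated entirely to the
#' survival package and is not part of the screening pipeline's validated
#' surface.
#'
#' @param data Per-case tibble.
#' @param time_col,event_col Column names of follow-up time and event.
#' @param covariates Character vector of covariate column names.
#' @return A `coxph` fit.
#' @export
fit_cox <- function(data, time_col, event_col, covariates) {
  d <- data[!is.na(data[[time_col]]) & !is.na(data[[event_col]]), ]
  d$.time <- d[[time_col]]
  d$.event <- as_event(d[[event_col]])
  f <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(covariates, collapse = " + ")
  ))
  survival::coxph(f, data = d)
}
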