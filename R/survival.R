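#' Kaplan-Meier event-free-survival estimate
#'
#' Product-limit estimator computed from first principles.  At each distinct
#' event time t with n at risk and d events, the survival estimate is
#' multiplied by (1 - d/n).  Censored animals leave the risk set without an
#' event; censorings tied with events are taken to occur just after the
#' events (standard convention).  The median EFS is the smallest time at
#' which S(t) <= 0.5 (left endpoint of a flat step at exactly 0.5), or
#' not reached when S never drops that far.
#'
#' @param times Event or censoring times (days), positive.
#' @param status `"event"`/`"censored"` character vector, or logical/0-1
#'   (TRUE/1 = event).  May also be omitted if `times` is a data.frame in the
#'   event-table layout (columns `time_days`, `status`).
#' @return An object of class `"surv_curve"`: list with `time` (distinct
#'   event times), `n_risk`, `n_event`, `survival`, `median_efs` (NA when not
#'   reached), `median_reached`, `n`.
#' @examples
#' km <- km_fit(c(10, 20, 30), c(1, 1, 1))
#' km$survival          # 2/3, 1/3, 0
#' km$median_efs        # 20
#' @export
km_fit <- function(times, status = NULL) {
  if (is.data.frame(times)) {
    status <- times$status
    times <- times$time_days
  }
  if (!length(times)) stop("no event records", call. = FALSE)
  ev <- parse_status(status, length(times))
  ord <- order(times)
  times <- times[ord]; ev <- ev[ord]

  utimes <- sort(unique(times[ev]))
  n <- length(times)
  s <- 1
  surv <- numeric(length(utimes))
  n_risk <- integer(length(utimes))
  n_event <- integer(length(utimes))
  for (j in seq_along(utimes)) {
    t <- utimes[j]
    n_risk[j] <- sum(times >= t)
    n_event[j] <- sum(times == t & ev)
    s <- s * (1 - n_event[j] / n_risk[j])
    surv[j] <- s
  }
  below <- which(surv <= 0.5)
  median_reached <- length(below) > 0
  structure(
    list(time = utimes, n_risk = n_risk, n_event = n_event, survival = surv,
         median_efs = if (median_reached) utimes[below[1]] else NA_real_,
         median_reached = median_reached, n = n),
    class = "surv_curve")
}

parse_status <- function(status, n) {
  if (is.null(status)) stop("`status` is required", call. = FALSE)
  if (is.character(status)) {
    if (!all(status %in% c("event", "censored")))
      stop("status must be 'event' or 'censored'", call. = FALSE)
    status == "event"
  } else {
    as.logical(status)
  }
}

#' @export
print.surv_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier EFS curve: n = %d, %d events\n",
              x$n, sum(x$n_event)))
  cat(sprintf("  median EFS: %s days\n",
              if (x$median_reached) format(x$median_efs) else "not reached"))
  invisible(x)
}

#' @export
#' @param x A `"surv_curve"`.
#' @param xlab,ylab,... Passed to [graphics::plot()].
#' @rdname km_fit
plot.surv_curve <- function(x, xlab = "Days", ylab = "Event-free survival",
                            ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * length(x$survival))])
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Median time to event from a fitted curve
#'
#' @param curve A `"surv_curve"` from [km_fit()].
#' @return The median EFS in days, or `NA` with a message attribute when the
#'   curve never reaches 0.5 (reported as "not reached").
#' @export
median_time_to_event <- function(curve) {
  stopifnot(inherits(curve, "surv_curve"))
  curve$median_efs
}

#' Two-group log-rank test
#'
#' The standard observed-minus-expected chi-square statistic on one degree of
#' freedom, computed from first principles.  At each distinct event time the
#' expected number of events in group A is d * nA/n and the variance is the
#' hypergeometric d (n-d) nA nB / (n^2 (n-1)); ties are handled by the
#' simultaneous-event convention.  The p-value is the chi-square(1) upper
#' tail (equivalently a two-sided normal test on the score).  p-values are
#' never reported as exactly zero: values below 1e-16 are floored there and
#' flagged.
#'
#' @param times_a,status_a,times_b,status_b Times and statuses per group, in
#'   any form [km_fit()] accepts.
#' @return List of class `"logrank_result"`: `statistic`, `p_value`,
#'   `p_floored` (TRUE when the computed tail fell below 1e-16 and the value
#'   should be read as "p < 1e-16"), `n_a`, `n_b`.
#' @export
logrank <- function(times_a, status_a = NULL, times_b, status_b = NULL) {
  if (is.data.frame(times_a)) { status_a <- times_a$status; times_a <- times_a$time_days }
  if (is.data.frame(times_b)) { status_b <- times_b$status; times_b <- times_b$time_days }
  if (!length(times_a) || !length(times_b))
    stop("both groups need at least one record", call. = FALSE)
  ev_a <- parse_status(status_a, length(times_a))
  ev_b <- parse_status(status_b, length(times_b))

  times <- c(times_a, times_b)
  ev <- c(ev_a, ev_b)
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  utimes <- sort(unique(times[ev]))
  o_minus_e <- 0
  v <- 0
  for (t in utimes) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d <- sum(times == t & ev)
    d_a <- sum(times == t & ev & grp == 0L)
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1)
      v <- v + d * (n - d) * n_a * (n - n_a) / (n^2 * (n - 1))
  }
  if (v <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- o_minus_e^2 / v
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  p_floored <- p < 1e-16
  if (p_floored) p <- 1e-16
  structure(list(statistic = stat, p_value = p, p_floored = p_floored,
                 n_a = length(times_a), n_b = length(times_b)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square(1) = %.4g, p %s %.3g (n = %d vs %d)\n",
              x$statistic, if (x$p_floored) "<" else "=", x$p_value,
              x$n_a, x$n_b))
  invisible(x)
}
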