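## Survival comparison between ctDNA-positive and ctDNA-negative patients:
## Kaplan-Meier product-limit curves, the two-sided logrank test, the
## Mantel-Haenszel hazard ratio derived from the logrank quantities, and
## restricted mean survival (area under the KM step function).
##
## These estimators are implemented here directly; the survival package
## serves as an independent cross-check in the test suite.

#' Kaplan-Meier product-limit estimator
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times \eqn{t_i}, with \eqn{d_i} events among \eqn{n_i} at risk. Subjects
#' censored at an event time are still at risk for it (events precede
#' censorings at ties).
#'
#' @param time Follow-up times (> 0, same unit throughout; years here).
#' @param event Event indicator (1/TRUE = event observed, 0/FALSE = censored).
#' @return A `km_curve`: data.frame-like list with `time`, `n_risk`,
#'   `n_event`, `surv`, plus the sample size and maximum follow-up time.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 0))
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0L) stop("cannot estimate a survival curve from an empty group")
  if (length(event) != length(time)) stop("'time' and 'event' lengths differ")
  event <- as.integer(as.logical(event))
  et <- sort(unique(time[event == 1L]))
  st <- sort(time)
  ## at risk at t = subjects with time >= t (censored at t still at risk)
  n_risk <- length(time) - findInterval(et, st, left.open = TRUE)
  n_event <- tabulate(match(time[event == 1L], et), length(et))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
         n = length(time), n_events = sum(event), max_time = max(time)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n", x$n, x$n_events))
  if (length(x$time))
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     survival = round(x$surv, 4)), row.names = FALSE)
  else cat("  no events; S(t) = 1 throughout follow-up\n")
  invisible(x)
}

#' @export
summary.km_curve <- function(object, times = object$time, ...) {
  s <- vapply(times, function(t) {
    i <- which(object$time <= t)
    if (length(i)) object$surv[max(i)] else 1
  }, 0)
  data.frame(time = times, survival = s)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (years)", ylab = "Survival probability",
                          col = 1, add = FALSE, ...) {
  tt <- c(0, rep(x$time, each = 2), x$max_time)
  ss <- c(1, 1, rep(x$surv, each = 2))
  if (!add)
    plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab,
         col = col, ...)
  else lines(tt, ss, col = col, ...)
  invisible(x)
}

## shared logrank machinery: observed and hypergeometric expected events and
## variance for group 1, accumulated over distinct event times
.logrank_quantities <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  event <- as.integer(as.logical(event))
  if (sum(event) < 1L) stop("no events observed; the logrank test is undefined")
  et <- sort(unique(time[event == 1L]))
  l1 <- levels(g)[1L]
  st <- sort(time)
  s1 <- sort(time[g == l1])
  n_risk <- length(time) - findInterval(et, st, left.open = TRUE)
  n1_risk <- length(s1) - findInterval(et, s1, left.open = TRUE)
  d <- tabulate(match(time[event == 1L], et), length(et))
  d1 <- tabulate(match(time[event == 1L & g == l1], et), length(et))
  E1 <- d * n1_risk / n_risk
  v <- ifelse(n_risk > 1L,
              d * (n1_risk / n_risk) * (1 - n1_risk / n_risk) *
                (n_risk - d) / (n_risk - 1L),
              0)
  O <- sum(d)
  list(levels = levels(g), O = c(sum(d1), O - sum(d1)),
       E = c(sum(E1), O - sum(E1)), V = sum(v))
}

#' Two-sided logrank test
#'
#' At each distinct event time the expected number of group-1 events and its
#' variance follow the hypergeometric distribution of events among those at
#' risk; the statistic \eqn{(O_1 - E_1)^2 / V} is referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event).
#' @param group Two-level group labels.
#' @return A `logrank_test` with `statistic`, `p_value`, per-group `observed`
#'   and `expected`, and the variance `V`.
#' @export
logrank_test <- function(time, event, group) {
  q <- .logrank_quantities(time, event, group)
  if (q$V <= 0) stop("zero logrank variance; the test is undefined")
  stat <- (q$O[1L] - q$E[1L])^2 / q$V
  structure(
    list(statistic = stat, p_value = pchisq(stat, 1L, lower.tail = FALSE),
         observed = setNames(q$O, q$levels), expected = setNames(q$E, q$levels),
         variance = q$V, groups = q$levels),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-sided logrank test\n")
  print(data.frame(group = x$groups, observed = x$observed,
                   expected = round(x$expected, 2)), row.names = FALSE)
  cat(sprintf("chi-square = %.4f (1 df), p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Mantel-Haenszel hazard ratio from logrank quantities
#'
#' \eqn{\log HR = (O_1 - E_1) / V} with confidence interval
#' \eqn{\exp(\log HR \pm z / \sqrt{V})}; the first factor level of `group`
#' is the numerator.
#'
#' @inheritParams logrank_test
#' @param conf_level Confidence level (default 0.95).
#' @return A `hazard_ratio` with `hr`, `ci_lower`, `ci_upper`, `log_hr`, `se`.
#' @export
hazard_ratio <- function(time, event, group, conf_level = 0.95) {
  q <- .logrank_quantities(time, event, group)
  if (q$V <= 0) stop("zero logrank variance; the hazard ratio is undefined")
  log_hr <- (q$O[1L] - q$E[1L]) / q$V
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(q$V)
  structure(
    list(hr = exp(log_hr), ci_lower = exp(log_hr - z * se),
         ci_upper = exp(log_hr + z * se), log_hr = log_hr, se = se,
         conf_level = conf_level, groups = q$levels),
    class = "hazard_ratio"
  )
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel hazard ratio (%s vs %s): %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$groups[1L], x$groups[2L], x$hr, 100 * x$conf_level,
              x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Restricted mean survival time
#'
#' Exact area under the Kaplan-Meier step function on `[0, horizon]`; the
#' estimator behind reported "mean" survival times when follow-up is
#' censored.
#'
#' @param curve A [km_fit()] result.
#' @param horizon Upper limit in the curve's time unit; must not exceed the
#'   maximum observed follow-up.
#' @return Restricted mean survival in the same unit.
#' @export
restricted_mean_survival <- function(curve, horizon) {
  stopifnot(inherits(curve, "km_curve"))
  if (horizon > curve$max_time)
    stop("'horizon' exceeds the maximum observed follow-up time (",
         curve$max_time, ")")
  et <- curve$time[curve$time <= horizon]
  s_left <- c(1, curve$surv[curve$time <= horizon])
  knots <- c(0, et, horizon)
  sum(diff(knots) * s_left)
}

#' Compare survival between ctDNA groups
#'
#' Convenience wrapper producing both group curves, the logrank test, the
#' Mantel-Haenszel hazard ratio and restricted mean survival per group, from
#' an outcomes table.
#'
#' @param outcomes data.frame with `time_years`, `event` and `group` (two
#'   levels; by convention ctDNA_positive vs ctDNA_negative).
#' @param horizon Optional restricted-mean horizon; defaults to the maximum
#'   observed follow-up.
#' @return A `ctdna_survival` list: `curves` (named by group), `logrank`,
#'   `hazard_ratio`, `rmst` (named numeric), `horizon`.
#' @export
compare_survival <- function(outcomes, horizon = NULL) {
  need <- c("time_years", "event", "group")
  if (!all(need %in% names(outcomes)))
    stop("'outcomes' needs columns: ", paste(need, collapse = ", "))
  g <- factor(outcomes$group)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (is.null(horizon)) horizon <- max(outcomes$time_years)
  curves <- lapply(levels(g), function(l) {
    i <- g == l
    km_fit(outcomes$time_years[i], outcomes$event[i])
  })
  names(curves) <- levels(g)
  rmst <- vapply(curves, function(cv)
    restricted_mean_survival(cv, min(horizon, cv$max_time)), 0)
  structure(
    list(curves = curves,
         logrank = logrank_test(outcomes$time_years, outcomes$event, g),
         hazard_ratio = hazard_ratio(outcomes$time_years, outcomes$event, g),
         rmst = rmst, horizon = horizon),
    class = "ctdna_survival"
  )
}

#' @export
print.ctdna_survival <- function(x, ...) {
  for (nm in names(x$curves))
    cat(sprintf("%s: n = %d, events = %d, restricted mean = %.2f y\n",
                nm, x$curves[[nm]]$n, x$curves[[nm]]$n_events, x$rmst[[nm]]))
  print(x$logrank)
  print(x$hazard_ratio)
  invisible(x)
}

#' @export
plot.ctdna_survival <- function(x, col = c(2, 4), ...) {
  plot(x$curves[[1L]], col = col[1L], ...)
  plot(x$curves[[2L]], col = col[2L], add = TRUE)
  legend("bottomleft", legend = names(x$curves), col = col, lty = 1, bty = "n")
  invisible(x)
}
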