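## Event definition, log-linear event-time interpolation, Kaplan-Meier
## medians with censored-median bounds, and the Peto-Peto modified
## Gehan-Wilcoxon two-sample test.

#' Time to tumor-volume quadrupling
#'
#' The event is quadrupling of the tumor volume from baseline (day 0). The
#' exact event time is interpolated between the measurement directly
#' preceding and the one directly following the crossing, assuming log-linear
#' (exponential) growth:
#' `t = t1 + (t2 - t1) * (log(4 V0) - log(V1)) / (log(V2) - log(V1))`.
#' If the first crossing measurement equals the threshold exactly, its day is
#' the event time. Mice that never cross are censored at their last
#' observation day. If the preceding volume is 0 the log is undefined and the
#' function falls back to linear interpolation with a warning.
#'
#' @param record A [mouse_record()].
#' @param multiple Event threshold as a multiple of V0 (default 4).
#' @return List of class `event_result`: `event` (logical), `time` (days) and
#'   `threshold_volume` (mm^3).
#' @export
time_to_event <- function(record, multiple = 4) {
  vol <- record$volumes
  v0 <- vol$volume[vol$day == 0]
  if (length(v0) != 1 || v0 <= 0) {
    xt_stop("baseline volume V0 must be a single positive value", "xt_domain_error")
  }
  if (nrow(vol) < 2) {
    xt_stop("need at least one post-baseline measurement", "xt_insufficient_data")
  }
  thr <- multiple * v0
  cross <- which(vol$volume >= thr & vol$day > 0)
  if (!length(cross)) {
    return(structure(list(event = FALSE, time = max(vol$day),
                          threshold_volume = thr), class = "event_result"))
  }
  i2 <- cross[1]
  t2 <- vol$day[i2]; v2 <- vol$volume[i2]
  if (v2 == thr) {
    t <- t2
  } else {
    # last measurement below threshold before the crossing (baseline qualifies)
    i1 <- max(which(vol$day < t2 & vol$volume < thr))
    t1 <- vol$day[i1]; v1 <- vol$volume[i1]
    if (v1 <= 0) {
      xt_warn("zero volume before crossing: using linear interpolation",
              "xt_linear_fallback")
      t <- t1 + (t2 - t1) * (thr - v1) / (v2 - v1)
    } else {
      t <- t1 + (t2 - t1) * (log(thr) - log(v1)) / (log(v2) - log(v1))
    }
  }
  structure(list(event = TRUE, time = t, threshold_volume = thr),
            class = "event_result")
}

#' Kaplan-Meier median with censored-median bound
#'
#' Product-limit median: the smallest event time at which the pooled survival
#' estimate drops to <= 0.5. When the curve never reaches 0.5 the median is
#' "not reached" and the largest follow-up time is reported as a lower bound
#' (rendered `">bound"`).
#'
#' @param times Follow-up times, days.
#' @param events Logical (or 0/1) event indicators.
#' @return Object of class `km_median` with fields `reached` and `value` (if
#'   reached) or `bound`.
#' @export
km_median <- function(times, events) {
  if (!length(times) || length(times) != length(events)) {
    xt_stop("times and events must be non-empty and equal length", "xt_domain_error")
  }
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  at <- which(fit$n.event > 0 & fit$surv <= 0.5 + 1e-12)
  if (length(at)) {
    km_median_reached(fit$time[at[1]])
  } else {
    km_median_bound(max(times))
  }
}

#' @rdname km_median
#' @param value Median event-free survival, days.
#' @export
km_median_reached <- function(value) {
  structure(list(reached = TRUE, value = value, bound = NULL), class = "km_median")
}

#' @rdname km_median
#' @param bound Last follow-up time, days (median not reached).
#' @export
km_median_bound <- function(bound) {
  structure(list(reached = FALSE, value = NULL, bound = bound), class = "km_median")
}

#' @export
format.km_median <- function(x, digits = 2, ...) {
  if (x$reached) as.character(round(x$value, digits))
  else paste0(">", round(x$bound, digits))
}

#' @export
print.km_median <- function(x, ...) {
  cat("KM median:", format(x), "days\n")
  invisible(x)
}

km_effective <- function(x) if (x$reached) x$value else x$bound

#' EFS contrast between two arms given their KM medians
#'
#' Computes the absolute difference (`EFS T - C`) and ratio (`EFS T/C`) of
#' median event-free survival. When the treated median is not reached, its
#' last-follow-up bound substitutes in both quantities, so the reported
#' contrast is a conservative lower bound and is flagged as such.
#'
#' @param control,treated [km_median()] objects.
#' @return List with `efs_t_minus_c`, `efs_t_over_c`, and `treated_bound`
#'   (logical: contrast computed from a censored-median bound).
#' @export
efs_contrast <- function(control, treated) {
  stopifnot(inherits(control, "km_median"), inherits(treated, "km_median"))
  if (!control$reached) {
    xt_stop("control median not reached: EFS T-C undefined", "xt_evaluability_error")
  }
  tt <- km_effective(treated)
  list(efs_t_minus_c = tt - control$value,
       efs_t_over_c = tt / control$value,
       treated_bound = !treated$reached)
}

#' Per-model EFS summary for a control vs treated comparison
#'
#' @param control,treated Lists with elements `times` and `events`.
#' @param method p-value method passed to [peto_peto_test()].
#' @return Object of class `efs_summary`: both [km_median()]s, the
#'   [efs_contrast()] quantities, and the Peto-Peto Gehan-Wilcoxon p-value.
#' @export
efs_summary <- function(control, treated, method = "asymptotic") {
  if (!length(control$times) || !length(treated$times)) {
    xt_stop("both arms must be non-empty", "xt_domain_error")
  }
  cm <- km_median(control$times, control$events)
  tm <- km_median(treated$times, treated$events)
  ct <- efs_contrast(cm, tm)
  test <- peto_peto_test(control, treated, method = method)
  structure(list(control_median = cm, treated_median = tm,
                 efs_t_minus_c = ct$efs_t_minus_c,
                 efs_t_over_c = ct$efs_t_over_c,
                 treated_bound = ct$treated_bound,
                 p_value = test$p_value, test = test),
            class = "efs_summary")
}

#' @export
print.efs_summary <- function(x, ...) {
  cat(sprintf("EFS medians: control %s, treated %s days\n",
              format(x$control_median), format(x$treated_median)))
  cat(sprintf("EFS T-C = %.2f%s, T/C = %.2f%s, Gehan-Wilcoxon p = %.4g\n",
              x$efs_t_minus_c, if (x$treated_bound) " (bound)" else "",
              x$efs_t_over_c, if (x$treated_bound) " (bound)" else "",
              x$p_value))
  invisible(x)
}

## Peto-Peto modified Gehan-Wilcoxon test -----------------------------------

# Weighted log-rank ingredients on the pooled sample. Weights are the
# left-continuous pooled Kaplan-Meier estimate at each distinct event time;
# ties are grouped with the hypergeometric variance.
peto_stat <- function(time, event, in_a) {
  ev_times <- sort(unique(time[event]))
  if (!length(ev_times)) return(list(u = 0, v = 0, z = 0, n_event_times = 0))
  u <- 0; vv <- 0
  surv <- 1
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event & time == t)
    n1_j <- sum(at_risk & in_a)
    d1_j <- sum(event & time == t & in_a)
    w <- surv # left-continuous KM: product over strictly earlier event times
    e1 <- d_j * n1_j / n_j
    var_j <- if (n_j > 1) {
      d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    } else 0
    u <- u + w * (d1_j - e1)
    vv <- vv + w^2 * var_j
    surv <- surv * (1 - d_j / n_j)
  }
  z <- if (vv > 0) u / sqrt(vv) else 0
  list(u = u, v = vv, z = z, n_event_times = length(ev_times))
}

#' Peto-Peto modified Gehan-Wilcoxon test
#'
#' Two-sample weighted log-rank test in which each distinct event time is
#' weighted by the left-continuous pooled-sample Kaplan-Meier survival
#' estimate, emphasizing early events. `method = "asymptotic"` reports
#' `z = (O - E)/sqrt(V)` with the hypergeometric variance and a two-sided
#' normal p-value; `method = "exact_permutation"` enumerates all assignments
#' of the pooled subjects to two groups of the observed sizes and reports the
#' fraction with `|z| >=` the observed `|z|`.
#'
#' @param group_a,group_b Lists with elements `times` and `events`.
#' @param method `"asymptotic"` or `"exact_permutation"`.
#' @return Object of class `xeno_test`: `statistic` (z), `p_value`, `method`.
#' @export
peto_peto_test <- function(group_a, group_b,
                           method = c("asymptotic", "exact_permutation")) {
  method <- match.arg(method)
  na <- length(group_a$times); nb <- length(group_b$times)
  if (!na || !nb) xt_stop("both groups must be non-empty", "xt_domain_error")
  time <- c(group_a$times, group_b$times)
  event <- as.logical(c(group_a$events, group_b$events))
  in_a <- c(rep(TRUE, na), rep(FALSE, nb))
  if (!any(event)) {
    xt_warn("no events in pooled sample; p = 1", "xt_no_events")
    return(structure(list(statistic = 0, p_value = 1, method = method),
                     class = "xeno_test"))
  }
  obs <- peto_stat(time, event, in_a)
  if (method == "asymptotic") {
    p <- 2 * pnorm(-abs(obs$z))
    return(structure(list(statistic = obs$z, p_value = min(p, 1),
                          method = method), class = "xeno_test"))
  }
  n <- na + nb
  n_assign <- choose(n, na)
  if (n_assign > 2e5) {
    xt_stop("exact permutation infeasible for these group sizes", "xt_domain_error")
  }
  assigns <- combn(n, na)
  zs <- apply(assigns, 2, function(idx) {
    lab <- rep(FALSE, n); lab[idx] <- TRUE
    peto_stat(time, event, lab)$z
  })
  p <- mean(abs(zs) >= abs(obs$z) - 1e-10)
  structure(list(statistic = obs$z, p_value = p, method = method),
            class = "xeno_test")
}

#' @export
print.xeno_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, two-sided p = %.4g (%s)\n",
              x$test_name %||% "Peto-Peto Gehan-Wilcoxon", x$statistic,
              x$p_value, x$method))
  invisible(x)
}
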