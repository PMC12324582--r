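# Fixtures built in code, plus independent oracle implementations used to
# cross-check the package's statistics.

make_record <- function(volumes, days = seq_along(volumes) * 3 - 3,
                        id = "m1", model = "MOD", arm = "treated",
                        fate = "completed", weights = NULL) {
  mouse_record(id, model, arm, data.frame(day = days, volume = volumes),
               weights = weights, fate = fate)
}

surv_grp <- function(times, events) list(times = times, events = events)

write_toy_study_csv <- function(path) {
  df <- data.frame(
    mouse_id = rep(c("a", "b"), each = 3),
    model_id = "TOY", arm = rep(c("vehicle", "treated"), each = 3),
    day = rep(c(0, 3, 7), 2),
    volume = c(200, 300, 450, 210, 180, 150),
    weight = c(20, 19.5, 19, 21, 20.5, 20.2))
  write.csv(df, path, row.names = FALSE)
  df
}

# Independent weighted log-rank z: vectorized formulation, distinct code path
# from the package's accumulator loop. Weights are the left-continuous pooled
# Kaplan-Meier estimate.
oracle_peto_z <- function(times, events, in_a) {
  ut <- sort(unique(times[events]))
  if (!length(ut)) return(0)
  n_risk <- sapply(ut, function(t) sum(times >= t))
  d <- sapply(ut, function(t) sum(events & times == t))
  n1 <- sapply(ut, function(t) sum(times >= t & in_a))
  d1 <- sapply(ut, function(t) sum(events & times == t & in_a))
  km <- cumprod(1 - d / n_risk)
  w <- c(1, km[-length(km)])
  u <- sum(w * (d1 - d * n1 / n_risk))
  v <- sum(w^2 * ifelse(n_risk > 1,
                        d * (n1 / n_risk) * (1 - n1 / n_risk) *
                          (n_risk - d) / (n_risk - 1), 0))
  if (v <= 0) 0 else u / sqrt(v)
}

oracle_peto_exact_p <- function(times, events, in_a) {
  n <- length(times)
  na <- sum(in_a)
  obs <- abs(oracle_peto_z(times, events, in_a))
  zs <- apply(utils::combn(n, na), 2, function(idx) {
    lab <- rep(FALSE, n); lab[idx] <- TRUE
    oracle_peto_z(times, events, lab)
  })
  mean(abs(zs) >= obs - 1e-10)
}

# Independent ORM rule table. Deliberately written as a flat sequence of
# guard clauses over precomputed features rather than the package's
# priority-chain, so a disagreement flags a real rule mistake.
oracle_orm <- function(days, volumes, detection_limit = 0,
                       treatment_end_day = 42, window_end = 42,
                       treated = TRUE, control_median = NULL,
                       event_time = NULL, event = NULL) {
  v0 <- volumes[days == 0]
  post_days <- days[days > 0]
  post_vols <- volumes[days > 0]
  zero <- post_vols <= detection_limit
  # longest zero-run restricted to readings after treatment end
  sel <- post_days > treatment_end_day
  run <- 0; best <- 0
  for (z in zero[sel]) {
    run <- if (z) run + 1 else 0
    best <- max(best, run)
  }
  inw <- post_days <= window_end
  rtvs <- post_vols[inw] / v0
  min_rtv <- min(rtvs)
  final_rtv <- rtvs[length(rtvs)]
  if (best >= 3) return("MCR")
  if (any(zero)) return("CR")
  if (min_rtv <= 0.5) return("PR")
  if (final_rtv <= 1.25) return("SD")
  if (!treated) return("PD")
  # censored PD mice are split on their censoring time, same as events
  if (event_time > 2 * control_median) "PD2" else "PD1"
}

# random trajectory generator for the classifier property tests
random_trajectory <- function() {
  days <- seq(0, 70, by = 7)
  v0 <- runif(1, 150, 250)
  shape <- sample(c("grow", "shrink", "v", "zero", "zero_late"), 1)
  v <- switch(shape,
    grow = v0 * exp(cumsum(c(0, runif(length(days) - 1, -0.1, 0.4)))),
    shrink = v0 * exp(cumsum(c(0, runif(length(days) - 1, -0.5, 0.05)))),
    v = v0 * exp(c(0, cumsum(runif(5, -0.6, -0.1)),
                   cumsum(runif(length(days) - 6, 0, 0.5)))),
    zero = { x <- v0 * exp(-0.15 * days); x[x < 20] <- 0; x },
    zero_late = { x <- v0 * exp(-0.08 * days)
                  x[days >= sample(c(28, 49, 56), 1)] <- 0; x })
  v[1] <- v0
  list(days = days, volumes = v)
}
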