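## Stochastic tumor-growth study simulator.
##
## Latent tumor volume is piecewise exponential (log-linear): the control
## growth rate applies off drug, the on-drug net rate while dosed. This is
## deliberately the same growth model the event-time interpolation assumes.
## Measurement noise is multiplicative lognormal with unit mean. Body weight
## drifts down while dosed (toxicity) and recovers toward baseline off drug;
## dosing is paused on >=15% weight loss and resumed when weight recovers to
## >90% of baseline, mirroring a chow dosing-holiday rule.

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults emulate a small
#' neuroblastoma xenograft panel study: 3 evaluable mice per arm, baseline
#' volume 200 +/- 50 mm^3, twice-weekly measurements, control growth rate
#' 0.105/day (tumor quadrupling in roughly two weeks), 10% caliper CV.
#'
#' @param n_per_arm Mice per arm.
#' @param v0_mean,v0_sd Baseline tumor-volume distribution, mm^3.
#' @param growth_rate Control exponential growth rate, per day.
#' @param effect_class One of `"none"`, `"growth_delay"`, `"stasis"`,
#'   `"regression"`, `"cure"`, `"regress_regrow"`. Sets the default
#'   `on_drug_rate` and, for `"cure"`, eradicates the tumor permanently once
#'   the latent volume falls below `measurable_floor`.
#' @param on_drug_rate Net exponential rate while dosed (negative =
#'   regression); `NULL` uses the `effect_class` preset.
#' @param regrow_day Day regrowth resumes for `"regress_regrow"`.
#' @param noise_cv Lognormal measurement coefficient of variation.
#' @param measurement_days Measurement grid, days; default twice weekly
#'   (0, 3, 7, 10, 14, ...).
#' @param weight_baseline,weight_sd Baseline body-weight distribution, g.
#' @param toxicity_rate Fractional body-weight loss per dosed day.
#' @param recovery_rate Fractional body-weight regain per day off drug.
#' @param weight_noise_cv Lognormal CV of weight measurements.
#' @param toxic_death_prob Probability a treated mouse is removed as a toxic
#'   death at a uniformly chosen dosed measurement day.
#' @param measurable_floor Latent volume (mm^3) below which the recorded
#'   volume is 0 ("not measurable").
#' @param seed Integer seed used by [simulate_study()].
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_arm = 3, v0_mean = 200, v0_sd = 50,
                              growth_rate = 0.105,
                              effect_class = c("none", "growth_delay", "stasis",
                                               "regression", "cure",
                                               "regress_regrow"),
                              on_drug_rate = NULL, regrow_day = 42,
                              noise_cv = 0.1,
                              measurement_days = NULL,
                              weight_baseline = 20, weight_sd = 1.5,
                              toxicity_rate = 0.002, recovery_rate = 0.02,
                              weight_noise_cv = 0.005,
                              toxic_death_prob = 0, measurable_floor = 5,
                              seed = 1L) {
  effect_class <- match.arg(effect_class)
  if (is.null(on_drug_rate)) {
    on_drug_rate <- switch(effect_class,
      none = growth_rate, growth_delay = growth_rate / 3, stasis = 0,
      regression = -0.05, cure = -0.35, regress_regrow = -0.15)
  }
  if (!all(is.finite(c(growth_rate, on_drug_rate)))) {
    xt_stop("growth rates must be finite", "xt_validation_error")
  }
  if (noise_cv < 0 || n_per_arm < 1) {
    xt_stop("need noise_cv >= 0 and n_per_arm >= 1", "xt_validation_error")
  }
  structure(list(n_per_arm = as.integer(n_per_arm), v0_mean = v0_mean,
                 v0_sd = v0_sd, growth_rate = growth_rate,
                 effect_class = effect_class, on_drug_rate = on_drug_rate,
                 regrow_day = regrow_day, noise_cv = noise_cv,
                 measurement_days = measurement_days,
                 weight_baseline = weight_baseline, weight_sd = weight_sd,
                 toxicity_rate = toxicity_rate, recovery_rate = recovery_rate,
                 weight_noise_cv = weight_noise_cv,
                 toxic_death_prob = toxic_death_prob,
                 measurable_floor = measurable_floor, seed = as.integer(seed)),
            class = "simulation_config")
}

twice_weekly_grid <- function(max_day) {
  # 0, 3, 7, 10, 14, ... : Mon/Thu-style twice-weekly caliper days
  wk <- seq(0, max_day + 7, by = 7)
  sort(unique(c(wk, wk + 3)))[sort(unique(c(wk, wk + 3))) <= max_day]
}

in_windows <- function(day, windows) {
  if (!length(windows)) return(FALSE)
  any(vapply(windows, function(w) day >= w[1] && day < w[2], logical(1)))
}

lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -s^2 / 2, sd = s)) # unit mean
}

#' Simulate one mouse
#'
#' Draws a baseline volume and weight, integrates the piecewise-exponential
#' latent trajectory over the effective dosing schedule (design windows
#' modified by the weight-loss dosing-holiday rule), applies lognormal
#' measurement noise, and truncates the series at the volume endpoint or
#' `max_day`. Uses the current RNG state; seed externally (or via
#' [simulate_study()]) for reproducibility.
#'
#' @param config [simulation_config()].
#' @param arm [arm_design()] for the mouse's arm.
#' @param design [study_design()].
#' @param mouse_id,model_id Labels for the record.
#' @return A [mouse_record()]. The effective dosed days (after holidays) are
#'   attached as attribute `"dosed_days"` and the noise-free latent volumes as
#'   `"latent_volume"`, for diagnostics.
#' @export
simulate_mouse <- function(config, arm, design, mouse_id = "m1",
                           model_id = design$model_id) {
  days <- config$measurement_days %||% twice_weekly_grid(design$max_day)
  days <- sort(unique(days[days <= design$max_day]))
  stopifnot(days[1] == 0)
  nd <- length(days)

  v0 <- max(rnorm(1, config$v0_mean, config$v0_sd), 1)
  w0 <- max(rnorm(1, config$weight_baseline, config$weight_sd), 5)

  latent <- numeric(nd); latent[1] <- v0
  weight <- numeric(nd); weight[1] <- w0
  holiday <- FALSE
  eradicated <- FALSE
  dosed_days <- numeric(0)

  rate_at <- function(day, dosed) {
    if (!dosed) return(config$growth_rate)
    if (config$effect_class == "regress_regrow" && day >= config$regrow_day) {
      return(config$growth_rate)
    }
    config$on_drug_rate
  }

  for (i in 2:nd) {
    t0 <- days[i - 1]; t1 <- days[i]
    # dosing-holiday state, decided from the weight measured at t0
    if (!holiday && weight[i - 1] <= 0.85 * w0) holiday <- TRUE
    else if (holiday && weight[i - 1] > 0.90 * w0) holiday <- FALSE

    # integrate latent volume over [t0, t1), splitting at schedule changes
    cuts <- c(t0, t1)
    for (w in arm$dosing_windows) cuts <- c(cuts, w)
    if (config$effect_class == "regress_regrow") cuts <- c(cuts, config$regrow_day)
    cuts <- sort(unique(cuts[cuts >= t0 & cuts <= t1]))
    v <- latent[i - 1]
    dosed_time <- 0
    for (k in seq_len(length(cuts) - 1)) {
      a <- cuts[k]; b <- cuts[k + 1]
      dosed <- arm$treated && !holiday && in_windows(a, arm$dosing_windows)
      if (dosed) {
        dosed_time <- dosed_time + (b - a)
        dosed_days <- c(dosed_days, seq(a, b - 1))
      }
      if (!eradicated) {
        v <- v * exp(rate_at(a, dosed) * (b - a))
        if (config$effect_class == "cure" && v <= config$measurable_floor) {
          v <- 0; eradicated <- TRUE
        }
      }
    }
    latent[i] <- v

    # body weight: toxicity drift while dosed, recovery toward baseline off drug
    dt <- t1 - t0
    wnew <- weight[i - 1] * (1 - config$toxicity_rate)^dosed_time
    wnew <- min(wnew * (1 + config$recovery_rate)^(dt - dosed_time), w0)
    weight[i] <- wnew * lognorm_factor(1, config$weight_noise_cv)
  }

  observed <- latent * lognorm_factor(nd, config$noise_cv)
  observed[latent < config$measurable_floor] <- 0
  observed[1] <- max(observed[1], 1) # baseline stays positive

  # endpoint removal: the mouse exits at the day its latent volume crosses the
  # cap (log-linear inversion between grid points), with a final measurement
  # taken at the cap itself
  fate <- "completed"
  keep <- nd
  endpoint_row <- NULL
  hit <- which(latent >= design$endpoint_volume)
  if (length(hit) && hit[1] > 1) {
    i <- hit[1]
    t_cross <- days[i - 1] + (days[i] - days[i - 1]) *
      (log(design$endpoint_volume) - log(latent[i - 1])) /
      (log(latent[i]) - log(latent[i - 1]))
    keep <- i - 1
    fate <- "tumor_endpoint"
    endpoint_row <- list(
      day = t_cross,
      volume = design$endpoint_volume * lognorm_factor(1, config$noise_cv),
      weight = weight[i - 1])
  }

  # toxic death: removal at a uniformly chosen dosed measurement day
  if (arm$treated && config$toxic_death_prob > 0 &&
      runif(1) < config$toxic_death_prob) {
    cand <- which(days > 0 & days <= max(dosed_days, 0) & seq_len(nd) <= keep)
    if (length(cand)) {
      keep <- cand[sample.int(length(cand), 1)]
      fate <- "toxic_death"
      endpoint_row <- NULL
    }
  }

  idx <- seq_len(keep)
  vols <- data.frame(day = days[idx], volume = observed[idx])
  wts <- data.frame(day = days[idx], weight = weight[idx])
  if (!is.null(endpoint_row) && fate == "tumor_endpoint") {
    vols <- rbind(vols, data.frame(day = endpoint_row$day,
                                   volume = endpoint_row$volume))
    wts <- rbind(wts, data.frame(day = endpoint_row$day,
                                 weight = endpoint_row$weight))
  }
  rec <- mouse_record(mouse_id, model_id, arm$arm, volumes = vols,
                      weights = wts, fate = fate)
  attr(rec, "dosed_days") <- dosed_days[dosed_days < max(vols$day)]
  attr(rec, "latent_volume") <-
    c(latent[idx], if (!is.null(endpoint_row)) design$endpoint_volume)
  rec
}

#' Simulate a whole study
#'
#' `n_per_arm` mice per design arm, seeded from `config$seed` so that
#' identical (config, design) inputs give bit-identical studies.
#'
#' @inheritParams simulate_mouse
#' @return An `xeno_study`: list with `design` and `records`.
#' @export
simulate_study <- function(config, design = study_design()) {
  set.seed(config$seed)
  records <- list()
  for (arm in design$arms) {
    for (j in seq_len(config$n_per_arm)) {
      id <- sprintf("%s_%s_%02d", design$model_id, arm$arm, j)
      records[[id]] <- simulate_mouse(config, arm, design, mouse_id = id)
    }
  }
  structure(list(design = design, records = records), class = "xeno_study")
}

#' Recover the exponential growth rate of a record
#'
#' Least-squares slope of log(volume) versus day over the positive recorded
#' volumes — a validation helper for the simulator (on noise-free control
#' mice it returns the generating rate exactly).
#'
#' @param record A [mouse_record()].
#' @return Estimated per-day rate.
#' @export
recover_growth_rate <- function(record) {
  v <- record$volumes
  v <- v[v$volume > 0, ]
  if (nrow(v) < 2) {
    xt_stop("need at least 2 positive volumes to estimate a growth rate",
            "xt_insufficient_data")
  }
  unname(coef(lm(log(volume) ~ day, data = v))[2])
}
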