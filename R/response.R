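## Objective response measure (ORM) classification, group median scoring,
## study evaluability and panel-level response rates, following the
## Pediatric Preclinical Testing Consortium conventions.
##
## Per-mouse categories (priority MCR > CR > PR > SD > PD):
##   MCR  no measurable tumor for >= 3 consecutive readings after the end of
##        treatment
##   CR   tumor not measurable at >= 1 reading (short or intermittent runs)
##        without meeting MCR
##   PR   >= 50% regression at some point (minRTV <= 0.5), measurable
##        throughout
##   SD   minRTV > 0.5 and <= 25% growth at end of window (final RTV <= 1.25)
##   PD   minRTV > 0.5 and final RTV > 1.25; treated mice split into PD1/PD2
##        by whether time-to-event exceeds 200% of the control median

orm_scores <- c(PD = 0, PD1 = 0, PD2 = 2, SD = 4, PR = 6, CR = 8, MCR = 10)

#' Relative tumor volume series
#'
#' RTV(t) = V(t)/V0. The minimum RTV (minRTV) is taken over all post-baseline
#' measurements inside the response window (baseline excluded); `final_rtv`
#' is the RTV at the last in-window measurement. minRTV 0 means the tumor
#' became undetectable; values below 1 indicate regression.
#'
#' @param record A [mouse_record()].
#' @param window_end End of the response window, days (default 42, the end of
#'   continuous dosing).
#' @return Object of class `rtv_series`: data.frame `rtv` (day, rtv),
#'   `min_rtv`, `final_rtv`, `v0`.
#' @export
compute_rtv <- function(record, window_end = 42) {
  vol <- record$volumes
  v0 <- vol$volume[vol$day == 0]
  if (length(v0) != 1 || v0 <= 0) {
    xt_stop("baseline volume V0 must be positive", "xt_domain_error")
  }
  inwin <- vol[vol$day > 0 & vol$day <= window_end, ]
  if (!nrow(inwin)) {
    xt_stop("no post-baseline measurement inside the response window",
            "xt_insufficient_data")
  }
  rtv <- data.frame(day = inwin$day, rtv = inwin$volume / v0)
  structure(list(rtv = rtv, min_rtv = min(rtv$rtv),
                 final_rtv = rtv$rtv[nrow(rtv)], v0 = v0),
            class = "rtv_series")
}

# longest run of TRUE in a logical vector
longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Classify one mouse's objective response
#'
#' Applies the ORM rules in priority order MCR, CR, PR, SD, PD. "Measurable"
#' means recorded volume above `detection_limit`. Treated PD mice are split
#' into PD1 (time-to-event <= 200% of the control median) and PD2 (> 200%);
#' a treated PD mouse that never quadruples is split on its censoring time
#' (with a warning when that time does not exceed 200% of the control
#' median). Control mice keep the unsplit "PD" label. Mice removed as toxic
#' deaths are not evaluable.
#'
#' @param record A [mouse_record()].
#' @param rtv Optional precomputed [compute_rtv()]; computed if `NULL`.
#' @param control_median_event_time Control-group median time-to-event, days
#'   (required for treated PD mice).
#' @param treatment_end_day Day treatment is completed (default 42); MCR
#'   requires its zero-readings run strictly after this day.
#' @param detection_limit Volume at or below which a tumor is not measurable.
#' @param treated Is the mouse in a treated arm? (controls are never PD1/PD2)
#' @param window_end Response window passed to [compute_rtv()].
#' @return Object of class `response_call`: `category`, `score`, `evaluable`.
#' @export
classify_mouse <- function(record, rtv = NULL, control_median_event_time = NULL,
                           treatment_end_day = 42, detection_limit = 0,
                           treated = TRUE, window_end = 42) {
  if (record$fate == "toxic_death") {
    return(structure(list(category = NA_character_, score = NA_real_,
                          evaluable = FALSE), class = "response_call"))
  }
  if (is.null(rtv)) rtv <- compute_rtv(record, window_end = window_end)
  post <- record$volumes[record$volumes$day > 0, ]
  measurable <- post$volume > detection_limit

  after_tx <- post$day > treatment_end_day
  category <- if (longest_run(!measurable[after_tx]) >= 3) {
    "MCR"
  } else if (any(!measurable)) {
    "CR"
  } else if (rtv$min_rtv <= 0.5) {
    "PR"
  } else if (rtv$final_rtv <= 1.25) {
    "SD"
  } else if (!treated) {
    "PD"
  } else {
    if (is.null(control_median_event_time)) {
      xt_stop("treated PD mouse needs the control median event time",
              "xt_evaluability_error")
    }
    ev <- time_to_event(record)
    if (!ev$event && ev$time <= 2 * control_median_event_time) {
      xt_warn("censored PD mouse classified on its censoring time",
              "xt_censored_pd")
    }
    if (ev$time > 2 * control_median_event_time) "PD2" else "PD1"
  }
  structure(list(category = category, score = unname(orm_scores[category]),
                 evaluable = TRUE), class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  if (!x$evaluable) cat("<response_call> not evaluable\n")
  else cat(sprintf("<response_call> %s (score %g)\n", x$category, x$score))
  invisible(x)
}

score_to_category <- function(median_score, treated = TRUE) {
  # a median halfway between categories maps to the lower category
  map <- c(PD1 = 0, PD2 = 2, SD = 4, PR = 6, CR = 8, MCR = 10)
  cat <- names(map)[max(which(map <= median_score + 1e-9))]
  if (!treated && cat %in% c("PD1", "PD2")) cat <- "PD"
  cat
}

activity_tier_of <- function(category) {
  if (category %in% c("PR", "CR", "MCR")) "high"
  else if (category %in% c("SD", "PD2")) "intermediate"
  else "low"
}

#' Group-level response from per-mouse calls
#'
#' Each evaluable mouse contributes its ORM score (PD1 = 0, PD2 = 2, SD = 4,
#' PR = 6, CR = 8, MCR = 10; unsplit control PD scores 0); the group median
#' determines the overall response, and a median halfway between two
#' categories is assigned to the lower one (a median score of 9 is CR).
#' Groups with PR, CR or MCR count as objective responses ("high" activity);
#' SD or PD2 is intermediate; PD1 is low.
#'
#' @param calls List of [classify_mouse()] results.
#' @param treated Treated-arm group? Controls render 0/2 medians as "PD".
#' @return Object of class `group_response`: `median_score`, `category`,
#'   `n_evaluable`, `activity_tier`.
#' @export
score_group <- function(calls, treated = TRUE) {
  scores <- vapply(calls, function(c) if (isTRUE(c$evaluable)) c$score else NA_real_,
                   numeric(1))
  scores <- scores[!is.na(scores)]
  if (!length(scores)) {
    xt_stop("no evaluable mice in group", "xt_evaluability_error")
  }
  med <- median(scores)
  category <- score_to_category(med, treated = treated)
  structure(list(median_score = med, category = category,
                 n_evaluable = length(scores),
                 activity_tier = activity_tier_of(category)),
            class = "group_response")
}

#' @export
print.group_response <- function(x, ...) {
  cat(sprintf("<group_response> %s (median score %g, n=%d, %s activity)\n",
              x$category, x$median_score, x$n_evaluable, x$activity_tier))
  invisible(x)
}

#' Study evaluability
#'
#' A study is unevaluable when more than 25% of its mice die of toxicity or
#' when the control group itself responds (better than SD, i.e. PR/CR/MCR).
#'
#' @param control_group A [score_group()] result for the control arm.
#' @param toxic_death_fraction Fraction of mice removed as toxic deaths.
#' @return List: `evaluable` (logical), `reason` (character or NA).
#' @export
study_evaluable <- function(control_group, toxic_death_fraction = 0) {
  if (toxic_death_fraction > 0.25) {
    return(list(evaluable = FALSE,
                reason = sprintf("toxic deaths %.0f%% exceed 25%%",
                                 100 * toxic_death_fraction)))
  }
  if (control_group$category %in% c("PR", "CR", "MCR")) {
    return(list(evaluable = FALSE,
                reason = sprintf("control group responded (%s)",
                                 control_group$category)))
  }
  list(evaluable = TRUE, reason = NA_character_)
}

#' Panel-level response rates
#'
#' Summarizes the treated-group response categories of a model panel:
#' objective response rate (ORR; fraction of groups at PR/CR/MCR),
#' anti-tumor-activity rate (high or intermediate activity, i.e. everything
#' except PD1), the CR-or-MCR count, and per-category counts.
#'
#' @param groups Character vector of group categories, or a list of
#'   [score_group()] results.
#' @return List of class `panel_summary`: `n`, `orr`, `orr_pct`,
#'   `activity_rate`, `activity_pct`, `n_cr_or_mcr`, `counts`.
#' @export
panel_summary <- function(groups) {
  cats <- if (is.character(groups)) groups
          else vapply(groups, `[[`, character(1), "category")
  if (!length(cats)) xt_stop("need at least one group", "xt_domain_error")
  bad <- setdiff(cats, names(orm_scores))
  if (length(bad)) {
    xt_stop(sprintf("unknown category: %s", paste(bad, collapse = ", ")),
            "xt_validation_error")
  }
  tiers <- vapply(cats, activity_tier_of, character(1))
  counts <- table(factor(cats, levels = c("PD", "PD1", "PD2", "SD", "PR",
                                          "CR", "MCR")))
  structure(list(n = length(cats),
                 orr = mean(tiers == "high"),
                 orr_pct = 100 * mean(tiers == "high"),
                 activity_rate = mean(tiers != "low"),
                 activity_pct = 100 * mean(tiers != "low"),
                 n_cr_or_mcr = sum(cats %in% c("CR", "MCR")),
                 counts = counts),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Panel of %d groups: ORR %.0f%%, anti-tumor activity %.0f%%, CR/MCR %d\n",
              x$n, x$orr_pct, x$activity_pct, x$n_cr_or_mcr))
  print(x$counts)
  invisible(x)
}
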