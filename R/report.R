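## Pipeline orchestration: read -> events/EFS -> classification -> metrics,
## emitting a study report shaped like a panel efficacy table (one row per
## model x arm, plus a panel block with response rates).

#' Run the full efficacy-evaluation pipeline on a study
#'
#' For every model in the study, pairs the control arm with each treated arm
#' and computes: per-mouse quadrupling events ([time_to_event()]),
#' Kaplan-Meier median EFS per arm with censored-median bounds, EFS T-C and
#' T/C ([efs_contrast()]), the Peto-Peto Gehan-Wilcoxon p-value, per-mouse
#' minRTV with arm mean +/- SD and a Wilcoxon rank-sum comparison, per-mouse
#' ORM calls and the group median response, study evaluability, and
#' panel-level response rates over the treated groups. Toxic-death mice are
#' censored at removal for EFS and excluded from ORM scoring (but counted in
#' the toxic-death fraction).
#'
#' @param study An `xeno_study` (from [read_study()] or [simulate_study()]),
#'   or a list of [mouse_record()] plus a `design`.
#' @param design [study_design()]; taken from `study` when omitted.
#' @param test_method `"asymptotic"` or `"exact_permutation"` for the EFS
#'   test.
#' @param control_pattern Regex (case-insensitive) identifying control arms.
#' @return Object of class `study_report`: `table` (one row per model/arm),
#'   `panel` ([panel_summary()] over treated groups), `notes` (fallbacks and
#'   warnings triggered), `options`.
#' @export
run_pipeline <- function(study, design = NULL,
                         test_method = c("asymptotic", "exact_permutation"),
                         control_pattern = "vehicle|control") {
  test_method <- match.arg(test_method)
  if (inherits(study, "xeno_study")) {
    design <- design %||% study$design
    records <- study$records
  } else {
    records <- study
    if (is.null(design)) xt_stop("design required", "xt_validation_error")
  }
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)

  models <- unique(vapply(records, `[[`, character(1), "model_id"))
  rows <- list()
  treated_groups <- list()

  for (model in models) {
    recs <- records[vapply(records, `[[`, character(1), "model_id") == model]
    arms <- vapply(recs, `[[`, character(1), "arm")
    is_ctrl_arm <- grepl(control_pattern, unique(arms), ignore.case = TRUE)
    ctrl_arm <- unique(arms)[is_ctrl_arm][1]
    if (is.na(ctrl_arm)) xt_stop(sprintf("model %s: no control arm", model),
                                 "xt_validation_error")

    toxic_frac <- mean(vapply(recs, function(r) r$fate == "toxic_death",
                              logical(1)))
    arm_data <- lapply(split(recs, arms), function(rs) {
      ev <- lapply(rs, function(r) {
        withCallingHandlers(
          time_to_event(r),
          xenotrial_warning = function(w) {
            note(conditionMessage(w)); invokeRestart("muffleWarning")
          })
      })
      rtv <- lapply(rs, function(r) {
        tryCatch(compute_rtv(r, window_end = design$response_window_end),
                 xt_insufficient_data = function(e) NULL)
      })
      list(records = rs,
           surv = list(times = vapply(ev, `[[`, numeric(1), "time"),
                       events = vapply(ev, `[[`, logical(1), "event")),
           min_rtv = vapply(rtv, function(x)
             if (is.null(x)) NA_real_ else x$min_rtv, numeric(1)),
           rtv = rtv)
    })

    ctrl <- arm_data[[ctrl_arm]]
    ctrl_km <- km_median(ctrl$surv$times, ctrl$surv$events)
    ctrl_calls <- classify_arm(ctrl$records, ctrl$rtv, NULL, design,
                               treated = FALSE, note = note)
    ctrl_group <- score_group(ctrl_calls, treated = FALSE)
    evalr <- study_evaluable(ctrl_group, toxic_frac)
    if (!evalr$evaluable) note(sprintf("model %s unevaluable: %s", model,
                                       evalr$reason))

    rows[[length(rows) + 1]] <- report_row(
      model, ctrl_arm, ctrl, ctrl_km, NULL, NULL, ctrl_group, evalr$evaluable)

    for (trt_arm in setdiff(unique(arms), ctrl_arm)) {
      trt <- arm_data[[trt_arm]]
      es <- withCallingHandlers(
        efs_summary(ctrl$surv, trt$surv, method = test_method),
        xenotrial_warning = function(w) {
          note(conditionMessage(w)); invokeRestart("muffleWarning")
        })
      if (es$treated_bound) {
        note(sprintf("model %s: treated median not reached; using bound >%g",
                     model, es$treated_median$bound))
      }
      rtv_p <- tryCatch(
        wilcoxon_rank_sum(ctrl$min_rtv[!is.na(ctrl$min_rtv)],
                          trt$min_rtv[!is.na(trt$min_rtv)],
                          method = "exact")$p_value,
        xenotrial_warning = function(w) 1, error = function(e) NA_real_)
      if (!ctrl_km$reached) {
        xt_stop(sprintf("model %s: control median not reached", model),
                "xt_evaluability_error")
      }
      calls <- classify_arm(trt$records, trt$rtv, ctrl_km$value, design,
                            treated = TRUE, note = note)
      grp <- score_group(calls, treated = TRUE)
      treated_groups[[paste(model, trt_arm)]] <- grp

      rows[[length(rows) + 1]] <- report_row(
        model, trt_arm, trt, es$treated_median, es, rtv_p, grp,
        evalr$evaluable)
    }
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  panel <- if (length(treated_groups)) panel_summary(treated_groups) else NULL
  structure(list(table = table, panel = panel, notes = unique(notes),
                 options = list(test_method = test_method,
                                response_window_end = design$response_window_end,
                                detection_limit = design$detection_limit)),
            class = "study_report")
}

classify_arm <- function(rs, rtvs, ctrl_median, design, treated, note) {
  lapply(seq_along(rs), function(i) {
    if (is.null(rtvs[[i]]) && rs[[i]]$fate != "toxic_death") {
      note(sprintf("mouse %s: no in-window measurement; not evaluable",
                   rs[[i]]$mouse_id))
      return(structure(list(category = NA_character_, score = NA_real_,
                            evaluable = FALSE), class = "response_call"))
    }
    withCallingHandlers(
      classify_mouse(rs[[i]], rtv = rtvs[[i]],
                     control_median_event_time = ctrl_median,
                     treatment_end_day = design$response_window_end,
                     detection_limit = design$detection_limit,
                     treated = treated,
                     window_end = design$response_window_end),
      xenotrial_warning = function(w) {
        note(sprintf("mouse %s: %s", rs[[i]]$mouse_id, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  })
}

report_row <- function(model, arm, arm_data, km, es, rtv_p, grp, evaluable) {
  mr <- arm_data$min_rtv[!is.na(arm_data$min_rtv)]
  data.frame(
    model = model, arm = arm, n = length(arm_data$records),
    n_evaluable = grp$n_evaluable,
    km_median = km_effective(km), km_reached = km$reached,
    efs_t_minus_c = if (is.null(es)) NA_real_ else es$efs_t_minus_c,
    efs_t_over_c = if (is.null(es)) NA_real_ else es$efs_t_over_c,
    contrast_is_bound = if (is.null(es)) NA else es$treated_bound,
    p_gehan_wilcoxon = if (is.null(es)) NA_real_ else es$p_value,
    min_rtv_mean = if (length(mr)) mean(mr) else NA_real_,
    min_rtv_sd = if (length(mr) > 1) sd(mr) else 0,
    min_rtv_p = if (is.null(rtv_p)) NA_real_ else rtv_p,
    median_score = grp$median_score, med_resp = grp$category,
    activity_tier = grp$activity_tier, evaluable_study = evaluable,
    stringsAsFactors = FALSE)
}

## rendering and serialization ----------------------------------------------

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "",
         trimws(formatC(round(x, digits), format = "g", digits = 15)))
}

#' Render a study report as a text table
#'
#' `style = "wide"` mirrors the conventional panel efficacy-table layout
#' (Model, Grp, N, KM med, EFS T-C, EFS T/C, P-value, minRTV, Med resp), with
#' unreached medians rendered as `">bound"`; `style = "tidy"` returns the
#' full numeric table.
#'
#' @param report A `study_report`.
#' @param style `"wide"` or `"tidy"`.
#' @return A data.frame of character (wide) or numeric (tidy) columns.
#' @export
render_table <- function(report, style = c("wide", "tidy")) {
  style <- match.arg(style)
  t <- report$table
  if (style == "tidy") return(t)
  km <- ifelse(t$km_reached, fmt_num(t$km_median),
               paste0(">", fmt_num(t$km_median)))
  if (!nrow(t)) km <- character(0)
  data.frame(
    Model = t$model, Grp = t$arm, N = t$n, `KM med` = km,
    `EFS T-C` = fmt_num(t$efs_t_minus_c),
    `EFS T/C` = fmt_num(t$efs_t_over_c),
    `P-value` = fmt_num(t$p_gehan_wilcoxon, 4),
    minRTV = ifelse(is.na(t$min_rtv_mean), "",
                    paste0(fmt_num(t$min_rtv_mean), "+/-", fmt_num(t$min_rtv_sd))),
    `minRTV P` = fmt_num(t$min_rtv_p, 4),
    `Med resp` = t$med_resp,
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Xenograft efficacy study report\n")
  print(render_table(x, "wide"), row.names = FALSE)
  if (!is.null(x$panel)) {
    cat(sprintf("\nPanel: ORR %.0f%% (%d/%d), activity %.0f%%, CR/MCR %d\n",
                x$panel$orr_pct, round(x$panel$orr * x$panel$n), x$panel$n,
                x$panel$activity_pct, x$panel$n_cr_or_mcr))
  }
  if (length(x$notes)) cat("\nNotes:\n", paste0("  - ", x$notes, "\n"), sep = "")
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
as.data.frame.study_report <- function(x, ...) x$table

#' Write a study report to CSV or JSON
#'
#' Numeric fields round-trip: reading the written file reproduces them to
#' printed precision. CSV holds the per-arm table (the panel block, if any,
#' goes to a `<path>.panel.csv` side file); JSON holds both.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  if (!inherits(report, "study_report")) {
    xt_stop("report must be a study_report", "xt_usage_error")
  }
  format <- tryCatch(match.arg(format),
                     error = function(e) xt_stop("unknown format", "xt_usage_error"))
  if (format == "csv") {
    write.csv(report$table, path, row.names = FALSE)
    if (!is.null(report$panel)) {
      pf <- data.frame(orr_pct = report$panel$orr_pct,
                       activity_pct = report$panel$activity_pct,
                       n_cr_or_mcr = report$panel$n_cr_or_mcr,
                       n_groups = report$panel$n)
      write.csv(pf, paste0(path, ".panel.csv"), row.names = FALSE)
    }
  } else {
    out <- list(table = report$table, notes = report$notes,
                options = report$options)
    if (!is.null(report$panel)) {
      out$panel <- list(orr_pct = report$panel$orr_pct,
                        activity_pct = report$panel$activity_pct,
                        n_cr_or_mcr = report$panel$n_cr_or_mcr,
                        n_groups = report$panel$n)
    }
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
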