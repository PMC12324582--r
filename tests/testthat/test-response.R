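test_that("relative tumor volume series excludes baseline from the minimum", {
  r <- make_record(c(200, 250, 400), days = c(0, 3, 7))
  s <- compute_rtv(r)
  expect_equal(s$rtv$rtv, c(1.25, 2))
  expect_equal(s$min_rtv, 1.25)
  expect_equal(s$final_rtv, 2)

  # cured mouse: minRTV 0
  r <- make_record(c(200, 100, 0, 0, 0), days = c(0, 7, 14, 21, 28))
  expect_equal(compute_rtv(r)$min_rtv, 0)

  # V-shaped trajectory
  r <- make_record(c(200, 100, 50, 300), days = c(0, 3, 7, 10))
  s <- compute_rtv(r)
  expect_equal(s$min_rtv, 0.25)
  expect_equal(s$final_rtv, 1.5)

  # window restriction: late measurements do not affect minRTV
  r <- make_record(c(200, 300, 10), days = c(0, 40, 60))
  expect_equal(compute_rtv(r, window_end = 42)$min_rtv, 1.5)
  expect_error(compute_rtv(make_record(c(200, 100), days = c(0, 50))),
               class = "xt_insufficient_data")
})

test_that("ORM categories follow the rule table", {
  days <- seq(0, 70, by = 7)
  # three consecutive zero readings after treatment end -> MCR
  v <- c(200, 150, 80, 30, 10, 0, 0, 0, 0, 0, 0)
  expect_equal(classify_mouse(make_record(v, days = days))$category, "MCR")
  # zeros only before treatment end -> CR (not maintained)
  v <- c(200, 0, 0, 0, 100, 150, 200, 250, 300, 350, 400)
  expect_equal(classify_mouse(make_record(v, days = days),
                              control_median_event_time = 10)$category, "CR")
  # two zero readings after treatment end: CR, not MCR
  v <- c(200, 150, 80, 30, 10, 8, 6, 0, 0, 6, 8)
  expect_equal(classify_mouse(make_record(v, days = days))$category, "CR")
  # >= 50% regression, measurable throughout -> PR
  v <- c(200, 150, 80, 80, 90, 100, 110, 120, 130, 140, 150)
  expect_equal(classify_mouse(make_record(v, days = days))$category, "PR")
  # exactly 50% regression counts as PR
  v <- c(200, 100, 150, 180, 200, 210, 220, 230, 240, 245, 248)
  expect_equal(classify_mouse(make_record(v, days = days))$category, "PR")
  # modest shrink, end below 125% of baseline -> SD
  v <- c(200, 180, 190, 200, 210, 220, 240, 240, 240, 240, 240)
  expect_equal(classify_mouse(make_record(v, days = days))$category, "SD")
  # growth beyond 125%: PD, split by time-to-event vs 2x control median
  v <- 200 * exp(0.1 * days)
  expect_equal(classify_mouse(make_record(v, days = days),
                              control_median_event_time = 10)$category, "PD1")
  v <- 200 * exp(0.04 * days) # quadruples around day 35
  expect_equal(classify_mouse(make_record(v, days = days),
                              control_median_event_time = 10)$category, "PD2")
  # control mice keep the unsplit PD label
  v <- 200 * exp(0.1 * days)
  call <- classify_mouse(make_record(v, days = days, arm = "vehicle"),
                         treated = FALSE)
  expect_equal(call$category, "PD")
  expect_equal(call$score, 0)
  # treated PD without a control median is an evaluability error
  expect_error(classify_mouse(make_record(v, days = days)),
               class = "xt_evaluability_error")
  # toxic deaths are not evaluable
  call <- classify_mouse(make_record(c(200, 300), days = c(0, 7),
                                     fate = "toxic_death"))
  expect_false(call$evaluable)
  # censored PD mouse splits on its censoring time, with a warning when that
  # time does not exceed 200% of the control median
  v <- c(200, 210, 240, 280, 320, 360, 400, 420, 460, 500, 550)
  expect_warning(
    call <- classify_mouse(make_record(v, days = days),
                           control_median_event_time = 60),
    class = "xt_censored_pd")
  expect_equal(call$category, "PD1")
})

test_that("classifier agrees with the independent rule-table oracle", {
  set.seed(17)
  n_checked <- 0
  for (i in 1:2000) {
    tr <- random_trajectory()
    rec <- make_record(tr$volumes, days = tr$days)
    ctrl_med <- runif(1, 5, 30)
    ev <- time_to_event(rec)
    got <- suppressWarnings(
      classify_mouse(rec, control_median_event_time = ctrl_med))$category
    want <- oracle_orm(tr$days, tr$volumes, control_median = ctrl_med,
                       event_time = ev$time, event = ev$event)
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 2000)
})

test_that("raising the detection limit never moves a call away from CR/MCR", {
  rank_of <- function(cat) match(cat, c("PD1", "PD2", "SD", "PR", "CR", "MCR"))
  set.seed(18)
  for (i in 1:200) {
    tr <- random_trajectory()
    rec <- make_record(tr$volumes, days = tr$days)
    calls <- lapply(c(0, 10, 50), function(dl) {
      suppressWarnings(classify_mouse(rec, control_median_event_time = 12,
                                      detection_limit = dl))$category
    })
    r <- vapply(calls, rank_of, integer(1))
    # measurability is monotone in the limit, so the category can only move
    # up the priority order, never away from CR/MCR
    expect_true(all(diff(r) >= 0))
  }
})

test_that("group scoring takes the median and ties go to the lower category", {
  call <- function(cat) structure(list(category = cat,
                                       score = c(PD = 0, PD1 = 0, PD2 = 2, SD = 4,
                                                 PR = 6, CR = 8, MCR = 10)[[cat]],
                                       evaluable = TRUE), class = "response_call")
  g <- score_group(list(call("CR"), call("MCR")))
  expect_equal(g$median_score, 9)
  expect_equal(g$category, "CR") # score 9 maps down to CR
  expect_equal(g$activity_tier, "high")

  g <- score_group(list(call("PD1"), call("PD1"), call("PD1")))
  expect_equal(g$category, "PD1")
  expect_equal(g$activity_tier, "low")

  g <- score_group(list(call("PD1"), call("SD"), call("PR")))
  expect_equal(g$median_score, 4)
  expect_equal(g$category, "SD")
  expect_equal(g$activity_tier, "intermediate")

  # order invariance, and adding a mouse at the median leaves the category
  calls <- list(call("PD2"), call("PR"), call("SD"))
  g1 <- score_group(calls)
  g2 <- score_group(rev(calls))
  expect_equal(g1$category, g2$category)
  g3 <- score_group(c(calls, list(call("SD"))))
  expect_equal(g3$category, g1$category)

  # unevaluable mice are excluded; none evaluable is an error
  tox <- structure(list(category = NA, score = NA_real_, evaluable = FALSE),
                   class = "response_call")
  expect_equal(score_group(list(call("CR"), tox))$n_evaluable, 1)
  expect_error(score_group(list(tox)), class = "xt_evaluability_error")

  # control group label collapses to PD
  expect_equal(score_group(list(call("PD"), call("PD"), call("SD")),
                           treated = FALSE)$category, "PD")
})

test_that("study evaluability needs <= 25% toxic deaths and a non-responding control", {
  pd_group <- structure(list(median_score = 0, category = "PD",
                             n_evaluable = 3, activity_tier = "low"),
                        class = "group_response")
  pr_group <- structure(list(median_score = 6, category = "PR",
                             n_evaluable = 3, activity_tier = "high"),
                        class = "group_response")
  expect_true(study_evaluable(pd_group, 0)$evaluable)
  expect_true(study_evaluable(pd_group, 0.25)$evaluable)
  expect_false(study_evaluable(pd_group, 2 / 6)$evaluable)
  expect_false(study_evaluable(pr_group, 0)$evaluable)
})

test_that("panel summary reproduces ORR and activity from response categories", {
  cats <- c("MCR", "MCR", "CR", "CR", "CR", "CR", "CR", "PR",
            "PD2", "PD2", "PD2", "PD2", "PD2", "PD2", "PD1")
  p <- panel_summary(cats)
  expect_equal(p$orr, 8 / 15)
  expect_equal(round(p$orr_pct), 53)
  expect_equal(p$activity_rate, 14 / 15)
  expect_equal(round(p$activity_pct), 93)
  expect_equal(p$n_cr_or_mcr, 7)

  expect_equal(panel_summary(c("PD1", "PD1"))$orr, 0)
  expect_equal(panel_summary(c("PD1", "PD1"))$activity_rate, 0)
  expect_equal(panel_summary("MCR")$orr_pct, 100)
  expect_error(panel_summary(character(0)), class = "xt_domain_error")
  expect_error(panel_summary("XX"), class = "xt_validation_error")
})
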