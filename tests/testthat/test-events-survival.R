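test_that("time to quadrupling interpolates log-linearly between brackets", {
  # crossing exactly at an observation
  r <- make_record(c(100, 400), days = c(0, 7))
  ev <- time_to_event(r)
  expect_true(ev$event)
  expect_equal(ev$time, 7)
  expect_equal(ev$threshold_volume, 400)

  # closed form: solve 300 * (600/300)^((t-7)/3) = 400
  r <- make_record(c(100, 300, 600), days = c(0, 7, 10))
  expect_equal(time_to_event(r)$time, 7 + 3 * log(400 / 300) / log(600 / 300))

  # censored when never crossing
  r <- make_record(c(100, 200, 390), days = c(0, 35, 70))
  ev <- time_to_event(r)
  expect_false(ev$event)
  expect_equal(ev$time, 70)

  # first post-baseline measurement already across: bracket with (0, V0)
  r <- make_record(c(100, 800), days = c(0, 6))
  expect_equal(time_to_event(r)$time, 6 * log(4) / log(8))

  # zero bracketing volume falls back to linear interpolation
  r <- make_record(c(100, 0, 800), days = c(0, 3, 6))
  expect_warning(ev <- time_to_event(r), class = "xt_linear_fallback")
  expect_equal(ev$time, 3 + 3 * 400 / 800)

  expect_error(time_to_event(make_record(c(0, 10), days = c(0, 3))),
               class = "xt_domain_error")
})

test_that("interpolated event time is bracketed and monotone in V0", {
  set.seed(4)
  for (i in 1:50) {
    days <- c(0, sort(sample(3:70, 8)))
    v <- 150 * exp(cumsum(c(0, runif(8, 0, 0.6))))
    r <- make_record(v, days = days)
    ev <- time_to_event(r)
    if (ev$event) {
      i2 <- which(v >= ev$threshold_volume & days > 0)[1]
      expect_gte(ev$time, days[i2 - 1])
      expect_lte(ev$time, days[i2])
    }
    # larger baseline (same later volumes) can only delay the event
    r2 <- make_record(c(v[1] * 1.3, v[-1]), days = days)
    ev2 <- time_to_event(r2)
    if (ev$event && ev2$event) expect_gte(ev2$time, ev$time)
  }
})

test_that("KM median follows the product-limit estimator", {
  m <- km_median(c(10, 20, 30), c(TRUE, TRUE, TRUE))
  expect_true(m$reached)
  expect_equal(m$value, 20)

  # hand-computed: S(10)=1 (censored), S(20)=0.5 with risk set of 2
  m <- km_median(c(10, 20, 30), c(FALSE, TRUE, TRUE))
  expect_equal(m$value, 20)

  m <- km_median(c(10, 20, 84), c(FALSE, FALSE, FALSE))
  expect_false(m$reached)
  expect_equal(m$bound, 84)
  expect_equal(format(m), ">84")

  expect_error(km_median(numeric(0), logical(0)), class = "xt_domain_error")

  # uncensored samples: KM median equals the lower empirical median, and the
  # survival curve is non-increasing from 1
  set.seed(8)
  for (i in 1:20) {
    tt <- sample(1:40, 7, replace = TRUE)
    m <- km_median(tt, rep(TRUE, 7))
    expect_equal(m$value, sort(tt)[4])
    fit <- survival::survfit(survival::Surv(tt, rep(1, 7)) ~ 1)
    expect_true(all(diff(fit$surv) <= 1e-12))
  }
})

test_that("EFS contrasts use the censored-median bound convention", {
  ct <- efs_contrast(km_median_reached(18.52), km_median_reached(104.32))
  expect_equal(ct$efs_t_minus_c, 85.8)
  expect_equal(round(ct$efs_t_over_c, 2), 5.63)
  expect_false(ct$treated_bound)

  ct <- efs_contrast(km_median_reached(8.38), km_median_bound(84))
  expect_equal(ct$efs_t_minus_c, 75.62)
  expect_equal(round(ct$efs_t_over_c, 2), 10.02)
  expect_true(ct$treated_bound)

  expect_error(efs_contrast(km_median_bound(70), km_median_reached(10)),
               class = "xt_evaluability_error")

  # identical arms: T-C 0, T/C 1, p = 1
  g <- surv_grp(c(8, 12, 20), c(TRUE, TRUE, TRUE))
  es <- efs_summary(g, g)
  expect_equal(es$efs_t_minus_c, 0)
  expect_equal(es$efs_t_over_c, 1)
  expect_equal(es$p_value, 1)
})

test_that("Peto-Peto test matches the independent oracle and brute force", {
  ctrl <- surv_grp(c(5, 6, 7), c(TRUE, TRUE, TRUE))
  trt <- surv_grp(c(20, 25, 30), c(TRUE, TRUE, TRUE))

  t_asym <- peto_peto_test(ctrl, trt)
  expect_equal(t_asym$statistic, 1.5 / sqrt(0.5))
  expect_equal(t_asym$p_value, 2 * pnorm(-1.5 / sqrt(0.5)))

  # complete separation at 3 vs 3: exact permutation p = 2/20
  t_ex <- peto_peto_test(ctrl, trt, method = "exact_permutation")
  expect_equal(t_ex$p_value, 0.1)

  # antisymmetry under group swap
  t_swap <- peto_peto_test(trt, ctrl)
  expect_equal(t_swap$statistic, -t_asym$statistic)
  expect_equal(t_swap$p_value, t_asym$p_value)

  # no events -> p = 1 with warning
  expect_warning(
    t0 <- peto_peto_test(surv_grp(c(10, 20), c(FALSE, FALSE)),
                         surv_grp(c(15, 25), c(FALSE, FALSE))),
    class = "xt_no_events")
  expect_equal(t0$p_value, 1)

  # statistic and exact p agree with the independently coded oracle on
  # randomized small fixtures with censoring and ties
  set.seed(12)
  for (i in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    times <- sample(1:12, na + nb, replace = TRUE)
    events <- runif(na + nb) < 0.8
    if (!any(events)) events[1] <- TRUE
    a <- surv_grp(times[1:na], events[1:na])
    b <- surv_grp(times[(na + 1):(na + nb)], events[(na + 1):(na + nb)])
    in_a <- c(rep(TRUE, na), rep(FALSE, nb))
    expect_equal(peto_peto_test(a, b)$statistic,
                 oracle_peto_z(times, events, in_a))
    expect_equal(peto_peto_test(a, b, method = "exact_permutation")$p_value,
                 oracle_peto_exact_p(times, events, in_a))
  }
})

test_that("Peto-Peto statistic agrees with survdiff(rho = 1) on untied data", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(6:10, 1)
    times <- sample(seq(2, 90, by = 2), n)
    events <- runif(n) < 0.8
    if (sum(events) < 2) events[1:2] <- TRUE
    grp <- runif(n) < 0.5
    if (all(grp) || !any(grp)) grp[1] <- !grp[1]
    sd1 <- survival::survdiff(survival::Surv(times, events) ~ grp, rho = 1)
    z <- peto_peto_test(surv_grp(times[grp], events[grp]),
                        surv_grp(times[!grp], events[!grp]))$statistic
    expect_equal(z^2, unname(sd1$chisq), tolerance = 1e-8)
  }
})

test_that("without censoring the Peto-Peto ordering matches Gehan/Mann-Whitney", {
  # all 10 splits of 5 distinct times into groups of 2 and 3
  times <- c(3, 8, 15, 27, 41)
  splits <- utils::combn(5, 2)
  # weighted log-rank numerator (O - E with left-continuous KM weights),
  # computed from first principles for distinct all-event times
  peto_u <- function(in_a) {
    n <- 5
    sum(vapply(1:n, function(j) {
      (n - j + 1) / n * (in_a[j] - sum(in_a[j:n]) / (n - j + 1))
    }, numeric(1)))
  }
  ord <- order(times)
  u <- apply(splits, 2, function(idx) peto_u(ord %in% idx))
  mw <- apply(splits, 2, function(idx) {
    sum(outer(times[idx], times[-idx], ">")) # Mann-Whitney U of group A
  })
  # pairwise agreement: large Mann-Whitney U of group A (late times) means a
  # small weighted log-rank score, dataset for dataset, ties included
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(sign(round(u[i] - u[j], 9)), -sign(mw[i] - mw[j]))
  }
  # the package statistic reproduces the independent oracle on each split
  pkg_z <- apply(splits, 2, function(idx) {
    peto_peto_test(surv_grp(times[idx], rep(TRUE, 2)),
                   surv_grp(times[-idx], rep(TRUE, 3)))$statistic
  })
  orc_z <- apply(splits, 2, function(idx) {
    oracle_peto_z(times, rep(TRUE, 5), seq_len(5) %in% idx)
  })
  expect_equal(pkg_z, orc_z)
})
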