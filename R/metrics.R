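## Tumor-growth-inhibition, body-weight change and small-sample two-group
## comparisons.

#' Percent tumor growth inhibition
#'
#' `%TGI = ((TVvehicle_last - TVvehicle_day0) - (TVtreated_last -
#' TVtreated_day0)) / (TVvehicle_last - TVvehicle_day0) * 100`, computed on
#' group mean volumes. Values above 100% indicate net regression of the
#' treated tumors. Undefined when the vehicle arm did not grow.
#'
#' @param tv_vehicle_last,tv_vehicle_day0 Vehicle-arm mean volumes, mm^3.
#' @param tv_treated_last,tv_treated_day0 Treated-arm mean volumes, mm^3.
#' @return %TGI.
#' @export
tgi <- function(tv_vehicle_last, tv_vehicle_day0, tv_treated_last,
                tv_treated_day0) {
  dv <- tv_vehicle_last - tv_vehicle_day0
  if (!is.finite(dv) || dv <= 0) {
    xt_stop("TGI undefined: vehicle arm net change is not positive",
            "xt_domain_error")
  }
  dt <- tv_treated_last - tv_treated_day0
  (dv - dt) / dv * 100
}

#' Percent tumor growth inhibition from study records
#'
#' Computes arm-mean volumes at day 0 and at the latest day on which every
#' vehicle-arm mouse still has a measurement (or `last_day` if given), then
#' applies [tgi()].
#'
#' @param records List of [mouse_record()].
#' @param vehicle_arm,treated_arm Arm labels.
#' @param last_day Optional override of the "last" day.
#' @return List: `tgi_pct`, `last_day`.
#' @export
tgi_from_study <- function(records, vehicle_arm, treated_arm, last_day = NULL) {
  arms <- vapply(records, `[[`, character(1), "arm")
  veh <- records[arms == vehicle_arm]
  trt <- records[arms == treated_arm]
  if (!length(veh) || !length(trt)) {
    xt_stop("vehicle or treated arm not found", "xt_validation_error")
  }
  if (is.null(last_day)) {
    last_day <- min(vapply(veh, function(r) max(r$volumes$day), numeric(1)))
  }
  mean_at <- function(rs, day) {
    mean(vapply(rs, function(r) {
      v <- r$volumes[r$volumes$day <= day, ]
      v$volume[nrow(v)]
    }, numeric(1)))
  }
  list(tgi_pct = tgi(mean_at(veh, last_day), mean_at(veh, 0),
                     mean_at(trt, last_day), mean_at(trt, 0)),
       last_day = last_day)
}

#' Percent body-weight change
#'
#' `%BW = (BW_last - BW_day0) / BW_day0 * 100` on an animal's own weight
#' series (first vs last measurement).
#'
#' @param weights `data.frame(day, weight)` with at least two rows.
#' @return Percent change.
#' @export
pct_bw_change <- function(weights) {
  weights <- weights[order(weights$day), ]
  if (nrow(weights) < 2) xt_stop("need at least two weights", "xt_insufficient_data")
  w0 <- weights$weight[1]
  if (w0 <= 0) xt_stop("baseline weight must be positive", "xt_domain_error")
  (weights$weight[nrow(weights)] - w0) / w0 * 100
}

#' Wilcoxon rank-sum test (exact enumeration or normal approximation)
#'
#' `method = "exact"` enumerates every assignment of the pooled observations
#' to two groups of the observed sizes (feasible at typical xenograft arm
#' sizes) and reports the two-sided probability of a rank sum at least as far
#' from its null mean as observed; ties are handled by midranks. `method =
#' "normal_approx"` uses the tie-corrected normal approximation of
#' [stats::wilcox.test()].
#'
#' @param group_a,group_b Numeric vectors.
#' @param method `"exact"` or `"normal_approx"`.
#' @return Object of class `xeno_test`: `statistic` (rank sum of group A for
#'   exact, z for approximate), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b,
                              method = c("exact", "normal_approx")) {
  method <- match.arg(method)
  na <- length(group_a); nb <- length(group_b)
  if (!na || !nb) xt_stop("both groups must be non-empty", "xt_domain_error")
  pooled <- c(group_a, group_b)
  n <- na + nb
  if (length(unique(pooled)) == 1) {
    xt_warn("all values tied across groups; p = 1", "xt_all_tied")
    return(structure(list(statistic = 0, p_value = 1, method = method,
                          test_name = "Wilcoxon rank sum"), class = "xeno_test"))
  }
  if (method == "exact") {
    if (choose(n, na) > 2e5) {
      xt_stop("exact enumeration infeasible for these group sizes",
              "xt_domain_error")
    }
    rk <- rank(pooled)
    w_obs <- sum(rk[seq_len(na)])
    mu <- na * (n + 1) / 2
    ws <- combn(n, na, function(idx) sum(rk[idx]))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-10)
    structure(list(statistic = w_obs, p_value = p, method = method,
                   test_name = "Wilcoxon rank sum"), class = "xeno_test")
  } else {
    wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                       correct = FALSE))
    z <- qnorm_z_from_p(wt$p.value, sign(wt$statistic - na * nb / 2))
    structure(list(statistic = z, p_value = wt$p.value, method = method,
                   test_name = "Wilcoxon rank sum"), class = "xeno_test")
  }
}

qnorm_z_from_p <- function(p, s) {
  z <- -stats::qnorm(p / 2)
  if (is.na(s) || s == 0) 0 else s * z
}
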