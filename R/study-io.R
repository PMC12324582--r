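## Domain types and delimited-text I/O for longitudinal xenograft studies.
##
## A study is stored long ("tidy"): one row per animal per measurement day,
## because measurement days are not guaranteed to align across mice.

#' Tumor volume from caliper dimensions
#'
#' Converts a length/width caliper reading to a volume using the standard
#' prolate-ellipsoid approximation `0.52 * L * W^2` (mm^3). By convention the
#' length is the larger dimension; if `width > length` the two are swapped and
#' a warning is raised.
#'
#' @param length Tumor length, mm (the larger caliper dimension). Vectorised.
#' @param width Tumor width, mm.
#' @return Tumor volume in mm^3.
#' @examples
#' volume_from_calipers(10, 5) # 130
#' @export
volume_from_calipers <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    xt_stop("caliper dimensions must be positive and finite", "xt_domain_error")
  }
  swap <- width > length
  if (any(swap)) {
    xt_warn("width > length; dimensions swapped (length is the larger axis)",
            "xt_swap_warning")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  0.52 * length * width^2
}

## constructors -------------------------------------------------------------

#' Single-mouse study record
#'
#' Bundles one animal's tumor-volume and body-weight time series with its
#' identifiers and fate. Day 0 is randomization / treatment start; the day-0
#' volume is the baseline V0 used for relative tumor volume and the
#' quadrupling event threshold.
#'
#' @param mouse_id,model_id,arm Character labels.
#' @param volumes `data.frame(day, volume)`, sorted, day 0 present, mm^3.
#' @param weights Optional `data.frame(day, weight)` in grams.
#' @param fate One of `"completed"`, `"tumor_endpoint"`, `"toxic_death"`,
#'   `"other_removal"`.
#' @return An object of class `mouse_record`.
#' @export
mouse_record <- function(mouse_id, model_id, arm, volumes, weights = NULL,
                         fate = "completed") {
  volumes <- as.data.frame(volumes)
  if (!all(c("day", "volume") %in% names(volumes))) {
    xt_stop("volumes needs columns 'day' and 'volume'", "xt_validation_error")
  }
  volumes <- volumes[order(volumes$day), c("day", "volume")]
  if (anyDuplicated(volumes$day)) {
    xt_stop(sprintf("mouse '%s': duplicate measurement day", mouse_id),
            "xt_validation_error")
  }
  if (volumes$day[1] != 0) {
    xt_stop(sprintf("mouse '%s': first measurement must be at day 0", mouse_id),
            "xt_validation_error")
  }
  if (any(volumes$volume < 0) || any(volumes$day < 0)) {
    xt_stop(sprintf("mouse '%s': negative day or volume", mouse_id),
            "xt_validation_error")
  }
  fate <- match.arg(fate, c("completed", "tumor_endpoint", "toxic_death",
                            "other_removal"))
  if (!is.null(weights)) {
    weights <- as.data.frame(weights)[, c("day", "weight")]
    weights <- weights[order(weights$day), ]
    if (any(weights$weight <= 0)) {
      xt_stop(sprintf("mouse '%s': non-positive body weight", mouse_id),
              "xt_validation_error")
    }
  }
  structure(
    list(mouse_id = as.character(mouse_id), model_id = as.character(model_id),
         arm = as.character(arm), volumes = volumes, weights = weights,
         fate = fate, fate_day = max(volumes$day)),
    class = "mouse_record")
}

#' @export
print.mouse_record <- function(x, ...) {
  cat(sprintf("<mouse_record> %s  model=%s arm=%s  %d measurements, fate=%s (day %g)\n",
              x$mouse_id, x$model_id, x$arm, nrow(x$volumes), x$fate, x$fate_day))
  invisible(x)
}

#' Treatment-arm design
#'
#' @param arm Arm label.
#' @param dosing_windows List of `c(start, end)` half-open day intervals during
#'   which drug chow is given; empty for control arms.
#' @param treated Logical; defaults to `TRUE` iff any dosing window is given.
#' @return An object of class `arm_design`.
#' @export
arm_design <- function(arm, dosing_windows = list(),
                       treated = length(dosing_windows) > 0) {
  dosing_windows <- lapply(dosing_windows, as.numeric)
  if (length(dosing_windows)) {
    ok <- vapply(dosing_windows, function(w) length(w) == 2 && w[1] < w[2],
                 logical(1))
    if (!all(ok)) xt_stop("each dosing window must be c(start, end), start < end",
                          "xt_validation_error")
    o <- order(vapply(dosing_windows, `[`, numeric(1), 1))
    dosing_windows <- dosing_windows[o]
    starts <- vapply(dosing_windows, `[`, numeric(1), 1)
    ends <- vapply(dosing_windows, `[`, numeric(1), 2)
    if (any(starts[-1] < ends[-length(ends)])) {
      xt_stop("dosing windows overlap", "xt_validation_error")
    }
  }
  if (!treated && length(dosing_windows)) {
    xt_stop("untreated arm cannot have dosing windows", "xt_validation_error")
  }
  structure(list(arm = as.character(arm), treated = isTRUE(treated),
                 dosing_windows = dosing_windows),
            class = "arm_design")
}

#' Study design
#'
#' Endpoint and analysis-window settings for one xenograft model study.
#' Defaults follow common practice for subcutaneous xenograft panels: endpoint
#' at 2000 mm^3 (2 cm^3) or day 70, response window 42 days (end of continuous
#' dosing), and a tumor counted as "not measurable" when its recorded volume is
#' at or below `detection_limit` (default 0, i.e. recorded zeros).
#'
#' @param model_id Model label.
#' @param arms List of [arm_design()] objects.
#' @param endpoint_volume Tumor-volume endpoint, mm^3.
#' @param max_day Maximum follow-up day.
#' @param response_window_end End of the response-evaluation window, days.
#' @param detection_limit Volume at or below which a tumor is not measurable.
#' @return Object of class `study_design`.
#' @export
study_design <- function(model_id = "model",
                         arms = list(arm_design("vehicle"),
                                     arm_design("treated",
                                                dosing_windows = list(c(0, 42)))),
                         endpoint_volume = 2000, max_day = 70,
                         response_window_end = 42, detection_limit = 0) {
  if (endpoint_volume <= 0) xt_stop("endpoint_volume must be > 0", "xt_validation_error")
  if (!(response_window_end > 0 && response_window_end <= max_day)) {
    xt_stop("need 0 < response_window_end <= max_day", "xt_validation_error")
  }
  stopifnot(all(vapply(arms, inherits, logical(1), "arm_design")))
  names(arms) <- vapply(arms, `[[`, character(1), "arm")
  structure(list(model_id = as.character(model_id), arms = arms,
                 endpoint_volume = endpoint_volume, max_day = max_day,
                 response_window_end = response_window_end,
                 detection_limit = detection_limit),
            class = "study_design")
}

## readers ------------------------------------------------------------------

#' Read a longitudinal study table (and optional design) from delimited text
#'
#' The measurement table is CSV with header and required columns `mouse_id`,
#' `model_id`, `arm`, `day`, `volume`; optional `weight` (g) and `fate`.
#' The design file may be YAML (fields of [study_design()], arms with
#' `dosing_windows` as start/end pairs) or CSV (one row per arm/window with
#' columns `arm`, `treated`, `window_start`, `window_end`). When no design is
#' given, arms whose label matches "vehicle" or "control" (case-insensitively)
#' become the untreated arm and all others get a continuous [0, 42) window.
#'
#' @param table_path Path to the measurement CSV.
#' @param design_path Optional path to a YAML/CSV design file.
#' @return A list with elements `design` ([study_design()]) and `records`
#'   (list of [mouse_record()]), of class `xeno_study`.
#' @export
read_study <- function(table_path, design_path = NULL) {
  df <- read.csv(table_path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "model_id", "arm", "day", "volume")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    xt_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")), "xt_format_error")
  }
  records <- records_from_long(df)
  design <- if (is.null(design_path)) {
    default_design_for(df)
  } else {
    read_design(design_path)
  }
  structure(list(design = design, records = records), class = "xeno_study")
}

records_from_long <- function(df) {
  df <- df[order(df$mouse_id, df$day), ]
  lapply(split(df, df$mouse_id), function(d) {
    weights <- NULL
    if ("weight" %in% names(d) && any(!is.na(d$weight))) {
      weights <- data.frame(day = d$day[!is.na(d$weight)],
                            weight = d$weight[!is.na(d$weight)])
    }
    fate <- "completed"
    if ("fate" %in% names(d)) {
      f <- d$fate[!is.na(d$fate) & nzchar(d$fate)]
      if (length(f)) fate <- f[length(f)]
    }
    mouse_record(d$mouse_id[1], d$model_id[1], d$arm[1],
                 volumes = d[, c("day", "volume")], weights = weights,
                 fate = fate)
  })
}

default_design_for <- function(df) {
  arms <- unique(df$arm)
  ctrl <- grepl("vehicle|control", arms, ignore.case = TRUE)
  if (!any(ctrl)) ctrl[1] <- TRUE
  study_design(
    model_id = df$model_id[1],
    arms = lapply(seq_along(arms), function(i) {
      if (ctrl[i]) arm_design(arms[i])
      else arm_design(arms[i], dosing_windows = list(c(0, 42)))
    }))
}

#' Read a study design from YAML or CSV
#'
#' @param path Design file; `.yaml`/`.yml` or `.csv`.
#' @return A [study_design()].
#' @export
read_design <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    arms <- lapply(y$arms, function(a) {
      arm_design(a$arm,
                 dosing_windows = lapply(a$dosing_windows, unlist),
                 treated = a$treated %||% (length(a$dosing_windows) > 0))
    })
    study_design(model_id = y$model_id %||% "model", arms = arms,
                 endpoint_volume = y$endpoint_volume %||% 2000,
                 max_day = y$max_day %||% 70,
                 response_window_end = y$response_window_end %||% 42,
                 detection_limit = y$detection_limit %||% 0)
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE)
    arms <- lapply(split(d, d$arm), function(a) {
      treated <- isTRUE(as.logical(a$treated[1]))
      wins <- list()
      if (treated && "window_start" %in% names(a)) {
        ok <- !is.na(a$window_start)
        wins <- lapply(which(ok), function(i) c(a$window_start[i], a$window_end[i]))
      }
      arm_design(a$arm[1], dosing_windows = wins, treated = treated)
    })
    study_design(model_id = if ("model_id" %in% names(d)) d$model_id[1] else "model",
                 arms = unname(arms))
  }
}

## writers ------------------------------------------------------------------

#' Write study records back to the long CSV dialect
#'
#' Inverse of [read_study()]: parsing then serializing reproduces the table up
#' to column order and float formatting.
#'
#' @param records List of [mouse_record()] (or an `xeno_study`).
#' @param path Output CSV path.
#' @export
write_study <- function(records, path) {
  if (inherits(records, "xeno_study")) records <- records$records
  rows <- lapply(records, function(r) {
    d <- data.frame(mouse_id = r$mouse_id, model_id = r$model_id, arm = r$arm,
                    day = r$volumes$day, volume = r$volumes$volume,
                    weight = NA_real_, fate = "", stringsAsFactors = FALSE)
    if (!is.null(r$weights)) {
      m <- match(d$day, r$weights$day)
      d$weight <- r$weights$weight[m]
    }
    d$fate[nrow(d)] <- r$fate
    d
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.xeno_study <- function(x, ...) {
  cat(sprintf("<xeno_study> model %s: %d mice in %d arms (%s)\n",
              x$design$model_id, length(x$records), length(x$design$arms),
              paste(names(x$design$arms), collapse = ", ")))
  invisible(x)
}
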