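#' Normalize a series to the noleap calendar
#'
#' Removes every Feb 29 step so each year contributes exactly 365 days
#' (2920 steps at 3 h, 8760 at 1 h), the convention of climate-model
#' output. Non-leap years pass through unchanged.
#'
#' @param x a [meteo_series()], [indoor_series()] or any data.frame with a
#'   POSIXct `timestamp` column.
#' @return the same object with Feb 29 removed and calendar `"noleap"`.
#' @export
to_noleap <- function(x) {
  stopifnot(is.data.frame(x), "timestamp" %in% names(x))
  feb29 <- format(x$timestamp, "%m-%d", tz = "UTC") == "02-29"
  out <- x[!feb29, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "step_hours") <- attr(x, "step_hours")
  attr(out, "calendar") <- "noleap"
  class(out) <- class(x)
  out
}

#' Exceedance hours per year
#'
#' Counts the steps at or above the threshold per calendar year and
#' converts to hours by multiplying with the step width (a 3-h series value
#' counts as three hours). Returns the mean over years.
#'
#' @param values numeric series (e.g. `T_i` or `PET_i`).
#' @param timestamps POSIXct timestamps, noleap-normalized.
#' @param threshold inclusive threshold (degC): counted when
#'   `value >= threshold`.
#' @param step_hours step width, 1 or 3 (other values need
#'   `allow_any_step = TRUE`).
#' @param allow_any_step permit non-standard steps.
#' @return mean exceedance hours per year; attribute `"per_year"` holds the
#'   per-year values.
#' @export
exceedance_hours_per_year <- function(values, timestamps, threshold,
                                      step_hours, allow_any_step = FALSE) {
  if (!step_hours %in% c(1, 3) && !allow_any_step) {
    stop("step_hours must be 1 or 3 (or set allow_any_step = TRUE)")
  }
  yr <- ts_year(timestamps)
  per_year <- vapply(split(values, yr),
                     function(v) sum(v >= threshold) * step_hours,
                     numeric(1))
  structure(mean(per_year), per_year = per_year)
}

#' Heat days per year
#'
#' A day is a heat day when its daily maximum meets or exceeds the
#' threshold. Days with an incomplete set of steps (partial first/last
#' days) are excluded and counted in attribute `"excluded_days"`. Returns
#' the mean count over years; the per-day flag vector is exposed for run
#' analysis.
#'
#' @inheritParams exceedance_hours_per_year
#' @param step_hours series step (hours), used to detect partial days.
#' @return mean heat days per year, with attributes `per_year`,
#'   `flags` (data.frame `date`, `year`, `flag`) and `excluded_days`.
#' @export
heat_days_per_year <- function(values, timestamps, threshold, step_hours) {
  date <- ts_date(timestamps)
  per_day <- tapply(values, date, max)
  n_steps <- tapply(values, date, length)
  complete <- n_steps == 24 / step_hours
  flags <- data.frame(date = as.Date(names(per_day)),
                      flag = as.numeric(per_day) >= threshold)
  flags$year <- as.integer(format(flags$date, "%Y"))
  excluded <- sum(!complete)
  flags <- flags[complete, , drop = FALSE]
  per_year <- vapply(split(flags$flag, flags$year), sum, numeric(1))
  structure(mean(per_year), per_year = per_year,
            flags = flags[c("date", "year", "flag")],
            excluded_days = excluded)
}

#' Mean length of consecutive heat-day runs
#'
#' Within each year, maximal runs of consecutive flagged days are extracted
#' and their mean length taken; the cross-year mean is returned. Years
#' without any run contribute 0 by default (`empty_years = "zero"`) or can
#' be excluded (`"exclude"`); `pooled = TRUE` instead averages over all
#' runs of all years together.
#'
#' @param flags logical per-day heat flags (chronological).
#' @param years year of each day.
#' @param empty_years convention for years without runs.
#' @param pooled pool runs across years instead of per-year means.
#' @return mean run length in days.
#' @export
mean_consecutive_run <- function(flags, years,
                                 empty_years = c("zero", "exclude"),
                                 pooled = FALSE) {
  empty_years <- match.arg(empty_years)
  runs_by_year <- lapply(split(flags, years), function(f) {
    r <- rle(f)
    r$lengths[r$values]
  })
  if (pooled) {
    all_runs <- unlist(runs_by_year)
    return(if (length(all_runs) == 0) 0 else mean(all_runs))
  }
  per_year <- vapply(runs_by_year, function(r) {
    if (length(r) == 0) NA_real_ else mean(r)
  }, numeric(1))
  if (empty_years == "zero") per_year[is.na(per_year)] <- 0
  else per_year <- per_year[!is.na(per_year)]
  if (length(per_year) == 0) 0 else mean(per_year)
}

season_of <- function(timestamps) {
  m <- ts_month(timestamps)
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

#' Keep typical working hours
#'
#' Retains steps whose UTC hour lies in the closed interval
#' \[09:00, 18:00\]; at 3-h resolution these are the 09, 12, 15 and 18
#' steps — 4 of the 8 daily steps, 1460 per noleap year.
#'
#' @param x data.frame with a POSIXct `timestamp` column (series objects
#'   pass through with attributes preserved).
#' @return the filtered object.
#' @export
filter_working_hours <- function(x) {
  keep <- ts_hod(x$timestamp) >= 9 & ts_hod(x$timestamp) <= 18
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("step_hours", "calendar")) attr(out, a) <- attr(x, a)
  class(out) <- class(x)
  out
}

#' Stress-class frequency distribution
#'
#' Percentage of steps in each PET stress class, per stratum: the full
#' year, each season (DJF/MAM/JJA/SON) and working hours (09:00-18:00
#' UTC). Percentages within a stratum sum to 100; an empty stratum is
#' reported with `NA` percentages and `n = 0`, not as zeros.
#'
#' @param PET_i numeric PET series (degC).
#' @param timestamps POSIXct timestamps, noleap-normalized.
#' @param strata character subset of
#'   `c("full-year", "DJF", "MAM", "JJA", "SON", "working-hours")`.
#' @return tidy data.frame with columns `stratum`, `class`, `pct`, `n`.
#' @export
stress_frequency <- function(PET_i, timestamps,
                             strata = c("full-year", "DJF", "MAM", "JJA",
                                        "SON", "working-hours")) {
  strata <- match.arg(strata, several.ok = TRUE)
  cls <- classify_pet(PET_i)
  season <- season_of(timestamps)
  hod <- ts_hod(timestamps)
  sel <- list(
    "full-year" = rep(TRUE, length(PET_i)),
    "DJF" = season == "DJF", "MAM" = season == "MAM",
    "JJA" = season == "JJA", "SON" = season == "SON",
    "working-hours" = hod >= 9 & hod <= 18
  )
  out <- do.call(rbind, lapply(strata, function(st) {
    keep <- sel[[st]]
    n <- sum(keep)
    pct <- if (n == 0) rep(NA_real_, nlevels(cls)) else {
      as.numeric(table(cls[keep])) / n * 100
    }
    data.frame(stratum = st, class = levels(cls), pct = pct, n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Exposure statistics for one period
#'
#' Bundles the exposure metrics for one variable over one period: per
#' threshold the mean exceedance hours/year, heat days/year and mean
#' consecutive-run length, plus overall/DJF/JJA means and (for `PET_i`)
#' the stress-class frequency distribution.
#'
#' @param values numeric series.
#' @param timestamps POSIXct, noleap.
#' @param variable `"T_i"` or `"PET_i"` (selects the threshold set:
#'   26/30/35 for `T_i`; 23/29/35/41 for `PET_i`).
#' @param step_hours series step.
#' @param period label for the report.
#' @return a `heat_metrics_report` list with elements `period`, `variable`,
#'   `n_years`, `means`, `thresholds` (data.frame) and `stress_freq`.
#' @export
heat_metrics_report <- function(values, timestamps, variable = c("T_i", "PET_i"),
                                step_hours, period = "historical") {
  variable <- match.arg(variable)
  thresholds <- if (variable == "T_i") c(26, 30, 35) else c(23, 29, 35, 41)
  season <- season_of(timestamps)
  tab <- do.call(rbind, lapply(thresholds, function(thr) {
    hrs <- exceedance_hours_per_year(values, timestamps, thr, step_hours)
    hd <- heat_days_per_year(values, timestamps, thr, step_hours)
    fl <- attr(hd, "flags")
    run <- mean_consecutive_run(fl$flag, fl$year)
    data.frame(threshold = thr, hours_per_year = as.numeric(hrs),
               heat_days_per_year = as.numeric(hd),
               mean_run_days = run)
  }))
  means <- c(overall = mean(values),
             DJF = mean(values[season == "DJF"]),
             JJA = mean(values[season == "JJA"]))
  rep <- list(period = period, variable = variable,
              n_years = length(unique(ts_year(timestamps))),
              means = means, thresholds = tab,
              stress_freq = if (variable == "PET_i") {
                stress_frequency(values, timestamps)
              } else NULL)
  class(rep) <- "heat_metrics_report"
  rep
}

#' Write a heat-metrics report as tidy CSV
#'
#' One row per period x threshold x metric; stress-class frequencies are
#' appended with their stratum.
#'
#' @param report a `heat_metrics_report`.
#' @param path file path.
#' @export
write_metrics_csv <- function(report, path) {
  thr <- report$thresholds
  rows <- data.frame(
    period = report$period, variable = report$variable,
    threshold = rep(thr$threshold, 3),
    stratum = "full-year",
    metric = rep(c("hours_per_year", "heat_days_per_year", "mean_run_days"),
                 each = nrow(thr)),
    value = c(thr$hours_per_year, thr$heat_days_per_year, thr$mean_run_days)
  )
  rows <- rbind(rows, data.frame(
    period = report$period, variable = report$variable, threshold = NA,
    stratum = names(report$means), metric = "mean",
    value = as.numeric(report$means)
  ))
  if (!is.null(report$stress_freq)) {
    sf <- report$stress_freq
    rows <- rbind(rows, data.frame(
      period = report$period, variable = report$variable, threshold = NA,
      stratum = sf$stratum, metric = paste0("pct_", sf$class),
      value = sf$pct
    ))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
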