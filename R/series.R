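#' Meteorological and indoor series containers
#'
#' A `meteo_series` is a data.frame with a UTC `timestamp` column at a regular
#' 1 h or 3 h step and the six outdoor driver variables: air temperature `T_a`
#' (degC, 2 m), dew point `T_d` (degC, 2 m), wind speed `v` (m/s, 10 m),
#' pressure `p` (hPa), global irradiance `G` (W/m2) and long-wave downwelling
#' radiation `A_G` (W/m2). An `indoor_series` holds `T_i` (degC), `RH` (%),
#' globe temperature `T_g` (degC), indoor air speed `v_i` (m/s) and,
#' once filled in, `PET_i` (degC), aligned to the driving outdoor series.
#'
#' @param df data.frame with a POSIXct UTC `timestamp` column and the
#'   variable columns named above.
#' @param step_hours regular step in hours (1 or 3).
#' @param calendar `"standard"` or `"noleap"` (all Feb 29 removed).
#' @return the validated object of class `meteo_series` / `indoor_series`.
#' @name series
NULL

METEO_VARS <- c("T_a", "T_d", "v", "p", "G", "A_G")
INDOOR_VARS <- c("T_i", "RH", "T_g", "v_i")

#' @rdname series
#' @export
meteo_series <- function(df, step_hours, calendar = "standard") {
  obj <- new_series(df, step_hours, calendar, METEO_VARS, "meteo_series")
  validate_meteo_series(obj)
  obj
}

#' @rdname series
#' @export
indoor_series <- function(df, step_hours, calendar = "standard") {
  obj <- new_series(df, step_hours, calendar, INDOOR_VARS, "indoor_series")
  validate_indoor_series(obj)
  obj
}

new_series <- function(df, step_hours, calendar, vars, class) {
  stopifnot(is.data.frame(df), "timestamp" %in% names(df))
  missing <- setdiff(vars, names(df))
  if (length(missing) > 0L) {
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct (UTC)")
  }
  attr(df, "step_hours") <- step_hours
  attr(df, "calendar") <- calendar
  class(df) <- c(class, "ih_series", class(df))
  df
}

step_hours <- function(x) attr(x, "step_hours")
series_calendar <- function(x) attr(x, "calendar")

check_timestamps <- function(x) {
  ts <- as.numeric(x$timestamp)
  d <- diff(ts)
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  step <- step_hours(x) * 3600
  if (identical(series_calendar(x), "standard")) {
    if (any(d != step)) stop("timestamps must have a constant step")
  } else {
    # noleap: gaps of exactly one removed day are allowed
    ok <- d == step | d == step + 86400
    if (!all(ok)) stop("irregular step in noleap series")
  }
  invisible(x)
}

validate_meteo_series <- function(x) {
  check_timestamps(x)
  if (anyNA(x[METEO_VARS])) stop("missing values in meteo series")
  if (any(x$T_d > x$T_a + 1e-9)) stop("invariant violated: T_d > T_a")
  if (any(x$G < 0)) stop("invariant violated: G < 0")
  if (any(x$p <= 0)) stop("invariant violated: p <= 0")
  if (any(x$v < 0)) stop("invariant violated: v < 0")
  if (any(x$A_G <= 0)) stop("invariant violated: A_G <= 0")
  invisible(x)
}

validate_indoor_series <- function(x) {
  check_timestamps(x)
  if (anyNA(x[INDOOR_VARS])) stop("missing values in indoor series")
  if (any(x$RH < 0 | x$RH > 100)) stop("invariant violated: RH outside [0, 100]")
  if (any(x$v_i < 0)) stop("invariant violated: v_i < 0")
  invisible(x)
}

#' @export
print.ih_series <- function(x, ...) {
  cat(sprintf(
    "<%s> %d steps of %g h (%s calendar), %s .. %s\n",
    class(x)[1], nrow(x), step_hours(x), series_calendar(x),
    format(min(x$timestamp), "%Y-%m-%d %H:%M", tz = "UTC"),
    format(max(x$timestamp), "%Y-%m-%d %H:%M", tz = "UTC")
  ))
  NextMethod()
}

#' Read and write series as CSV
#'
#' CSV layout: an ISO-8601 UTC `timestamp` column plus one column per
#' variable. Step and calendar are inferred on read.
#'
#' @param x a `meteo_series` or `indoor_series`.
#' @param path file path.
#' @param type `"meteo"` or `"indoor"`.
#' @return `read_series_csv` returns the series; `write_series_csv` returns
#'   `path` invisibly.
#' @export
write_series_csv <- function(x, path) {
  out <- as.data.frame(x)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, type = c("meteo", "indoor")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  d <- diff(as.numeric(df$timestamp))
  step <- min(d) / 3600
  calendar <- if (any(d > min(d))) "noleap" else "standard"
  if (type == "meteo") meteo_series(df, step, calendar)
  else indoor_series(df, step, calendar)
}

# day-of-year and hour-of-day helpers (UTC)
ts_doy <- function(ts) as.integer(format(ts, "%j", tz = "UTC"))
ts_hod <- function(ts) as.integer(format(ts, "%H", tz = "UTC"))
ts_year <- function(ts) as.integer(format(ts, "%Y", tz = "UTC"))
ts_month <- function(ts) as.integer(format(ts, "%m", tz = "UTC"))
ts_date <- function(ts) as.Date(ts, tz = "UTC")

#' @export
`[.ih_series` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "timestamp" %in% names(out)) {
    attr(out, "step_hours") <- attr(x, "step_hours")
    attr(out, "calendar") <- attr(x, "calendar")
    class(out) <- class(x)
  }
  out
}
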