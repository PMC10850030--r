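#' Outdoor climate generator configuration
#'
#' Parameterises the synthetic outdoor weather generator, which emulates the
#' statistical structure of a reanalysis grid-cell extract for a mid-latitude
#' site: an annual-mean level, seasonal and diurnal sinusoidal cycles, AR(1)
#' noise, a daylight-masked irradiance model and physically consistent
#' couplings (dew point generated as air temperature minus a non-negative
#' depression; long-wave downwelling radiation coupled to air temperature).
#'
#' Each variable entry is a list of: `mean` (annual mean in variable units),
#' `seasonal_amp` and `diurnal_amp` (cosine amplitudes), `ar` (per-step AR(1)
#' coefficient in \[0, 1)), `sd` (innovation standard deviation). `T_d` is
#' driven by a depression (K below `T_a`, floored at 0); `G` by a peak
#' clear-sky irradiance `peak` minus seasonal modulation, with multiplicative
#' noise `sd_frac`; `A_G` additionally couples to the `T_a` anomaly with
#' slope `coef_T` (W/m2/K).
#'
#' @param step_hours series step, 1 or 3 hours.
#' @param span_years number of years generated (>= 1).
#' @param start first timestamp (UTC midnight of this date).
#' @param seed integer seed; identical config + seed gives identical output.
#' @param calendar `"standard"` (default) or `"noleap"`.
#' @param T_a,T_d,v,p,G,A_G per-variable parameter lists (see Details).
#' @param solar list: `peak_doy` (warmest day of year), `peak_hod` (warmest
#'   hour), `half_width` and `half_width_amp` (hours) defining the seasonal
#'   daylight half-window around solar noon.
#' @return an `outdoor_climate_config` list.
#' @export
outdoor_climate_config <- function(step_hours = 3, span_years = 1,
                                   start = "1970-01-01", seed = 1,
                                   calendar = "standard",
                                   T_a = list(), T_d = list(), v = list(),
                                   p = list(), G = list(), A_G = list(),
                                   solar = list()) {
  if (!step_hours %in% c(1, 3)) stop("step_hours must be 1 or 3")
  if (span_years < 1) stop("span_years must be >= 1")
  defaults <- list(
    T_a = list(mean = 10.5, seasonal_amp = 9, diurnal_amp = 4, ar = 0.8, sd = 1.0),
    T_d = list(depression_mean = 4, seasonal_amp = 1.5, ar = 0.8, sd = 0.8),
    v = list(mean = 2.5, diurnal_amp = 0.8, ar = 0.7, sd = 0.8),
    p = list(mean = 1005, seasonal_amp = 3, ar = 0.9, sd = 1.5),
    G = list(peak = 800, seasonal_amp = 350, sd_frac = 0.15),
    A_G = list(mean = 310, seasonal_amp = 40, coef_T = 3, ar = 0.8, sd = 8),
    solar = list(peak_doy = 197, peak_hod = 15, half_width = 6, half_width_amp = 2)
  )
  user <- list(T_a = T_a, T_d = T_d, v = v, p = p, G = G, A_G = A_G,
               solar = solar)
  vars <- lapply(names(defaults), function(nm) {
    utils::modifyList(defaults[[nm]], user[[nm]])
  })
  names(vars) <- names(defaults)
  for (nm in c("T_a", "T_d", "v", "p", "A_G")) {
    amp <- unlist(vars[[nm]][grepl("amp", names(vars[[nm]]))])
    if (any(amp < 0)) stop("amplitudes must be >= 0 (", nm, ")")
    if (vars[[nm]]$ar < 0 || vars[[nm]]$ar >= 1) {
      stop("AR coefficient must be in [0, 1) (", nm, ")")
    }
  }
  structure(c(list(step_hours = step_hours, span_years = span_years,
                   start = start, seed = seed, calendar = calendar), vars),
            class = "outdoor_climate_config")
}

# cosine seasonal cycle, +1 at peak_doy
seasonal_cycle <- function(doy, peak_doy) cos(2 * pi * (doy - peak_doy) / 365)

# cosine diurnal cycle, +1 at peak_hod
diurnal_cycle <- function(hod, peak_hod) cos(2 * pi * (hod - peak_hod) / 24)

# seasonal daylight half-window (hours around solar noon at 12 UTC)
daylight_half_width <- function(doy, solar) {
  pmax(0.5, solar$half_width + solar$half_width_amp *
         seasonal_cycle(doy, solar$peak_doy))
}

ar1_noise <- function(n, ar, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  e <- stats::rnorm(n, sd = sd)
  if (ar == 0) return(e)
  as.numeric(stats::filter(e, ar, method = "recursive"))
}

#' Generate a synthetic outdoor weather series
#'
#' @param cfg an [outdoor_climate_config()].
#' @return a [meteo_series()] satisfying all container invariants
#'   (strictly increasing regular timestamps, `T_d <= T_a`, `G >= 0` with
#'   nighttime zeros, `p > 0`, `v >= 0`, `A_G > 0`, no missing values).
#' @export
generate_outdoor_series <- function(cfg) {
  stopifnot(inherits(cfg, "outdoor_climate_config"))
  set.seed(cfg$seed)
  start <- as.POSIXct(paste0(cfg$start, " 00:00:00"), tz = "UTC")
  n_days <- round(cfg$span_years * 365.25)
  n <- as.integer(n_days * 24 / cfg$step_hours)
  ts <- start + (seq_len(n) - 1) * cfg$step_hours * 3600
  doy <- ts_doy(ts)
  hod <- ts_hod(ts)
  seas <- seasonal_cycle(doy, cfg$solar$peak_doy)
  diur <- diurnal_cycle(hod, cfg$solar$peak_hod)

  T_a <- cfg$T_a$mean + cfg$T_a$seasonal_amp * seas +
    cfg$T_a$diurnal_amp * diur + ar1_noise(n, cfg$T_a$ar, cfg$T_a$sd)

  depression <- pmax(0, cfg$T_d$depression_mean +
                       cfg$T_d$seasonal_amp * seas +
                       ar1_noise(n, cfg$T_d$ar, cfg$T_d$sd))
  T_d <- T_a - depression

  v <- pmax(0, cfg$v$mean + cfg$v$diurnal_amp * diur +
              ar1_noise(n, cfg$v$ar, cfg$v$sd))

  p <- cfg$p$mean + cfg$p$seasonal_amp * seas +
    ar1_noise(n, cfg$p$ar, cfg$p$sd)

  # irradiance: cosine hump inside the seasonal daylight window, else 0
  hw <- daylight_half_width(doy, cfg$solar)
  in_day <- abs(hod - 12) < hw
  shape <- ifelse(in_day, cos(pi * (hod - 12) / (2 * hw)), 0)
  peak <- pmax(0, cfg$G$peak - cfg$G$seasonal_amp * (1 - seas) / 2)
  noise_mult <- if (cfg$G$sd_frac > 0) {
    pmax(0, 1 + stats::rnorm(n, sd = cfg$G$sd_frac))
  } else 1
  G <- peak * shape * noise_mult
  G[!in_day] <- 0

  A_G <- cfg$A_G$mean + cfg$A_G$seasonal_amp * seas +
    cfg$A_G$coef_T * (T_a - cfg$T_a$mean - cfg$T_a$seasonal_amp * seas) +
    ar1_noise(n, cfg$A_G$ar, cfg$A_G$sd)
  A_G <- pmax(1, A_G)

  out <- data.frame(timestamp = ts, T_a = T_a, T_d = T_d, v = v, p = p,
                    G = G, A_G = A_G)
  s <- meteo_series(out, cfg$step_hours, "standard")
  if (identical(cfg$calendar, "noleap")) s <- to_noleap(s)
  s
}

#' Climate scenario configuration
#'
#' Describes an imposed change relative to the base climate of a generated
#' series, emulating one member of a downscaled projection ensemble under a
#' forcing pathway (RCP2.6 / RCP4.5 / RCP8.5). Three additive components per
#' variable, all defaulting to 0:
#'
#' * `bias` — static model bias, present in historical and future model
#'   worlds alike (what bias correction must remove);
#' * `offset` — warming already realised before the series window (uniform
#'   shift; the climate-change signal for a late-century window);
#' * `trend` — total change accrued linearly across the series window
#'   (ramp from 0 at the first step to `trend` at the last).
#'
#' For the zero-bounded variables `G` and `v` the three components are
#' interpreted as relative fractions and applied multiplicatively, which
#' preserves nighttime zeros and non-negativity.
#'
#' `seasonal_mod` scales the warming term (`offset` + ramp) by
#' `1 + seasonal_mod * cos(seasonal cycle)`, giving extra summer warming for
#' positive values.
#'
#' @param label scenario family label, e.g. `"RCP8.5"`.
#' @param member ensemble member id.
#' @param bias,offset,trend named numeric vectors over the meteo variables
#'   (unnamed scalars are applied to `T_a` only).
#' @param seasonal_mod seasonal modulation fraction of the warming term.
#' @param seed member seed (reserved; scenario application is deterministic).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(label, member = 1L, bias = 0, offset = 0,
                            trend = 0, seasonal_mod = 0, seed = 1L) {
  if (!nzchar(label)) stop("label must be nonempty")
  expand <- function(x) {
    full <- stats::setNames(numeric(length(METEO_VARS)), METEO_VARS)
    if (is.null(names(x))) {
      if (length(x) != 1) stop("unnamed scenario vectors must be scalar")
      full["T_a"] <- x
    } else {
      bad <- setdiff(names(x), METEO_VARS)
      if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
      full[names(x)] <- x
    }
    if (any(!is.finite(full))) stop("scenario changes must be finite")
    full
  }
  structure(list(label = label, member = as.integer(member),
                 bias = expand(bias), offset = expand(offset),
                 trend = expand(trend), seasonal_mod = seasonal_mod,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Apply a climate scenario to an outdoor series
#'
#' Adds the scenario's static bias, realised offset and linear within-window
#' ramp to each variable (multiplicatively for `G` and `v`; see
#' [scenario_config()]). For a linear ramp the mean difference to the input
#' equals `bias + offset + trend / 2`. Physical invariants are re-imposed
#' afterwards (`T_d` clipped to `T_a`, `v` and `G` floored at 0).
#'
#' @param series a [meteo_series()].
#' @param scenario a [scenario_config()].
#' @return a new `meteo_series` with the imposed change.
#' @export
apply_climate_scenario <- function(series, scenario) {
  stopifnot(inherits(series, "meteo_series"),
            inherits(scenario, "scenario_config"))
  n <- nrow(series)
  u <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  seas_w <- 1 + scenario$seasonal_mod *
    seasonal_cycle(ts_doy(series$timestamp), 197)
  out <- series
  mult_vars <- c("G", "v")
  for (var in METEO_VARS) {
    warming <- (scenario$offset[var] + scenario$trend[var] * u) * seas_w
    if (var %in% mult_vars) {
      out[[var]] <- series[[var]] * (1 + scenario$bias[var]) * (1 + warming)
    } else {
      out[[var]] <- series[[var]] + scenario$bias[var] + warming
    }
  }
  out$T_d <- pmin(out$T_d, out$T_a)
  out$v <- pmax(out$v, 0)
  out$G <- pmax(out$G, 0)
  out$A_G <- pmax(out$A_G, 1)
  validate_meteo_series(out)
  out
}
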