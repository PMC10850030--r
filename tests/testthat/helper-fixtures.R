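# Shared fixtures built in code.

# a fully deterministic, cycle-free generator config
flat_config <- function(...) {
  outdoor_climate_config(
    T_a = list(seasonal_amp = 0, diurnal_amp = 0, ar = 0, sd = 0),
    T_d = list(seasonal_amp = 0, ar = 0, sd = 0),
    v = list(diurnal_amp = 0, ar = 0, sd = 0),
    p = list(seasonal_amp = 0, ar = 0, sd = 0),
    G = list(peak = 0, seasonal_amp = 0, sd_frac = 0),
    A_G = list(seasonal_amp = 0, coef_T = 0, ar = 0, sd = 0),
    ...
  )
}

# hand-built constant outdoor series (bypasses the generator)
constant_series <- function(n, step = 3, T_a = 10, T_d = 6, v = 1, p = 1000,
                            G = 0, A_G = 300, start = "2001-01-01") {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = step * 3600, length.out = n)
  meteo_series(data.frame(timestamp = ts, T_a = T_a, T_d = T_d, v = v,
                          p = p, G = G, A_G = A_G), step)
}

# brute-force exposure oracles (independent of the package implementations)
brute_exceedance_hours <- function(values, years, thr, step) {
  mean(vapply(split(values, years),
              function(v) sum(vapply(v, function(x) x >= thr, logical(1))) * step,
              numeric(1)))
}

brute_heat_day_flags <- function(values, dates, thr) {
  ud <- unique(dates)
  vapply(ud, function(d) max(values[dates == d]) >= thr, logical(1))
}

brute_mean_run <- function(flags, years) {
  per_year <- vapply(unique(years), function(y) {
    f <- flags[years == y]
    runs <- integer(0); cur <- 0L
    for (x in f) {
      if (x) cur <- cur + 1L
      else if (cur > 0) { runs <- c(runs, cur); cur <- 0L }
    }
    if (cur > 0) runs <- c(runs, cur)
    if (length(runs) == 0) 0 else mean(runs)
  }, numeric(1))
  mean(per_year)
}
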