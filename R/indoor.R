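#' Building response parameters
#'
#' Single-node first-order thermal model of a workplace room. The indoor air
#' temperature follows
#' \deqn{dT_i/dt = (T_a - T_i)/\tau + a G + q(t) + \max(0, k (T_{set} - T_i))}
#' i.e. relaxation towards outdoor temperature with time constant `tau`,
#' solar gain proportional to global irradiance, an internal-gain schedule,
#' and proportional heating towards a setpoint when fitted.
#'
#' @param tau thermal time constant (h), > 0. Heavy construction = large.
#' @param a solar-gain coefficient (K/h per W/m2), >= 0.
#' @param q_base baseline internal gain (K/h), e.g. appliances.
#' @param q_work additional internal gain during occupancy hours (K/h).
#' @param work_hours integer hours of day (UTC) with occupancy gains.
#' @param T_set heating setpoint (degC) or `NA` for an unheated building.
#' @param k heating gain (1/h), >= 0; ignored when `T_set` is `NA`.
#' @param v_i constant indoor air speed (m/s); 0.1 is the standard
#'   still-indoor-air assumption used when no air-speed sensor is present.
#' @param c_g globe-temperature radiant coefficient (K per W/m2): the globe
#'   reads `T_i + c_g * G`, emulating radiant load on a near-window sensor.
#' @param noise_sd white measurement/process noise on indoor channels (K).
#' @return a `building_parameters` list.
#' @export
building_parameters <- function(tau = 40, a = 1e-4, q_base = 0.02,
                                q_work = 0.05, work_hours = 8:17,
                                T_set = NA_real_, k = 0.5, v_i = 0.1,
                                c_g = 0.004, noise_sd = 0.3) {
  if (tau <= 0) stop("tau must be > 0")
  if (a < 0) stop("a must be >= 0")
  if (k < 0) stop("k must be >= 0")
  if (v_i < 0) stop("v_i must be >= 0")
  structure(list(tau = tau, a = a, q_base = q_base, q_work = q_work,
                 work_hours = as.integer(work_hours), T_set = T_set, k = k,
                 v_i = v_i, c_g = c_g, noise_sd = noise_sd),
            class = "building_parameters")
}

#' Simulate indoor conditions from outdoor weather
#'
#' Integrates the single-node building model of [building_parameters()] over
#' an outdoor [meteo_series()] by explicit Euler with internal sub-stepping:
#' the sub-step is chosen `<= min(tau, 1/(1/tau + k)) / 2`, so any `tau > 0`
#' is integrated stably regardless of the series step (outdoor forcing is
#' held constant within each outer step). With `substeps = FALSE` the series
#' step itself is used and a step exceeding `tau` is rejected as unstable.
#'
#' Indoor relative humidity conserves the outdoor vapour pressure (from the
#' outdoor dew point) re-evaluated at `T_i`, clipped to \[5, 100\] %. The
#' globe channel reads `T_i + c_g * G`; indoor air speed is constant `v_i`.
#' `PET_i` is left `NA` until filled by [add_pet()].
#'
#' @param series outdoor [meteo_series()].
#' @param bld [building_parameters()].
#' @param seed integer seed for the indoor noise channels.
#' @param T_i0 initial indoor temperature (default: setpoint if heated, else
#'   first outdoor temperature).
#' @param substeps use stabilising sub-stepping (default `TRUE`).
#' @return an [indoor_series()] aligned to `series`.
#' @export
simulate_indoor <- function(series, bld, seed = 1L, T_i0 = NULL,
                            substeps = TRUE) {
  stopifnot(inherits(series, "meteo_series"),
            inherits(bld, "building_parameters"))
  dt <- step_hours(series)
  heated <- !is.na(bld$T_set)
  rate <- 1 / bld$tau + if (heated) bld$k else 0
  if (!substeps && dt > bld$tau) {
    stop(sprintf("unstable step: dt = %g h > tau = %g h", dt, bld$tau))
  }
  n_sub <- if (substeps) max(1L, ceiling(dt * rate * 2)) else 1L
  h <- dt / n_sub

  set.seed(seed)
  n <- nrow(series)
  hod <- ts_hod(series$timestamp)
  q <- bld$q_base + bld$q_work * (hod %in% bld$work_hours)
  T_i <- numeric(n)
  state <- if (!is.null(T_i0)) T_i0 else if (heated) bld$T_set else series$T_a[1]
  for (t in seq_len(n)) {
    for (s in seq_len(n_sub)) {
      heat <- if (heated) max(0, bld$k * (bld$T_set - state)) else 0
      state <- state + h * ((series$T_a[t] - state) / bld$tau +
                              bld$a * series$G[t] + q[t] + heat)
    }
    T_i[t] <- state
  }
  if (bld$noise_sd > 0) {
    T_i <- T_i + stats::rnorm(n, sd = bld$noise_sd)
    T_g_noise <- stats::rnorm(n, sd = bld$noise_sd)
    RH_noise <- stats::rnorm(n, sd = 5 * bld$noise_sd)
  } else {
    T_g_noise <- RH_noise <- numeric(n)
  }
  e_out <- saturation_vapor_pressure(series$T_d)
  RH <- pmin(100, pmax(5, 100 * e_out / saturation_vapor_pressure(T_i) +
                         RH_noise))
  T_g <- T_i + bld$c_g * series$G + T_g_noise
  out <- data.frame(timestamp = series$timestamp, T_i = T_i, RH = RH,
                    T_g = T_g, v_i = bld$v_i, PET_i = NA_real_)
  indoor_series(out, dt, series_calendar(series))
}
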