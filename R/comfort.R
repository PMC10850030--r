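#' Saturation and actual vapour pressure
#'
#' Magnus-type saturation curve over water (WMO constants):
#' \deqn{e_s(T) = 6.112 \exp(17.62 T / (243.12 + T))}
#' with `T` in degC and the result in hPa. `vapor_pressure` scales by
#' relative humidity: `VP = RH/100 * e_s(T)`.
#'
#' @param T temperature (degC).
#' @param RH relative humidity (%), in \[0, 100\].
#' @return vapour pressure (hPa).
#' @export
saturation_vapor_pressure <- function(T) {
  6.112 * exp(17.62 * T / (243.12 + T))
}

#' @rdname saturation_vapor_pressure
#' @export
vapor_pressure <- function(T, RH) {
  if (any(RH < 0 | RH > 100, na.rm = TRUE)) stop("RH must be in [0, 100]")
  RH / 100 * saturation_vapor_pressure(T)
}

#' Globe thermometer specification
#'
#' Standard-globe constants for the ISO 7726 forced-convection conversion of
#' globe temperature to mean radiant temperature.
#'
#' @param diameter globe diameter (m), default 0.15 (standard globe).
#' @param emissivity globe emissivity in (0, 1], default 0.95.
#' @return a `globe_spec` list.
#' @export
globe_spec <- function(diameter = 0.15, emissivity = 0.95) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0, 1]")
  structure(list(diameter = diameter, emissivity = emissivity),
            class = "globe_spec")
}

#' Mean radiant temperature from globe temperature
#'
#' ISO 7726 forced-convection relation:
#' \deqn{T_{mrt} = [ (T_g + 273.15)^4 +
#'   \frac{1.1 \times 10^8 \, v^{0.6}}{\varepsilon D^{0.4}} (T_g - T_a)
#'   ]^{1/4} - 273.15}
#' Reduces exactly to `T_g` when `v = 0` or `T_g = T_a` (no convective
#' exchange).
#'
#' @param T_g globe temperature (degC).
#' @param T_a air temperature (degC).
#' @param v air speed (m/s), >= 0.
#' @param globe a [globe_spec()].
#' @return mean radiant temperature (degC); vectorised.
#' @export
mrt_from_globe <- function(T_g, T_a, v, globe = globe_spec()) {
  if (any(v < 0, na.rm = TRUE)) stop("v must be >= 0")
  conv <- 1.1e8 * v^0.6 / (globe$emissivity * globe$diameter^0.4)
  (pmax(0, (T_g + 273.15)^4 + conv * (T_g - T_a)))^0.25 - 273.15
}

#' Standardized person for PET
#'
#' Defaults are the standardized person of the PET convention: 35-year-old
#' male, 1.75 m, 75 kg, 0.9 clo clothing insulation, 80 W of light activity
#' added to basal metabolism.
#'
#' @param age years.
#' @param sex `"male"` or `"female"`.
#' @param height m.
#' @param weight kg.
#' @param clo clothing insulation (clo).
#' @param work activity metabolism above basal (W).
#' @return a `person_parameters` list.
#' @export
person_parameters <- function(age = 35, sex = c("male", "female"),
                              height = 1.75, weight = 75, clo = 0.9,
                              work = 80) {
  sex <- match.arg(sex)
  vals <- c(age = age, height = height, weight = weight, clo = clo,
            work = work)
  if (any(vals <= 0)) stop("person parameters must be positive")
  structure(list(age = age, sex = sex, height = height, weight = weight,
                 clo = clo, work = work),
            class = "person_parameters")
}

#' PET stress classes
#'
#' Physiological stress classes with boundaries 18, 23, 29, 35, 41 degC.
#' The comfortable band is the open interval (18, 23); the heat thresholds
#' are inclusive at the lower edge (a PET of exactly 29 is moderate heat
#' stress), and PET = 18 falls to cold stress. Cold sub-classes are lumped
#' into one "cold stress" class.
#'
#' @param PET physiologically equivalent temperature (degC); vectorised.
#' @return factor with levels `cold stress`, `no thermal stress`,
#'   `slight heat stress`, `moderate heat stress`, `strong heat stress`,
#'   `extreme heat stress`.
#' @export
classify_pet <- function(PET) {
  if (any(!is.finite(PET))) stop("PET must be finite")
  lv <- pet_stress_levels()
  idx <- ifelse(PET <= 18, 1L,
         ifelse(PET < 23, 2L,
         ifelse(PET < 29, 3L,
         ifelse(PET < 35, 4L,
         ifelse(PET < 41, 5L, 6L)))))
  factor(lv[idx], levels = lv)
}

pet_stress_levels <- function() {
  c("cold stress", "no thermal stress", "slight heat stress",
    "moderate heat stress", "strong heat stress", "extreme heat stress")
}

#' Fill PET into an indoor series
#'
#' Batch entry point: derives mean radiant temperature from the globe
#' channel, vapour pressure from `T_i` and `RH`, and writes `PET_i` for
#' every step of an [indoor_series()].
#'
#' @param indoor an [indoor_series()].
#' @param person a [person_parameters()].
#' @param globe a [globe_spec()].
#' @return the series with `PET_i` filled.
#' @export
add_pet <- function(indoor, person = person_parameters(),
                    globe = globe_spec()) {
  stopifnot(inherits(indoor, "indoor_series"))
  tmrt <- mrt_from_globe(indoor$T_g, indoor$T_i, indoor$v_i, globe)
  vp <- vapor_pressure(indoor$T_i, indoor$RH)
  indoor$PET_i <- pet(indoor$T_i, tmrt, vp, indoor$v_i, person)
  indoor
}
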