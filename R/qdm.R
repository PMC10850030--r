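#' Fit a quantile delta mapping
#'
#' Stores the empirical distributions of an observed-historical and a
#' model-historical sample of one variable. Quantile functions use linear
#' interpolation between order statistics (`stats::quantile` type 7);
#' non-exceedance probabilities for values being corrected come from
#' plotting positions `(rank - 0.5) / n`, so corrections beyond the
#' historical support use the edge delta (constant extrapolation).
#'
#' @param obs_hist numeric vector, observed historical sample.
#' @param mod_hist numeric vector, model historical sample.
#' @param mode `"additive"` (temperature-like) or `"multiplicative"`
#'   (zero-bounded variables such as irradiance and wind).
#' @param group `"pooled"` (default) or `"month"` for calendar-month
#'   grouping; monthly fitting needs `obs_ts` / `mod_ts` timestamps.
#' @param trace multiplicative-mode threshold: denominator quantiles are
#'   floored at `trace`, so near-zero reference values never blow up and
#'   zeros map to zeros.
#' @param obs_ts,mod_ts POSIXct timestamps (only for `group = "month"`).
#' @return a `qdm_mapping`.
#' @export
fit_qdm <- function(obs_hist, mod_hist, mode = c("additive", "multiplicative"),
                    group = c("pooled", "month"), trace = 0.05,
                    obs_ts = NULL, mod_ts = NULL) {
  mode <- match.arg(mode)
  group <- match.arg(group)
  if (length(obs_hist) == 0L || length(mod_hist) == 0L) {
    stop("samples must be non-empty")
  }
  if (mode == "multiplicative" &&
      (any(obs_hist < 0) || any(mod_hist < 0))) {
    stop("multiplicative mode requires non-negative samples")
  }
  if (group == "month") {
    if (is.null(obs_ts) || is.null(mod_ts)) {
      stop("monthly grouping requires obs_ts and mod_ts")
    }
    om <- split(obs_hist, ts_month(obs_ts))
    mm <- split(mod_hist, ts_month(mod_ts))
    if (!setequal(names(om), names(mm)) || any(lengths(om) == 0) ||
        any(lengths(mm) == 0)) {
      stop("empty calendar-month group")
    }
    groups <- lapply(names(om), function(m) {
      list(obs = sort(om[[m]]), mod = sort(mm[[m]]))
    })
    names(groups) <- names(om)
  } else {
    groups <- list(all = list(obs = sort(obs_hist), mod = sort(mod_hist)))
  }
  structure(list(mode = mode, group = group, trace = trace,
                 groups = groups),
            class = "qdm_mapping")
}

qdm_apply_one <- function(g, x, mode, trace) {
  n <- length(x)
  tau <- (rank(x, ties.method = "average") - 0.5) / n
  q_oh <- stats::quantile(g$obs, tau, type = 7, names = FALSE)
  q_mh <- stats::quantile(g$mod, tau, type = 7, names = FALSE)
  if (mode == "additive") {
    q_oh + (x - q_mh)
  } else {
    q_oh * x / pmax(q_mh, trace)
  }
}

#' Apply a quantile delta mapping to a future sample
#'
#' For each value x of the sample, the non-exceedance probability tau is
#' taken from the sample's own empirical distribution; the corrected value
#' is `F_oh^-1(tau) + [x - F_mh^-1(tau)]` in additive mode and
#' `F_oh^-1(tau) * x / F_mh^-1(tau)` in multiplicative mode (denominator
#' floored at the trace threshold). This preserves the model's projected
#' change at every quantile while removing the historical bias.
#'
#' @param mapping a [fit_qdm()] result.
#' @param x numeric vector to correct (the model-future sample).
#' @param ts POSIXct timestamps of `x` (required for monthly mappings).
#' @return corrected vector, same length and order as `x`.
#' @export
apply_qdm <- function(mapping, x, ts = NULL) {
  stopifnot(inherits(mapping, "qdm_mapping"))
  if (mapping$group == "pooled") {
    return(qdm_apply_one(mapping$groups$all, x, mapping$mode, mapping$trace))
  }
  if (is.null(ts)) stop("monthly mapping requires timestamps")
  out <- numeric(length(x))
  for (m in names(mapping$groups)) {
    sel <- ts_month(ts) == as.integer(m)
    if (!any(sel)) next
    out[sel] <- qdm_apply_one(mapping$groups[[m]], x[sel], mapping$mode,
                              mapping$trace)
  }
  out
}

#' Bias-correct a scenario series against a historical reference
#'
#' Fits and applies QDM per variable: additive mode for `T_a`, `T_d`, `p`
#' and `A_G`; multiplicative (trace 0.05) for the zero-bounded `G` and `v`.
#' Physical invariants are re-imposed afterwards and every repair is
#' counted: `T_d` clipped to `T_a`, negative `G`/`v` floored at 0, `A_G`
#' floored at 1 W/m2. Repair counts are attached as attribute `"repairs"`.
#'
#' @param obs_hist,mod_hist,mod_fut [meteo_series()] sharing the six
#'   variables; the historical pair covers the same period semantics.
#' @param modes named character vector overriding per-variable transfer
#'   modes.
#' @param group `"pooled"` or `"month"`.
#' @return corrected future `meteo_series`, with attribute `repairs`
#'   (named counts) and `qdm_mappings` (per-variable mappings for audit).
#' @export
correct_scenario <- function(obs_hist, mod_hist, mod_fut,
                             modes = NULL, group = "pooled") {
  for (s in list(obs_hist, mod_hist, mod_fut)) {
    stopifnot(inherits(s, "meteo_series"))
  }
  default_modes <- c(T_a = "additive", T_d = "additive", v = "multiplicative",
                     p = "additive", G = "multiplicative", A_G = "additive")
  if (!is.null(modes)) default_modes[names(modes)] <- modes
  out <- mod_fut
  mappings <- list()
  for (var in METEO_VARS) {
    mp <- fit_qdm(obs_hist[[var]], mod_hist[[var]],
                  mode = default_modes[[var]], group = group,
                  obs_ts = obs_hist$timestamp, mod_ts = mod_hist$timestamp)
    out[[var]] <- apply_qdm(mp, mod_fut[[var]], ts = mod_fut$timestamp)
    mappings[[var]] <- mp
  }
  repairs <- c(T_d = sum(out$T_d > out$T_a),
               G = sum(out$G < 0), v = sum(out$v < 0),
               A_G = sum(out$A_G < 1))
  out$T_d <- pmin(out$T_d, out$T_a)
  out$G <- pmax(out$G, 0)
  out$v <- pmax(out$v, 0)
  out$A_G <- pmax(out$A_G, 1)
  validate_meteo_series(out)
  attr(out, "repairs") <- repairs
  attr(out, "qdm_mappings") <- mappings
  out
}

#' Serialize a QDM mapping to JSON for audit
#'
#' @param mapping a `qdm_mapping`.
#' @param path file path.
#' @export
write_qdm <- function(mapping, path) {
  jsonlite::write_json(unclass(mapping), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
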