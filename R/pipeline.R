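#' Workplace experiment configuration
#'
#' Describes one workplace for the end-to-end projection experiment: either
#' a synthetic building (generator + building model) or an ingest path to a
#' sensor CSV with the same schema as synthetic output. Period lengths
#' default to desk scale (1 training year, 3-year periods) so a full run
#' stays in minutes; production runs mirror 30-year periods.
#'
#' @param id workplace identifier string.
#' @param type workplace type label: `"office"`, `"laboratory/workshop"`,
#'   `"production"`, `"storage/logistics"` or `"agriculture/forestry"`.
#' @param building a [building_parameters()] (synthetic mode), or `NULL`
#'   when `sensor_path` is given.
#' @param sensor_path CSV path of measured indoor series (ingest mode);
#'   exactly one of `building` / `sensor_path` must be set.
#' @param outdoor an [outdoor_climate_config()] describing the reference
#'   outdoor climate (the "grid cell" of this workplace).
#' @param person a [person_parameters()].
#' @param targets surrogate targets, subset of `c("T_i", "PET_i")`.
#' @param train_years,hist_years,fut_years span of the training era and the
#'   historical / future projection periods.
#' @param hist_start,fut_start first dates of the two periods.
#' @param hyper training hyperparameter overrides (see
#'   [train_surrogate()]).
#' @param seed master seed; fans out to generation, simulation, splitting
#'   and training.
#' @return a `workplace_config`.
#' @export
workplace_config <- function(id, type = "office", building = building_parameters(),
                             sensor_path = NULL,
                             outdoor = outdoor_climate_config(),
                             person = person_parameters(),
                             targets = c("T_i", "PET_i"),
                             train_years = 1, hist_years = 3, fut_years = 3,
                             hist_start = "1970-01-01",
                             fut_start = "2070-01-01",
                             hyper = list(), seed = 1L) {
  if (is.null(building) == is.null(sensor_path)) {
    stop("exactly one of building / sensor_path must be set")
  }
  targets <- match.arg(targets, c("T_i", "PET_i"), several.ok = TRUE)
  structure(list(id = id, type = type, building = building,
                 sensor_path = sensor_path, outdoor = outdoor,
                 person = person, targets = targets,
                 train_years = train_years, hist_years = hist_years,
                 fut_years = fut_years, hist_start = hist_start,
                 fut_start = fut_start, hyper = hyper,
                 seed = as.integer(seed)),
            class = "workplace_config")
}

stage_log <- function(log, stage, msg) {
  c(log, sprintf("[%s] %s", stage, msg))
}

#' Run the end-to-end projection for one workplace
#'
#' Stages, in order: (1) obtain the training-era outdoor and indoor series
#' (generated, or ingested from `sensor_path`); (2) fill `PET_i` via the
#' MEMI model; (3) train one surrogate per target; (4) project the
#' historical period from the reference outdoor series; (5) per scenario
#' member, bias-correct by QDM against the reference and project the future
#' period; (6) compute heat metrics per period; (7) deltas future minus
#' historical. All stage seeds derive from the master seed; QDM repair
#' counts and early-stopping epochs are logged.
#'
#' @param cfg a [workplace_config()].
#' @param scenarios list of [scenario_config()] (>= 1).
#' @return a `projection_report`: list with `workplace`, `surrogates`,
#'   `historical` (per-target [heat_metrics_report()]), `members` (per
#'   member: reports + delta tables), `ensembles` (per scenario label, via
#'   [aggregate_ensemble()]) and `log`.
#' @export
run_workplace_projection <- function(cfg, scenarios) {
  stopifnot(inherits(cfg, "workplace_config"), length(scenarios) >= 1)
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      4L + 2L * length(scenarios))
  log <- character()

  # (1) training era
  out_train_cfg <- cfg$outdoor
  out_train_cfg$span_years <- cfg$train_years
  out_train_cfg$seed <- seeds[1]
  out_train <- generate_outdoor_series(out_train_cfg)
  if (!is.null(cfg$sensor_path)) {
    indoor <- read_series_csv(cfg$sensor_path, type = "indoor")
    log <- stage_log(log, "data", paste("ingested", cfg$sensor_path))
  } else {
    indoor <- simulate_indoor(out_train, cfg$building, seed = seeds[2])
    log <- stage_log(log, "data", sprintf(
      "simulated %d training steps (tau=%g h)", nrow(indoor),
      cfg$building$tau))
  }

  # (2) PET on the training indoor series
  if ("PET_i" %in% cfg$targets) {
    indoor <- add_pet(indoor, cfg$person)
    log <- stage_log(log, "pet", sprintf("PET_i filled for %d steps",
                                         nrow(indoor)))
  }

  # (3) surrogates
  fm <- build_feature_matrix(out_train)
  keep <- match(fm$timestamps, indoor$timestamp)
  surrogates <- list()
  for (k in seq_along(cfg$targets)) {
    tgt <- cfg$targets[k]
    y <- indoor[[tgt]][keep]
    m <- train_surrogate(fm, y, hyper = cfg$hyper, seed = seeds[3] + k - 1L,
                         workplace_id = cfg$id, target = tgt)
    surrogates[[tgt]] <- m
    log <- stage_log(log, "train", sprintf(
      "%s: test MAE %.3f K, best epoch %d/%d", tgt, m$test_mae,
      m$meta$best_epoch, m$meta$epochs_run))
  }

  # (4) historical projection from the reference outdoor series
  obs_cfg <- cfg$outdoor
  obs_cfg$span_years <- cfg$hist_years
  obs_cfg$start <- cfg$hist_start
  obs_cfg$seed <- seeds[4]
  obs_hist <- generate_outdoor_series(obs_cfg)
  historical <- project_period(surrogates, obs_hist, "historical")
  log <- stage_log(log, "historical", sprintf(
    "projected %d steps over %d years", nrow(obs_hist), cfg$hist_years))

  # (5)-(7) members
  members <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    mh_cfg <- obs_cfg
    mh_cfg$seed <- seeds[4 + 2 * i - 1]
    bias_only <- sc
    bias_only$offset[] <- 0
    bias_only$trend[] <- 0
    mod_hist <- apply_climate_scenario(generate_outdoor_series(mh_cfg),
                                       bias_only)
    mf_cfg <- cfg$outdoor
    mf_cfg$span_years <- cfg$fut_years
    mf_cfg$start <- cfg$fut_start
    mf_cfg$seed <- seeds[4 + 2 * i]
    mod_fut <- apply_climate_scenario(generate_outdoor_series(mf_cfg), sc)
    corrected <- correct_scenario(obs_hist, mod_hist, mod_fut)
    rep_counts <- attr(corrected, "repairs")
    log <- stage_log(log, "qdm", sprintf(
      "%s member %d: repairs %s", sc$label, sc$member,
      paste(names(rep_counts), rep_counts, sep = "=", collapse = " ")))
    future <- project_period(surrogates, corrected, "future")
    deltas <- lapply(cfg$targets, function(tgt) {
      compare_periods(historical[[tgt]], future[[tgt]])
    })
    names(deltas) <- cfg$targets
    members[[i]] <- list(label = sc$label, member = sc$member,
                         future = future, deltas = deltas)
  }

  labels <- unique(vapply(members, `[[`, character(1), "label"))
  ensembles <- lapply(labels, function(lb) {
    sel <- members[vapply(members, `[[`, character(1), "label") == lb]
    lapply(stats::setNames(cfg$targets, cfg$targets), function(tgt) {
      aggregate_ensemble(lapply(sel, function(m) m$future[[tgt]]), lb)
    })
  })
  names(ensembles) <- labels

  structure(list(workplace = cfg[c("id", "type", "targets", "seed")],
                 surrogates = surrogates, historical = historical,
                 members = members, ensembles = ensembles, log = log),
            class = "projection_report")
}

# predict all targets over one period series and compute metrics
project_period <- function(surrogates, series, period) {
  out <- lapply(surrogates, function(m) {
    pred <- to_noleap(predict_series(m, series))
    tgt <- m$meta$target
    heat_metrics_report(pred[[tgt]], pred$timestamp, variable = tgt,
                        step_hours = attr(pred, "step_hours"),
                        period = period)
  })
  names(out) <- vapply(surrogates, function(m) m$meta$target, character(1))
  out
}

#' Aggregate ensemble members
#'
#' Mean and min-max range per metric across the members of one scenario
#' family, matching the "mean (range)" presentation of ensemble tables.
#' The per-year medians across members are exposed alongside the means.
#'
#' @param member_reports list of [heat_metrics_report()] for the same
#'   variable and period.
#' @param label scenario family label (e.g. `"RCP8.5"`).
#' @return an `ensemble_summary`: list with `label`, `n_members`, `means`
#'   (data.frame value/min/max/median per mean statistic) and `thresholds`
#'   (data.frame per threshold and metric).
#' @export
aggregate_ensemble <- function(member_reports, label) {
  stopifnot(length(member_reports) >= 1)
  periods <- vapply(member_reports, `[[`, character(1), "period")
  if (length(unique(periods)) != 1) stop("mixed-period members rejected")
  vars <- vapply(member_reports, `[[`, character(1), "variable")
  if (length(unique(vars)) != 1) stop("mixed-variable members rejected")

  mean_mat <- do.call(rbind, lapply(member_reports, `[[`, "means"))
  means <- data.frame(statistic = colnames(mean_mat),
                      mean = colMeans(mean_mat),
                      min = apply(mean_mat, 2, min),
                      max = apply(mean_mat, 2, max),
                      median = apply(mean_mat, 2, stats::median))
  rownames(means) <- NULL

  thr0 <- member_reports[[1]]$thresholds
  metrics <- c("hours_per_year", "heat_days_per_year", "mean_run_days")
  thr <- do.call(rbind, lapply(metrics, function(mc) {
    vals <- vapply(member_reports, function(r) r$thresholds[[mc]],
                   numeric(nrow(thr0)))
    vals <- matrix(vals, nrow = nrow(thr0))
    data.frame(threshold = thr0$threshold, metric = mc,
               mean = rowMeans(vals),
               min = apply(vals, 1, min), max = apply(vals, 1, max),
               median = apply(vals, 1, stats::median))
  }))
  structure(list(label = label, n_members = length(member_reports),
                 period = periods[1], variable = vars[1],
                 means = means, thresholds = thr),
            class = "ensemble_summary")
}

#' Compare two periods
#'
#' Absolute deltas and percent changes per metric between a historical and
#' a future [heat_metrics_report()]. Percent change is `NA` with
#' `undefined = TRUE` when the historical value is 0.
#'
#' @param hist,fut reports with identical variable and thresholds.
#' @return a `delta_table` data.frame: `metric`, `threshold`, `hist`,
#'   `fut`, `delta`, `pct_change`, `undefined`.
#' @export
compare_periods <- function(hist, fut) {
  if (!identical(hist$variable, fut$variable) ||
      !identical(hist$thresholds$threshold, fut$thresholds$threshold)) {
    stop("mismatched report shapes")
  }
  rows <- list()
  for (mc in c("hours_per_year", "heat_days_per_year", "mean_run_days")) {
    rows[[mc]] <- data.frame(metric = mc,
                             threshold = hist$thresholds$threshold,
                             hist = hist$thresholds[[mc]],
                             fut = fut$thresholds[[mc]])
  }
  rows$means <- data.frame(metric = paste0("mean_", names(hist$means)),
                           threshold = NA_real_,
                           hist = as.numeric(hist$means),
                           fut = as.numeric(fut$means))
  out <- do.call(rbind, rows)
  out$delta <- out$fut - out$hist
  out$undefined <- out$hist == 0
  out$pct_change <- ifelse(out$undefined, NA_real_,
                           100 * out$delta / out$hist)
  rownames(out) <- NULL
  class(out) <- c("delta_table", class(out))
  out
}

#' Write a projection report as a JSON summary
#'
#' @param report a `projection_report`.
#' @param path file path.
#' @export
write_projection_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "heat_metrics_report") ||
        inherits(x, "ensemble_summary")) unclass(x)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, strip)
    else x
  }
  obj <- list(workplace = report$workplace,
              historical = strip(report$historical),
              members = strip(lapply(report$members, function(m) {
                m[c("label", "member", "future", "deltas")]
              })),
              ensembles = strip(report$ensembles),
              log = report$log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
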