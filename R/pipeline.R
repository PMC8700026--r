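#' Scenario grid orchestration
#'
#' Fans the model out over the full scenario grid -- starting ages x
#' screening intervals x delivery settings x costing perspectives --
#' with a no-screening comparator per (age, perspective) cell, and
#' renders the results table with incremental metrics and NMB.
#'
#' @name dmscreen-pipeline
NULL

CONFIG_KEYS <- c("params", "life_table", "ages", "intervals", "settings",
                 "perspectives", "lambda", "psa_n", "seed", "out_dir")

#' Validate and normalise a run configuration
#'
#' Accepts a named list or a path to a JSON document. Unknown keys and
#' missing referenced files are errors; absent keys take the base-case
#' defaults (age 40; all three intervals; both settings and
#' perspectives; threshold 2715.3 USD/QALY; life table synthesised to
#' a life expectancy at birth of 73.6 years).
#'
#' @param config Named list or JSON file path; `NULL` for defaults.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(params = NULL, life_table = list(target_e0 = 73.6),
                   ages = 40, intervals = INTERVALS, settings = SETTINGS,
                   perspectives = c("societal", "provider"),
                   lambda = model_constants()$wtp_threshold,
                   psa_n = 1000, seed = 1L, out_dir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!is.null(config$params) && !file.exists(config$params))
    stop("parameter file not found: ", config$params)
  if (is.character(config$life_table) && !file.exists(config$life_table))
    stop("life table file not found: ", config$life_table)
  if (!length(config$ages)) stop("config field 'ages' must be non-empty")
  if (!length(config$intervals) || !all(config$intervals %in% INTERVALS))
    stop("config field 'intervals' must be a non-empty subset of: ",
         paste(INTERVALS, collapse = ", "))
  if (!length(config$settings) || !all(config$settings %in% SETTINGS))
    stop("config field 'settings' must be a non-empty subset of: ",
         paste(SETTINGS, collapse = ", "))
  if (!all(config$perspectives %in% c("societal", "provider")) ||
      !length(config$perspectives))
    stop("config field 'perspectives' must be a non-empty subset of ",
         "societal, provider")
  stopifnot(config$lambda > 0, config$psa_n >= 1)
  config$seed <- as.integer(config$seed)
  # explicit rebuild: plain [ subsetting mangles NULL-valued keys
  out <- stats::setNames(lapply(CONFIG_KEYS, function(k) config[[k]]),
                         CONFIG_KEYS)
  structure(out, class = "run_config")
}

resolve_life_table <- function(cfg) {
  lt_spec <- cfg$life_table
  if (is.character(lt_spec)) read_life_table(lt_spec)
  else calibrate_life_table(lt_spec$target_e0)
}

#' Run the full scenario grid
#'
#' One row per (setting, interval, starting age, perspective) cell plus
#' a no-screening comparator row per (age, perspective). Incremental
#' metrics and the dominance flag compare each screening row against
#' its cell's comparator; NMB uses the configured threshold.
#'
#' @param config `run_config` (or anything [validate_config()]
#'   accepts).
#' @return Data frame of class `results_table`. If `out_dir` is set in
#'   the config, `results.csv` and `summary.json` are written there.
#' @export
run_grid <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  specs <- param_specs(cfg$params)
  pset <- parameter_set(specs)
  lt <- resolve_life_table(cfg)
  rows <- list()
  for (age in cfg$ages) {
    for (pp in cfg$perspectives) {
      base <- evaluate_strategy(NULL, pset, lt, start_age = age,
                                perspective = pp)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = "no_screening", setting = NA_character_,
        interval = NA_character_, start_age = age, perspective = pp,
        screening_cost = base$screening_cost,
        treatment_cost = base$treatment_cost,
        total_cost = base$total_cost, ly = base$ly, qaly = base$qaly,
        delta_cost = NA_real_, delta_ly = NA_real_,
        delta_qaly = NA_real_, icer = NA_real_, flag = NA_character_,
        nmb = nmb(base, cfg$lambda))
      for (setting in cfg$settings) {
        for (iv in cfg$intervals) {
          strat <- screening_strategy(setting, iv, age)
          alt <- evaluate_strategy(strat, pset, lt, perspective = pp)
          cmp <- icer(base, alt)
          rows[[length(rows) + 1L]] <- data.frame(
            strategy = strat$id, setting = setting, interval = iv,
            start_age = age, perspective = pp,
            screening_cost = alt$screening_cost,
            treatment_cost = alt$treatment_cost,
            total_cost = alt$total_cost, ly = alt$ly, qaly = alt$qaly,
            delta_cost = cmp$delta_cost, delta_ly = cmp$delta_ly,
            delta_qaly = cmp$delta_qaly, icer = cmp$icer,
            flag = cmp$flag, nmb = nmb(alt, cfg$lambda))
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("results_table", "data.frame")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(cfg$out_dir, "results.csv"),
                     row.names = FALSE)
    best <- res[!is.na(res$nmb) & res$strategy != "no_screening", ]
    best <- best[order(-best$nmb), ][1, c("strategy", "perspective",
                                          "nmb")]
    jsonlite::write_json(
      list(n_rows = nrow(res), lambda = cfg$lambda,
           best_strategy = as.list(best)),
      file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE)
  }
  res
}
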