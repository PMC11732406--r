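# Orchestration: simulate (or ingest) -> exclusion rules -> lambda_mob ->
# decile stratification -> Mann-Kendall trend tests -> joint grids ->
# regression suite, as one configured, logged, reproducible run.
#
# The run config is a declarative YAML file (or equivalent R list):
#
#   simulate: {grid_n: 20, dzn_block: 2, beta_eo: -0.1, ...}   # either
#   inputs:  {origins: o.geojson, destinations: d.geojson,     # or
#             visits: v.csv, coverage: c.csv, ses: s.csv}
#   periods: [{label: baseline, duration_days: 30, effect_scale: 0}, ...]
#   scenarios: {lockdown: {test: test, baseline: baseline}}
#   cbd: [25, 25]          # km; defaults to the grid centre
#   weights_k: 8
#   mk_method: normal_approx
#   seed: 1

.known_config_keys <- c("simulate", "inputs", "periods", "scenarios", "cbd",
                        "weights_k", "mk_method", "seed", "log_level", "out")

.as_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.config_periods <- function(config) {
  if (is.null(config$periods)) {
    return(list(period_spec("baseline"), period_spec("test")))
  }
  lapply(config$periods, function(p) {
    period_spec(p$label,
                duration_days = p$duration_days %||% 30L,
                effect_scale = p$effect_scale %||%
                  if (identical(p$label, "test")) 1 else 0,
                panel_rate = p$panel_rate)
  })
}

.config_city <- function(config) {
  sim <- config$simulate %||% list()
  args <- sim[intersect(names(sim), names(formals(city_config)))]
  args$periods <- .config_periods(config)
  if (!is.null(config$seed)) args$seed <- config$seed
  do.call(city_config, args)
}

#' Validate a run configuration
#'
#' Schema and cross-reference checks: unknown top-level keys are
#' non-fatal warnings; missing scenarios, scenarios citing undeclared
#' periods, invalid durations and invalid simulate blocks are fatal.
#'
#' @param config path to a YAML config or an equivalent list.
#' @return Object of class `config_report` with `errors`, `warnings` and
#'   `valid`.
#' @export
validate_config <- function(config) {
  config <- .as_run_config(config)
  errors <- character(0)
  warns <- character(0)
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    warns <- c(warns, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    errors <- c(errors, "need either a `simulate` or an `inputs` block")
  }
  periods <- tryCatch(.config_periods(config), error = function(e) {
    errors <<- c(errors, conditionMessage(e))
    NULL
  })
  labels <- if (is.null(periods)) character(0) else {
    vapply(periods, function(p) p$label, character(1L))
  }
  if (is.null(config$scenarios) || !length(config$scenarios)) {
    errors <- c(errors, "no scenarios defined")
  } else {
    for (nm in names(config$scenarios)) {
      sc <- config$scenarios[[nm]]
      for (side in c("test", "baseline")) {
        if (is.null(sc[[side]])) {
          errors <- c(errors, paste0("scenario '", nm, "' has no ", side,
                                     " period"))
        } else if (!is.null(periods) && !sc[[side]] %in% labels &&
                   is.null(config$inputs)) {
          errors <- c(errors, paste0("scenario '", nm, "' cites unknown period '",
                                     sc[[side]], "'"))
        }
      }
    }
  }
  if (!is.null(config$simulate)) {
    tryCatch(.config_city(config),
             error = function(e) errors <<- c(errors, conditionMessage(e)))
  }
  structure(list(errors = errors, warnings = warns,
                 valid = length(errors) == 0L),
            class = "config_report")
}

#' @exportS3Method base::print
print.config_report <- function(x, ...) {
  cat("<config_report>", if (x$valid) "VALID" else "INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

.log_stage <- function(lines, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  c(lines, msg)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for each scenario and writes the standard output
#' tables (`lambda_<scenario>.csv`, `exclusions_<scenario>.csv`,
#' `deciles.csv`, `decile_medians.csv`, `joint_grid_<scenario>.csv`,
#' `letter_values_<scenario>.csv`, `trend_results.csv`,
#' `model_summary.csv`) plus `manifest.json` (config, seed, file digests,
#' package version) and `run.log`.  Identical config + seed give
#' identical outputs.
#'
#' @param config path to a YAML run config or an equivalent list.
#' @param out output directory; overrides `config$out`.
#' @param seed master seed; overrides `config$seed`.
#' @return Invisibly, a list with all in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  config <- .as_run_config(config)
  rep <- validate_config(config)
  if (!rep$valid) {
    stop("config error: ", paste(rep$errors, collapse = "; "), call. = FALSE)
  }
  out_dir <- out %||% config$out %||% stop("no output directory given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)

  # --- stage: data --------------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- .config_city(config)
    cfg$seed <- seed
    city <- simulate_city(cfg, seed = seed)
    origins <- city$origins
    destinations <- city$destinations
    visits <- city$visits
    coverage <- city$coverage
    seifa <- city$seifa
    log_lines <- .log_stage(log_lines, "simulate",
      sprintf("%d origins, %d destinations, %d visit rows",
              n_regions(origins), n_regions(destinations), nrow(visits)))
  } else {
    inp <- config$inputs
    origins <- read_partitions(inp$origins, "origin")
    destinations <- read_partitions(inp$destinations, "destination")
    visits <- read_visits(inp$visits)
    coverage <- read_coverage(inp$coverage)
    seifa <- read_ses(inp$ses)
    log_lines <- .log_stage(log_lines, "ingest",
      sprintf("%d origins, %d destinations, %d visit rows",
              n_regions(origins), n_regions(destinations), nrow(visits)))
  }

  # --- stage: geometry ----------------------------------------------------
  excluded <- find_excluded_pairs(origins, destinations)
  container <- coverage_container(origins, destinations)
  log_lines <- .log_stage(log_lines, "geometry",
    sprintf("%d excluded pairs, %d origins without coverage container",
            nrow(excluded), sum(is.na(container))))

  deciles <- seifa_deciles(seifa)
  write.csv(deciles, file.path(out_dir, "deciles.csv"), row.names = FALSE)

  cbd <- as.numeric(config$cbd %||%
    if (!is.null(config$simulate)) .city_centre(.config_city(config)) else
      colMeans(origins$centroids))
  k <- config$weights_k %||% 8L
  mk_method <- config$mk_method %||% "normal_approx"

  trend_rows <- list()
  model_rows <- list()
  med_rows <- list()
  results <- list()

  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    out_t <- aggregate_outflow(visits, excluded, sc$test)
    out_b <- aggregate_outflow(visits, excluded, sc$baseline)
    mob <- compute_lambda(out_t, out_b, coverage,
                          period_test = sc$test, period_base = sc$baseline)
    log_lines <- .log_stage(log_lines, paste0("lambda:", nm),
      sprintf("%d origins defined, %d omitted", nrow(mob$lambda),
              nrow(mob$exclusions)))
    write.csv(mob$lambda, file.path(out_dir, paste0("lambda_", nm, ".csv")),
              row.names = FALSE)
    write.csv(mob$exclusions,
              file.path(out_dir, paste0("exclusions_", nm, ".csv")),
              row.names = FALSE)

    lv <- letter_values(mob$lambda$lambda_mob)
    write.csv(lv, file.path(out_dir, paste0("letter_values_", nm, ".csv")),
              row.names = FALSE)

    for (index in c("EO", "ER")) {
      med <- decile_medians(mob, deciles, index)
      tr <- mk_test(med, method = mk_method)
      med_rows[[paste(nm, index)]] <- data.frame(
        scenario = nm, index = index, decile = 1:10, median_lambda = med,
        stringsAsFactors = FALSE)
      trend_rows[[paste(nm, index)]] <- data.frame(
        scenario = nm, index = index, n = tr$n, S = tr$S, var_S = tr$var_S,
        z = tr$z, p_two_sided = tr$p_two_sided, method = tr$method,
        stringsAsFactors = FALSE)
    }
    grid <- joint_median_grid(mob, deciles)
    gl <- expand.grid(er_decile = 1:10, eo_decile = 1:10)
    gl$median_lambda <- grid$median[cbind(gl$er_decile, gl$eo_decile)]
    gl$count <- grid$count[cbind(gl$er_decile, gl$eo_decile)]
    gl$scenario <- nm
    write.csv(gl, file.path(out_dir, paste0("joint_grid_", nm, ".csv")),
              row.names = FALSE)

    # --- regression suite on the defined-lambda subset --------------------
    ids <- mob$lambda$origin_id
    sidx <- match(ids, seifa$origin_id)
    Z <- standardize_predictors(cbind(ER = seifa$er_score[sidx],
                                      EO = seifa$eo_score[sidx]))
    dcbd <- distance_to_cbd(origins, cbd)[ids]
    Zd <- standardize_predictors(cbind(ER = seifa$er_score[sidx],
                                       EO = seifa$eo_score[sidx],
                                       dist_cbd = dcbd))
    yv <- mob$lambda$lambda_mob
    w <- build_weights(origins$centroids[ids, , drop = FALSE], k = k,
                       eigenvalues = TRUE)
    fits <- list(
      fit_ols(yv, Z, model = "ols"),
      fit_ols(yv, Zd, model = "ols_cbd"),
      fit_spatial_lag(yv, Z, w),
      fit_spatial_error(yv, Z, w)
    )
    log_lines <- .log_stage(log_lines, paste0("models:", nm),
      sprintf("AIC: %s", paste(sprintf("%s=%.1f",
        vapply(fits, `[[`, "", "model"),
        vapply(fits, `[[`, 0, "aic")), collapse = " ")))
    for (f in fits) {
      cf <- f$coefficients
      model_rows[[paste(nm, f$model)]] <- data.frame(
        scenario = nm, model = f$model, predictor = names(cf),
        coefficient = as.numeric(cf), se = as.numeric(f$se),
        p = as.numeric(f$p_values),
        rho_lag = f$rho_lag %||% NA_real_,
        lambda_err = f$lambda_err %||% NA_real_,
        log_likelihood = f$log_likelihood, aic = f$aic,
        stringsAsFactors = FALSE)
    }
    results[[nm]] <- list(mobility = mob, fits = fits,
                          comparison = model_comparison(fits))
  }

  write.csv(do.call(rbind, med_rows), file.path(out_dir, "decile_medians.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, trend_rows), file.path(out_dir, "trend_results.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, model_rows), file.path(out_dir, "model_summary.csv"),
            row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), c("manifest.json", "run.log")))
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("mobishift")),
    config = config[setdiff(names(config), "out")],
    digests = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(out_dir = out_dir, results = results,
                 trend = do.call(rbind, trend_rows),
                 models = do.call(rbind, model_rows)))
}
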