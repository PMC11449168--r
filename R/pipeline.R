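## End-to-end orchestration: configuration, staged runs with logging and a
## manifest, and the minimum-observations sensitivity analysis.

#' Study configuration
#'
#' All paper-silent constants live here with their defaults: the study
#' timezone offset used for calendar binning (UTC+10), the 60-minute COA
#' bin, the 1 km kernel bandwidth on a 0.5 km grid, the 240 s association
#' window, and the inclusion thresholds. Sampler settings are nested as
#' [prior_spec()] / [dhglm_control()] objects.
#'
#' @param tz_offset_hours study timezone offset from UTC, hours.
#' @param coa_bin_min COA temporal bin, minutes.
#' @param grid_from_km,grid_to_km,grid_step_km chainage grid for UDs.
#' @param bandwidth_km kernel bandwidth, km.
#' @param association_window_s co-occurrence window, seconds.
#' @param association_mode `"pairwise"` or `"binned"`.
#' @param min_unique_locations minimum unique COA positions per monthly UD.
#' @param min_months minimum months per individual for model inclusion.
#' @param channel_width_km nominal channel width (km) for km^2 home ranges.
#' @param priors a [prior_spec()].
#' @param control a [dhglm_control()].
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `study_config`.
#' @export
study_config <- function(tz_offset_hours = 10, coa_bin_min = 60,
                         grid_from_km = 0, grid_to_km = 100,
                         grid_step_km = 0.5, bandwidth_km = 1,
                         association_window_s = 240,
                         association_mode = "pairwise",
                         min_unique_locations = 5L, min_months = 2L,
                         channel_width_km = 0.1,
                         priors = prior_spec(), control = dhglm_control(),
                         seed = 1L, out_dir = tempfile("croctraits_run_")) {
  stopifnot(coa_bin_min > 0, grid_step_km > 0, bandwidth_km > 0,
            association_window_s > 0, min_unique_locations >= 1L,
            min_months >= 1L)
  structure(list(tz_offset_hours = tz_offset_hours, coa_bin_min = coa_bin_min,
                 grid_from_km = grid_from_km, grid_to_km = grid_to_km,
                 grid_step_km = grid_step_km, bandwidth_km = bandwidth_km,
                 association_window_s = association_window_s,
                 association_mode = association_mode,
                 min_unique_locations = as.integer(min_unique_locations),
                 min_months = as.integer(min_months),
                 channel_width_km = channel_width_km,
                 priors = priors, control = control,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys override [study_config()] defaults; `priors` and
#' `control` may be nested maps with the fields of [prior_spec()] and
#' [dhglm_control()].
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("priors", "control"))]
  if (!is.null(raw$priors)) args$priors <- do.call(prior_spec, raw$priors)
  if (!is.null(raw$control)) args$control <- do.call(dhglm_control, raw$control)
  do.call(study_config, args)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, metric derivation, model preparation, MCMC fit
#' and derived statistics, writing every intermediate table plus a manifest
#' with the configuration hash. Stage failures abort with the stage name.
#'
#' @param config a [study_config()].
#' @param source `"simulate_panel"` (behavioural panel with known truth),
#'   `"simulate_detections"` (mechanistic telemetry simulation followed by
#'   the full metric chain), or `"files"` (load tables from `paths`).
#' @param truth [synthetic_truth()] for `"simulate_panel"`.
#' @param scenario [telemetry_scenario()] for `"simulate_detections"`.
#' @param paths file paths for `"files"` (see [load_study()]).
#' @return list with `manifest`, `panel`, `fit`, `derived`, `out_dir`,
#'   invisibly.
#' @export
run_pipeline <- function(config = study_config(),
                         source = c("simulate_panel", "simulate_detections", "files"),
                         truth = synthetic_truth(), scenario = telemetry_scenario(),
                         paths = NULL) {
  source <- match.arg(source)
  stage <- "input"
  result <- tryCatch({
    tables <- list()
    if (source == "simulate_panel") {
      sim <- simulate_behaviour_panel(truth, seed = config$seed)
      panel <- sim$panel
      log_stage(stage, "simulated panel: %d rows, %d individuals",
                nrow(panel), truth$n_individuals)
      model_data <- prepare_model_data(panel, transform = "identity",
                                       standardize = FALSE,
                                       log_detections = FALSE,
                                       min_months = config$min_months)
    } else {
      study <- if (source == "simulate_detections") {
        simulate_detections(scenario)
      } else {
        load_study(paths, config)
      }
      log_stage(stage, "%d detections, %d receivers, %d individuals",
                nrow(study$detections), nrow(study$receivers),
                nrow(study$individuals))
      stage <- "metrics"
      mb <- monthly_behaviours(study, config)
      panel <- mb$panel
      tables$coas <- mb$coas
      log_stage(stage, "panel: %d individual-months", nrow(panel))
      stage <- "prepare"
      model_data <- prepare_model_data(panel, study$individuals,
                                       min_months = config$min_months)
    }
    tables$panel <- panel
    stage <- "fit"
    fit <- fit_dhglm(model_data, config$priors, config$control,
                     seed = config$seed)
    log_stage(stage, "%d draws, converged: %s", nrow(fit$draws), fit$converged)
    tables$fit_summary <- summarize_fit(
      fit, pars = fit$diagnostics$parameter)
    stage <- "derive"
    derived <- list(correlations = random_effect_correlations(fit))
    stats_rows <- list()
    for (k in BEHAVIOURS) {
      r <- repeatability(fit, k)
      cp <- coefficient_of_predictability(fit, k)
      stats_rows[[k]] <- data.frame(
        quantity = c("repeatability", "cv_p"), behaviour = k,
        mean = c(r$mean, cp$mean),
        hpd_low = c(r$hpd[["lower"]], cp$hpd[["lower"]]),
        hpd_high = c(r$hpd[["upper"]], cp$hpd[["upper"]]),
        plugin = c(r$plugin, cp$plugin))
      derived[[paste0("realized_phenotype_", k)]] <- realized_phenotypes(fit, k)
      derived[[paste0("realized_riiv_", k)]] <- realized_riiv(fit, k)
    }
    derived$stats <- do.call(rbind, c(stats_rows, make.row.names = FALSE))
    tables$derived_stats <- derived$stats
    tables$correlations <- derived$correlations
    stage <- "write"
    manifest <- write_outputs(tables, config$out_dir, config = unclass(config))
    log_stage(stage, "wrote %d tables to %s (config %s)",
              length(manifest$files), config$out_dir,
              substr(manifest$config_hash, 1, 8))
    list(manifest = manifest, panel = panel, fit = fit, derived = derived,
         out_dir = config$out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Sensitivity of the fit to the minimum-observations threshold
#'
#' Refits the model for each minimum-months threshold and tabulates
#' per-parameter posterior means and HPDs side by side, plus the maximum
#' absolute change of each fixed-effect posterior mean across thresholds.
#'
#' @param panel behaviour panel (either shape accepted by
#'   [prepare_model_data()]).
#' @param thresholds integer vector of minimum-months values (>= 2 values;
#'   output ordered ascending).
#' @param individuals metadata for raw panels.
#' @param config a [study_config()] supplying priors/sampler settings.
#' @param ... passed to [prepare_model_data()] (e.g. `transform`,
#'   `standardize` for synthetic panels).
#' @return list with `table` (parameter x threshold summary) and
#'   `max_abs_change` (named vector over fixed effects).
#' @export
sensitivity_analysis <- function(panel, thresholds, individuals = NULL,
                                 config = study_config(), ...) {
  if (length(thresholds) < 2L) stop("need at least two thresholds", call. = FALSE)
  thresholds <- sort(unique(as.integer(thresholds)))
  summaries <- list()
  for (th in thresholds) {
    md <- tryCatch(
      prepare_model_data(panel, individuals, min_months = th, ...),
      error = function(e) stop(sprintf(
        "threshold %d excludes all individuals: %s", th, conditionMessage(e)),
        call. = FALSE))
    fit <- fit_dhglm(md, config$priors, config$control, seed = config$seed)
    s <- summarize_fit(fit, pars = fit$diagnostics$parameter)
    s <- s[c("parameter", "mean", "hpd_low", "hpd_high")]
    names(s)[-1L] <- paste0(names(s)[-1L], "_min", th)
    summaries[[as.character(th)]] <- s
  }
  tab <- Reduce(function(a, b) merge(a, b, by = "parameter", sort = FALSE),
                summaries)
  fixed <- grep("^(mean|disp)_", tab$parameter)
  mean_cols <- grep("^mean_min", names(tab))
  mm <- as.matrix(tab[fixed, mean_cols, drop = FALSE])
  max_change <- apply(mm, 1L, function(x) max(x) - min(x))
  names(max_change) <- tab$parameter[fixed]
  list(table = tab, max_abs_change = max_change, thresholds = thresholds)
}
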