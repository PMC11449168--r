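## Assembly of the monthly behaviour panel from raw detections: sociability,
## mean daily river distance, consecutive-month site fidelity and detection
## counts per individual-month.

#' Monthly behaviour panel from detections
#'
#' Runs the full metric chain: centres of activity, monthly activity,
#' monthly utilization distributions and site fidelity, co-occurrence
#' sociability, and detection counts, merged on individual-month. Any field
#' may be missing for a given month (e.g. too few locations for a home
#' range); missingness is preserved, not zero-filled.
#'
#' @param study list with `detections`, `receivers` (as from [load_study()]
#'   or [simulate_detections()]).
#' @param config a [study_config()].
#' @return list with `panel` (data frame `individual_id`, `month`,
#'   `sociability`, `activity_km_per_day`, `site_fidelity`, `n_detections`),
#'   `coas`, and `uds`.
#' @export
monthly_behaviours <- function(study, config = study_config()) {
  tz <- config$tz_offset_hours
  coas <- compute_coas(study$detections, study$receivers,
                       bin_duration_min = config$coa_bin_min)
  activity <- monthly_activity(coas, tz_offset_hours = tz)
  uds <- monthly_uds(coas, tz_offset_hours = tz,
                     grid_from_km = config$grid_from_km,
                     grid_to_km = config$grid_to_km,
                     grid_step_km = config$grid_step_km,
                     bandwidth_km = config$bandwidth_km,
                     min_unique_locations = config$min_unique_locations,
                     channel_width_km = config$channel_width_km)
  fidelity <- list()
  for (id in names(uds)) {
    sf <- site_fidelity_series(uds[[id]])
    if (nrow(sf)) fidelity[[id]] <- cbind(individual_id = id, sf)
  }
  fidelity <- if (length(fidelity)) do.call(rbind, fidelity) else
    data.frame(individual_id = character(0), month = character(0),
               site_fidelity = numeric(0))
  social <- monthly_social_table(study$detections,
                                 window_s = config$association_window_s,
                                 mode = config$association_mode,
                                 tz_offset_hours = tz)
  mon <- month_of(study$detections$timestamp, tz)
  counts <- aggregate(list(n_detections = mon),
                      by = list(individual_id = study$detections$tag_id, month = mon),
                      FUN = length)

  panel <- merge(counts, social[c("individual_id", "month", "sociability")],
                 by = c("individual_id", "month"), all.x = TRUE)
  panel <- merge(panel, activity, by = c("individual_id", "month"), all.x = TRUE)
  panel <- merge(panel, fidelity, by = c("individual_id", "month"), all.x = TRUE)
  panel <- panel[order(panel$individual_id, panel$month),
                 c("individual_id", "month", "sociability",
                   "activity_km_per_day", "site_fidelity", "n_detections")]
  rownames(panel) <- NULL
  list(panel = panel, coas = coas, uds = uds)
}
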