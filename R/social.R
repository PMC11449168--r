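## Co-occurrence based social metrics: monthly social environments, pairwise
## association events at shared receivers, sociability, and the associate
## counts that feed the home-range/associates model.

#' Monthly social environment of a focal individual
#'
#' The potential associates of a focal individual in a calendar month: every
#' tagged conspecific with at least one detection during that month at any
#' receiver where the focal was detected that month. Contemporaneity within
#' the month is not required. If the focal was not detected in the month the
#' result is absent (`NULL`), not an empty set.
#'
#' @param focal focal individual id.
#' @param month calendar month "YYYY-MM" (in study-local time).
#' @param detections detection table.
#' @param tz_offset_hours study timezone offset for month binning.
#' @return character vector of conspecific ids, or `NULL`.
#' @export
social_environment <- function(focal, month, detections, tz_offset_hours = 10) {
  mon <- month_of(detections$timestamp, tz_offset_hours)
  dm <- detections[mon == month, , drop = FALSE]
  focal_rec <- unique(dm$receiver_id[dm$tag_id == focal])
  if (!length(focal_rec)) return(NULL)
  sort(unique(dm$tag_id[dm$receiver_id %in% focal_rec & dm$tag_id != focal]))
}

#' Detect pairwise association events
#'
#' Two individuals are associating when they are detected at the same
#' receiver with timestamps at most `window_s` apart. The default semantics
#' are a sliding pairwise window (|dt| <= window); `mode = "binned"` instead
#' declares co-occurrence within fixed windows of length `window_s` anchored
#' at the epoch, for comparison with bin-based implementations.
#'
#' @param detections detection table.
#' @param window_s association window, seconds (default 240 s = 4 min).
#' @param mode `"pairwise"` (default) or `"binned"`.
#' @param tz_offset_hours study timezone offset used to label each event
#'   with a calendar month (month of the earlier detection).
#' @return data frame `individual_a`, `individual_b` (canonical sorted
#'   pair), `receiver_id`, `time_a`, `time_b`, `month`.
#' @export
detect_associations <- function(detections, window_s = 240,
                                mode = c("pairwise", "binned"),
                                tz_offset_hours = 10) {
  mode <- match.arg(mode)
  stopifnot(window_s > 0)
  out <- list()
  for (rec in unique(detections$receiver_id)) {
    d <- detections[detections$receiver_id == rec, , drop = FALSE]
    if (nrow(d) < 2L) next
    d <- d[order(d$timestamp), , drop = FALSE]
    tt <- as.numeric(d$timestamp)
    if (mode == "pairwise") {
      ends <- findInterval(tt + window_s, tt)
      n_after <- pmax(ends - seq_along(tt), 0L)
      if (sum(n_after) == 0L) next
      i1 <- rep(seq_along(tt), n_after)
      i2 <- sequence(n_after) + i1
    } else {
      bin <- floor(tt / window_s)
      grp <- split(seq_along(tt), bin)
      grp <- grp[lengths(grp) >= 2L]
      if (!length(grp)) next
      prs <- lapply(grp, function(ii) {
        cmb <- utils::combn(ii, 2L)
        cbind(cmb[1L, ], cmb[2L, ])
      })
      prs <- do.call(rbind, prs)
      i1 <- prs[, 1L]; i2 <- prs[, 2L]
    }
    keep <- d$tag_id[i1] != d$tag_id[i2]
    i1 <- i1[keep]; i2 <- i2[keep]
    if (!length(i1)) next
    ta <- d$tag_id[i1]; tb <- d$tag_id[i2]
    swap <- ta > tb
    pa <- ifelse(swap, tb, ta)
    pb <- ifelse(swap, ta, tb)
    out[[rec]] <- data.frame(
      individual_a = pa, individual_b = pb, receiver_id = rec,
      time_a = d$timestamp[i1], time_b = d$timestamp[i2],
      month = month_of(pmin(d$timestamp[i1], d$timestamp[i2]), tz_offset_hours),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(individual_a = character(0), individual_b = character(0),
                      receiver_id = character(0),
                      time_a = as.POSIXct(character(0), tz = "UTC"),
                      time_b = as.POSIXct(character(0), tz = "UTC"),
                      month = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Partners of an individual in an event table, optionally month-filtered.
association_partners <- function(events, focal, month = NULL) {
  if (!is.null(month)) events <- events[events$month == month, , drop = FALSE]
  sort(unique(c(events$individual_b[events$individual_a == focal],
                events$individual_a[events$individual_b == focal])))
}

#' Monthly sociability of a focal individual
#'
#' Sociability is the proportion of the focal's social environment (potential
#' associates) that it was observed associating with: |observed| /
#' |potential|. With an empty environment the ratio is undefined and
#' sociability is missing.
#'
#' @inheritParams detect_associations
#' @param focal focal individual id.
#' @param month calendar month "YYYY-MM".
#' @param events optional precomputed event table from
#'   [detect_associations()] (recomputed when omitted).
#' @return list with `individual_id`, `month`, `potential`, `observed`,
#'   `sociability` (NA when undefined).
#' @export
monthly_sociability <- function(focal, month, detections, window_s = 240,
                                mode = c("pairwise", "binned"),
                                tz_offset_hours = 10, events = NULL) {
  potential <- social_environment(focal, month, detections, tz_offset_hours)
  if (is.null(potential)) {
    return(list(individual_id = focal, month = month, potential = NULL,
                observed = NULL, sociability = NA_real_))
  }
  if (is.null(events)) {
    events <- detect_associations(detections, window_s, mode, tz_offset_hours)
  }
  observed <- intersect(association_partners(events, focal, month), potential)
  soc <- if (length(potential)) length(observed) / length(potential) else NA_real_
  list(individual_id = focal, month = month, potential = potential,
       observed = observed, sociability = soc)
}

#' Monthly sociability table for all individuals
#'
#' @inheritParams detect_associations
#' @return data frame `individual_id`, `month`, `n_potential`, `n_observed`,
#'   `sociability` — one row per individual-month in which the individual
#'   was detected.
#' @export
monthly_social_table <- function(detections, window_s = 240,
                                 mode = c("pairwise", "binned"),
                                 tz_offset_hours = 10) {
  mode <- match.arg(mode)
  events <- detect_associations(detections, window_s, mode, tz_offset_hours)
  mon <- month_of(detections$timestamp, tz_offset_hours)
  combos <- unique(data.frame(individual_id = detections$tag_id, month = mon,
                              stringsAsFactors = FALSE))
  rows <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    s <- monthly_sociability(combos$individual_id[r], combos$month[r],
                             detections, window_s, mode, tz_offset_hours,
                             events = events)
    rows[[r]] <- data.frame(individual_id = s$individual_id, month = s$month,
                            n_potential = length(s$potential),
                            n_observed = length(s$observed),
                            sociability = s$sociability,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monthly potential and observed associate counts
#'
#' Builds the response table for the home-range/associates model: per
#' individual-month with a home-range estimate, one row for the number of
#' potential associates and one for the number observed.
#'
#' @param social_table output of [monthly_social_table()].
#' @param uds nested UD list from [monthly_uds()] providing `hr_size_km2`;
#'   individual-months without a UD are omitted.
#' @return data frame `individual_id`, `month`, `hr_size_km2`, `type`
#'   ("potential"/"observed"), `count`.
#' @export
monthly_associate_counts <- function(social_table, uds) {
  rows <- list()
  for (r in seq_len(nrow(social_table))) {
    id <- social_table$individual_id[r]
    m <- social_table$month[r]
    ud <- uds[[id]][[m]]
    if (is.null(ud)) next
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = id, month = m, hr_size_km2 = ud$hr_size_km2,
      type = c("potential", "observed"),
      count = c(social_table$n_potential[r], social_table$n_observed[r]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(individual_id = character(0), month = character(0),
                      hr_size_km2 = numeric(0), type = character(0),
                      count = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
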