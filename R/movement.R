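## Movement metrics: centre-of-activity estimation, daily river distance,
## 1D river-constrained kernel utilization distributions, home-range size and
## consecutive-month site fidelity. The river is a single channel, so the
## least-cost in-river distance between positions equals the absolute
## difference of their chainages and all spatial work is done in 1D.

#' Project planar points onto the river centreline
#'
#' Returns the chainage (along-channel distance, km) of the nearest point on
#' the centreline. When a point is equidistant from two segments the lower
#' chainage is chosen (documented tie-break).
#'
#' @param position numeric vector `c(x, y)`, a 2-column matrix, or a data
#'   frame with columns `x`, `y` (planar km).
#' @param axis a [river_axis()].
#' @return numeric vector of chainages, km.
#' @export
project_to_chainage <- function(position, axis) {
  stopifnot(inherits(axis, "river_axis"))
  if (is.null(dim(position))) position <- matrix(position, ncol = 2L)
  if (is.data.frame(position)) position <- cbind(position$x, position$y)
  n <- nrow(position)
  if (length(axis$x) < 2L) stop("empty river axis", call. = FALSE)
  best_d2 <- rep(Inf, n)
  best_ch <- rep(NA_real_, n)
  eps <- 1e-12
  for (s in seq_len(length(axis$x) - 1L)) {
    ax <- axis$x[s]; ay <- axis$y[s]
    dx <- axis$x[s + 1L] - ax; dy <- axis$y[s + 1L] - ay
    len2 <- dx * dx + dy * dy
    t <- ((position[, 1L] - ax) * dx + (position[, 2L] - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- ax + t * dx; py <- ay + t * dy
    d2 <- (position[, 1L] - px)^2 + (position[, 2L] - py)^2
    ch <- axis$chainage_km[s] + t * sqrt(len2)
    closer <- d2 < best_d2 - eps
    tie_lower <- abs(d2 - best_d2) <= eps & ch < best_ch
    upd <- closer | (tie_lower & !is.na(best_ch))
    best_d2[upd] <- d2[upd]
    best_ch[upd] <- ch[upd]
  }
  best_ch
}

#' Short-term centres of activity
#'
#' Partitions time into half-open bins `[start, start + bin)` aligned to the
#' epoch and computes, per individual and bin with at least one detection,
#' the detection-count-weighted mean receiver chainage. Bins without
#' detections yield no record.
#'
#' @param detections detection table (validated; every receiver_id must be
#'   present in `receivers`).
#' @param receivers receiver station table with `chainage_km`.
#' @param bin_duration_min temporal bin width, minutes (default 60).
#' @return data frame `individual_id`, `bin_start` (POSIXct UTC),
#'   `chainage_km`, `n_detections`.
#' @export
compute_coas <- function(detections, receivers, bin_duration_min = 60) {
  stopifnot(bin_duration_min > 0)
  i <- match(detections$receiver_id, receivers$receiver_id)
  if (anyNA(i)) {
    stop(sprintf("unknown receiver id '%s' in detections",
                 detections$receiver_id[which(is.na(i))[1L]]), call. = FALSE)
  }
  ch <- receivers$chainage_km[i]
  bin_s <- bin_duration_min * 60
  bin_start <- floor(as.numeric(detections$timestamp) / bin_s) * bin_s
  key <- data.frame(individual_id = detections$tag_id, bin_start = bin_start)
  agg_sum <- aggregate(ch, by = key, FUN = sum)
  agg_n <- aggregate(ch, by = key, FUN = length)
  out <- data.frame(individual_id = agg_sum$individual_id,
                    bin_start = as.POSIXct(agg_sum$bin_start,
                                           origin = "1970-01-01", tz = "UTC"),
                    chainage_km = agg_sum$x / agg_n$x,
                    n_detections = agg_n$x,
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monthly mean daily river distance
#'
#' Distances between successive centres of activity (|delta chainage|) are
#' assigned to the calendar day of the earlier COA, summed by day, and
#' averaged over the days of each month that have at least one travel
#' segment. A month with fewer than two COAs yields no value (missing, not
#' zero).
#'
#' @param coas COA table from [compute_coas()] (one or more individuals).
#' @param tz_offset_hours study timezone offset used for day/month binning.
#' @return data frame `individual_id`, `month` ("YYYY-MM"),
#'   `activity_km_per_day`.
#' @export
monthly_activity <- function(coas, tz_offset_hours = 10) {
  res <- list()
  for (id in unique(coas$individual_id)) {
    cc <- coas[coas$individual_id == id, , drop = FALSE]
    cc <- cc[order(cc$bin_start), , drop = FALSE]
    n <- nrow(cc)
    mon <- month_of(cc$bin_start, tz_offset_hours)
    coas_per_month <- table(mon)
    if (n < 2L) next
    seg_dist <- abs(diff(cc$chainage_km))
    seg_day <- day_of(cc$bin_start[-n], tz_offset_hours)
    seg_month <- mon[-n]
    daily <- aggregate(seg_dist, by = list(day = seg_day, month = seg_month), FUN = sum)
    monthly <- aggregate(daily$x, by = list(month = daily$month), FUN = mean)
    keep <- names(coas_per_month)[coas_per_month >= 2L]
    monthly <- monthly[monthly$month %in% keep, , drop = FALSE]
    if (nrow(monthly)) {
      res[[id]] <- data.frame(individual_id = id, month = monthly$month,
                              activity_km_per_day = monthly$x,
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(individual_id = character(0), month = character(0),
               activity_km_per_day = numeric(0))
  rownames(out) <- NULL
  out
}

#' Monthly utilization distribution on river chainage
#'
#' Gaussian kernel density of the month's COA positions over a 1D chainage
#' grid, truncated and renormalized to the river extent. The 95% home range
#' is the smallest set of grid bins (by descending density) whose mass
#' reaches 0.95; its linear extent is the home-range size.
#'
#' @param locations numeric COA chainages (km) of one individual-month.
#' @param grid_from_km,grid_to_km,grid_step_km chainage grid (bin centres at
#'   `from + step/2, ...`).
#' @param bandwidth_km Gaussian kernel SD, km.
#' @param min_unique_locations minimum distinct positions required (default
#'   5); below it the UD is absent and `NULL` is returned.
#' @param channel_width_km nominal channel width used to express home-range
#'   size in km^2.
#' @return object of class `monthly_ud` (list with `grid_km`, `step_km`,
#'   `density`, `hr95_mask`, `hr_size_km`, `hr_size_km2`,
#'   `n_unique_locations`) or `NULL`.
#' @export
estimate_monthly_ud <- function(locations, grid_from_km = 0, grid_to_km = 100,
                                grid_step_km = 0.5, bandwidth_km = 1,
                                min_unique_locations = 5L,
                                channel_width_km = 0.1) {
  if (bandwidth_km <= 0 || grid_step_km <= 0) {
    stop("bandwidth and grid step must be positive", call. = FALSE)
  }
  locations <- locations[is.finite(locations)]
  n_unique <- length(unique(locations))
  if (n_unique < min_unique_locations) return(NULL)
  centers <- seq(grid_from_km + grid_step_km / 2, grid_to_km, by = grid_step_km)
  dens <- rowSums(vapply(locations, function(l) dnorm(centers, l, bandwidth_km),
                         numeric(length(centers))))
  total <- sum(dens)
  if (total <= 0) stop("degenerate density (all mass outside the grid)", call. = FALSE)
  dens <- dens / total
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  k <- which(cum >= 0.95)[1L]
  mask <- logical(length(centers))
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(grid_km = centers, step_km = grid_step_km, density = dens,
                 hr95_mask = mask, hr_size_km = k * grid_step_km,
                 hr_size_km2 = k * grid_step_km * channel_width_km,
                 n_unique_locations = n_unique),
            class = "monthly_ud")
}

#' Volume of intersection between two utilization distributions
#'
#' `VI = sum over bins of min(density_a, density_b)`: 0 for disjoint home
#' ranges, 1 for identical ones. Both UDs must share the same grid.
#'
#' @param ud_a,ud_b `monthly_ud` objects.
#' @return overlap in \[0, 1\].
#' @export
volume_of_intersection <- function(ud_a, ud_b) {
  if (length(ud_a$grid_km) != length(ud_b$grid_km) ||
      any(abs(ud_a$grid_km - ud_b$grid_km) > 1e-9)) {
    stop("utilization distributions are on different grids", call. = FALSE)
  }
  sum(pmin(ud_a$density, ud_b$density))
}

#' Consecutive-month site fidelity
#'
#' For each pair of consecutive calendar months with both UDs present, the
#' volume of intersection is assigned to the later month. A gap month breaks
#' both of its pairs.
#'
#' @param uds named list of `monthly_ud` objects keyed by month "YYYY-MM".
#' @return data frame `month`, `site_fidelity`.
#' @export
site_fidelity_series <- function(uds) {
  uds <- uds[!vapply(uds, is.null, TRUE)]
  months <- names(uds)
  if (length(months) < 2L) {
    return(data.frame(month = character(0), site_fidelity = numeric(0)))
  }
  idx <- month_index(months)
  ord <- order(idx)
  months <- months[ord]; idx <- idx[ord]
  out <- list()
  for (j in 2:length(months)) {
    if (idx[j] - idx[j - 1L] == 1L) {
      out[[length(out) + 1L]] <- data.frame(
        month = months[j],
        site_fidelity = volume_of_intersection(uds[[months[j - 1L]]], uds[[months[j]]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(month = character(0), site_fidelity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Monthly utilization distributions for every individual
#'
#' Groups a COA table by individual and calendar month and fits the monthly
#' UD for each group with at least the minimum number of unique positions.
#'
#' @param coas COA table from [compute_coas()].
#' @param tz_offset_hours study timezone offset for month binning.
#' @param ... passed to [estimate_monthly_ud()].
#' @return nested list `uds[[individual_id]][[month]]`.
#' @export
monthly_uds <- function(coas, tz_offset_hours = 10, ...) {
  out <- list()
  coas$month <- month_of(coas$bin_start, tz_offset_hours)
  for (id in unique(coas$individual_id)) {
    cc <- coas[coas$individual_id == id, , drop = FALSE]
    uds <- list()
    for (m in unique(cc$month)) {
      ud <- estimate_monthly_ud(cc$chainage_km[cc$month == m], ...)
      if (!is.null(ud)) uds[[m]] <- ud
    }
    if (length(uds)) out[[id]] <- uds
  }
  out
}
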