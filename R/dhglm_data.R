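## Preparation of model-ready data for the joint mean/dispersion model:
## response transforms, standardization, covariate coding and index building.

cube_root <- function(x) sign(x) * abs(x)^(1 / 3)

apply_transform <- function(x, type) {
  switch(type, identity = x, cuberoot = cube_root(x),
         stop(sprintf("unknown transform '%s'", type), call. = FALSE))
}

## Design matrix shared by the mean and dispersion submodels:
## intercept, 11 month dummies (January reference), standardized total
## length, standardized (log) detection count.
dhglm_design <- function(month, tl, det) {
  p <- 14L
  X <- matrix(0, nrow = length(month), ncol = p)
  X[, 1L] <- 1
  for (j in 2:12) X[, j] <- as.numeric(month == j)
  X[, 13L] <- tl
  X[, 14L] <- det
  colnames(X) <- c("(Intercept)", paste0("month_", month_names[2:12]),
                   "total_length", "detections")
  X
}

#' Prepare model data for the double-hierarchical model
#'
#' Transforms and standardizes the three responses, codes the covariates and
#' builds individual/year indices. Two panel shapes are accepted:
#'
#' * a raw monthly behaviour panel from [monthly_behaviours()] (columns
#'   `individual_id`, `month` "YYYY-MM", `sociability`,
#'   `activity_km_per_day`, `site_fidelity`, `n_detections`) together with an
#'   `individuals` table supplying total length. Sociability and activity are
#'   cube-root transformed, all responses standardized to mean 0 / SD 1 over
#'   their available values, total length standardized, and detection counts
#'   log-transformed then standardized.
#' * a synthetic panel from [simulate_behaviour_panel()] (already on the
#'   transformed, standardized scale with standardized covariates); pass
#'   `transform = "identity"`, `standardize = FALSE`,
#'   `log_detections = FALSE` and it passes through unchanged.
#'
#' Individuals observed in fewer than `min_months` months (months with at
#' least one observed response) are dropped; rows with no observed response
#' are dropped.
#'
#' @param panel behaviour panel (either shape above).
#' @param individuals metadata table with `individual_id`, `total_length_m`
#'   (raw shape only).
#' @param transform per-response transforms, recycled to length 3
#'   (sociability, activity, site fidelity).
#' @param standardize standardize responses and total length.
#' @param log_detections log-transform detection counts before
#'   standardization.
#' @param min_months minimum months per individual (default 2).
#' @return object of class `dhglm_data`: list with `y` (n x 3, NA =
#'   missing), `X` (n x 14 design), `id`, `year`, `month` (integer
#'   indices), `id_levels`, `year_levels`, and `transforms` (per-response
#'   type, centre and scale for back-transformation).
#' @export
prepare_model_data <- function(panel, individuals = NULL,
                               transform = c("cuberoot", "cuberoot", "identity"),
                               standardize = TRUE, log_detections = TRUE,
                               min_months = 2L) {
  if (nrow(panel) == 0L) stop("empty behaviour panel", call. = FALSE)
  transform <- rep(transform, length.out = 3L)
  synthetic_shape <- all(c("total_length", "detections", "activity") %in% names(panel))
  if (synthetic_shape) {
    resp_cols <- c("sociability", "activity", "site_fidelity")
    month <- as.integer(panel$month)
    year_levels <- sort(unique(panel$year))
    year <- match(panel$year, year_levels)
    tl <- panel$total_length
    det <- panel$detections
  } else {
    resp_cols <- c("sociability", "activity_km_per_day", "site_fidelity")
    ml <- split_month_label(panel$month)
    month <- ml$month
    year_levels <- sort(unique(ml$year))
    year <- match(ml$year, year_levels)
    if (is.null(individuals)) {
      stop("individuals table required for raw panels (total length covariate)",
           call. = FALSE)
    }
    tl_raw <- individuals$total_length_m[match(panel$individual_id,
                                               individuals$individual_id)]
    if (anyNA(tl_raw)) stop("panel contains individuals missing from metadata",
                            call. = FALSE)
    tl <- if (standardize) as.numeric(scale(tl_raw)) else tl_raw
    det_raw <- if (log_detections) log(panel$n_detections) else panel$n_detections
    det <- if (standardize) as.numeric(scale(det_raw)) else det_raw
  }

  y <- matrix(NA_real_, nrow = nrow(panel), ncol = 3L,
              dimnames = list(NULL, BEHAVIOURS))
  transforms <- list()
  for (k in seq_len(3L)) {
    raw <- panel[[resp_cols[k]]]
    tr <- apply_transform(raw, transform[k])
    ctr <- 0; scl <- 1
    if (standardize) {
      ctr <- mean(tr, na.rm = TRUE)
      scl <- sd(tr, na.rm = TRUE)
      if (!is.finite(scl) || scl == 0) {
        stop(sprintf("response '%s' has zero variance", resp_cols[k]), call. = FALSE)
      }
      tr <- (tr - ctr) / scl
    }
    y[, k] <- tr
    transforms[[BEHAVIOURS[k]]] <- list(type = transform[k], centre = ctr, scale = scl)
  }

  keep_row <- rowSums(!is.na(y)) > 0L
  panel <- panel[keep_row, , drop = FALSE]
  y <- y[keep_row, , drop = FALSE]
  month <- month[keep_row]; year <- year[keep_row]
  tl <- tl[keep_row]; det <- det[keep_row]

  months_per_id <- tapply(panel$month, panel$individual_id,
                          function(m) length(unique(m)))
  keep_ids <- names(months_per_id)[months_per_id >= min_months]
  keep_row <- panel$individual_id %in% keep_ids
  if (!any(keep_row)) stop("no individuals left after the minimum-months filter",
                           call. = FALSE)
  panel <- panel[keep_row, , drop = FALSE]
  y <- y[keep_row, , drop = FALSE]
  month <- month[keep_row]; year <- year[keep_row]
  tl <- tl[keep_row]; det <- det[keep_row]

  id_levels <- sort(unique(panel$individual_id))
  structure(list(
    y = y,
    X = dhglm_design(month, tl, det),
    id = match(panel$individual_id, id_levels),
    year = year,
    month = month,
    id_levels = id_levels,
    year_levels = year_levels,
    transforms = transforms), class = "dhglm_data")
}
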