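## Generative mirror of the joint mean/dispersion model: monthly behavioural
## panels with known truth, used for parameter-recovery testing.

BEHAVIOURS <- c("soc", "act", "fid")
RANEF_NAMES <- c("a_soc", "a_act", "a_fid", "b_soc", "b_act", "b_fid")

named3 <- function(x, nm = BEHAVIOURS) {
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  names(x) <- nm
  x
}

month_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 3L, ncol(m) == 11L)
  dimnames(m) <- list(BEHAVIOURS, month_names[2:12])
  m
}

#' Generating truth for a synthetic behavioural panel
#'
#' Defines the full generative model: per-behaviour fixed effects of the mean
#' and dispersion submodels, the 6x6 individual-level covariance (SDs of the
#' three mean intercepts and of the three log-dispersion intercepts plus all
#' 15 correlations), the 6x6 year-level covariance, panel dimensions and
#' per-behaviour missingness rates. Defaults emulate a decade-scale estuarine
#' crocodile telemetry study: 118 individuals with a two-year panel each
#' (about 2830 individual-months), behaviour-specific availability (site
#' fidelity observable in roughly half the months), and fixed-effect /
#' variance-component magnitudes typical of standardized monthly sociability,
#' activity and site-fidelity responses.
#'
#' @param beta0,gamma0 length-3 intercepts (mean / log-dispersion model).
#' @param beta_month,gamma_month 3x11 month effects (February..December,
#'   January is the reference).
#' @param beta_tl,beta_det,gamma_tl,gamma_det length-3 slopes for standardized
#'   total length and standardized (log) detection count.
#' @param sd_id,sd_year length-6 SDs in the order a_soc, a_act, a_fid, b_soc,
#'   b_act, b_fid.
#' @param cor_id,cor_year 6x6 correlation matrices (same order).
#' @param n_individuals,n_months panel dimensions; months run consecutively
#'   from January of year 1.
#' @param missingness length-3 per-behaviour MCAR deletion rates.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(
    beta0 = c(-0.20, 0.33, 0.00),
    beta_month = rbind(
      soc = c(0.01, -0.37, 0.12, 0.02, 0.09, 0.20, 0.29, 0.39, 0.38, 0.27, 0.24),
      act = c(-0.07, -0.08, 0.04, 0.07, -0.12, -0.22, -0.13, -0.06, -0.02, -0.07, 0.00),
      fid = c(-0.14, -0.28, -0.52, -0.36, -0.39, -0.18, -0.41, -0.14, 0.02, -0.02, -0.06)),
    beta_tl = c(0.02, 0.34, 0.13),
    beta_det = c(0.64, 0.15, 0.11),
    gamma0 = c(-0.38, -0.28, -0.25),
    gamma_month = rbind(
      soc = c(0.21, 0.11, 0.16, -0.01, 0.02, -0.05, -0.07, -0.37, -0.40, -0.21, -0.28),
      act = c(0.02, 0.01, -0.04, 0.01, 0.02, -0.04, -0.13, -0.15, -0.18, -0.14, -0.12),
      fid = c(0.15, 0.20, 0.35, 0.23, 0.20, 0.21, 0.09, 0.00, -0.04, -0.08, -0.02)),
    gamma_tl = c(-0.03, -0.05, -0.08),
    gamma_det = c(-0.30, -0.22, -0.04),
    sd_id = c(0.27, 0.58, 0.49, 0.29, 0.31, 0.26),
    cor_id = default_cor_id(),
    sd_year = c(0.04, 0.11, 0.04, 0.08, 0.08, 0.07),
    cor_year = diag(6),
    n_individuals = 118L,
    n_months = 24L,
    missingness = c(0.002, 0.003, 0.487)) {
  truth <- list(
    beta0 = named3(beta0), beta_month = month_matrix(beta_month),
    beta_tl = named3(beta_tl), beta_det = named3(beta_det),
    gamma0 = named3(gamma0), gamma_month = month_matrix(gamma_month),
    gamma_tl = named3(gamma_tl), gamma_det = named3(gamma_det),
    sd_id = setNames(as.numeric(sd_id), RANEF_NAMES),
    cor_id = as.matrix(cor_id),
    sd_year = setNames(as.numeric(sd_year), RANEF_NAMES),
    cor_year = as.matrix(cor_year),
    n_individuals = as.integer(n_individuals),
    n_months = as.integer(n_months),
    missingness = named3(missingness))
  class(truth) <- "synthetic_truth"
  validate_truth(truth)
}

default_cor_id <- function() {
  R <- diag(6)
  dimnames(R) <- list(RANEF_NAMES, RANEF_NAMES)
  pairs <- list(
    c("a_soc", "a_act", -0.33), c("a_act", "a_fid", -0.41), c("a_soc", "a_fid", 0.10),
    c("a_soc", "b_soc", -0.56), c("a_act", "b_act", 0.01), c("a_fid", "b_fid", -0.66))
  for (p in pairs) {
    R[p[[1]], p[[2]]] <- R[p[[2]], p[[1]]] <- as.numeric(p[[3]])
  }
  R
}

validate_truth <- function(truth) {
  for (nm in c("cor_id", "cor_year")) {
    R <- truth[[nm]]
    if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)) || !is_psd(R)) {
      stop(sprintf("%s is not a symmetric positive semi-definite matrix", nm),
           call. = FALSE)
    }
    if (any(abs(diag(R) - 1) > 1e-10) || any(abs(R) > 1 + 1e-10)) {
      stop(sprintf("%s is not a correlation matrix", nm), call. = FALSE)
    }
  }
  if (any(truth$sd_id < 0) || any(truth$sd_year < 0)) {
    stop("random-effect SDs must be non-negative", call. = FALSE)
  }
  if (any(truth$missingness < 0 | truth$missingness > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  if (truth$n_individuals < 1L || truth$n_months < 1L) {
    stop("panel dimensions must be positive", call. = FALSE)
  }
  truth
}

truth_sigma <- function(truth, level = c("id", "year")) {
  level <- match.arg(level)
  sds <- if (level == "id") truth$sd_id else truth$sd_year
  R <- if (level == "id") truth$cor_id else truth$cor_year
  sd_cor_to_cov(sds, R)
}

## Draw MVN with possibly singular covariance (SDs of 0 are legal truths).
rmvn_psd <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(vals), length(vals))
  z <- matrix(rnorm(n * length(vals)), nrow = length(vals))
  t(L %*% z)
}

#' Simulate a monthly behavioural panel with known truth
#'
#' For individual i, behaviour k and month t the response is drawn as
#' `y ~ Normal(mu, sigma)` with
#' `mu = beta0_k + month_k(t) + beta_tl_k * TL_i + beta_det_k * D_it + a_ik + u_{year(t),k}`
#' and
#' `log sigma = gamma0_k + gmonth_k(t) + gamma_tl_k * TL_i + gamma_det_k * D_it + b_ik + v_{year(t),k}`,
#' with `(a_i, b_i) ~ MVN(0, Sigma_ID)` and `(u_y, v_y) ~ MVN(0, Sigma_year)`.
#' Covariates are generated already standardized, so the panel is on the
#' model-ready (transformed) scale. Cells are then deleted completely at
#' random at the per-behaviour missingness rates.
#'
#' @param truth a [synthetic_truth()].
#' @param seed integer seed; if `NULL` one is drawn and reported by message.
#' @return list with `panel` (data frame: individual_id, month_index, month,
#'   year, total_length, detections, sociability, activity, site_fidelity),
#'   `truth` (echo), and `ranef` (list of the drawn id- and year-level
#'   effects).
#' @export
simulate_behaviour_panel <- function(truth = synthetic_truth(), seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message(sprintf("simulate_behaviour_panel: drew seed %d", seed))
  }
  set.seed(seed)
  nid <- truth$n_individuals
  nt <- truth$n_months
  n_years <- (nt - 1L) %/% 12L + 1L

  ids <- sprintf("ind_%03d", seq_len(nid))
  tl <- rnorm(nid)
  w_id <- rmvn_psd(nid, truth_sigma(truth, "id"))
  w_year <- rmvn_psd(n_years, truth_sigma(truth, "year"))
  colnames(w_id) <- colnames(w_year) <- RANEF_NAMES

  idx_i <- rep(seq_len(nid), each = nt)
  idx_t <- rep(seq_len(nt), times = nid)
  month <- (idx_t - 1L) %% 12L + 1L
  year <- (idx_t - 1L) %/% 12L + 1L
  det <- rnorm(nid * nt)

  month_fx <- function(mmat) cbind(0, mmat)  # January reference
  y <- matrix(NA_real_, nrow = nid * nt, ncol = 3L)
  for (k in seq_len(3L)) {
    bm <- month_fx(truth$beta_month)[k, month]
    gm <- month_fx(truth$gamma_month)[k, month]
    mu <- truth$beta0[k] + bm + truth$beta_tl[k] * tl[idx_i] +
      truth$beta_det[k] * det + w_id[idx_i, k] + w_year[year, k]
    log_sigma <- truth$gamma0[k] + gm + truth$gamma_tl[k] * tl[idx_i] +
      truth$gamma_det[k] * det + w_id[idx_i, k + 3L] + w_year[year, k + 3L]
    y[, k] <- rnorm(nid * nt, mu, exp(log_sigma))
    drop <- runif(nid * nt) < truth$missingness[k]
    y[drop, k] <- NA_real_
  }

  panel <- data.frame(
    individual_id = ids[idx_i],
    month_index = idx_t,
    month = month,
    year = year,
    total_length = tl[idx_i],
    detections = det,
    sociability = y[, 1L],
    activity = y[, 2L],
    site_fidelity = y[, 3L],
    stringsAsFactors = FALSE)

  list(panel = panel, truth = truth,
       ranef = list(id = w_id, year = w_year, total_length = tl, seed = seed))
}
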