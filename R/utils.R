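#' Highest posterior density interval
#'
#' Narrowest interval containing a given mass of a sample, computed by the
#' standard sliding-window method on the sorted draws.
#'
#' @param x numeric vector of posterior draws.
#' @param prob target mass, default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  if (n == 1L) return(c(lower = x, upper = x))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  j <- which.min(widths)
  c(lower = x[j], upper = x[j + k])
}

## Split-Rhat (Gelman et al.): each chain halved, between/within variance ratio.
split_rhat <- function(draws, chain) {
  chains <- split(draws, chain)
  halves <- unlist(lapply(chains, function(z) {
    m <- length(z) %/% 2L
    if (m < 2L) return(list(z))
    list(z[seq_len(m)], z[(m + 1L):(2L * m)])
  }), recursive = FALSE)
  halves <- halves[lengths(halves) >= 2L]
  if (length(halves) < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(z) z[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Effective sample size via the initial positive sequence of autocorrelations,
## pooled across chains.
ess_basic <- function(draws, chain) {
  chains <- split(draws, chain)
  n <- min(lengths(chains))
  if (n < 4L) return(length(draws))
  rho <- rowMeans(vapply(chains, function(z) {
    z <- z[seq_len(n)]
    if (sd(z) == 0) return(rep(0, min(n - 1L, 100L)))
    a <- acf(z, lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1L]
    as.numeric(a)
  }, numeric(min(n - 1L, 100L))))
  s <- 0
  for (k in seq(1L, length(rho) - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
  }
  ess <- length(draws) / (1 + 2 * s)
  min(ess, length(draws))
}

## Multivariate normal draws via Cholesky (lower) factor of the covariance.
rmvn_chol <- function(n, sigma) {
  p <- ncol(sigma)
  L <- t(chol(sigma))
  z <- matrix(rnorm(n * p), nrow = p)
  t(L %*% z)
}

## Assemble a covariance matrix from SDs and a correlation matrix.
sd_cor_to_cov <- function(sds, corr) {
  diag(sds, length(sds)) %*% corr %*% diag(sds, length(sds))
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

## Stable hash of a configuration list (for run manifests).
config_hash <- function(config) {
  digest::digest(config, algo = "sha256")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- Study-time helpers -----------------------------------------------------
## Timestamps are stored in UTC; calendar binning shifts by the study's fixed
## UTC offset (hours) before formatting, so month/day boundaries are local.

study_local <- function(timestamp, tz_offset_hours) {
  timestamp + tz_offset_hours * 3600
}

month_of <- function(timestamp, tz_offset_hours) {
  format(study_local(timestamp, tz_offset_hours), "%Y-%m", tz = "UTC")
}

day_of <- function(timestamp, tz_offset_hours) {
  format(study_local(timestamp, tz_offset_hours), "%Y-%m-%d", tz = "UTC")
}

## "2019-03" -> list(year = 2019, month = 3)
split_month_label <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)
  list(year = as.integer(vapply(parts, `[`, "", 1L)),
       month = as.integer(vapply(parts, `[`, "", 2L)))
}

## Consecutive-month predicate on "YYYY-MM" labels.
month_index <- function(label) {
  p <- split_month_label(label)
  p$year * 12L + (p$month - 1L)
}

month_names <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
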