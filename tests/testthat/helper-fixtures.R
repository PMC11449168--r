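## Shared fixtures and the brute-force density oracle.

utc <- function(x) as.POSIXct(x, tz = "UTC")

## straight east-west axis: chainage equals x
straight_axis <- function(length_km = 100) {
  river_axis(data.frame(x = c(0, length_km), y = c(0, 0)))
}

make_detections <- function(tag, receiver, timestamp) {
  croctraits:::as_detections(data.frame(
    tag_id = tag, receiver_id = receiver, timestamp = timestamp,
    stringsAsFactors = FALSE))
}

## hand-built model data container (bypasses prepare_model_data so tests can
## control the exact row set and missingness pattern)
toy_dhglm_data <- function(nid = 5L, nt = 4L, nyr = 2L, seed = 1L,
                           miss_prob = 0.15) {
  set.seed(seed)
  n <- nid * nt
  month <- rep(seq_len(nt), nid) %% 12L + 1L
  X <- croctraits:::dhglm_design(month, rnorm(n), rnorm(n))
  y <- matrix(rnorm(3 * n), n, 3)
  y[runif(3 * n) < miss_prob] <- NA
  ## every row keeps at least one observed response
  for (t in which(rowSums(!is.na(y)) == 0L)) y[t, 1L] <- rnorm(1)
  structure(list(
    y = y, X = X,
    id = rep(seq_len(nid), each = nt),
    year = rep_len(seq_len(nyr), n),
    month = month,
    id_levels = sprintf("ind_%02d", seq_len(nid)),
    year_levels = seq_len(nyr),
    transforms = list(soc = list(type = "identity", centre = 0, scale = 1),
                      act = list(type = "identity", centre = 0, scale = 1),
                      fid = list(type = "identity", centre = 0, scale = 1))),
    class = "dhglm_data")
}

random_corr <- function(q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(q * q), q)
  S <- crossprod(A) + diag(q) * 0.5
  d <- 1 / sqrt(diag(S))
  diag(d) %*% S %*% diag(d)
}

random_dhglm_params <- function(data, seed = 1L) {
  set.seed(seed)
  nid <- length(data$id_levels)
  nyr <- length(data$year_levels)
  p <- ncol(data$X)
  list(beta = matrix(rnorm(p * 3, 0, 0.3), p, 3),
       gamma = matrix(rnorm(p * 3, 0, 0.2), p, 3),
       a = matrix(rnorm(nid * 3, 0, 0.4), nid, 3),
       b = matrix(rnorm(nid * 3, 0, 0.3), nid, 3),
       u = matrix(rnorm(nyr * 3, 0, 0.2), nyr, 3),
       v = matrix(rnorm(nyr * 3, 0, 0.2), nyr, 3),
       sd_id = runif(6, 0.2, 0.8),
       cor_id = random_corr(6),
       sd_year = runif(6, 0.1, 0.5),
       cor_year = random_corr(6))
}

## Independent oracle: direct cell-by-cell summation; MVN terms through
## explicit determinant/solve (no Cholesky, no shared code with the package).
brute_force_log_density <- function(params, data, priors = prior_spec()) {
  lp <- 0
  for (t in seq_len(nrow(data$y))) {
    for (k in 1:3) {
      if (is.na(data$y[t, k])) next
      mu <- sum(data$X[t, ] * params$beta[, k]) +
        params$a[data$id[t], k] + params$u[data$year[t], k]
      ls <- sum(data$X[t, ] * params$gamma[, k]) +
        params$b[data$id[t], k] + params$v[data$year[t], k]
      lp <- lp + dnorm(data$y[t, k], mu, exp(ls), log = TRUE)
    }
  }
  mvn_term <- function(W, sds, R) {
    Sig <- diag(sds) %*% R %*% diag(sds)
    Si <- solve(Sig)
    ld <- log(det(Sig))
    s <- 0
    for (i in seq_len(nrow(W))) {
      w <- W[i, ]
      s <- s - 0.5 * (6 * log(2 * pi) + ld + c(w %*% Si %*% w))
    }
    s
  }
  lp <- lp + mvn_term(cbind(params$a, params$b), params$sd_id, params$cor_id)
  lp <- lp + mvn_term(cbind(params$u, params$v), params$sd_year, params$cor_year)
  lp <- lp + sum(dnorm(c(params$beta), 0, priors$sd_beta, log = TRUE))
  lp <- lp + sum(dnorm(c(params$gamma), 0, priors$sd_gamma, log = TRUE))
  lp <- lp + sum(log(2) + dnorm(c(params$sd_id, params$sd_year), 0,
                                priors$sd_sd, log = TRUE))
  lp <- lp + (priors$lkj_eta - 1) *
    (log(det(params$cor_id)) + log(det(params$cor_year)))
  lp
}

## lightweight stand-in for a dhglm_fit when only draws are needed
fake_fit <- function(draws, transforms = NULL, id_levels = NULL) {
  structure(list(draws = draws,
                 data = list(transforms = transforms, id_levels = id_levels)),
            class = "dhglm_fit")
}

scaled_control <- function(iter = 1200L, warmup = 600L) {
  dhglm_control(chains = 2L, iter = iter, warmup = warmup, thin = 1L)
}
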