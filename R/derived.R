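## Derived personality/predictability statistics computed from the posterior:
## repeatability, coefficient of predictability, realized phenotypes and
## realized residual intra-individual variation (rIIV), mean-dispersion
## correlations and behavioural syndromes. All quantities are computed
## per posterior draw and then summarized (full uncertainty propagation);
## plug-in point-estimate versions are provided for worked examples on
## published tables.

match_behaviour <- function(behaviour) {
  full <- c(sociability = "soc", activity = "act", site_fidelity = "fid")
  if (behaviour %in% BEHAVIOURS) return(behaviour)
  if (behaviour %in% names(full)) return(full[[behaviour]])
  stop(sprintf("unknown behaviour '%s'", behaviour), call. = FALSE)
}

#' Repeatability from point estimates
#'
#' Variance-partitioning formula
#' `R = V_id / (V_id + V_year + V_res)` with `V_id = sd_id^2`,
#' `V_year = sd_year^2` and the residual variance taken from the dispersion
#' -model intercept on the log scale: `V_res = (exp(gamma0))^2`.
#'
#' @param sd_id among-individual SD of the mean-model intercepts.
#' @param sd_year among-year SD of the mean-model intercepts.
#' @param gamma0 dispersion-model intercept (log residual SD).
#' @return repeatability in \[0, 1\].
#' @export
repeatability_point <- function(sd_id, sd_year, gamma0) {
  v_id <- sd_id^2
  v_id / (v_id + sd_year^2 + exp(gamma0)^2)
}

#' Posterior repeatability of a behaviour
#'
#' Applies [repeatability_point()] per posterior draw and summarizes with
#' mean and 95% HPD interval. The plug-in value at the posterior means is
#' reported alongside.
#'
#' @param fit a `dhglm_fit`.
#' @param behaviour `"soc"`, `"act"` or `"fid"` (full names accepted).
#' @return list `draws`, `mean`, `hpd`, `plugin`.
#' @export
repeatability <- function(fit, behaviour) {
  k <- match_behaviour(behaviour)
  d <- fit$draws
  r <- repeatability_point(d[, paste0("sd_id_a_", k)],
                           d[, paste0("sd_year_a_", k)],
                           d[, paste0("disp_", k, "_(Intercept)")])
  plugin <- repeatability_point(mean(d[, paste0("sd_id_a_", k)]),
                                mean(d[, paste0("sd_year_a_", k)]),
                                mean(d[, paste0("disp_", k, "_(Intercept)")]))
  list(draws = r, mean = mean(r), hpd = hpd_interval(r), plugin = plugin)
}

#' Coefficient of predictability from a point estimate
#'
#' `CV_p = sqrt(exp(omega^2) - 1)` where `omega` is the among-individual SD
#' of the dispersion-model intercepts (the spread of individual log rIIVs).
#'
#' @param omega among-individual dispersion SD.
#' @return CV_p, non-negative.
#' @export
cv_p_point <- function(omega) {
  sqrt(exp(omega^2) - 1)
}

#' Posterior coefficient of predictability of a behaviour
#'
#' @inheritParams repeatability
#' @return list `draws`, `mean`, `hpd`, `plugin`.
#' @export
coefficient_of_predictability <- function(fit, behaviour) {
  k <- match_behaviour(behaviour)
  om <- fit$draws[, paste0("sd_id_b_", k)]
  r <- cv_p_point(om)
  list(draws = r, mean = mean(r), hpd = hpd_interval(r),
       plugin = cv_p_point(mean(om)))
}

back_transform_mean <- function(z, transform) {
  x <- z * transform$scale + transform$centre
  if (transform$type == "cuberoot") x <- x^3
  x
}

#' Realized behavioural phenotypes in original units
#'
#' Per draw and individual, the population intercept plus the individual's
#' mean random intercept is destandardized and (for cube-root transformed
#' responses) cubed back to the original scale, then summarized.
#'
#' @inheritParams repeatability
#' @return data frame `individual_id`, `mean`, `hpd_low`, `hpd_high`.
#' @export
realized_phenotypes <- function(fit, behaviour) {
  k <- match_behaviour(behaviour)
  tr <- fit$data$transforms[[k]]
  ids <- fit$data$id_levels
  b0 <- fit$draws[, paste0("mean_", k, "_(Intercept)")]
  out <- data.frame(individual_id = ids, mean = NA_real_,
                    hpd_low = NA_real_, hpd_high = NA_real_)
  for (i in seq_along(ids)) {
    z <- b0 + fit$draws[, paste0("id_a_", k, "[", ids[i], "]")]
    x <- back_transform_mean(z, tr)
    h <- hpd_interval(x)
    out$mean[i] <- mean(x)
    out$hpd_low[i] <- h[["lower"]]
    out$hpd_high[i] <- h[["upper"]]
  }
  out
}

#' Realized residual intra-individual variation in original units
#'
#' Per draw and individual, `exp(gamma0 + b_i)` rescaled by the response's
#' standardization SD. For cube-root transformed responses the cube is a
#' nonlinear map of the mean, not of an SD, so the original-unit rIIV is
#' approximate (SD-scale back-transform only) and flagged as such.
#'
#' @inheritParams repeatability
#' @return data frame `individual_id`, `mean`, `hpd_low`, `hpd_high`;
#'   attribute `approximate` is TRUE for power-transformed responses.
#' @export
realized_riiv <- function(fit, behaviour) {
  k <- match_behaviour(behaviour)
  tr <- fit$data$transforms[[k]]
  ids <- fit$data$id_levels
  g0 <- fit$draws[, paste0("disp_", k, "_(Intercept)")]
  out <- data.frame(individual_id = ids, mean = NA_real_,
                    hpd_low = NA_real_, hpd_high = NA_real_)
  for (i in seq_along(ids)) {
    s <- exp(g0 + fit$draws[, paste0("id_b_", k, "[", ids[i], "]")]) * tr$scale
    h <- hpd_interval(s)
    out$mean[i] <- mean(s)
    out$hpd_low[i] <- h[["lower"]]
    out$hpd_high[i] <- h[["upper"]]
  }
  attr(out, "approximate") <- tr$type == "cuberoot"
  out
}

#' Mean-rIIV correlations and behavioural syndromes
#'
#' Extracts from the posterior the among-individual correlation between each
#' behaviour's mean and dispersion intercepts (phenotype vs consistency) and
#' the pairwise correlations of the mean intercepts (behavioural
#' syndromes), summarized with mean and 95% HPD; `significant` flags
#' intervals excluding zero.
#'
#' @param fit a `dhglm_fit`.
#' @return data frame `quantity`, `pair`, `mean`, `hpd_low`, `hpd_high`,
#'   `significant`.
#' @export
random_effect_correlations <- function(fit) {
  want <- rbind(
    data.frame(quantity = "mean_riiv", pair = BEHAVIOURS,
               par = paste0("cor_id_a_", BEHAVIOURS, "_b_", BEHAVIOURS)),
    data.frame(quantity = "syndrome",
               pair = c("soc_act", "soc_fid", "act_fid"),
               par = c("cor_id_a_soc_a_act", "cor_id_a_soc_a_fid",
                       "cor_id_a_act_a_fid")))
  out <- data.frame(quantity = want$quantity, pair = want$pair,
                    mean = NA_real_, hpd_low = NA_real_, hpd_high = NA_real_,
                    significant = NA)
  for (r in seq_len(nrow(want))) {
    x <- fit$draws[, want$par[r]]
    h <- hpd_interval(x)
    out$mean[r] <- mean(x)
    out$hpd_low[r] <- h[["lower"]]
    out$hpd_high[r] <- h[["upper"]]
    out$significant[r] <- h[["lower"]] > 0 || h[["upper"]] < 0
  }
  out
}

#' Extract the posterior-mean 6x6 correlation matrix
#'
#' @param fit a `dhglm_fit`.
#' @param level `"id"` or `"year"`.
#' @return symmetric 6x6 matrix with unit diagonal.
#' @export
posterior_cor_matrix <- function(fit, level = c("id", "year")) {
  level <- match.arg(level)
  R <- diag(6)
  dimnames(R) <- list(RANEF_NAMES, RANEF_NAMES)
  for (i in 2:6) {
    for (j in seq_len(i - 1L)) {
      nm <- paste0("cor_", level, "_", RANEF_NAMES[j], "_", RANEF_NAMES[i])
      R[i, j] <- R[j, i] <- mean(fit$draws[, nm])
    }
  }
  R
}

#' Poisson mixed model for monthly associate counts
#'
#' Bayesian Poisson GLMM with log link: the monthly number of associates is
#' predicted by standardized home-range size, association type (potential vs
#' observed) and their interaction, with random intercepts for individual
#' and year. Fitted by coordinate-wise adaptive random-walk Metropolis;
#' priors are Normal(0, 5) on coefficients and half-Normal(0, 1) on
#' random-effect SDs.
#'
#' @param counts table from [monthly_associate_counts()] (or simulated:
#'   columns `individual_id`, `month` "YYYY-MM" or `year`, `hr_size_km2`,
#'   `type`, `count`).
#' @param chains,iter,warmup MCMC settings.
#' @param seed integer seed.
#' @return object of class `associates_fit`: `draws` of the four fixed
#'   effects and both SDs, `summary` with means and 95% HPDs, `fitted`
#'   posterior-mean rates.
#' @export
fit_associates_glmm <- function(counts, chains = 2L, iter = 4000L,
                                warmup = 2000L, seed = 1L) {
  if (all(counts$count == 0)) stop("all counts are zero", call. = FALSE)
  hr <- as.numeric(scale(counts$hr_size_km2))
  type_obs <- as.numeric(counts$type == "observed")
  Xf <- cbind(1, hr, type_obs, hr * type_obs)
  colnames(Xf) <- c("(Intercept)", "hr_size", "type_observed",
                    "hr_size:type_observed")
  id_levels <- sort(unique(counts$individual_id))
  id <- match(counts$individual_id, id_levels)
  yr_raw <- if ("year" %in% names(counts)) counts$year
    else split_month_label(counts$month)$year
  yr_levels <- sort(unique(yr_raw))
  yr <- match(yr_raw, yr_levels)
  nid <- length(id_levels); nyr <- length(yr_levels)
  yv <- counts$count
  rows_id <- split(seq_along(yv), id)
  rows_yr <- split(seq_along(yv), yr)

  n_fix <- ncol(Xf)
  npar <- n_fix + 2L + nid + nyr
  keep_names <- c(colnames(Xf), "sd_individual", "sd_year")

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    th <- c(rnorm(n_fix, 0, 0.1), log(0.5) + rnorm(2, 0, 0.2),
            rnorm(nid, 0, 0.1), rnorm(nyr, 0, 0.1))
    lp_row <- as.numeric(Xf %*% th[1:n_fix]) + th[n_fix + 2L + id] +
      th[n_fix + 2L + nid + yr]
    loglik <- function(rows) sum(dpois(yv[rows], exp(lp_row[rows]), log = TRUE))
    lscale <- rep(log(0.3), npar)
    acc <- integer(npar); tries <- integer(npar); batch <- 0L
    kept <- matrix(NA_real_, nrow = iter - warmup, ncol = n_fix + 2L)
    for (it in seq_len(iter)) {
      for (c_i in seq_len(npar)) {
        eps <- exp(lscale[c_i]) * rnorm(1L)
        if (c_i <= n_fix) {
          d_lp <- eps * Xf[, c_i]
          new_rows <- lp_row + d_lp
          dlp <- sum(dpois(yv, exp(new_rows), log = TRUE)) - loglik(seq_along(yv)) +
            dnorm(th[c_i] + eps, 0, 5, TRUE) - dnorm(th[c_i], 0, 5, TRUE)
          if (log(runif(1L)) < dlp) {
            th[c_i] <- th[c_i] + eps; lp_row <- new_rows; acc[c_i] <- acc[c_i] + 1L
          }
        } else if (c_i <= n_fix + 2L) {
          ## log SDs: conditional on effects, Gaussian-likelihood in the effects
          which_sd <- c_i - n_fix
          eff <- if (which_sd == 1L) th[n_fix + 2L + seq_len(nid)]
            else th[n_fix + 2L + nid + seq_len(nyr)]
          cur <- th[c_i]; newv <- cur + eps
          dlp <- sum(dnorm(eff, 0, exp(newv), TRUE)) - sum(dnorm(eff, 0, exp(cur), TRUE)) +
            (log(2) + dnorm(exp(newv), 0, 1, TRUE) + newv) -
            (log(2) + dnorm(exp(cur), 0, 1, TRUE) + cur)
          if (log(runif(1L)) < dlp) { th[c_i] <- newv; acc[c_i] <- acc[c_i] + 1L }
        } else {
          ## random effect coordinate
          if (c_i <= n_fix + 2L + nid) {
            g <- c_i - n_fix - 2L; rows <- rows_id[[as.character(g)]]
            sd_g <- exp(th[n_fix + 1L])
          } else {
            g <- c_i - n_fix - 2L - nid; rows <- rows_yr[[as.character(g)]]
            sd_g <- exp(th[n_fix + 2L])
          }
          if (is.null(rows)) rows <- integer(0)
          new_rows <- lp_row[rows] + eps
          dlp <- sum(dpois(yv[rows], exp(new_rows), log = TRUE)) - loglik(rows) +
            dnorm(th[c_i] + eps, 0, sd_g, TRUE) - dnorm(th[c_i], 0, sd_g, TRUE)
          if (log(runif(1L)) < dlp) {
            th[c_i] <- th[c_i] + eps; lp_row[rows] <- new_rows; acc[c_i] <- acc[c_i] + 1L
          }
        }
        tries[c_i] <- tries[c_i] + 1L
      }
      if (it <= warmup && it %% 50L == 0L) {
        batch <- batch + 1L
        delta <- min(0.05, 1 / sqrt(batch))
        rate <- ifelse(tries > 0L, acc / tries, 0.44)
        lscale <- lscale + ifelse(rate > 0.44, delta, -delta)
        acc[] <- 0L; tries[] <- 0L
      }
      if (it > warmup) {
        kept[it - warmup, ] <- c(th[1:n_fix], exp(th[n_fix + 1:2]))
      }
    }
    kept
  }

  draws <- do.call(rbind, lapply(seq_len(chains), function(ch)
    run_chain(seed + 7919L * (ch - 1L))))
  colnames(draws) <- keep_names
  summary <- summarize_fit(draws)
  fitted <- exp(as.numeric(Xf %*% colMeans(draws[, 1:n_fix, drop = FALSE])))
  structure(list(draws = draws, summary = summary, fitted = fitted,
                 data = counts), class = "associates_fit")
}
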