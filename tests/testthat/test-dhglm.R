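test_that("model data preparation applies the documented transforms", {
  panel <- data.frame(
    individual_id = rep(c("A", "B"), each = 4),
    month = rep(c("2019-01", "2019-02", "2019-03", "2019-04"), 2),
    sociability = c(0.064, 0.1, 0.2, 0.3, 0.05, 0.15, 0.25, 0.35),
    activity_km_per_day = c(1, 2, 3, 4, 2, 3, 4, 5),
    site_fidelity = c(0.5, 0.6, 0.7, 0.8, 0.4, 0.5, 0.6, 0.7),
    n_detections = c(10, 20, 30, 40, 50, 60, 70, 80))
  ind <- data.frame(individual_id = c("A", "B"), sex = "male",
                    total_length_m = c(2, 4))
  md <- prepare_model_data(panel, ind)
  ## cube root before standardization: 0.064 -> 0.4
  tr <- md$transforms$soc
  expect_equal(as.numeric(md$y[1, "soc"]) * tr$scale + tr$centre, 0.4)
  ## standardization round-trip
  expect_equal(md$y[, "soc"] * tr$scale + tr$centre,
               croctraits:::cube_root(panel$sociability))
  expect_equal(mean(md$y[, "act"]), 0, tolerance = 1e-12)
  expect_equal(sd(md$y[, "act"]), 1, tolerance = 1e-12)
  expect_equal(ncol(md$X), 14L)
  ## site fidelity is not power-transformed
  expect_equal(md$transforms$fid$type, "identity")

  ## zero-variance response is rejected by name
  panel2 <- panel
  panel2$site_fidelity <- 0.5
  expect_error(prepare_model_data(panel2, ind), "site_fidelity")
})

test_that("synthetic panels pass through prepare_model_data unchanged", {
  sim <- simulate_behaviour_panel(synthetic_truth(n_individuals = 10,
                                                  n_months = 6), seed = 2)
  md <- prepare_model_data(sim$panel, transform = "identity",
                           standardize = FALSE, log_detections = FALSE)
  keep <- rowSums(!is.na(sim$panel[c("sociability", "activity",
                                     "site_fidelity")])) > 0
  expect_equal(md$y[, "soc"], sim$panel$sociability[keep])
  expect_equal(md$y[, "act"], sim$panel$activity[keep])
  expect_equal(md$X[, "total_length"], sim$panel$total_length[keep])
})

test_that("the minimum-months filter drops sparse individuals", {
  panel <- data.frame(
    individual_id = c("A", "A", "A", "B"),
    month = c("2019-01", "2019-02", "2019-03", "2019-01"),
    sociability = c(1, 2, 3, 4) / 10,
    activity_km_per_day = 1:4,
    site_fidelity = c(0.1, 0.2, 0.3, 0.4),
    n_detections = c(5, 5, 5, 5))
  ind <- data.frame(individual_id = c("A", "B"), sex = "male",
                    total_length_m = c(2, 3))
  md <- prepare_model_data(panel, ind, min_months = 2L)
  expect_equal(md$id_levels, "A")
  expect_error(prepare_model_data(panel, ind, min_months = 5L), "no individuals")
})

test_that("the log posterior matches a brute-force evaluation on small instances", {
  for (seed in 1:4) {
    data <- toy_dhglm_data(nid = 5L, nt = 4L, seed = seed)
    params <- random_dhglm_params(data, seed = seed + 10L)
    got <- dhglm_log_density(params, data)
    want <- brute_force_log_density(params, data)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("the log posterior is cellwise additive and guards invalid proposals", {
  data <- toy_dhglm_data(nid = 4L, nt = 3L, seed = 7, miss_prob = 0)
  params <- random_dhglm_params(data, seed = 3L)
  full <- dhglm_log_density(params, data)
  ## masking one cell removes exactly its Normal log density
  t <- 5L; k <- 2L
  mu <- sum(data$X[t, ] * params$beta[, k]) + params$a[data$id[t], k] +
    params$u[data$year[t], k]
  ls <- sum(data$X[t, ] * params$gamma[, k]) + params$b[data$id[t], k] +
    params$v[data$year[t], k]
  cell <- dnorm(data$y[t, k], mu, exp(ls), log = TRUE)
  data_masked <- data
  data_masked$y[t, k] <- NA
  expect_equal(dhglm_log_density(params, data_masked), full - cell,
               tolerance = 1e-10)

  ## a non-PSD correlation proposal yields -Inf, not an error
  bad <- params
  bad$cor_id <- matrix(0.99, 6, 6) - diag(6) * -0.01
  bad$cor_id[1, 2] <- bad$cor_id[2, 1] <- -0.99
  expect_identical(dhglm_log_density(bad, data), -Inf)
  neg <- params
  neg$sd_id[1] <- -0.1
  expect_identical(dhglm_log_density(neg, data), -Inf)
})

test_that("the toy all-zero parameter case reduces to standard normal cells", {
  data <- toy_dhglm_data(nid = 2L, nt = 2L, seed = 5, miss_prob = 0)
  data$y[] <- NA
  data$y[1:3, 1] <- c(0.5, -1, 0.2)  # three observed cells
  p <- ncol(data$X)
  params <- list(beta = matrix(0, p, 3), gamma = matrix(0, p, 3),
                 a = matrix(0, 2, 3), b = matrix(0, 2, 3),
                 u = matrix(0, 2, 3), v = matrix(0, 2, 3),
                 sd_id = rep(0.5, 6), cor_id = diag(6),
                 sd_year = rep(0.5, 6), cor_year = diag(6))
  got <- dhglm_log_density(params, data)
  ## closed form: three standard-normal cells plus prior terms written out
  lik <- sum(dnorm(c(0.5, -1, 0.2), 0, 1, log = TRUE))
  prior_fixed <- 2 * 3 * p * dnorm(0, 0, 5, log = TRUE)
  ranef_at_zero <- 4 * (-0.5 * (6 * log(2 * pi) + 6 * log(0.25)))  # 2 id + 2 yr
  prior_sds <- 12 * (log(2) + dnorm(0.5, 0, 1, log = TRUE))
  expect_equal(got, lik + prior_fixed + ranef_at_zero + prior_sds,
               tolerance = 1e-10)
})

test_that("HPD summaries behave like highest-density intervals", {
  ## constant draws collapse to a point
  const <- summarize_fit(matrix(2, 100, 1, dimnames = list(NULL, "c")))
  expect_equal(const$mean, 2)
  expect_equal(const$hpd_low, 2)
  expect_equal(const$hpd_high, 2)

  set.seed(8)
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize_fit(z)
  expect_equal(s$hpd_low, -1.96, tolerance = 0.05)
  expect_equal(s$hpd_high, 1.96, tolerance = 0.05)

  ## on a right-skewed sample the HPD is shorter than the equal-tailed interval
  x <- exp(rnorm(2e4))
  h <- hpd_interval(x)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(h[["upper"]] - h[["lower"]], q[[2]] - q[[1]])

  ## agreement with an independent HPD implementation
  hc <- coda::HPDinterval(coda::as.mcmc(x))
  expect_equal(unname(h), c(hc[1, "lower"], hc[1, "upper"]), tolerance = 1e-8)
})

test_that("fitting is deterministic under a fixed seed", {
  sim <- simulate_behaviour_panel(synthetic_truth(n_individuals = 12,
                                                  n_months = 8), seed = 4)
  md <- prepare_model_data(sim$panel, transform = "identity",
                           standardize = FALSE, log_detections = FALSE)
  ctl <- dhglm_control(chains = 2, iter = 200, warmup = 100, thin = 2)
  f1 <- suppressWarnings(fit_dhglm(md, control = ctl, seed = 42))
  f2 <- suppressWarnings(fit_dhglm(md, control = ctl, seed = 42))
  expect_identical(f1$draws, f2$draws)
  ## retained draw count honours chains/warmup/thinning
  expect_equal(nrow(f1$draws), 2L * (200L - 100L) / 2L)
  f3 <- suppressWarnings(fit_dhglm(md, control = ctl, seed = 43))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a panel without individual effects concentrates the SDs near zero", {
  truth <- synthetic_truth(sd_id = rep(0, 6), sd_year = c(rep(0.05, 3), rep(0.05, 3)),
                           gamma0 = rep(0, 3),
                           n_individuals = 100, n_months = 36,
                           missingness = rep(0, 3))
  sim <- simulate_behaviour_panel(truth, seed = 19)
  md <- prepare_model_data(sim$panel, transform = "identity",
                           standardize = FALSE, log_detections = FALSE)
  fit <- suppressWarnings(fit_dhglm(md, control = scaled_control(), seed = 6))
  for (k in c("a_soc", "a_act", "a_fid")) {
    expect_lt(mean(fit$draws[, paste0("sd_id_", k)]), 0.15)
  }
})
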