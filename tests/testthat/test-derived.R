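test_that("variance-partitioning repeatability matches hand calculations", {
  ## activity-like inputs: 0.58^2 / (0.58^2 + 0.11^2 + exp(-0.28)^2)
  expect_equal(round(repeatability_point(0.58, 0.11, -0.28), 2), 0.37)
  ## sociability-like inputs
  expect_equal(round(repeatability_point(0.27, 0.04, -0.38), 2), 0.13)
  ## limits: no year or residual variance drives R to 1
  expect_equal(repeatability_point(0.5, 0, -1e3), 1)
  expect_equal(repeatability_point(0, 0.5, 0), 0)
})

test_that("the coefficient of predictability is sqrt(exp(omega^2) - 1)", {
  expect_equal(round(cv_p_point(0.29), 2), 0.30)
  expect_equal(round(cv_p_point(0.31), 2), 0.32)
  expect_equal(cv_p_point(0), 0)
  ## monotone increasing in omega
  om <- seq(0, 1.5, by = 0.05)
  expect_true(all(diff(cv_p_point(om)) > 0))
})

test_that("posterior repeatability and CV_p summarize per-draw computations", {
  set.seed(1)
  n <- 5000
  draws <- cbind("sd_id_a_soc" = abs(rnorm(n, 0.27, 0.02)),
                 "sd_year_a_soc" = abs(rnorm(n, 0.04, 0.01)),
                 "disp_soc_(Intercept)" = rnorm(n, -0.38, 0.05),
                 "sd_id_b_soc" = abs(rnorm(n, 0.29, 0.02)))
  fit <- fake_fit(draws)
  r <- repeatability(fit, "sociability")
  expect_equal(r$draws, repeatability_point(draws[, 1], draws[, 2], draws[, 3]))
  expect_true(all(r$draws >= 0 & r$draws <= 1))
  expect_equal(r$mean, mean(r$draws))
  expect_lt(r$hpd[["lower"]], r$mean)
  expect_equal(round(r$plugin, 2), 0.13, tolerance = 0.02)
  ## plug-in of posterior means differs from the per-draw mean but both valid
  expect_false(isTRUE(all.equal(r$plugin, r$mean, tolerance = 1e-12)))
  expect_true(r$plugin >= 0 && r$plugin <= 1)

  cp <- coefficient_of_predictability(fit, "soc")
  expect_equal(cp$draws, cv_p_point(draws[, "sd_id_b_soc"]))
  expect_true(all(cp$draws >= 0))
})

test_that("realized phenotypes back-transform to original units", {
  n <- 2000
  set.seed(2)
  draws <- cbind("mean_soc_(Intercept)" = rep(-0.20, n),
                 "id_a_soc[A]" = rep(0, n),
                 "id_a_soc[B]" = rnorm(n, 0.5, 0.01),
                 "id_a_soc[C]" = rnorm(n, -0.5, 0.01))
  tr <- list(soc = list(type = "cuberoot", centre = 0.42, scale = 0.12))
  fit <- fake_fit(draws, transforms = tr, id_levels = c("A", "B", "C"))
  rp <- realized_phenotypes(fit, "soc")
  ## (-0.20 * 0.12 + 0.42)^3 = 0.396^3
  expect_equal(rp$mean[rp$individual_id == "A"], 0.396^3, tolerance = 1e-12)
  ## ordering by realized phenotype equals ordering by the random intercept
  expect_true(rp$mean[rp$individual_id == "B"] > rp$mean[rp$individual_id == "A"])
  expect_true(rp$mean[rp$individual_id == "A"] > rp$mean[rp$individual_id == "C"])
})

test_that("realized rIIV exponentiates and rescales the dispersion effects", {
  n <- 1000
  draws <- cbind("disp_act_(Intercept)" = rep(0, n),
                 "id_b_act[A]" = rep(0, n),
                 "id_b_act[B]" = rep(log(2), n))
  tr <- list(act = list(type = "identity", centre = 0, scale = 1))
  fit <- fake_fit(draws, transforms = tr, id_levels = c("A", "B"))
  rv <- realized_riiv(fit, "act")
  expect_equal(rv$mean[rv$individual_id == "A"], 1)
  ## b = log 2 doubles the population residual SD
  expect_equal(rv$mean[rv$individual_id == "B"], 2)
  expect_false(attr(rv, "approximate"))
  tr2 <- list(act = list(type = "cuberoot", centre = 1, scale = 0.5))
  fit2 <- fake_fit(draws, transforms = tr2, id_levels = c("A", "B"))
  rv2 <- realized_riiv(fit2, "act")
  expect_true(attr(rv2, "approximate"))
  expect_equal(rv2$mean[rv2$individual_id == "A"], 0.5)
})

test_that("correlation extraction is symmetric with a unit diagonal", {
  sim <- simulate_behaviour_panel(synthetic_truth(n_individuals = 15,
                                                  n_months = 6), seed = 3)
  md <- prepare_model_data(sim$panel, transform = "identity",
                           standardize = FALSE, log_detections = FALSE)
  fit <- suppressWarnings(fit_dhglm(md, control = dhglm_control(
    chains = 1, iter = 120, warmup = 60, thin = 1), seed = 2))
  R <- posterior_cor_matrix(fit, "id")
  expect_equal(R, t(R))
  expect_equal(diag(R), setNames(rep(1, 6), rownames(R)))
  expect_true(all(abs(R) <= 1 + 1e-9))
  cors <- random_effect_correlations(fit)
  expect_equal(nrow(cors), 6L)
  expect_equal(cors$significant, cors$hpd_low > 0 | cors$hpd_high < 0)
})

test_that("the associates model recovers a negative hr-by-type interaction", {
  set.seed(9)
  nid <- 24L; nm <- 8L
  hr <- runif(nid, 0.5, 4)
  rows <- expand.grid(i = seq_len(nid), m = seq_len(nm))
  e_i <- rnorm(nid, 0, 0.2)
  hr_z <- (hr - mean(hr)) / sd(hr)
  counts <- rbind(
    data.frame(individual_id = sprintf("i%02d", rows$i), year = 2019L,
               hr_size_km2 = hr[rows$i], type = "potential",
               count = rpois(nrow(rows), exp(1.0 + 0.3 * hr_z[rows$i] + e_i[rows$i]))),
    data.frame(individual_id = sprintf("i%02d", rows$i), year = 2019L,
               hr_size_km2 = hr[rows$i], type = "observed",
               count = rpois(nrow(rows), exp(0.4 - 0.2 * hr_z[rows$i] + e_i[rows$i]))))
  fit <- fit_associates_glmm(counts, chains = 2L, iter = 2500L,
                             warmup = 1200L, seed = 4)
  s <- fit$summary
  inter <- s[s$parameter == "hr_size:type_observed", ]
  expect_lt(inter$mean, 0)
  expect_lt(inter$hpd_high, 0)  # truth: -0.2 - 0.3 = -0.5 on the log rate
  expect_true(all(fit$fitted > 0))
  ## cross-check point estimates against an independent frequentist fit
  counts$type <- factor(counts$type, levels = c("potential", "observed"))
  glmer_fit <- lme4::glmer(count ~ scale(hr_size_km2) * type + (1 | individual_id),
                           data = counts, family = poisson())
  fe <- lme4::fixef(glmer_fit)
  expect_equal(unname(s$mean[s$parameter == "hr_size:type_observed"]),
               unname(fe[["scale(hr_size_km2):typeobserved"]]), tolerance = 0.1)

  zero <- counts; zero$count <- 0L
  expect_error(fit_associates_glmm(zero), "zero")
})

test_that("a type-constant simulation leaves the interaction uncertain", {
  set.seed(14)
  nid <- 20L
  hr <- runif(nid, 0.5, 4)
  hr_z <- (hr - mean(hr)) / sd(hr)
  rows <- expand.grid(i = seq_len(nid), m = 1:6)
  counts <- do.call(rbind, lapply(c("potential", "observed"), function(ty)
    data.frame(individual_id = sprintf("i%02d", rows$i), year = 2019L,
               hr_size_km2 = hr[rows$i], type = ty,
               count = rpois(nrow(rows), exp(0.8 + 0.25 * hr_z[rows$i])))))
  fit <- fit_associates_glmm(counts, chains = 2L, iter = 2000L,
                             warmup = 1000L, seed = 8)
  inter <- fit$summary[fit$summary$parameter == "hr_size:type_observed", ]
  expect_true(inter$hpd_low < 0 && inter$hpd_high > 0)
})
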