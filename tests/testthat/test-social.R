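test_that("the social environment is the month's receiver-sharing conspecific set", {
  fx <- fixture_scenario("soc_half")
  env <- social_environment("F", "2019-01", fx$detections)
  expect_equal(env, c("B", "C"))  # D only at an unshared receiver

  ## focal undetected that month: absent, not empty
  expect_null(social_environment("F", "2019-02", fx$detections))

  ## conspecific at a shared receiver but in another month is excluded
  det <- rbind(fx$detections,
               data.frame(tag_id = "E", receiver_id = "R1",
                          timestamp = utc("2019-02-01 10:00:00")))
  expect_equal(social_environment("F", "2019-01", det), c("B", "C"))

  ## focal detected with no conspecifics anywhere: empty set
  solo <- make_detections("F", "R1", utc("2019-03-01 10:00:00"))
  expect_equal(social_environment("F", "2019-03", solo), character(0))
})

test_that("association events require same receiver within the window", {
  t0 <- utc("2019-01-10 08:00:00")
  det <- make_detections(c("F", "B", "F", "C", "F", "B"),
                         c("R1", "R1", "R2", "R2", "R3", "R4"),
                         t0 + c(0, 120, 1000, 1300, 2000, 2010))
  ev <- detect_associations(det, window_s = 240)
  ## F-B at R1 (dt 120) only: F-C dt 300 too far, F-B at different receivers
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$individual_a, "B")
  expect_equal(ev$individual_b, "F")
  expect_equal(ev$receiver_id, "R1")
})

test_that("sociability is observed over potential with the documented edge cases", {
  fx <- fixture_scenario("soc_half")
  s <- monthly_sociability("F", "2019-01", fx$detections)
  expect_equal(s$potential, c("B", "C"))
  expect_equal(s$observed, "B")
  expect_equal(s$sociability, 0.5)

  ## associating with the whole environment gives 1
  t0 <- utc("2019-05-10 08:00:00")
  det <- make_detections(c("F", "B"), "R1", t0 + c(0, 60))
  expect_equal(monthly_sociability("F", "2019-05", det)$sociability, 1)

  ## non-empty environment with no associations gives 0
  det2 <- make_detections(c("F", "B"), "R1", t0 + c(0, 6000))
  expect_equal(monthly_sociability("F", "2019-05", det2)$sociability, 0)

  ## empty environment: sociability missing, not zero
  det3 <- make_detections("F", "R1", t0)
  expect_true(is.na(monthly_sociability("F", "2019-05", det3)$sociability))
})

test_that("binned mode uses fixed windows where pairwise uses sliding ones", {
  t0 <- utc("2019-01-10 00:00:00")  # epoch-aligned bins
  ## 230 s apart but in different 240 s bins
  det <- make_detections(c("F", "B"), "R1", t0 + c(120, 350))
  expect_equal(nrow(detect_associations(det, mode = "pairwise")), 1L)
  expect_equal(nrow(detect_associations(det, mode = "binned")), 0L)
  ## same bin: both modes agree
  det2 <- make_detections(c("F", "B"), "R1", t0 + c(10, 100))
  expect_equal(nrow(detect_associations(det2, mode = "binned")), 1L)
})

test_that("observed is a subset of potential and the relation is symmetric", {
  sim <- simulate_detections(telemetry_scenario(n_individuals = 8,
                                                span_days = 20, seed = 17))
  tab <- monthly_social_table(sim$detections)
  expect_true(all(tab$n_observed <= tab$n_potential))
  expect_true(all(tab$sociability >= 0 & tab$sociability <= 1, na.rm = TRUE))
  ev <- detect_associations(sim$detections)
  ## symmetry is asserted for events not straddling a month boundary
  ev <- ev[croctraits:::month_of(ev$time_a, 10) ==
             croctraits:::month_of(ev$time_b, 10), ]
  for (m in unique(ev$month)) {
    for (r in which(ev$month == m)[1:min(10, sum(ev$month == m))]) {
      a <- ev$individual_a[r]; b <- ev$individual_b[r]
      sa <- monthly_sociability(a, m, sim$detections, events = ev)
      sb <- monthly_sociability(b, m, sim$detections, events = ev)
      expect_true(b %in% sa$observed)
      expect_true(a %in% sb$observed)
    }
  }
})

test_that("widening the association window never shrinks an observed set", {
  sim <- simulate_detections(telemetry_scenario(n_individuals = 6,
                                                span_days = 15, seed = 23))
  narrow <- monthly_social_table(sim$detections, window_s = 120)
  wide <- monthly_social_table(sim$detections, window_s = 600)
  joined <- merge(narrow, wide, by = c("individual_id", "month"),
                  suffixes = c("_narrow", "_wide"))
  expect_true(all(joined$n_observed_wide >= joined$n_observed_narrow))
  expect_equal(joined$n_potential_wide, joined$n_potential_narrow)
})

test_that("associate counts pair potential and observed rows with home-range size", {
  fx <- fixture_scenario("soc_half")
  tab <- monthly_social_table(fx$detections)
  ud <- estimate_monthly_ud(c(5, 6, 7, 8, 9))
  uds <- list(F = list("2019-01" = ud))
  counts <- monthly_associate_counts(tab, uds)
  frow <- counts[counts$individual_id == "F", ]
  expect_equal(nrow(frow), 2L)
  expect_equal(frow$count[frow$type == "potential"], 2L)
  expect_equal(frow$count[frow$type == "observed"], 1L)
  expect_equal(unique(frow$hr_size_km2), ud$hr_size_km2)
  ## individuals without a UD are omitted; counts are non-negative integers
  expect_false(any(counts$individual_id != "F"))
  expect_true(all(counts$count >= 0))
})
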