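test_that("projection returns chainage of the nearest centreline point", {
  ax <- straight_axis(100)
  expect_equal(project_to_chainage(c(12, 0), ax), 12)
  ## perpendicular offset does not move the along-channel position
  expect_equal(project_to_chainage(c(40, 0.3), ax), 40)
  expect_equal(project_to_chainage(c(40, -0.3), ax), 40)
  ## point past the end clamps to the terminal vertex
  expect_equal(project_to_chainage(c(105, 1), ax), 100)
  expect_error(project_to_chainage(c(0, 0), structure(list(x = 1, y = 1,
    chainage_km = 0), class = "river_axis")), "empty")
})

test_that("equidistant projection ties resolve to the lower chainage", {
  ## U-shaped channel: the centre point is 0.5 km from both straight reaches
  ax <- river_axis(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  expect_equal(project_to_chainage(c(0.5, 0.5), ax), 0.5)
})

test_that("COAs are detection-weighted mean chainages within half-open bins", {
  fx <- fixture_scenario("coa_weighted")
  coas <- compute_coas(fx$detections, fx$receivers, bin_duration_min = 60)
  expect_equal(nrow(coas), 1L)
  expect_equal(coas$chainage_km, 12.5)  # (3*10 + 1*20) / 4

  ## all detections at one receiver: COA equals that receiver's chainage
  det <- make_detections("A", "R1", utc("2019-01-01 10:00:00") + c(0, 60, 120))
  rec <- data.frame(receiver_id = "R1", chainage_km = 7)
  expect_equal(compute_coas(det, rec)$chainage_km, 7)

  ## detections straddling a bin boundary give one COA per bin
  det2 <- make_detections("A", c("R1", "R2"),
                          utc(c("2019-01-01 10:59:00", "2019-01-01 11:01:00")))
  rec2 <- data.frame(receiver_id = c("R1", "R2"), chainage_km = c(5, 15))
  coas2 <- compute_coas(det2, rec2)
  expect_equal(nrow(coas2), 2L)
  expect_equal(coas2$chainage_km, c(5, 15))

  expect_error(compute_coas(det2, rec), "unknown receiver")
})

test_that("COA chainage is bounded by contributing receiver chainages", {
  sim <- simulate_detections(telemetry_scenario(n_individuals = 4,
                                                span_days = 4, seed = 2))
  coas <- compute_coas(sim$detections, sim$receivers)
  expect_true(all(coas$chainage_km >= min(sim$receivers$chainage_km) - 1e-9))
  expect_true(all(coas$chainage_km <= max(sim$receivers$chainage_km) + 1e-9))
  ## halving the bin width never decreases the number of COA records
  coas30 <- compute_coas(sim$detections, sim$receivers, bin_duration_min = 30)
  expect_gte(nrow(coas30), nrow(coas))
})

test_that("monthly activity sums segment distances by day and averages by month", {
  mk_coas <- function(times, ch) data.frame(
    individual_id = "A", bin_start = utc(times), chainage_km = ch,
    n_detections = 1L)
  ## one day: 10 -> 14 -> 12 gives 6 km
  one <- mk_coas(c("2019-01-05 01:00", "2019-01-05 05:00", "2019-01-05 09:00"),
                 c(10, 14, 12))
  act <- monthly_activity(one, tz_offset_hours = 0)
  expect_equal(act$activity_km_per_day, 6)

  ## day sums 6 and 2 average to 4 km/day
  two <- mk_coas(c("2019-01-05 01:00", "2019-01-05 05:00", "2019-01-05 09:00",
                   "2019-01-06 01:00", "2019-01-06 09:00"),
                 c(10, 14, 12, 12, 14))
  ## segment 12 -> 12 crosses midnight and contributes 0 to day 1's sum
  act2 <- monthly_activity(two, tz_offset_hours = 0)
  expect_equal(act2$activity_km_per_day, 4)

  ## a single COA in a month yields no value, not zero
  single <- mk_coas("2019-02-05 01:00", 10)
  expect_equal(nrow(monthly_activity(single, tz_offset_hours = 0)), 0L)
})

test_that("the study timezone shifts month assignment", {
  ## 2019-01-31 15:00 UTC is 2019-02-01 01:00 at UTC+10
  det <- make_detections("A", "R1", utc("2019-01-31 15:00:00") + c(0, 60))
  rec <- data.frame(receiver_id = "R1", chainage_km = 5)
  coas <- compute_coas(det, rec)
  expect_equal(croctraits:::month_of(coas$bin_start, 10), "2019-02")
  expect_equal(croctraits:::month_of(coas$bin_start, 0), "2019-01")
})

test_that("monthly UD normalizes, respects the minimum-locations rule, peaks correctly", {
  ud <- estimate_monthly_ud(c(49.9, 49.95, 50, 50.05, 50.1), bandwidth_km = 1)
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
  expect_equal(ud$grid_km[which.max(ud$density)], 50, tolerance = 0.5)
  in_mask <- ud$grid_km[ud$hr95_mask]
  expect_true(all(diff(sort(in_mask)) <= ud$step_km + 1e-9))  # contiguous
  expect_true(min(in_mask) <= 50 && max(in_mask) >= 50)
  expect_gte(sum(ud$density[ud$hr95_mask]), 0.95)
  ## minimality: dropping the least-dense masked bin falls under 0.95
  masked <- sort(ud$density[ud$hr95_mask])
  expect_lt(sum(ud$density[ud$hr95_mask]) - masked[1L], 0.95)
  expect_equal(ud$hr_size_km, sum(ud$hr95_mask) * ud$step_km)

  expect_null(estimate_monthly_ud(c(1, 2, 3, 4)))          # 4 unique < 5
  expect_null(estimate_monthly_ud(rep(c(1, 2, 3, 4), 3)))  # still 4 unique
  expect_null(estimate_monthly_ud(rep(50, 5)))             # identical positions
  expect_error(estimate_monthly_ud(1:5, bandwidth_km = 0), "positive")
})

test_that("volume of intersection is exact on analytic cases and symmetric", {
  ud <- estimate_monthly_ud(c(48, 49, 50, 51, 52))
  expect_equal(volume_of_intersection(ud, ud), 1, tolerance = 1e-12)

  fx <- fixture_scenario("vi_disjoint")
  g <- fx$grid
  ud_a <- estimate_monthly_ud(fx$locations_a, g$from_km, g$to_km, g$step_km,
                              g$bandwidth_km)
  ud_b <- estimate_monthly_ud(fx$locations_b, g$from_km, g$to_km, g$step_km,
                              g$bandwidth_km)
  expect_equal(volume_of_intersection(ud_a, ud_b), 0, tolerance = 1e-9)

  ## uniform on [0,10] vs uniform on [5,15]: analytic overlap 0.5
  centers <- seq(0.25, 100, by = 0.5)
  uni <- function(lo, hi) {
    d <- as.numeric(centers > lo & centers < hi)
    structure(list(grid_km = centers, step_km = 0.5, density = d / sum(d)),
              class = "monthly_ud")
  }
  expect_equal(volume_of_intersection(uni(0, 10), uni(5, 15)), 0.5)

  ## symmetry and bounds on random UDs
  set.seed(4)
  for (r in 1:5) {
    u1 <- estimate_monthly_ud(runif(8, 0, 100))
    u2 <- estimate_monthly_ud(runif(8, 0, 100))
    v <- volume_of_intersection(u1, u2)
    expect_equal(v, volume_of_intersection(u2, u1))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  u_small <- estimate_monthly_ud(runif(8, 0, 50), grid_to_km = 50)
  expect_error(volume_of_intersection(u1, u_small), "grid")
})

test_that("site fidelity pairs consecutive months and assigns to the later", {
  ud1 <- estimate_monthly_ud(c(10, 11, 12, 13, 14))
  ud2 <- estimate_monthly_ud(c(30, 31, 32, 33, 34))
  ## Jan, Feb, Apr: only the Jan-Feb pair is consecutive
  sf <- site_fidelity_series(list("2019-01" = ud1, "2019-02" = ud1,
                                  "2019-04" = ud2))
  expect_equal(sf$month, "2019-02")
  expect_equal(sf$site_fidelity, 1, tolerance = 1e-12)

  ## twelve consecutive months yield eleven values; December pairs across years
  months <- c(sprintf("2019-%02d", 2:12), "2020-01")
  uds <- setNames(rep(list(ud1), 12L), months)
  sf2 <- site_fidelity_series(uds)
  expect_equal(nrow(sf2), 11L)
  expect_true(all(sf2$site_fidelity == 1))
})

test_that("monthly activity is unchanged by a duplicate detection after dedup", {
  det <- make_detections(rep("A", 4), c("R1", "R2", "R1", "R2"),
                         utc("2019-01-05 01:00:00") + c(0, 3600, 7200, 10800))
  rec <- data.frame(receiver_id = c("R1", "R2"), chainage_km = c(10, 14))
  base_act <- monthly_activity(compute_coas(det, rec), 0)
  dup <- suppressMessages(croctraits:::as_detections(rbind(det, det[2, ])))
  dup_act <- monthly_activity(compute_coas(dup, rec), 0)
  expect_equal(dup_act, base_act)
})
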