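# Daily water-driven crop simulator: elementary process operations, the
# season loop, conservation, and stress monotonicity.

test_that("growing degree days follow the capped-linear form", {
  expect_equal(growing_degree_days(20, 8), 12)
  expect_equal(growing_degree_days(35, 8, 30), 22)
  expect_equal(growing_degree_days(5, 8), 0)
  expect_error(growing_degree_days(20, 30, 10), "tbase")
})

test_that("LAI from leaf measurements and the cover conversion", {
  # one plant, one 50 x 8 cm leaf, K 0.75, 8 plants m-2
  expect_equal(lai_from_leaves(50, 8, m = 1, density = 8), 0.24)
  expect_equal(lai_from_leaves(c(50, 50), c(8, 8), m = 1, density = 8), 0.48)
  expect_equal(lai_from_leaves(50, 8, m = 1, density = 16), 0.48)  # linear
  expect_equal(lai_from_leaves(numeric(0), numeric(0), m = 3, density = 8), 0)
  expect_error(lai_from_leaves(50, 8, m = 0, density = 8), "plant")

  expect_equal(lai_to_cc(0), 0)
  expect_equal(lai_to_cc(3), 1.005 * (1 - exp(-1.8))^1.2, tolerance = 1e-12)
  expect_equal(lai_to_cc(3), 0.809, tolerance = 1e-3)
  expect_equal(lai_to_cc(1e6), 1)  # clipped: the raw asymptote is 1.005
  expect_error(lai_to_cc(-1), "non-negative")
})

test_that("the stress coefficient interpolates the convex threshold form", {
  expect_equal(stress_coefficient(0.1, 0.2, 0.65, 3), 1)
  expect_equal(stress_coefficient(0.65, 0.2, 0.65, 3), 0)
  expect_equal(stress_coefficient(0.9, 0.2, 0.65, 3), 0)
  # midway, shape 3: 1 - (e^1.5 - 1)/(e^3 - 1)
  mid <- stress_coefficient(0.425, 0.2, 0.65, 3)
  expect_equal(mid, 1 - (exp(1.5) - 1) / (exp(3) - 1), tolerance = 1e-12)
  expect_equal(mid, 0.818, tolerance = 1e-3)
  expect_error(stress_coefficient(0.5, 0.2, 0.65, 0), "shape")
  expect_error(stress_coefficient(0.5, 0.7, 0.65), "p_upper")
})

test_that("canopy growth, senescence and limits behave per the model", {
  crop <- fx_crop
  cc0 <- crop$den * crop$ccs / 1e8
  expect_equal(cc0, 0.00375774)
  # exponential phase over 100 GDD at cgc 0.006
  expect_equal(canopy_step(cc0, crop, 100, 400, ks_exp = 1),
               cc0 * exp(0.6), tolerance = 1e-12)
  # zero expansion stress freezes growth
  expect_equal(canopy_step(0.3, crop, 100, 400, ks_exp = 0), 0.3)
  # no growth at/after maturity
  expect_lte(canopy_step(0.9, crop, 20, crop$mat), 0.9)
  # bounded by mcc
  expect_lte(canopy_step(crop$mcc, crop, 500, 1000, ks_exp = 1), crop$mcc)
})

test_that("the soil bucket conserves water exactly", {
  soil <- soil_profile()
  fcmm <- soil$theta_fc * soil$depth * 1000
  s <- soil_water_step(fcmm, 0, 0, 0, soil)
  expect_equal(s$storage, fcmm)
  expect_equal(s$drainage, 0)
  expect_equal(s$runoff, 0)

  s <- soil_water_step(fcmm, 30, 0, 0, soil)  # tau = 1: drains immediately
  expect_equal(s$drainage, 30)
  expect_equal(s$storage, fcmm)

  mid <- 0.28 * soil$depth * 1000
  s <- soil_water_step(mid, 20, 5, 6, soil)
  expect_equal(s$storage + s$drainage + s$runoff - mid, 19, tolerance = 1e-12)
  expect_error(soil_water_step(mid, -1, 0, 0, soil), "non-negative")
})

test_that("the transpiration/evaporation partition follows cover and stress", {
  crop <- fx_crop
  expect_equal(crop_et(0, 6, 1, crop)$tr, 0)
  expect_equal(crop_et(0.9, 6, 1, crop)$tr, 1.1 * 0.9 * 6, tolerance = 1e-12)
  expect_equal(crop_et(1, 6, 1, crop)$e, 0)
  half <- crop_et(0.9, 6, 0.5, crop)
  expect_equal(half$tr, 0.5 * 1.1 * 0.9 * 6, tolerance = 1e-12)
})

test_that("biomass accumulation is water-driven and thermally gated", {
  crop <- fx_crop
  expect_equal(biomass_step(1, 0, 6, crop, 500), 1)
  # wp 39.7, Tr/ET0 = 0.9 -> 35.73 g m-2 = 0.3573 t ha-1
  expect_equal(biomass_step(0, 5.4, 6, crop, 500), 0.3573, tolerance = 1e-12)
  expect_equal(biomass_step(0, 5.4, 6, crop, 5), 0)  # below stbio = 12 GDD
  expect_warning(b <- biomass_step(1, 1, 0, crop, 500), "ET0")
  expect_equal(b, 1)
})

test_that("the harvest index respects its reference value and cap", {
  crop <- fx_crop
  full <- yield_and_hi(20, crop)
  expect_equal(full$hi, 0.49)
  expect_equal(full$yield, 0.49 * 20 * 1000)
  expect_equal(yield_and_hi(0, crop)$yield, 0)
  # the cap is hi (1 + hinc) = 0.5635 whatever the stress history
  for (s in seq(0, 1, by = 0.1))
    expect_lte(yield_and_hi(20, crop, 1, s, 1)$hi, 0.49 * 1.15 + 1e-12)
  # pollination failure reduces yield
  expect_lt(yield_and_hi(20, crop, 1, 0, 0.7)$yield, full$yield)
})

test_that("a season run is deterministic and internally consistent", {
  a <- fx_sim()
  b <- fx_sim()
  expect_equal(a$daily, b$daily, tolerance = 1e-15)
  expect_equal(a$yield, b$yield)

  expect_true(all(a$daily$cc >= 0 & a$daily$cc <= fx_crop$mcc))
  expect_true(all(diff(a$daily$biomass) >= -1e-12))
  expect_true(all(a$daily$p >= 0 & a$daily$p <= 1))
  zmm <- fx_soil$depth * 1000
  expect_true(all(a$daily$theta >= fx_soil$theta_wp - 1e-9))
  expect_true(all(a$daily$theta <= fx_soil$theta_sat + 1e-9))
  expect_equal(a$wue, a$yield / a$et, tolerance = 1e-15)
  # water-balance ET equals the summed daily ET exactly
  expect_equal(seasonal_et(a$precip_total, a$irrigation_total, a$dsws,
                           a$runoff_total, a$drainage_total),
               a$et, tolerance = 1e-9)
})

test_that("the unstressed companion run has ETa equal to ETm per stage", {
  ref <- run_season(fx_crop, fx_soil, fx_weather, unstressed = TRUE)
  expect_equal(ref$stage_eta, ref$stage_etm, tolerance = 1e-12)
  stressed <- fx_sim(fx_schedule(stage_plan(c(initial = 1, rapid = 0.6,
                                              mid = 0.6, late = 1))))
  expect_true(all(stressed$stage_eta <= stressed$stage_etm + 1e-9))
})

test_that("water starvation collapses yield", {
  dry_wx <- fx_weather
  dry_wx$precip[] <- 0
  full <- run_season(fx_crop, fx_soil, dry_wx, fx_schedule(), .with_reference = FALSE)
  bare <- run_season(fx_crop, fx_soil, dry_wx, NULL, .with_reference = FALSE)
  # pinned from the simulator: pre-season stored soil water alone sustains
  # only a small fraction of the irrigated yield
  expect_lt(bare$yield, 0.25 * full$yield)
  expect_true(all(bare$daily$p[bare$daily$gdd > 1000] > fx_crop$psen))
})

test_that("a too-short weather series fails with the GDD shortfall", {
  short <- fx_weather[1:40, ]
  class(short) <- c("daily_weather", "data.frame")
  expect_error(run_season(fx_crop, fx_soil, short), "GDD")
})

test_that("export writes tidy daily CSV and JSON summary", {
  sim <- fx_sim()
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  export_sim_result(sim, csv, js)
  daily <- read.csv(csv)
  expect_identical(nrow(daily), sim$season_days)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$yield_kg_hm2, sim$yield, tolerance = 1e-9)
})
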