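# Weather generation, FAO-56 reference evapotranspiration, and stage-wise
# schedule construction.

test_that("weather generation is reproducible and respects its invariants", {
  cfg <- weather_gen_config(seed = 1)
  a <- generate_season(cfg)
  b <- generate_season(cfg)
  expect_identical(a, b)

  expect_true(all(a$tmin <= a$tavg & a$tavg <= a$tmax))
  expect_true(all(a$precip >= 0))
  expect_true(all(a$rh >= 0 & a$rh <= 100))
  expect_true(all(a$wind2m >= 0))

  dry <- generate_season(weather_gen_config(wet_prob = 0, seed = 3))
  expect_identical(sum(dry$precip), 0)

  expect_error(weather_gen_config(days = 0), "season length")
})

test_that("seasonal rainfall matches the compound-process expectation", {
  # wet ~ Bernoulli(p), depth ~ Exp(mean m): E = n p m,
  # Var = n (p E[X^2] - p^2 m^2) with E[X^2] = 2 m^2
  p <- 0.1; m <- 5; n <- 130
  mu <- n * p * m
  sdv <- sqrt(n * (p * 2 * m^2 - (p * m)^2))
  tot <- sum(generate_season(weather_gen_config(days = n, wet_prob = p,
                                                rain_mean = m, seed = 7))$precip)
  expect_lt(abs(tot - mu), 3 * sdv)
})

test_that("ET0 is finite and positive across many generated seasons", {
  for (s in seq_len(25)) {
    wx <- generate_season(weather_gen_config(days = 60, seed = s))
    expect_true(all(is.finite(wx$et0)))
    expect_true(all(wx$et0 > 0))
  }
})

test_that("Penman-Monteith matches the step-by-step reference computation", {
  # frozen from an independent hand calculation following the standard daily
  # procedure (Tmax 30, Tmin 18, RH 50%, u2 2 m/s, 9 h sunshine, DOY 186,
  # 45.77 N, 270 m)
  v <- et0_penman_monteith(tmax = 30, tmin = 18, rh = 50, wind2m = 2,
                           sunshine = 9, doy = 186)
  expect_equal(v, 5.549279, tolerance = 1e-6)
})

test_that("ET0 increases with radiation and degenerates correctly", {
  base <- et0_penman_monteith(30, 18, rh = 50, wind2m = 2, solar_rad = 11,
                              doy = 186)
  doubled <- et0_penman_monteith(30, 18, rh = 50, wind2m = 2, solar_rad = 22,
                                 doy = 186)
  expect_gt(doubled, base)

  # saturated, calm air: the aerodynamic term vanishes and ET0 reduces to the
  # radiation term 0.408 * Delta * Rn / (Delta + gamma), recomputed here from
  # the published steps
  calm <- et0_penman_monteith(25, 25, 25, rh = 100, wind2m = 0,
                              solar_rad = 15, doy = 186)
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  delta <- 4098 * e0(25) / (25 + 237.3)^2
  gamma <- 0.000665 * 101.3 * ((293 - 0.0065 * 270) / 293)^5.26
  phi <- 45.77 * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * 186)
  dec <- 0.409 * sin(2 * pi / 365 * 186 - 1.39)
  ws <- acos(-tan(phi) * tan(dec))
  ra <- 24 * 60 / pi * 0.082 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  rso <- (0.75 + 2e-5 * 270) * ra
  rnl <- 4.903e-9 * (25 + 273.16)^4 * (0.34 - 0.14 * sqrt(e0(25))) *
    (1.35 * 15 / rso - 0.35)
  rn <- 0.77 * 15 - rnl
  expect_equal(calm, 0.408 * delta * rn / (delta + gamma), tolerance = 1e-10)
  expect_error(et0_penman_monteith(30, 18, rh = 120, wind2m = 2, sunshine = 9,
                                   doy = 186), "humidity")
  expect_error(et0_penman_monteith(10, 18, rh = 50, wind2m = 2, sunshine = 9,
                                   doy = 186), "tmin")
})

test_that("treatment schedules split stage ETc across 12 grouped events", {
  etc <- c(initial = 80, rapid = 200, mid = 150, late = 77)
  ck <- fx_schedule(stage_plan(), etc)
  expect_identical(nrow(ck), 12L)
  expect_equal(attr(ck, "quota"), 507)  # full supply over all stages
  expect_identical(as.integer(table(factor(ck$stage,
                                           c("initial", "rapid", "mid", "late")))),
                   c(2L, 4L, 3L, 3L))
  expect_false(is.unsorted(ck$day))

  t8 <- fx_schedule(stage_plan(c(initial = 1, rapid = 0.6, mid = 0.6,
                                 late = 1)), etc)
  expect_equal(sum(t8$depth_mm[t8$stage == "rapid"]), 0.6 * 200)
  expect_equal(sum(t8$depth_mm[t8$stage == "mid"]), 0.6 * 150)

  zero <- fx_schedule(stage_plan(c(initial = 0, rapid = 0, mid = 0, late = 0)),
                      etc)
  expect_equal(sum(zero$depth_mm), 0)

  expect_error(fx_schedule(stage_plan(), c(initial = -1, rapid = 1, mid = 1,
                                           late = 1)), "non-negative")
  expect_error(stage_plan(c(initial = 1, rapid = 0.7, mid = 1, late = 1)),
               "fractions")
})

test_that("the nine treatment plans reproduce the deficit design", {
  plans <- treatment_plans()
  expect_identical(names(plans),
                   c("CK", "T1", "T2", "T3", "T4", "T5", "T6", "T7", "T8"))
  expect_equal(plans$T8$fractions[["rapid"]], 0.6)
  expect_equal(plans$T8$fractions[["mid"]], 0.6)
  expect_equal(plans$CK$fractions[["rapid"]], 1.0)
  expect_equal(plans$T3$fractions[["mid"]], 0.8)
  # NC stages are full supply everywhere
  for (p in plans) {
    expect_equal(p$fractions[["initial"]], 1.0)
    expect_equal(p$fractions[["late"]], 1.0)
  }
})

test_that("weather and schedule CSV round-trips preserve the objects", {
  wx <- generate_season(weather_gen_config(days = 40, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_weather_csv(wx, f)
  wx2 <- read_weather_csv(f)
  expect_equal(as.data.frame(wx2), as.data.frame(wx), tolerance = 1e-12)

  sch <- fx_schedule()
  g <- tempfile(fileext = ".csv")
  write_schedule_csv(sch, g)
  sch2 <- read_schedule_csv(g)
  expect_equal(sch2$depth_mm, sch$depth_mm, tolerance = 1e-12)
  expect_identical(sch2$day, sch$day)
})
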