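# EFAST design, spectral index estimation and the screening rule.

ishigami_specs <- param_spec(c("x1", "x2", "x3"),
                             lower = rep(-pi, 3), upper = rep(pi, 3))

test_that("the search-curve design is deterministic, bounded and symmetric", {
  d1 <- efast_design(ishigami_specs, ns = 1000, seed = 9)
  d2 <- efast_design(ishigami_specs, ns = 1000, seed = 9)
  expect_identical(d1$samples, d2$samples)
  expect_true(all(d1$samples > -pi & d1$samples < pi))

  one <- param_spec("x", 2, 6)
  d <- efast_design(one, ns = 1001, seed = 2)
  expect_lt(abs(mean(d$samples) - 4), 0.04)  # search-curve symmetry

  expect_error(efast_design(ishigami_specs, ns = 100),
               "65")
})

test_that("an additive linear model has Si summing to one and no interactions", {
  specs <- param_spec(c("a", "b", "c"), rep(0, 3), rep(1, 3))
  res <- efast_run(function(x) 1 * x[1] + 2 * x[2] + 3 * x[3], specs,
                   ns = 65 * 3 * 5, seed = 3)
  expect_lt(abs(sum(res$si) - 1), 0.05)
  expect_lt(max(res$sti - res$si), 0.03)
  expect_true(all(res$si <= res$sti + 0.02))
})

test_that("the estimator recovers the Ishigami analytic indices", {
  res <- efast_run(ishigami, ishigami_specs, ns = 3500, seed = 1,
                   vectorized = TRUE)
  # analytic: S1 = 0.3139, S2 = 0.4424, S3 = 0, ST3 = 0.2437
  expect_lt(abs(res$si[1] - 0.3139), 0.03)
  expect_lt(abs(res$si[2] - 0.4424), 0.03)
  expect_lt(abs(res$si[3]), 0.03)
  expect_lt(abs(res$sti[3] - 0.2437), 0.05)
  expect_gt(res$sti[3], res$si[3] + 0.15)
  expect_true(all(res$si <= res$sti + 0.02))
})

test_that("constant output degrades gracefully to zero indices", {
  d <- efast_design(ishigami_specs, ns = 300, seed = 5)
  w <- capture_warnings(res <- efast_indices(rep(2, 300 * 3), d))
  expect_match(w, "variance", all = TRUE)
  expect_length(w, 3)  # one per curve
  expect_true(all(res$si == 0 & res$sti == 0))
})

test_that("the screening rule is a strict-threshold union ordered by STi", {
  res <- structure(data.frame(
    name = c("a", "b", "c", "d"),
    si = c(0.06, 0.04, 0.05, 0.20),
    sti = c(0.12, 0.09, 0.10, 0.30),
    interaction = c(0.06, 0.05, 0.05, 0.10)),
    class = c("sensitivity_result", "data.frame"))
  sel <- screen_parameters(res)
  expect_identical(sel, c("d", "a"))  # b rejected; c rejected at equality
})

test_that("time-resolved indices expose phenology-gated parameters", {
  # a toy phenological model: parameter q only acts after "flowering"
  specs <- param_spec(c("g", "q"), c(0.5, 0.5), c(1.5, 1.5))
  times <- seq(0.1, 1, by = 0.3)
  d <- efast_design(specs, ns = 65 * 2 * 5, seed = 8)
  ymat <- vapply(times, function(tt)
    apply(d$samples, 1, function(x) x[1] * tt + if (tt > 0.5) x[2] else 0),
    numeric(nrow(d$samples)))
  res <- efast_indices_over_time(ymat, d)
  expect_lt(res[[1]]$si[2], 0.03)   # inactive before its stage
  expect_gt(res[[4]]$si[2], 0.3)    # dominant later
})

test_that("crop parameter ranges respect the profile invariants", {
  specs <- crop_param_ranges(fx_crop, c("wp", "cgc", "psen", "mcc"))
  expect_true(all(specs$lower < specs$upper))
  expect_lte(specs$upper[specs$name == "mcc"], 0.999)
  expect_error(crop_param_ranges(fx_crop, "nosuch"), "unknown")
})

test_that("a small sensitivity run on the simulator ranks wp among the top", {
  specs <- crop_param_ranges(fx_crop, c("wp", "cgc", "kcb"), frac = 0.2)
  sched <- fx_schedule()
  model <- function(x) {
    p <- crop_params(wp = x[1], cgc = x[2], kcb = x[3], base = fx_crop)
    run_season(p, fx_soil, fx_weather, sched, .with_reference = FALSE)$yield
  }
  res <- efast_run(model, specs, ns = 65 * 3, seed = 2)
  expect_true("wp" %in% screen_parameters(res))
  expect_true(all(res$si >= -0.02 & res$sti <= 1.02))
})
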