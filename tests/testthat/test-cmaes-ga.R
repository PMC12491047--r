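# CMA-ES core behavior and the allocation GA.

test_that("CMA-ES solves the 5-D sphere within the evaluation budget", {
  res <- cmaes_minimize(function(x) sum(x^2), rep(1, 5),
                        cmaes_config(sigma0 = 0.3, max_iter = 1000,
                                     max_evals = 3000, tol = 1e-10, seed = 1))
  expect_lt(res$value, 1e-8)
  expect_lte(res$evals, 3000)
})

test_that("CMA-ES is deterministic and translation-invariant", {
  f <- function(x) sum((x - 2)^2) + 0.5
  cfg <- cmaes_config(sigma0 = 0.4, max_iter = 120, seed = 7)
  a <- cmaes_minimize(f, c(0, 0, 0), cfg)
  b <- cmaes_minimize(f, c(0, 0, 0), cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$par, b$par)

  # translating the objective leaves the trace identical
  cshift <- 5
  g <- function(x) sum((x - 2 - cshift)^2) + 0.5
  at <- cmaes_minimize(g, c(0, 0, 0) + cshift, cfg)
  expect_equal(at$trace, a$trace, tolerance = 1e-9)

  # best-so-far is non-increasing
  expect_true(all(diff(a$trace) <= 0))
})

test_that("CMA-ES affine scaling is compensated by sigma0 scaling", {
  q <- function(x) sum(c(1, 4, 9) * x^2)
  cfg1 <- cmaes_config(sigma0 = 0.5, max_iter = 150, seed = 3)
  r1 <- cmaes_minimize(q, c(1, 1, 1), cfg1)
  s <- 10
  q2 <- function(x) q(x / s)
  cfg2 <- cmaes_config(sigma0 = 0.5 * s, max_iter = 150, seed = 3)
  r2 <- cmaes_minimize(q2, c(1, 1, 1) * s, cfg2)
  expect_lt(abs(r1$value - r2$value), 1e-6)
})

test_that("CMA-ES aborts on NaN and validates the start point", {
  expect_error(cmaes_minimize(function(x) NaN, c(1, 1)), "finite")
  bad <- function(x) if (sum(x^2) < 0.5) NaN else sum(x^2)
  expect_error(cmaes_minimize(bad, c(1, 1),
                              cmaes_config(sigma0 = 0.5, max_iter = 500,
                                           seed = 2)), "NaN")
})

test_that("the diagonal variant minimizes a moderately high-dimensional sum", {
  n <- 60
  res <- cmaes_minimize(function(x) sum(x^2), rep(1, n),
                        cmaes_config(sigma0 = 0.3, max_iter = 400,
                                     diagonal = TRUE, seed = 5))
  expect_lt(res$value, 1e-3 * n)
})

test_that("simplex repair clips, renormalizes and honors the cap", {
  s <- repair_simplex(c(-1, 2, 3, 0))
  expect_true(all(s >= 0))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  s2 <- repair_simplex(c(0.9, 0.05, 0.03, 0.02), share_cap = 0.4)
  expect_lte(max(s2), 0.4 + 1e-9)
  expect_equal(sum(s2), 1, tolerance = 1e-12)
  expect_error(repair_simplex(rep(1, 4), share_cap = 0.1), "cap")
})

test_that("the GA finds the symmetric optimum of a concave fitness", {
  # max sum(sqrt(s_i)) on the simplex -> equal shares 1/12 by symmetry
  res <- ga_optimize_allocation(function(s) sum(sqrt(s)), quota = 120,
                                ga_config(pop = 60, generations = 250,
                                          mut_sd = 0.02, seed = 11))
  expect_lt(max(abs(res$shares - 1 / 12)), 0.01)
  expect_true(all(diff(res$trace) >= -1e-12))  # elitism: non-decreasing
})

test_that("every GA genome stays on the capped simplex and beats the baseline", {
  seen <- new.env(); seen$bad <- 0
  fit <- function(s) {
    if (abs(sum(s) - 1) > 1e-9 || any(s < -1e-12)) seen$bad <- seen$bad + 1
    -sum((s - 1 / 12)^2)
  }
  base <- rep(c(0.2, 0.05), 6); base <- base / sum(base)
  res <- ga_optimize_allocation(fit, quota = 240,
                                ga_config(pop = 20, generations = 40, seed = 3),
                                baseline = base)
  expect_identical(seen$bad, 0)
  expect_gte(res$fitness, res$baseline_fitness)

  # zero quota returns the baseline untouched
  res0 <- ga_optimize_allocation(fit, quota = 0, baseline = base)
  expect_equal(res0$shares, base, tolerance = 1e-12)
  expect_error(ga_optimize_allocation(fit, quota = -1), "quota")
})
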