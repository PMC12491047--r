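# Low-rank trajectory features, additive reconstruction, and the adaptive
# residual-weight/parameter-diffusion step.

test_that("mode extraction recovers rank and energy structure", {
  # rank-1 synthetic matrix
  u <- rnorm(30); v <- c(1, 2, 3)
  X <- outer(u, v)
  basis <- extract_modes(X, center = FALSE)
  expect_identical(basis$r, 1L)
  expect_equal(basis$energy[1], 1, tolerance = 1e-12)

  set.seed(6)
  Y <- matrix(rnorm(20 * 12), 20, 12)
  b <- extract_modes(Y, energy_threshold = 0.9)
  G <- crossprod(b$modes)
  expect_equal(G, diag(ncol(Y)), tolerance = 1e-10)  # orthonormal modes
  expect_true(all(diff(b$energy) <= 1e-12))           # non-increasing
  expect_lte(sum(b$energy), 1 + 1e-12)

  # SVD identity: rank-r reconstruction error^2 = sum of discarded sigma^2
  for (r in 1:5) {
    err <- reconstruction_error(b, Y, rank = r)
    expect_equal(err^2, sum(b$singular_values[-seq_len(r)]^2),
                 tolerance = 1e-8)
  }
  # monotone non-increasing in rank
  errs <- vapply(1:12, function(r) reconstruction_error(b, Y, r), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))

  expect_error(extract_modes(matrix(0, 5, 3)), "degenerate")
  expect_error(extract_modes(matrix(1, 1, 3)), "two trajectory rows")
})

test_that("reconstruction is exactly additive through the retained modes", {
  set.seed(7)
  X <- matrix(rnorm(40 * 6), 40, 6)
  basis <- extract_modes(X, energy_threshold = 0.8)
  u0 <- rnorm(6)
  z <- rnorm(basis$r)
  expect_equal(reconstruct(u0, rep(0, basis$r), basis), u0)
  expect_equal(reconstruct(rep(0, 6), z, basis),
               drop(z %*% t(basis$modes[, 1:basis$r])), tolerance = 1e-12)
  # u - f_NN lies in the mode span: residual after projection is zero
  u <- reconstruct(u0, z, basis)
  diffv <- u - u0
  V <- basis$modes[, 1:basis$r, drop = FALSE]
  expect_equal(drop(diffv - V %*% crossprod(V, diffv)), rep(0, 6),
               tolerance = 1e-12)
})

test_that("the adaptive step triggers only on stalls and never weakens", {
  st <- adapt_state(patience = 5, sigma_d = 0.1)
  par <- rnorm(40)
  idx <- 21:40
  res <- c(water = 1e-2, production = 1e-6)

  # improving history: no-op
  out <- adapt_step(st, seq(10, 1, length.out = 10), par, res, idx, rng_seed = 1)
  expect_false(out$triggered)
  expect_identical(out$par, par)

  # flat history with a high water residual: weight doubled, only the
  # eligible positions perturbed
  out2 <- adapt_step(st, rep(5, 10), par, res, idx, rng_seed = 1)
  expect_true(out2$triggered)
  expect_identical(out2$term, "water")
  expect_equal(unname(out2$state$weights["water"]), 2)
  expect_equal(unname(out2$state$weights["production"]), 1)
  expect_identical(out2$par[1:20], par[1:20])
  expect_false(all(out2$par[idx] == par[idx]))
  expect_true(all(out2$state$weights >= 1))

  # determinism under the rng seed
  out2b <- adapt_step(st, rep(5, 10), par, res, idx, rng_seed = 1)
  expect_identical(out2$par, out2b$par)

  # a second trigger uses a smaller diffusion scale and caps the weight
  st2 <- out2$state
  out3 <- adapt_step(st2, rep(5, 20), par, res, idx, rng_seed = 2)
  expect_true(out3$triggered)
  expect_lt(out3$sigma_used, out2$sigma_used)
  for (i in 1:10) {
    st2 <- adapt_step(st2, rep(5, 20 * i + 20), par, res, idx, 2 + i)$state
  }
  expect_lte(max(st2$weights), 32)

  # short history never triggers
  out4 <- adapt_step(st, rep(5, 3), par, res, idx, 1)
  expect_false(out4$triggered)
  # low residuals never trigger
  out5 <- adapt_step(st, rep(5, 10), par, c(water = 1e-9, production = 1e-9),
                     idx, 1)
  expect_false(out5$triggered)
})
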