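# Network forward map and exact derivatives, water-balance residual by
# manufactured solutions, production function, and the loss decomposition.

test_that("the tanh network forward map matches hand evaluation", {
  net <- mlp_init(1, 1, hidden = 1, layers = 1, seed = 1)
  # single unit: beta = 1, omega = 1, b = 0 -> y = tanh(x)
  net$W[[1]] <- matrix(1); net$b[[1]] <- 0
  net$W[[2]] <- matrix(1); net$b[[2]] <- 0
  expect_equal(drop(mlp_forward(net, matrix(0.5))), tanh(0.5), tolerance = 1e-12)
  expect_equal(tanh(0.5), 0.4621, tolerance = 1e-4)

  zero <- mlp_init(3, 2, seed = 2)
  for (l in seq_along(zero$W)) { zero$W[[l]][] <- 0; zero$b[[l]][] <- 0 }
  expect_true(all(mlp_forward(zero, matrix(rnorm(12), 4)) == 0))

  # hidden activations are bounded, so outputs are bounded by the L1 norm of
  # the output layer
  net2 <- mlp_init(2, 1, seed = 3)
  x <- matrix(rnorm(200, 0, 10), ncol = 2)
  bound <- sum(abs(net2$W[[3]])) + abs(net2$b[[3]])
  expect_true(all(abs(mlp_forward(net2, x)) <= bound))
})

test_that("analytic network derivatives agree with finite differences", {
  net <- mlp_init(3, 1, seed = 4)
  x <- matrix(rnorm(15), ncol = 3)
  g <- mlp_forward_grad(net, x, wrt = 2)
  h <- 1e-5
  xp <- x; xp[, 2] <- xp[, 2] + h
  xm <- x; xm[, 2] <- xm[, 2] - h
  fd1 <- (mlp_forward(net, xp) - mlp_forward(net, xm)) / (2 * h)
  fd2 <- (mlp_forward(net, xp) - 2 * mlp_forward(net, x) +
            mlp_forward(net, xm)) / h^2
  expect_equal(g$d1, fd1, tolerance = 1e-6)
  expect_equal(g$d2, fd2, tolerance = 1e-4)
  expect_equal(g$value, mlp_forward(net, x), tolerance = 1e-12)
})

test_that("parameter flattening round-trips and indexes diffusion layers", {
  net <- mlp_init(6, 1, seed = 5)
  par <- mlp_flatten(net)
  expect_identical(length(par), as.integer(mlp_nparams(net)))
  net2 <- mlp_unflatten(net, par)
  x <- matrix(rnorm(12), 2)
  expect_equal(mlp_forward(net2, x), mlp_forward(net, x), tolerance = 1e-15)
  expect_error(mlp_unflatten(net, par[-1]), "length")
  idx <- mlp_diffusion_idx(net)
  n_input_layer <- length(net$W[[1]]) + length(net$b[[1]])
  expect_true(all(idx > n_input_layer))  # input layer never perturbed
  expect_identical(length(idx), as.integer(mlp_nparams(net) - n_input_layer))
})

test_that("manufactured solutions drive the water-balance residual to zero", {
  pts <- collocation_lhs(500, c(0, 1), c(0, 100), seed = 1)
  # constant field, no flux, no source
  f1 <- manufactured_field(function(z, t) rep(0.3, length(z)),
                           function(z, t) rep(0, length(z)),
                           function(z, t) rep(0, length(z)))
  expect_equal(water_balance_residual(f1, function(z, t) 0 * z, pts), 0)

  # theta = a t with source a
  a <- 0.002
  f2 <- manufactured_field(function(z, t) a * t,
                           function(z, t) rep(a, length(z)),
                           function(z, t) rep(0, length(z)))
  expect_equal(water_balance_residual(f2, function(z, t) rep(a, length(z)), pts),
               0, tolerance = 1e-30)

  # theta = sin(z) t with q = -dtheta/dz: S = theta_t + dq/dz
  f3 <- manufactured_field(function(z, t) sin(z) * t,
                           function(z, t) sin(z),
                           function(z, t) cos(z) * t,
                           function(z, t) -sin(z) * t)
  flux <- list(dq_dz = function(field, z, t) -field$dzz(z, t))
  s3 <- function(z, t) sin(z) + sin(z) * t
  expect_lt(water_balance_residual(f3, s3, pts, flux = flux), 1e-12)
  expect_error(water_balance_residual(f3, s3, pts[0, ], flux = flux), "empty")
})

test_that("the network-backed field satisfies its own linear manufactured PDE", {
  # train nothing: just check that residuals computed through the network are
  # consistent with its analytic derivatives on the drainage-free flux law
  sur <- surrogate_init(seed = 7)
  sc <- list(center = rep(0, 6), scale = rep(1, 6))
  field <- aquadeficit:::network_theta_field(sur$theta_net, rep(0.5, 4), sc)
  pts <- collocation_lhs(100, c(0, 1), c(0, 1), seed = 2)
  # with S chosen as the network's own dt + dq/dz, the residual must vanish
  s_self <- function(z, t) {
    th <- field$value(z, t)
    field$dt(z, t) + (-1e-4 * field$dzz(z, t) +
                        0.5 * (th > 0.3607) * field$dz(z, t))
  }
  expect_lt(water_balance_residual(field, s_self, pts), 1e-28)
})

test_that("the production function multiplies stage stress responses", {
  expect_equal(production_function(rep(1, 4)), 1)
  lam <- c(initial = 0, rapid = 1, mid = 1, late = 0.3)
  expect_equal(production_function(c(0.5, 1, 1, 1), lam), 1)  # lambda 0
  expect_equal(production_function(c(0.8, 0.9), c(0.5, 1)),
               0.8^0.5 * 0.9, tolerance = 1e-12)
  expect_equal(production_function(c(0.8, 0.9), c(0.5, 1)), 0.805,
               tolerance = 1e-3)
  expect_error(production_function(c(0, 1, 1, 1)), "positive")
})

test_that("lambda recovered by least squares reproduces simulator stress", {
  # self-consistency: generate schedules, fit lambda on the simulator's own
  # stage ET ratios and relative yields, then check the production residual
  set.seed(31)
  fracs <- matrix(runif(4 * 30, 0.45, 1), ncol = 4)
  ratios <- matrix(NA_real_, 30, 4); rel <- numeric(30)
  ref <- run_season(fx_crop, fx_soil, fx_weather, unstressed = TRUE)
  for (i in 1:30) {
    sch <- fx_schedule(etc = fracs[i, ] * fx_etc)
    sim <- run_season(fx_crop, fx_soil, fx_weather, sch, .with_reference = FALSE)
    ratios[i, ] <- pmin(1, pmax(1e-6, sim$stage_eta / ref$stage_eta))
    rel[i] <- min(1, sim$yield / ref$yield)
  }
  colnames(ratios) <- c("initial", "rapid", "mid", "late")
  lam <- fit_lambda(ratios, rel)
  expect_true(all(lam >= 0))
  pred <- apply(ratios, 1, production_function, lambda = lam)
  expect_lt(mean((pred - rel)^2), 1e-3)
})

test_that("the loss decomposition is exact with the default weights", {
  bd <- loss_breakdown(500, 0, 0)
  expect_equal(bd$total, 1)  # data weight 1/500
  bd2 <- loss_breakdown(0, 0.3, 0.2)
  expect_equal(bd2$total, 0.5)  # physics weight 1
  bd3 <- loss_breakdown(2, 0.3, 0.2, w_d = 0.1, w_f = 3)
  expect_equal(bd3$total, 0.1 * 2 + 3 * 0.5, tolerance = 1e-15)
  expect_equal(loss_breakdown(0, 0, 0)$total, 0)
  expect_error(loss_breakdown(NaN, 0, 0), "finite")
  expect_error(loss_breakdown(-1, 0, 0), "non-negative")
})
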