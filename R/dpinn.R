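# Dual physics-informed surrogate: a soil-water network theta(z, t, schedule)
# and a crop network (CC(t), B(t) -> yield), trained on simulator data with a
# soil-water-balance PDE residual and a multiplicative crop water production
# function residual added to the data loss.

#' Latin-hypercube collocation set
#'
#' Space-time points where the water-balance residual is evaluated.
#'
#' @param nf Number of collocation points (default 8000).
#' @param z_range Depth range (m), default the 0-1 m measurement profile.
#' @param t_range Time range (d).
#' @param seed Integer seed.
#' @return Data.frame of class \code{collocation_set} with columns \code{z},
#'   \code{t}.
#' @export
collocation_lhs <- function(nf = 8000L, z_range = c(0, 1), t_range = c(0, 130),
                            seed = 1L) {
  stop_if(nf < 1, "at least one collocation point is required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- lhs::randomLHS(nf, 2)
  structure(data.frame(z = z_range[1] + u[, 1] * diff(z_range),
                       t = t_range[1] + u[, 2] * diff(t_range)),
            class = c("collocation_set", "data.frame"))
}

#' Manufactured soil-moisture field
#'
#' Wraps analytic value/derivative functions of (z, t) in the interface the
#' residual evaluator expects, for method-of-manufactured-solutions checks.
#'
#' @param value,dt,dz,dzz Functions of \code{(z, t)} returning the field and
#'   its partial derivatives.
#' @return An object of class \code{theta_field}.
#' @export
manufactured_field <- function(value, dt, dz, dzz = function(z, t) 0 * z) {
  structure(list(value = value, dt = dt, dz = dz, dzz = dzz,
                 kind = "manufactured"), class = "theta_field")
}

network_theta_field <- function(net, features, scaling) {
  # inputs: (z, t, features...), standardized by `scaling` (list of center,
  # scale vectors over the full input row)
  force(net); force(features); force(scaling)
  eval_at <- function(z, t, wrt = NULL) {
    x <- cbind(z, t, matrix(features, length(z), length(features), byrow = TRUE))
    xs <- sweep(sweep(x, 2, scaling$center, "-"), 2, scaling$scale, "/")
    if (is.null(wrt)) return(list(value = mlp_forward(net, xs)))
    g <- mlp_forward_grad(net, xs, wrt)
    s <- scaling$scale[wrt]
    list(value = g$value, d1 = g$d1 / s, d2 = g$d2 / s^2)
  }
  structure(list(
    value = function(z, t) drop(eval_at(z, t)$value),
    dt = function(z, t) drop(eval_at(z, t, wrt = 2)$d1),
    dz = function(z, t) drop(eval_at(z, t, wrt = 1)$d1),
    dzz = function(z, t) drop(eval_at(z, t, wrt = 1)$d2),
    kind = "network"), class = "theta_field")
}

#' Soil-water-balance residual over a collocation set
#'
#' Mean squared residual of the conservation form
#' \code{r = dtheta/dt + dq/dz - S} with the diffusive-drainage flux law
#' \code{q = -D_w dtheta/dz + K_drain max(0, theta - theta_fc)}, so
#' \code{dq/dz = -D_w d2theta/dz2 + K_drain 1(theta > theta_fc) dtheta/dz}.
#' Derivatives come analytically from the field object.
#'
#' @param field A \code{theta_field} (manufactured or network-backed).
#' @param source Function \code{(z, t)} giving the source/sink term S
#'   (d^-1 volumetric).
#' @param points A \code{\link{collocation_lhs}} set (non-empty).
#' @param d_w Diffusivity constant (m2 d-1).
#' @param k_drain Drainage rate constant (d-1).
#' @param theta_fc Field capacity for the drainage switch.
#' @param flux Optional override: list(\code{dq_dz = function(field, z, t)})
#'   replacing the built-in flux law (used in manufactured tests).
#' @return Mean squared residual (scalar >= 0).
#' @export
water_balance_residual <- function(field, source, points, d_w = 1e-4,
                                   k_drain = 0.5, theta_fc = 0.3607,
                                   flux = NULL) {
  stopifnot(inherits(field, "theta_field"))
  stop_if(nrow(points) == 0, "empty collocation set")
  z <- points$z; t <- points$t
  dqdz <- if (!is.null(flux)) flux$dq_dz(field, z, t) else {
    th <- field$value(z, t)
    -d_w * field$dzz(z, t) + k_drain * (th > theta_fc) * field$dz(z, t)
  }
  r <- field$dt(z, t) + dqdz - source(z, t)
  mean(r^2)
}

#' Multiplicative crop water production function
#'
#' \code{Ya/Ym = prod_i (ETa_i / ETm_i)^(lambda_i)}: the relative yield is the
#' product over growth stages of the relative evapotranspiration raised to
#' the stage's water-stress sensitivity exponent.
#'
#' @param et_ratio Per-stage ETa/ETm ratios in (0, 1\].
#' @param lambda Per-stage sensitivity exponents (>= 0).
#' @return Relative yield Ya/Ym in (0, 1\].
#' @export
production_function <- function(et_ratio, lambda = default_lambda()) {
  stop_if(any(et_ratio <= 0), "ET ratios must be positive")
  stop_if(any(et_ratio > 1 + 1e-9), "ET ratios cannot exceed 1")
  stop_if(any(lambda < 0), "sensitivity exponents must be non-negative")
  stop_if(length(et_ratio) != length(lambda), "stage count mismatch")
  prod(pmin(1, et_ratio)^lambda)
}

#' Default stage water-stress sensitivity exponents
#'
#' (initial, rapid, mid, late) = (0.25, 1.0, 0.8, 0.3): the rapid and mid
#' stages are the most yield-sensitive to deficit. Overridable everywhere;
#' \code{\link{fit_lambda}} estimates them from simulator runs instead.
#'
#' @return Named numeric vector of four exponents.
#' @export
default_lambda <- function() c(initial = 0.25, rapid = 1.0, mid = 0.8, late = 0.3)

#' Least-squares estimate of the stage sensitivity exponents
#'
#' Fits \code{log(Ya/Ym) = sum_i lambda_i log(ETa_i/ETm_i)} by linear least
#' squares without intercept over a set of simulator runs, then polishes the
#' non-negative exponents by bounded minimization of the linear-scale
#' residual (the quantity the physics loss actually penalizes).
#'
#' @param et_ratios Matrix (runs x 4 stages) of ETa/ETm ratios in (0, 1\].
#' @param rel_yield Vector of Ya/Ym in (0, 1\].
#' @return Named numeric vector of non-negative exponents.
#' @export
fit_lambda <- function(et_ratios, rel_yield) {
  stop_if(any(et_ratios <= 0) || any(rel_yield <= 0),
          "ratios and relative yields must be positive")
  X <- log(as.matrix(et_ratios))
  X[X > 0] <- 0  # ratios are capped at 1
  y <- pmin(0, log(rel_yield))
  keep <- apply(X, 2, function(c) any(abs(c) > 1e-12))
  lam <- rep(0, ncol(X))
  if (any(keep)) {
    fit <- lm(y ~ 0 + X[, keep, drop = FALSE])
    lam[keep] <- pmax(0, coef(fit))
    if (length(rel_yield) > 1) {
      obj <- function(l) mean((exp(drop(X %*% l)) - exp(y))^2)
      pol <- stats::optim(lam, obj, method = "L-BFGS-B",
                          lower = rep(0, length(lam)),
                          upper = rep(10, length(lam)))
      if (pol$value < obj(lam)) lam <- pol$par
    }
  }
  setNames(lam, colnames(et_ratios) %||% STAGE_NAMES)
}

#' Physics-informed loss decomposition
#'
#' \code{L = w_d L_d + w_f l_h} with the data term \code{L_d} (mean squared
#' mismatch to the simulator trajectories) and the physics term \code{l_h}
#' (water-balance PDE residual plus production-function residual). Default
#' weights: physics 1, data 1/500.
#'
#' @param data_mse Data mean squared error (>= 0).
#' @param pde_mse Water-balance residual mean square (>= 0).
#' @param production_mse Production-function residual mean square (>= 0).
#' @param w_d,w_f Data and physics weights.
#' @return An object of class \code{loss_breakdown}: list with \code{total},
#'   \code{data}, \code{physics}, \code{pde}, \code{production},
#'   \code{w_d}, \code{w_f}. The total is exactly the weighted sum.
#' @export
loss_breakdown <- function(data_mse, pde_mse, production_mse,
                           w_d = 1 / 500, w_f = 1) {
  stop_if(any(!is.finite(c(data_mse, pde_mse, production_mse))),
          "loss terms must be finite (NaN encountered)")
  stop_if(any(c(data_mse, pde_mse, production_mse) < 0),
          "loss terms must be non-negative")
  physics <- pde_mse + production_mse
  structure(list(total = w_d * data_mse + w_f * physics, data = data_mse,
                 physics = physics, pde = pde_mse,
                 production = production_mse, w_d = w_d, w_f = w_f),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("Loss %.6g = %.4g x data %.6g + %.4g x physics %.6g (pde %.3g, production %.3g)\n",
              x$total, x$w_d, x$data, x$w_f, x$physics, x$pde, x$production))
  invisible(x)
}

# --- Surrogate construction and training ------------------------------------

#' Initialize the dual surrogate
#'
#' Two 2 x 17 tanh networks sharing one architecture: the soil-water net maps
#' (z, t, stage-depth features) to volumetric water content; the crop net
#' maps (t, stage-depth features) to canopy cover and cumulative biomass, and
#' the yield prediction is read at season end through the harvest index.
#'
#' @param n_features Number of schedule features (default 4 stage depths).
#' @param hidden,layers Architecture (defaults 17 neurons, 2 layers).
#' @param seed Integer seed.
#' @return An object of class \code{surrogate}.
#' @export
surrogate_init <- function(n_features = 4L, hidden = 17L, layers = 2L,
                           seed = 1L) {
  theta_net <- mlp_init(2L + n_features, 1L, hidden, layers,
                        seed = module_seed(seed, "dpinn"))
  crop_net <- mlp_init(1L + n_features, 2L, hidden, layers,
                       seed = module_seed(seed, "dpinn") + 1L)
  structure(list(theta_net = theta_net, crop_net = crop_net,
                 n_features = n_features, scaling = NULL, basis = NULL,
                 lambda = default_lambda(), trained = FALSE, seed = seed),
            class = "surrogate")
}

surrogate_flatten <- function(sur)
  c(mlp_flatten(sur$theta_net), mlp_flatten(sur$crop_net))

surrogate_unflatten <- function(sur, par) {
  n1 <- mlp_nparams(sur$theta_net)
  sur$theta_net <- mlp_unflatten(sur$theta_net, par[seq_len(n1)])
  sur$crop_net <- mlp_unflatten(sur$crop_net, par[-seq_len(n1)])
  sur
}

#' Build a surrogate training set from designed simulator runs
#'
#' Latin-hypercube design over per-stage ETc fractions in \[0.4, 1.1\];
#' each design point becomes a 12-event schedule (built from the unstressed
#' stage ETc of the given weather) and a full simulator season. Trajectories
#' are subsampled every \code{stride} days.
#'
#' @param params,soil,weather As in \code{\link{run_season}}.
#' @param n_runs Number of designed runs (default 200; scale down for smoke
#'   tests).
#' @param stride Day subsampling stride for the data loss (default 10).
#' @param seed Integer seed.
#' @return An object of class \code{surrogate_train_set}.
#' @export
build_training_set <- function(params, soil, weather, n_runs = 200L,
                               stride = 10L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(module_seed(seed, "dpinn"))
  ref <- run_season(params, soil, weather, unstressed = TRUE)
  etc <- ref$stage_eta
  windows <- stage_windows(params, weather)
  U <- lhs::randomLHS(n_runs, 4)
  frac <- 0.4 + U * 0.7

  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    depths <- frac[i, ] * etc
    sched <- build_schedule_from_stage_depths(depths, windows)
    sim <- run_season(params, soil, weather, sched, .with_reference = FALSE)
    days <- seq(1, sim$season_days, by = stride)
    runs[[i]] <- list(
      features = depths / 100,          # mm -> O(1) features
      t = sim$daily$day[days],
      theta = sim$daily$theta[days],
      cc = sim$daily$cc[days],
      biomass = sim$daily$biomass[days],
      yield = sim$yield,
      et_ratio = pmin(1, pmax(1e-6, sim$stage_eta / pmax(1e-9, ref$stage_eta))),
      # bucket forcing per day: the PDE source term for this run
      source_t = sim$daily$day,
      source = (sim$daily$irrigation + sim$daily$precip - sim$daily$eta -
                  sim$daily$drainage - sim$daily$runoff) / (soil$depth * 1000))
  }
  structure(list(runs = runs, ym = ref$yield, etm = ref$stage_eta,
                 season_days = ref$season_days, soil = soil,
                 theta_fc = soil$theta_fc, hi = params$hi, seed = seed),
            class = "surrogate_train_set")
}

build_schedule_from_stage_depths <- function(stage_depths, windows) {
  plan <- stage_plan()  # all 1.0; depths carried through stage_etc
  build_treatment_schedule(plan, setNames(stage_depths, STAGE_NAMES), windows)
}

surrogate_scaling <- function(train) {
  feats <- do.call(rbind, lapply(train$runs, function(r) r$features))
  tmax <- max(vapply(train$runs, function(r) max(r$t), numeric(1)))
  center <- c(z = 0.5, t = tmax / 2, colMeans(feats))
  scale <- c(z = 0.5, t = tmax / 2,
             pmax(apply(feats, 2, sd), 0.05))
  list(center = as.numeric(center), scale = as.numeric(scale))
}

#' Total physics-informed loss of a surrogate on a training set
#'
#' Data term: mean squared standardized mismatch of predicted soil moisture,
#' canopy cover, biomass and final yield against the simulator trajectories.
#' Physics term: water-balance residual at the collocation points (source
#' interpolated from each run's bucket forcing) plus the production-function
#' residual of the predicted relative yield against the multiplicative stress
#' form at the run's stage-ET ratios.
#'
#' @param sur A \code{surrogate} with scaling attached.
#' @param train A \code{surrogate_train_set}.
#' @param colloc A \code{\link{collocation_lhs}} set.
#' @param lambda Stage sensitivity exponents.
#' @param w_d,w_f Loss weights (defaults 1/500 and 1).
#' @param term_weights Optional multipliers for the two physics terms,
#'   c(water, production) — raised by the adaptive mechanism.
#' @param n_colloc_runs Residuals are averaged over this many training runs.
#' @return A \code{\link{loss_breakdown}}.
#' @export
total_loss <- function(sur, train, colloc, lambda = sur$lambda,
                       w_d = 1 / 500, w_f = 1, term_weights = c(1, 1),
                       n_colloc_runs = 3L) {
  stopifnot(inherits(sur, "surrogate"), inherits(train, "surrogate_train_set"))
  sc <- sur$scaling %||% surrogate_scaling(train)
  ctx <- loss_context(train, colloc, sc, lambda, n_colloc_runs)
  loss_eval(sur, ctx, w_d = w_d, w_f = w_f, term_weights = term_weights)
}

# Precompute everything in the loss that does not depend on the network
# parameters: standardized input matrices, stacked targets, interpolated PDE
# sources and production-function targets. Built once per training run.
loss_context <- function(train, colloc, sc, lambda = default_lambda(),
                         n_colloc_runs = 3L) {
  nf <- length(train$runs[[1]]$features)
  std <- function(x, center, scale)
    sweep(sweep(x, 2, center, "-"), 2, scale, "/")

  rows <- lapply(train$runs, function(r) {
    n <- length(r$t)
    cbind(r$t, matrix(r$features, n, nf, byrow = TRUE))
  })
  Xc <- std(do.call(rbind, rows), sc$center[-1], sc$scale[-1])
  Xt <- std(cbind(0.5, do.call(rbind, rows)), sc$center, sc$scale)
  nper <- vapply(train$runs, function(r) length(r$t), numeric(1))
  ends <- cumsum(nper)
  hi <- train$hi %||% 0.49

  idx <- seq_len(min(n_colloc_runs, length(train$runs)))
  ZC <- vector("list", length(idx)); SS <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    r <- train$runs[[idx[j]]]
    ZC[[j]] <- std(cbind(colloc$z, colloc$t,
                         matrix(r$features, nrow(colloc), nf, byrow = TRUE)),
                   sc$center, sc$scale)
    SS[[j]] <- approx(r$source_t, r$source,
                      xout = pmin(colloc$t, max(r$source_t)), rule = 2)$y
  }
  g <- vapply(idx, function(i)
    production_function(train$runs[[i]]$et_ratio, lambda), numeric(1))

  list(Xc = Xc, Xt = Xt,
       cc = unlist(lapply(train$runs, `[[`, "cc")),
       biomass = unlist(lapply(train$runs, `[[`, "biomass")),
       theta = unlist(lapply(train$runs, `[[`, "theta")),
       yield = vapply(train$runs, `[[`, numeric(1), "yield"),
       nper = nper, ends = ends, nobs = 4 * sum(nper),
       Zc = do.call(rbind, ZC), S = unlist(SS), n_phys = length(idx),
       nf_pts = nrow(colloc), g = g, phys_idx = idx,
       z_scale = sc$scale[1], t_scale = sc$scale[2],
       theta_fc = train$theta_fc, hi = hi, ym = train$ym)
}

# Fast loss evaluation against a precomputed context.
loss_eval <- function(sur, ctx, w_d = 1 / 500, w_f = 1,
                      term_weights = c(1, 1), d_w = 1e-4, k_drain = 0.5) {
  pred_c <- mlp_forward(sur$crop_net, ctx$Xc)
  pred_th <- drop(mlp_forward(sur$theta_net, ctx$Xt))
  yhat <- pred_c[ctx$ends, 2] * 1000 * ctx$hi
  se <- sum(((pred_th - ctx$theta) / 0.1)^2) +
    sum((pred_c[, 1] - ctx$cc)^2) +
    sum(((pred_c[, 2] - ctx$biomass) / 10)^2) +
    sum(ctx$nper * ((yhat - ctx$yield) / max(1, ctx$ym))^2)
  data_mse <- se / ctx$nobs

  g2 <- mlp_forward_grad2(sur$theta_net, ctx$Zc, wrt1 = 1, wrt2 = 2)
  th <- drop(g2$value)
  dz <- drop(g2$d1a) / ctx$z_scale
  dt <- drop(g2$d1b) / ctx$t_scale
  dzz <- drop(g2$d2a) / ctx$z_scale^2
  r <- dt + (-d_w * dzz + k_drain * (th > ctx$theta_fc) * dz) - ctx$S
  pde <- mean(r^2)

  yhat_rel <- yhat[ctx$phys_idx] / ctx$ym
  prodr <- mean((yhat_rel - ctx$g)^2)
  loss_breakdown(data_mse, term_weights[1] * pde, term_weights[2] * prodr,
                 w_d = w_d, w_f = w_f)
}

#' Train the dual surrogate with (separable) CMA-ES and dynamic reconstruction
#'
#' Evolves the flattened parameters of both networks under the
#' physics-informed loss using the diagonal-covariance CMA-ES variant (the
#' loss is not differentiable end to end). The adaptive mechanism monitors
#' the loss history each generation: on a stall with a dominant physics
#' residual it raises that residual's weight and diffuses the output- and
#' second-hidden-layer parameters (see \code{\link{adapt_step}}).
#'
#' @param sur A \code{surrogate}.
#' @param train A \code{surrogate_train_set}.
#' @param epochs CMA-ES generations (paper-scale default 17600; use a few
#'   thousand for smoke runs).
#' @param nf Collocation points (default 8000; scale down with epochs).
#' @param sigma0 Initial CMA-ES step size (default the 0.00208 learning-rate
#'   scale times 100, i.e. 0.208).
#' @param adapt An \code{\link{adapt_state}} or NULL to disable dynamic
#'   reconstruction.
#' @param dynamic_reconstruction If TRUE, attach a trajectory feature basis
#'   (\code{\link{extract_modes}}) used for low-rank output correction.
#' @param seed Integer seed.
#' @return The trained \code{surrogate} with fields \code{loss},
#'   \code{initial_loss}, \code{history}, \code{adapt_log}.
#' @export
train_surrogate <- function(sur, train, epochs = 17600L, nf = 8000L,
                            sigma0 = 0.208, adapt = adapt_state(),
                            dynamic_reconstruction = TRUE, seed = 1L) {
  stopifnot(inherits(sur, "surrogate"))
  sur$scaling <- surrogate_scaling(train)
  tmax <- max(vapply(train$runs, function(r) max(r$t), numeric(1)))
  colloc <- collocation_lhs(nf, c(0, 1), c(0, tmax),
                            seed = module_seed(seed, "dpinn"))
  if (dynamic_reconstruction) {
    traj <- do.call(rbind, lapply(train$runs, function(r)
      cbind(r$theta, r$cc, r$biomass / 10)))
    sur$basis <- extract_modes(traj)
  }

  term_w <- c(water = 1, production = 1)
  ctx <- loss_context(train, colloc, sur$scaling, sur$lambda)
  x0 <- surrogate_flatten(sur)
  obj <- function(par)
    loss_eval(surrogate_unflatten(sur, par), ctx, term_weights = term_w)$total
  init_bd <- loss_eval(sur, ctx, term_weights = c(1, 1))

  astate <- adapt
  alog <- list()
  cb <- if (is.null(adapt)) NULL else {
    idx1 <- mlp_diffusion_idx(sur$theta_net)
    n1 <- mlp_nparams(sur$theta_net)
    idx2 <- n1 + mlp_diffusion_idx(sur$crop_net)
    diff_idx <- c(idx1, idx2)
    function(state) {
      bd <- loss_eval(surrogate_unflatten(sur, state$mean), ctx,
                      term_weights = c(1, 1))
      stp <- adapt_step(astate, state$history, state$mean,
                        residuals = c(water = bd$pde, production = bd$production),
                        diffusion_idx = diff_idx,
                        rng_seed = module_seed(seed, "dynrec") + state$iter)
      astate <<- stp$state
      if (stp$triggered) {
        term_w <<- stp$state$weights
        alog[[length(alog) + 1]] <<- list(
          epoch = state$iter, term = stp$term,
          new_weight = unname(stp$state$weights[stp$term]),
          sigma_d = stp$sigma_used)
        return(list(mean = stp$par))
      }
      NULL
    }
  }

  res <- cmaes_minimize(obj, x0,
                        cmaes_config(sigma0 = sigma0, max_iter = epochs,
                                     diagonal = TRUE,
                                     seed = module_seed(seed, "dpinn")),
                        callback = cb)
  sur <- surrogate_unflatten(sur, res$par)
  sur$trained <- TRUE
  sur$hi <- train$hi %||% 0.49
  sur$initial_loss <- init_bd
  sur$loss <- loss_eval(sur, ctx, term_weights = c(1, 1))
  sur$history <- res$trace
  sur$adapt_log <- alog
  sur$term_weights <- term_w
  sur
}

#' Predict yield for a stage-depth allocation with the crop net
#'
#' @param sur A trained \code{surrogate}.
#' @param stage_depths Per-stage irrigation depths (mm, length 4).
#' @param t_end Season end day used for the yield readout.
#' @return Predicted yield (kg hm-2).
#' @export
surrogate_predict_yield <- function(sur, stage_depths, t_end) {
  stop_if(is.null(sur$scaling), "surrogate has no scaling; train it first")
  x <- c(t_end, stage_depths / 100)
  xs <- (x - sur$scaling$center[-1]) / sur$scaling$scale[-1]
  out <- mlp_forward(sur$crop_net, matrix(xs, nrow = 1))
  max(0, out[1, 2] * 1000 * (sur$hi %||% 0.49))
}

#' @export
print.surrogate <- function(x, ...) {
  cat(sprintf("Dual physics-informed surrogate (2 x %d tanh, %s)\n",
              x$theta_net$hidden, if (x$trained) "trained" else "untrained"))
  if (x$trained) {
    cat(sprintf("  loss %.5g (from %.5g); %d adapt trigger(s)\n",
                x$loss$total, x$initial_loss$total, length(x$adapt_log)))
  }
  invisible(x)
}
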