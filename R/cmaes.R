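# Covariance Matrix Adaptation Evolution Strategy (mu/mu_w, lambda) with
# cumulative step-size adaptation and rank-one/rank-mu covariance updates;
# a separable (diagonal-covariance) variant is provided for high-dimensional
# searches such as surrogate network training.

#' CMA-ES configuration
#'
#' @param lambda Population size (>= 4); default \code{4 + floor(3 log n)}.
#' @param sigma0 Initial step size (> 0).
#' @param max_iter Maximum generations.
#' @param max_evals Maximum objective evaluations (overrides max_iter when
#'   smaller).
#' @param tol Stop when the best objective falls below this value (for
#'   minimization to a known target; default -Inf disables).
#' @param ftol_rel Stop when the within-population objective spread falls
#'   below this relative tolerance.
#' @param diagonal If TRUE, use the separable variant (diagonal covariance).
#' @param seed Integer seed.
#' @return An object of class \code{cmaes_config}.
#' @export
cmaes_config <- function(lambda = NULL, sigma0 = 0.5, max_iter = 1000L,
                         max_evals = Inf, tol = -Inf, ftol_rel = 1e-12,
                         diagonal = FALSE, seed = 1L) {
  stop_if(!is.null(lambda) && lambda < 4, "lambda must be at least 4")
  stop_if(sigma0 <= 0, "sigma0 must be positive")
  structure(list(lambda = lambda, sigma0 = sigma0,
                 max_iter = as.integer(max_iter), max_evals = max_evals,
                 tol = tol, ftol_rel = ftol_rel, diagonal = diagonal,
                 seed = as.integer(seed)),
            class = "cmaes_config")
}

#' Minimize a black-box objective with CMA-ES
#'
#' Standard CMA-ES: rank-based recombination weights, cumulative step-size
#' adaptation, and rank-one plus rank-mu covariance adaptation. The best-so-far
#' trace is non-increasing by construction and the run is deterministic for a
#' fixed seed. A per-generation callback supports interleaved adaptation (used
#' by the surrogate trainer).
#'
#' @param objective Function of a numeric vector returning a finite scalar
#'   (NaN aborts with a diagnostic).
#' @param x0 Numeric start vector (objective must be finite there).
#' @param config A \code{\link{cmaes_config}}.
#' @param callback Optional \code{function(state)} called after each
#'   generation with the internal state (fields \code{mean, sigma, iter,
#'   best_value, history}); it may return a modified \code{mean} and/or
#'   multiplicative \code{sigma_scale} in a list to steer the search.
#' @return List with \code{par}, \code{value}, \code{trace} (best-so-far per
#'   generation), \code{evals}, \code{iters}.
#' @export
cmaes_minimize <- function(objective, x0, config = cmaes_config(),
                           callback = NULL) {
  n <- length(x0)
  f0 <- objective(x0)
  stop_if(!is.finite(f0), "objective is not finite at x0")
  lambda <- config$lambda %||% (4L + floor(3 * log(n)))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cs <- (mueff + 2) / (n + mueff + 5)
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  if (config$diagonal) {  # separable variant: larger learning rates
    c1 <- min(1, c1 * (n + 1.5) / 3)
    cmu <- min(1 - c1, cmu * (n + 1.5) / 3)
  }
  chin <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  xmean <- as.numeric(x0)
  sigma <- config$sigma0
  pc <- ps <- numeric(n)
  if (config$diagonal) {
    dC <- rep(1, n)
  } else {
    C <- diag(n); B <- diag(n); D <- rep(1, n); eigen_age <- 0
  }
  best_par <- x0; best_val <- f0
  evals <- 1; trace <- numeric(0); hist <- numeric(0)

  for (iter in seq_len(config$max_iter)) {
    if (evals + lambda > config$max_evals) break
    Z <- matrix(rnorm(n * lambda), nrow = n)
    if (config$diagonal) {
      Y <- Z * sqrt(dC)
    } else {
      Y <- B %*% (D * Z)
    }
    X <- xmean + sigma * Y
    fv <- apply(X, 2, objective)
    evals <- evals + lambda
    stop_if(any(is.nan(fv)), "objective returned NaN during CMA-ES search")
    ord <- order(fv)
    if (fv[ord[1]] < best_val) {
      best_val <- fv[ord[1]]; best_par <- X[, ord[1]]
    }
    trace <- c(trace, best_val)

    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ydelta <- drop(ysel %*% w)
    xmean <- xmean + sigma * ydelta

    if (config$diagonal) {
      zdelta <- drop((Z * 1)[, ord[seq_len(mu)], drop = FALSE] %*% w)
      ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * zdelta
    } else {
      cinv_y <- drop(B %*% ((1 / D) * crossprod(B, ydelta)))
      ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * cinv_y
    }
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * iter)) / chin <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ydelta

    if (config$diagonal) {
      dC <- (1 - c1 - cmu) * dC + c1 * (pc^2 + (1 - hsig) * cc * (2 - cc) * dC) +
        cmu * drop((ysel^2) %*% w)
      dC <- pmax(dC, 1e-30)
    } else {
      artmp <- ysel
      C <- (1 - c1 - cmu) * C +
        c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * artmp %*% (w * t(artmp))
      eigen_age <- eigen_age + 1
      if (eigen_age >= max(1, floor(1 / ((c1 + cmu) * n * 10)))) {
        eigen_age <- 0
        C <- (C + t(C)) / 2
        eg <- eigen(C, symmetric = TRUE)
        D <- sqrt(pmax(eg$values, 1e-30))
        B <- eg$vectors
      }
    }
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chin - 1))

    if (!is.null(callback)) {
      st <- callback(list(mean = xmean, sigma = sigma, iter = iter,
                          best_value = best_val, history = trace))
      if (is.list(st)) {
        if (!is.null(st$mean)) xmean <- st$mean
        if (!is.null(st$sigma_scale)) sigma <- sigma * st$sigma_scale
      }
    }

    if (best_val <= config$tol) break
    spread <- max(fv) - min(fv)
    if (spread <= config$ftol_rel * max(1e-300, abs(mean(fv)))) break
  }
  list(par = best_par, value = best_val, trace = trace,
       evals = evals, iters = length(trace))
}
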