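# Dynamic reconstruction: low-rank (POD/SVD) feature extraction of simulator
# trajectories, additive reconstruction through the retained modes, and the
# adaptive residual-weight / parameter-diffusion mechanism used when surrogate
# training stalls.

#' Extract orthonormal trajectory modes
#'
#' Column-centers the trajectory matrix and takes its singular value
#' decomposition; the retained rank is the smallest one whose cumulative
#' energy (squared singular values) reaches the threshold.
#'
#' @param trajectories Numeric matrix, rows = observations (run-days),
#'   columns = variables; at least 2 rows, finite, not all zero.
#' @param energy_threshold Cumulative energy fraction to retain (default
#'   0.99).
#' @param center Center columns before decomposition (default TRUE).
#' @return An object of class \code{feature_basis}: list with orthonormal
#'   \code{modes} (columns), \code{singular_values}, retained rank \code{r},
#'   \code{energy} fractions and the column \code{center}.
#' @export
extract_modes <- function(trajectories, energy_threshold = 0.99,
                          center = TRUE) {
  X <- as.matrix(trajectories)
  stop_if(nrow(X) < 2, "at least two trajectory rows are required")
  stop_if(any(!is.finite(X)), "trajectory matrix must be finite")
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  stop_if(all(abs(Xc) < .Machine$double.eps), "degenerate (constant) trajectory matrix")
  sv <- svd(Xc)
  energy <- sv$d^2 / sum(sv$d^2)
  r <- which(cumsum(energy) >= energy_threshold - 1e-12)[1]
  structure(list(modes = sv$v, singular_values = sv$d, r = r,
                 energy = energy, center = mu,
                 energy_threshold = energy_threshold),
            class = "feature_basis")
}

#' Project observations onto the retained modes
#'
#' @param basis A \code{feature_basis}.
#' @param x Matrix (rows = observations) or vector in the variable space.
#' @param rank Number of modes to use (default the retained rank).
#' @return Feature matrix z (rows x rank).
#' @export
project_features <- function(basis, x, rank = basis$r) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  sweep(x, 2, basis$center) %*% basis$modes[, seq_len(rank), drop = FALSE]
}

#' Additive dynamic reconstruction
#'
#' \code{u = f_NN + D(z)} with D the linear map through the retained
#' orthonormal modes: the base network output is corrected by the low-rank
#' feature contribution. The decomposition is exact and \code{u - f_NN}
#' always lies in the span of the retained modes.
#'
#' @param u_base Base network output (matrix rows x variables, or vector).
#' @param z Feature matrix/vector (columns = retained modes).
#' @param basis A \code{feature_basis}.
#' @return Reconstructed output u, same shape as \code{u_base}.
#' @export
reconstruct <- function(u_base, z, basis) {
  vec <- !is.matrix(u_base)
  if (vec) u_base <- matrix(u_base, nrow = 1)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  r <- ncol(z)
  stop_if(r > ncol(basis$modes), "more features than available modes")
  stop_if(nrow(z) != nrow(u_base), "feature/base row mismatch")
  u <- u_base + z %*% t(basis$modes[, seq_len(r), drop = FALSE])
  if (vec) drop(u) else u
}

#' Rank-r reconstruction error of a trajectory matrix
#'
#' Frobenius error of the best rank-r approximation; equals the square root
#' of the discarded squared singular values.
#'
#' @param basis A \code{feature_basis}.
#' @param trajectories The matrix the basis was extracted from.
#' @param rank Approximation rank.
#' @return Frobenius norm of the residual.
#' @export
reconstruction_error <- function(basis, trajectories, rank = basis$r) {
  Xc <- sweep(as.matrix(trajectories), 2, basis$center)
  V <- basis$modes[, seq_len(rank), drop = FALSE]
  sqrt(sum((Xc - Xc %*% V %*% t(V))^2))
}

#' Adaptive adjustment state
#'
#' Configuration and mutable state of the stall-triggered mechanism: when the
#' best loss has not improved relatively by more than \code{eps_rel} over
#' \code{patience} epochs and a physics residual exceeds its tolerance, the
#' corresponding residual weight is multiplied by \code{gamma} (capped) and
#' zero-mean Gaussian noise of scale \code{sigma_d} is added to the output-
#' and intermediate-layer parameters; \code{sigma_d} decays after each
#' trigger.
#'
#' @param patience Epochs without improvement before a trigger (default 200
#'   for scaled runs; 2000 at full budget).
#' @param eps_rel Relative improvement threshold (default 1e-3).
#' @param gamma Residual weight multiplier per trigger (default 2).
#' @param weight_cap Maximum residual weight (default 32).
#' @param sigma_d Initial diffusion scale, as a fraction of the parameter RMS
#'   (default 0.05).
#' @param decay Multiplicative sigma decay per trigger (default 0.7).
#' @param residual_tol Physics residual magnitude that counts as "high".
#' @return An object of class \code{adapt_state}.
#' @export
adapt_state <- function(patience = 200L, eps_rel = 1e-3, gamma = 2,
                        weight_cap = 32, sigma_d = 0.05, decay = 0.7,
                        residual_tol = 1e-4) {
  structure(list(patience = as.integer(patience), eps_rel = eps_rel,
                 gamma = gamma, weight_cap = weight_cap, sigma_d = sigma_d,
                 decay = decay, residual_tol = residual_tol,
                 weights = c(water = 1, production = 1),
                 trigger_count = 0L, last_trigger = 0L),
            class = "adapt_state")
}

#' One adaptive adjustment step
#'
#' No-op while the loss history improves; on a stall with a high physics
#' residual, raises that residual's weight (never lowering any weight) and
#' perturbs only the supplied parameter positions (the output and
#' intermediate layers). Deterministic for a fixed \code{rng_seed}.
#'
#' @param state An \code{\link{adapt_state}}.
#' @param history Numeric vector of best-so-far losses per epoch.
#' @param par Flat network parameter vector.
#' @param residuals Named numeric: current magnitudes of the physics
#'   residual terms (e.g. \code{c(water = ..., production = ...)}).
#' @param diffusion_idx Integer positions in \code{par} eligible for noise
#'   (output + intermediate layers only).
#' @param rng_seed Integer seed for the diffusion draw.
#' @return List with updated \code{state}, \code{par}, logical
#'   \code{triggered}, the boosted \code{term} and \code{sigma_used}.
#' @export
adapt_step <- function(state, history, par, residuals, diffusion_idx,
                       rng_seed = 1L) {
  stopifnot(inherits(state, "adapt_state"))
  n <- length(history)
  out <- list(state = state, par = par, triggered = FALSE, term = NA_character_,
              sigma_used = NA_real_)
  if (n < state$patience) return(out)
  if (n - state$last_trigger < state$patience) return(out)
  window <- history[(n - state$patience + 1):n]
  improved <- (window[1] - window[length(window)]) >
    state$eps_rel * max(abs(window[1]), 1e-12)
  if (improved) return(out)
  high <- residuals > state$residual_tol
  if (!any(high)) return(out)
  term <- names(residuals)[high][which.max(residuals[high])]

  state$weights[term] <- min(state$weight_cap,
                             state$weights[term] * state$gamma)
  sigma <- state$sigma_d * state$decay^state$trigger_count
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  scale <- sigma * sqrt(mean(par[diffusion_idx]^2) + 1e-12)
  par[diffusion_idx] <- par[diffusion_idx] +
    rnorm(length(diffusion_idx), 0, scale)
  state$trigger_count <- state$trigger_count + 1L
  state$last_trigger <- n
  list(state = state, par = par, triggered = TRUE, term = term,
       sigma_used = sigma)
}
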