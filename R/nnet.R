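# Small fully connected tanh networks (2 hidden layers by default) with
# analytic first and second derivatives with respect to a chosen input
# coordinate, so governing-equation residuals are evaluated exactly through
# the network rather than by finite differences.

#' Initialize a fully connected tanh network
#'
#' @param n_in Input dimension.
#' @param n_out Output dimension.
#' @param hidden Neurons per hidden layer (default 17).
#' @param layers Number of hidden layers (default 2).
#' @param seed Integer seed for the Gaussian fan-in initialization.
#' @return An object of class \code{mlp}: list of weight matrices \code{W}
#'   and bias vectors \code{b} plus architecture metadata.
#' @export
mlp_init <- function(n_in, n_out, hidden = 17L, layers = 2L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dims <- c(n_in, rep(hidden, layers), n_out)
  W <- b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, 1 / sqrt(dims[l])),
                     nrow = dims[l])
    b[[l]] <- rep(0, dims[l + 1])
  }
  structure(list(W = W, b = b, dims = dims, n_in = n_in, n_out = n_out,
                 hidden = hidden, layers = layers), class = "mlp")
}

#' Number of free parameters of a network
#' @param net An \code{mlp}.
#' @return Integer parameter count.
#' @export
mlp_nparams <- function(net) {
  sum(vapply(seq_along(net$W),
             function(l) length(net$W[[l]]) + length(net$b[[l]]), numeric(1)))
}

#' Flatten network parameters to a vector / restore them
#'
#' @param net An \code{mlp}.
#' @param par Flat numeric vector of length \code{mlp_nparams(net)}.
#' @return \code{mlp_flatten}: numeric vector; \code{mlp_unflatten}: an
#'   \code{mlp} with the given parameters.
#' @export
mlp_flatten <- function(net) {
  unlist(lapply(seq_along(net$W), function(l) c(net$W[[l]], net$b[[l]])))
}

#' @rdname mlp_flatten
#' @export
mlp_unflatten <- function(net, par) {
  stop_if(length(par) != mlp_nparams(net), "parameter vector length mismatch")
  pos <- 0
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]]); nb <- length(net$b[[l]])
    net$W[[l]] <- matrix(par[pos + seq_len(nw)], nrow = nrow(net$W[[l]]))
    net$b[[l]] <- par[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  net
}

#' Indices of the output-layer and last-hidden-layer parameters
#'
#' Used by the adaptive diffusion step, which perturbs only the output and
#' intermediate (second hidden) layers, never the input layer.
#'
#' @param net An \code{mlp}.
#' @return Integer vector of positions in the flattened parameter vector.
#' @export
mlp_diffusion_idx <- function(net) {
  sizes <- vapply(seq_along(net$W),
                  function(l) length(net$W[[l]]) + length(net$b[[l]]),
                  numeric(1))
  starts <- cumsum(c(0, sizes))
  keep <- seq_along(net$W)[-1]  # all but the input layer
  unlist(lapply(keep, function(l) starts[l] + seq_len(sizes[l])))
}

#' Network forward pass
#'
#' \code{y = W_L ( tanh( ... tanh(W_1 x + b_1) ... ) ) + b_L}, vectorized
#' over rows of \code{x}; the output layer is linear.
#'
#' @param net An \code{mlp}.
#' @param x Input matrix (rows = points) or vector.
#' @return Output matrix (rows = points, cols = outputs).
#' @export
mlp_forward <- function(net, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stop_if(ncol(x) != net$n_in, "input dimension mismatch")
  a <- x
  L <- length(net$W)
  for (l in seq_len(L - 1))
    a <- tanh(sweep(a %*% net$W[[l]], 2, net$b[[l]], "+"))
  sweep(a %*% net$W[[L]], 2, net$b[[L]], "+")
}

#' Forward pass with exact derivatives along one input coordinate
#'
#' Propagates the value together with first and second derivatives with
#' respect to input column \code{wrt} through the tanh layers by the chain
#' rule; no finite differences are involved.
#'
#' @param net An \code{mlp}.
#' @param x Input matrix (rows = points).
#' @param wrt Index of the input coordinate to differentiate along.
#' @return List with matrices \code{value}, \code{d1}, \code{d2}.
#' @export
mlp_forward_grad <- function(net, x, wrt) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stop_if(wrt < 1 || wrt > net$n_in, "wrt outside the input dimensions")
  a <- x
  da <- matrix(0, nrow(x), ncol(x)); da[, wrt] <- 1
  d2a <- matrix(0, nrow(x), ncol(x))
  L <- length(net$W)
  for (l in seq_len(L - 1)) {
    z1 <- da %*% net$W[[l]]
    z2 <- d2a %*% net$W[[l]]
    h <- tanh(sweep(a %*% net$W[[l]], 2, net$b[[l]], "+"))
    sech2 <- 1 - h^2
    a <- h
    da <- sech2 * z1
    d2a <- -2 * h * sech2 * z1^2 + sech2 * z2
  }
  list(value = sweep(a %*% net$W[[L]], 2, net$b[[L]], "+"),
       d1 = da %*% net$W[[L]],
       d2 = d2a %*% net$W[[L]])
}

# Fused pass: value, first derivatives along two input coordinates, and the
# second derivative along the first of them, in one propagation (used by the
# PDE residual, where theta_t, theta_z and theta_zz are all needed).
mlp_forward_grad2 <- function(net, x, wrt1, wrt2) {
  a <- x
  da1 <- matrix(0, nrow(x), ncol(x)); da1[, wrt1] <- 1
  da2 <- matrix(0, nrow(x), ncol(x)); da2[, wrt2] <- 1
  dd1 <- matrix(0, nrow(x), ncol(x))
  L <- length(net$W)
  for (l in seq_len(L - 1)) {
    W <- net$W[[l]]
    z1 <- da1 %*% W; z2 <- da2 %*% W; zz <- dd1 %*% W
    h <- tanh(sweep(a %*% W, 2, net$b[[l]], "+"))
    sech2 <- 1 - h^2
    a <- h
    da1 <- sech2 * z1
    da2 <- sech2 * z2
    dd1 <- -2 * h * sech2 * z1^2 + sech2 * zz
  }
  W <- net$W[[L]]
  list(value = sweep(a %*% W, 2, net$b[[L]], "+"),
       d1a = da1 %*% W, d1b = da2 %*% W, d2a = dd1 %*% W)
}
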