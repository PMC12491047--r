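# Extended Fourier Amplitude Sensitivity Test (EFAST): search-curve sampling,
# spectral estimation of first-order and total-order indices, and the
# screening rule used to pick calibration parameters.

#' Parameter specification table
#'
#' @param name Parameter names.
#' @param lower,upper Bounds (lower < upper).
#' @param nominal Optional nominal values inside the bounds.
#' @return A data.frame of class \code{param_spec}.
#' @export
param_spec <- function(name, lower, upper, nominal = (lower + upper) / 2) {
  stop_if(any(lower >= upper), "each lower bound must be below its upper bound")
  stop_if(any(nominal < lower | nominal > upper), "nominal outside bounds")
  structure(data.frame(name = name, lower = lower, upper = upper,
                       nominal = nominal, stringsAsFactors = FALSE),
            class = c("param_spec", "data.frame"))
}

#' Parameter ranges around a crop profile
#'
#' Builds +/- \code{frac} ranges around the nominal crop parameter values,
#' truncated where an ordering invariant would otherwise be violated
#' (depletion thresholds stay in (0, 1) and below their partners).
#'
#' @param params A \code{crop_params} object.
#' @param names Which parameters to vary.
#' @param frac Half-width as a fraction of the nominal value (default 0.25).
#' @return A \code{\link{param_spec}} table.
#' @export
crop_param_ranges <- function(params, names, frac = 0.25) {
  nominal <- vapply(names, function(n) {
    stop_if(is.null(params[[n]]), "unknown crop parameter: ", n)
    as.numeric(params[[n]])
  }, numeric(1))
  lower <- nominal * (1 - frac)
  upper <- nominal * (1 + frac)
  unitish <- names %in% c("mcc", "hi", "puexp", "plexp", "psto", "psen",
                          "ppol", "hinc", "hipsflo", "anaer")
  upper[unitish] <- pmin(upper[unitish], 0.999)
  param_spec(names, lower, upper, nominal)
}

#' EFAST sampling design
#'
#' One search curve per parameter: the parameter of interest runs at the
#' maximum interference-free frequency, the complement at low frequencies
#' (Saltelli's extended FAST assignment), with seeded random phase shifts.
#' Samples follow the search curve
#' \code{x = 0.5 + (1/pi) asin(sin(w s + phi))} scaled into each parameter's
#' range.
#'
#' @param specs A \code{\link{param_spec}} table (k parameters).
#' @param ns Samples per curve; must be at least \code{65 * k}.
#' @param m Interference factor (harmonics kept), default 4.
#' @param seed Integer seed for the phase shifts.
#' @return An object of class \code{efast_design}: list with the stacked
#'   sample matrix \code{samples} (\code{ns * k} rows, k columns, one block
#'   per curve), frequencies and bookkeeping.
#' @export
efast_design <- function(specs, ns = 65 * nrow(specs) * 5, m = 4, seed = 1L) {
  stopifnot(inherits(specs, "param_spec"))
  k <- nrow(specs)
  stop_if(ns < 65 * k,
          sprintf("ns = %d is too small: EFAST requires at least 65 x k = %d samples per curve",
                  ns, 65 * k))
  w0 <- floor((ns - 1) / (2 * m))      # driving frequency
  wm <- floor(w0 / (2 * m))            # complementary-frequency ceiling
  stop_if(w0 < 1 || wm < 1, "ns too small for the requested interference factor")
  comp <- if (wm >= k - 1 && k > 1) floor(seq(1, wm, length.out = k - 1)) else
    if (k > 1) (seq_len(k - 1) - 1) %% wm + 1 else integer(0)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s <- 2 * pi / ns * (seq_len(ns) - 1)
  samples <- matrix(NA_real_, nrow = ns * k, ncol = k,
                    dimnames = list(NULL, specs$name))
  omega <- matrix(NA_real_, nrow = k, ncol = k)
  for (i in seq_len(k)) {
    w <- numeric(k)
    w[i] <- w0
    w[-i] <- comp
    phi <- runif(k, 0, 2 * pi)
    x01 <- 0.5 + 1 / pi * asin(sin(outer(s, w) +
                                     matrix(phi, ns, k, byrow = TRUE)))
    rows <- (i - 1) * ns + seq_len(ns)
    samples[rows, ] <- sweep(sweep(x01, 2, specs$upper - specs$lower, "*"),
                             2, specs$lower, "+")
    omega[i, ] <- w
  }
  structure(list(samples = samples, ns = ns, k = k, m = m, w0 = w0,
                 omega = omega, specs = specs, seed = seed),
            class = "efast_design")
}

#' EFAST sensitivity indices
#'
#' Spectral decomposition of the model output along each search curve: the
#' first-order index Si is the variance at the driving frequency and its
#' harmonics over the total variance; the total-order index STi is one minus
#' the variance share of the complementary low-frequency band.
#'
#' @param y Model outputs for \code{design$samples}, length \code{ns * k}
#'   (finite).
#' @param design An \code{\link{efast_design}}.
#' @return An object of class \code{sensitivity_result}: data.frame with
#'   \code{name, si, sti, interaction}.
#' @export
efast_indices <- function(y, design) {
  stopifnot(inherits(design, "efast_design"))
  ns <- design$ns; k <- design$k; m <- design$m; w0 <- design$w0
  stop_if(length(y) != ns * k, "output length must equal ns * k")
  stop_if(any(!is.finite(y)), "model outputs must be finite")
  si <- sti <- numeric(k)
  for (i in seq_len(k)) {
    yi <- y[(i - 1) * ns + seq_len(ns)]
    if (var(yi) < .Machine$double.eps) {
      warning("zero output variance on curve ", i, "; indices reported as 0")
      next
    }
    f <- fft(yi)
    nspec <- floor((ns + 1) / 2) - 1
    sp <- (Mod(f[1 + seq_len(nspec)]) / ns)^2
    v <- 2 * sum(sp)
    d1 <- 2 * sum(sp[seq_len(m) * w0])
    dt <- 2 * sum(sp[seq_len(floor(w0 / 2))])
    si[i] <- d1 / v
    sti[i] <- 1 - dt / v
  }
  structure(data.frame(name = design$specs$name, si = si, sti = sti,
                       interaction = sti - si, stringsAsFactors = FALSE),
            class = c("sensitivity_result", "data.frame"))
}

#' Run an EFAST analysis of a model function
#'
#' @param model Function taking a numeric parameter vector (or a matrix row)
#'   and returning a scalar output, or a vectorized function of the whole
#'   sample matrix returning one value per row.
#' @param specs A \code{\link{param_spec}} table.
#' @param ns,m,seed Passed to \code{\link{efast_design}}.
#' @param vectorized If TRUE, \code{model} is called once on the matrix.
#' @return A \code{sensitivity_result}.
#' @export
efast_run <- function(model, specs, ns = 65 * nrow(specs) * 5, m = 4,
                      seed = 1L, vectorized = FALSE) {
  design <- efast_design(specs, ns, m, seed)
  y <- if (vectorized) model(design$samples) else
    apply(design$samples, 1, model)
  efast_indices(y, design)
}

#' Time-resolved EFAST indices
#'
#' @param ymat Matrix of outputs: \code{ns * k} rows, one column per output
#'   time step.
#' @param design An \code{\link{efast_design}}.
#' @return A list of \code{sensitivity_result} objects, one per column.
#' @export
efast_indices_over_time <- function(ymat, design) {
  lapply(seq_len(ncol(ymat)), function(j)
    suppressWarnings(efast_indices(ymat[, j], design)))
}

#' Screening rule for sensitive parameters
#'
#' A parameter is retained when its first-order index exceeds
#' \code{si_thresh} or its total-order index exceeds \code{sti_thresh}
#' (strict inequalities); results are ordered by total-order index,
#' descending.
#'
#' @param result A \code{sensitivity_result}.
#' @param si_thresh First-order threshold (default 0.05).
#' @param sti_thresh Total-order threshold (default 0.10).
#' @return Character vector of selected parameter names.
#' @export
screen_parameters <- function(result, si_thresh = 0.05, sti_thresh = 0.10) {
  stopifnot(inherits(result, "sensitivity_result"))
  sel <- result[result$si > si_thresh | result$sti > sti_thresh, ]
  sel$name[order(sel$sti, decreasing = TRUE)]
}

#' Ishigami test function
#'
#' \code{y = sin(x1) + a sin(x2)^2 + b x3^4 sin(x1)} on \[-pi, pi\]^3; the
#' standard benchmark with known analytic variance decomposition, used to
#' validate the EFAST estimator.
#'
#' @param x Numeric length-3 vector or a 3-column matrix.
#' @param a,b Coefficients (defaults 7 and 0.1).
#' @return Scalar or vector of outputs.
#' @export
ishigami <- function(x, a = 7, b = 0.1) {
  if (is.matrix(x))
    sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
  else sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
}
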