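# Goodness-of-fit and water-efficiency statistics.

#' Goodness-of-fit report
#'
#' Computes the four standard skill metrics for a simulated-vs-observed
#' comparison: squared Pearson correlation R2, root mean square error, the
#' Nash-Sutcliffe efficiency EF and Willmott's index of agreement d.
#' Optionally R2 can be taken about the 1:1 line (identical to EF) instead of
#' the regression definition.
#'
#' @param observed,simulated Equal-length numeric series, n >= 2; the observed
#'   series must not be constant.
#' @param r2_one_to_one If TRUE, report R2 about the 1:1 line instead of the
#'   squared Pearson correlation.
#' @return An object of class \code{fit_report}: list with \code{r2},
#'   \code{rmse}, \code{ef}, \code{d}, \code{n}.
#' @export
evaluate_fit <- function(observed, simulated, r2_one_to_one = FALSE) {
  stop_if(length(observed) != length(simulated), "series lengths differ")
  n <- length(observed)
  stop_if(n < 2, "at least two points are required")
  stop_if(sd(observed) == 0, "observed series has zero variance")
  err2 <- sum((simulated - observed)^2)
  om <- mean(observed)
  ef <- 1 - err2 / sum((observed - om)^2)
  d <- 1 - err2 / sum((abs(simulated - om) + abs(observed - om))^2)
  r2 <- if (r2_one_to_one) ef else {
    if (sd(simulated) == 0) 0 else stats::cor(observed, simulated)^2
  }
  structure(list(r2 = r2, rmse = sqrt(err2 / n), ef = ef, d = d, n = n),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Fit (n = %d): R2 = %.4f, RMSE = %.4f, EF = %.4f, d = %.4f\n",
              x$n, x$r2, x$rmse, x$ef, x$d))
  invisible(x)
}

#' Signed relative error in percent
#'
#' \code{100 * (simulated - observed) / observed}; positive when the model
#' overestimates.
#'
#' @param observed Positive reference value(s).
#' @param simulated Simulated value(s).
#' @return Signed relative error (%), vectorized.
#' @export
relative_error <- function(observed, simulated) {
  stop_if(any(observed <= 0), "observed values must be positive")
  100 * (simulated - observed) / observed
}

#' Seasonal evapotranspiration by the water-balance method
#'
#' \code{ET = P + I - dSWS - R - D} (all mm); the storage change may be
#' negative.
#'
#' @param precip,irrigation Seasonal totals (mm).
#' @param dsws Soil water storage change (mm, signed).
#' @param runoff,drainage Seasonal surface runoff and deep percolation (mm).
#' @return Seasonal crop water consumption ET (mm).
#' @export
seasonal_et <- function(precip, irrigation, dsws, runoff = 0, drainage = 0) {
  precip + irrigation - dsws - runoff - drainage
}

#' Water use efficiency
#'
#' Yield per unit of seasonal evapotranspiration.
#'
#' @param yield Yield (kg hm-2).
#' @param et Seasonal evapotranspiration (mm), > 0.
#' @return WUE (kg hm-2 mm-1).
#' @export
wue <- function(yield, et) {
  stop_if(any(et <= 0), "ET must be positive")
  yield / et
}

#' The printed yield-validation table
#'
#' Observed and simulated yields (kg hm-2) with the printed relative-error
#' column for the nine 2024 deficit treatments and the three farmer-control
#' seasons, shipped as package data.
#'
#' @return A data.frame with columns \code{treatment, observed_kg_hm2,
#'   simulated_kg_hm2, re_printed_pct}.
#' @export
yield_validation_table <- function() {
  read.csv(system.file("extdata", "yield_validation_2024.csv",
                       package = "aquadeficit"), check.names = TRUE)
}

#' The printed optimized-vs-unoptimized comparison table
#'
#' Unoptimized and optimized yield and WUE for the nine seasonal quotas
#' (334-507 mm), shipped as package data.
#'
#' @return A data.frame with quota, plan, yields (kg hm-2) and WUE columns.
#' @export
optimization_comparison_table <- function() {
  read.csv(system.file("extdata", "optimization_comparison.csv",
                       package = "aquadeficit"), check.names = TRUE)
}
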