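# Real-coded genetic algorithm on the 12-event allocation simplex: tournament
# selection, blend crossover, Gaussian mutation, and clip-renormalize repair.

#' GA configuration
#'
#' @param pop Population size.
#' @param generations Number of generations.
#' @param cx_rate Crossover probability per pair, in \[0, 1\].
#' @param mut_rate Per-gene mutation probability, in \[0, 1\].
#' @param mut_sd Gaussian mutation standard deviation (share units).
#' @param elitism Number of elites copied unchanged (>= 1).
#' @param tournament Tournament size for selection.
#' @param seed Integer seed.
#' @return An object of class \code{ga_config}.
#' @export
ga_config <- function(pop = 24L, generations = 60L, cx_rate = 0.9,
                      mut_rate = 0.25, mut_sd = 0.03, elitism = 2L,
                      tournament = 3L, seed = 1L) {
  stop_if(cx_rate < 0 || cx_rate > 1 || mut_rate < 0 || mut_rate > 1,
          "rates must be in [0, 1]")
  stop_if(elitism < 1, "elitism must keep at least one individual")
  structure(list(pop = as.integer(pop), generations = as.integer(generations),
                 cx_rate = cx_rate, mut_rate = mut_rate, mut_sd = mut_sd,
                 elitism = as.integer(elitism),
                 tournament = as.integer(tournament), seed = as.integer(seed)),
            class = "ga_config")
}

#' Project a genome onto the bounded allocation simplex
#'
#' Clips negative shares to zero, renormalizes to sum one, and iteratively
#' enforces the per-event upper bound.
#'
#' @param shares Numeric vector of event shares.
#' @param share_cap Upper bound per share (default 1 = no cap).
#' @return A repaired share vector on the simplex (sum 1, within bounds).
#' @export
repair_simplex <- function(shares, share_cap = 1) {
  stop_if(share_cap * length(shares) < 1 - 1e-12,
          "share cap too tight for a feasible simplex point")
  s <- pmax(0, shares)
  if (sum(s) == 0) s <- rep(1 / length(s), length(s))
  s <- s / sum(s)
  for (i in 1:50) {
    over <- s > share_cap
    if (!any(over)) break
    excess <- sum(s[over] - share_cap)
    s[over] <- share_cap
    free <- !over
    s[free] <- s[free] + excess * (if (sum(s[free]) > 0)
      s[free] / sum(s[free]) else 1 / sum(free))
  }
  s / sum(s)
}

#' Maximize a fitness over quota allocations with a genetic algorithm
#'
#' Genomes are 12 non-negative shares of the seasonal quota summing to one.
#' Tournament selection, blend (BLX-alpha) crossover, Gaussian mutation and
#' simplex repair; the baseline genome is injected into generation zero and
#' elitism makes the best fitness non-decreasing across generations.
#'
#' @param fitness Function(shares) -> scalar to maximize (defined on the
#'   simplex).
#' @param quota Seasonal irrigation quota (mm), > 0 (0 is allowed and yields
#'   the baseline immediately).
#' @param config A \code{\link{ga_config}}.
#' @param baseline Baseline share vector (seeded into the population).
#' @param n_events Number of events (genome length), default 12.
#' @param max_event_mm Per-event depth bound (mm) for drip feasibility;
#'   converted to a share cap at the given quota.
#' @return List with \code{shares}, \code{fitness}, \code{trace}
#'   (best-per-generation), \code{baseline_fitness}, \code{evals}.
#' @export
ga_optimize_allocation <- function(fitness, quota, config = ga_config(),
                                   baseline = NULL, n_events = 12L,
                                   max_event_mm = 60) {
  stop_if(quota < 0, "quota must be non-negative")
  cap <- if (quota > 0) min(1, max_event_mm / quota) else 1
  base <- repair_simplex(baseline %||% rep(1 / n_events, n_events), cap)
  base_fit <- fitness(base)
  if (quota == 0)
    return(list(shares = base, fitness = base_fit, trace = base_fit,
                baseline_fitness = base_fit, evals = 1L))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  np <- config$pop
  pop <- t(vapply(seq_len(np), function(i) {
    if (i == 1) base else repair_simplex(rexp(n_events), cap)
  }, numeric(n_events)))
  fit <- apply(pop, 1, fitness)
  evals <- np + 1L
  trace <- numeric(config$generations)

  for (g in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    elite_fit <- fit[ord[seq_len(config$elitism)]]

    pick <- function() {
      cand <- sample.int(np, config$tournament, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    children <- matrix(NA_real_, nrow = np, ncol = n_events)
    i <- 1L
    while (i <= np) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (runif(1) < config$cx_rate) {       # blend crossover, alpha = 0.5
        u <- runif(n_events, -0.5, 1.5)
        c1 <- u * p1 + (1 - u) * p2
        c2 <- (1 - u) * p1 + u * p2
      } else { c1 <- p1; c2 <- p2 }
      mut <- function(x) {
        hit <- runif(n_events) < config$mut_rate
        x[hit] <- x[hit] + rnorm(sum(hit), 0, config$mut_sd)
        x
      }
      children[i, ] <- repair_simplex(mut(c1), cap)
      if (i + 1L <= np) children[i + 1L, ] <- repair_simplex(mut(c2), cap)
      i <- i + 2L
    }
    children[seq_len(config$elitism), ] <- elite
    child_fit <- apply(children, 1, fitness)
    child_fit[seq_len(config$elitism)] <- elite_fit
    evals <- evals + np - config$elitism
    pop <- children; fit <- child_fit
    trace[g] <- max(fit)
  }
  best <- which.max(fit)
  list(shares = pop[best, ], fitness = fit[best], trace = trace,
       baseline_fitness = base_fit, evals = evals)
}
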