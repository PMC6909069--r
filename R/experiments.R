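# Deterministic per-replicate seed: base seed plus replicate index.
replicate_seed <- function(base_seed, r) as.integer(base_seed) + as.integer(r)

#' Monte Carlo replication of a simulation
#'
#' Runs `replicates` independent simulations of the same configuration,
#' each with a fresh random assignment of class and strategy (replicate
#' `r` uses seed `base_seed + r`), and aggregates per-category survival
#' fractions and final wealth as plain means and standard errors across
#' replicates.  The study baseline uses 100 replicates.
#'
#' @param config A [game_config()]; `config$seed` is the base seed
#'   (default 0 when unset).
#' @param replicates Number of replicates (>= 1).
#' @return An object of class `farmers_mc`:
#'   \describe{
#'     \item{aggregate}{data frame per category with `survival_mean`,
#'       `survival_se`, `wealth_mean`, `wealth_se`, `initial_mean`,
#'       `replicates_used` (replicates with the category present).}
#'     \item{replicates}{per-replicate per-category long data frame.}
#'     \item{totals}{per-replicate totals (population and wealth, initial
#'       and final).}
#'   }
#' @examples
#' mc <- run_monte_carlo(game_config(rows = 8, cols = 8, rounds = 10, seed = 1),
#'                       replicates = 5)
#' mc$aggregate
#' @seealso [survival_fraction()], [dieoff_fraction()],
#'   [find_equilibrium_turn_cost()]
#' @export
run_monte_carlo <- function(config, replicates = 100) {
  validate_config(config)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  base_seed <- if (is.null(config$seed)) 0L else config$seed

  reps <- vector("list", replicates)
  totals <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- replicate_seed(base_seed, r)
    res <- run_simulation(cfg_r)
    s <- res$summary
    s$replicate <- r
    reps[[r]] <- s
    totals[[r]] <- data.frame(replicate = r,
                              initial_pop = sum(s$initial_count),
                              final_pop = sum(s$final_count),
                              initial_wealth = sum(s$initial_wealth),
                              final_wealth = sum(s$final_wealth))
  }
  reps <- do.call(rbind, reps)
  totals <- do.call(rbind, totals)

  grid <- category_grid(config)
  agg <- grid
  agg$survival_mean <- NA_real_; agg$survival_se <- NA_real_
  agg$wealth_mean <- NA_real_; agg$wealth_se <- NA_real_
  agg$initial_mean <- NA_real_; agg$replicates_used <- NA_integer_
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  for (j in seq_len(nrow(grid))) {
    sel <- reps$class == grid$class[[j]] & reps$strategy == grid$strategy[[j]]
    present <- sel & reps$initial_count > 0
    surv <- reps$survival[present]
    agg$survival_mean[[j]] <- if (length(surv)) mean(surv) else NA_real_
    agg$survival_se[[j]] <- se(surv)
    agg$wealth_mean[[j]] <- mean(reps$final_wealth[sel])
    agg$wealth_se[[j]] <- se(reps$final_wealth[sel])
    agg$initial_mean[[j]] <- mean(reps$initial_count[sel])
    agg$replicates_used[[j]] <- sum(present)
  }
  structure(list(aggregate = agg, replicates = reps, totals = totals,
                 config = config, base_seed = base_seed,
                 n_replicates = replicates),
            class = "farmers_mc")
}

#' @export
print.farmers_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo aggregate: %d replicates, base seed %d\n",
              x$n_replicates, x$base_seed))
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean survival fraction of one category
#'
#' Mean over replicates of final count divided by initial count for the
#' given (initial class, strategy) category; replicates in which the
#' category drew zero initial members are excluded.
#'
#' @param aggregate A [run_monte_carlo()] result.
#' @param class `"poor"` or `"rich"`.
#' @param strategy One of [strategy_kinds()].
#' @return A fraction in \[0, 1\].
#' @export
survival_fraction <- function(aggregate, class, strategy) {
  stopifnot(inherits(aggregate, "farmers_mc"))
  class <- match.arg(class, c("poor", "rich"))
  strategy <- match.arg(strategy, FG_STRATEGIES)
  a <- aggregate$aggregate
  row <- a$class == class & a$strategy == strategy
  if (!any(row)) stop("category absent from the strategy mix: ",
                      class, "/", strategy)
  a$survival_mean[row]
}

#' Total population die-off fraction
#'
#' `1 - mean(final population / initial population)` over replicates: the
#' fraction of the initial population removed by the survival threshold.
#'
#' @param aggregate A [run_monte_carlo()] result.
#' @return A fraction in \[0, 1\].
#' @export
dieoff_fraction <- function(aggregate) {
  stopifnot(inherits(aggregate, "farmers_mc"))
  1 - mean(aggregate$totals$final_pop / aggregate$totals$initial_pop)
}

# Mean final-minus-initial total wealth of the target class at a given
# turn cost, over fixed replicate seeds (common random numbers keep the
# bisection objective a deterministic, monotone-in-cost function).
class_wealth_change <- function(config, target_class, replicates, base_seed) {
  diffs <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- replicate_seed(base_seed, r)
    s <- run_simulation(cfg_r)$summary
    sel <- if (target_class == "all") rep(TRUE, nrow(s)) else
      s$class == target_class
    diffs[[r]] <- sum(s$final_wealth[sel]) - sum(s$initial_wealth[sel])
  }
  mean(diffs)
}

#' Find the wealth-equilibrium cost per turn
#'
#' The wealth equilibrium is the turn cost at which a class's total wealth
#' after `config$rounds` rounds equals its initial total.  Societies tend
#' to operate near this point, so it serves as the model's operating-point
#' calibration.  The search bisects the turn cost against the Monte Carlo
#' mean wealth change of the target class, using the same replicate seeds
#' at every evaluation.
#'
#' For the two closed-form societies the result is analytic: an all
#' tit-for-tat society equilibrates at the mutual-cooperation payoff
#' (every interaction nets `reward_cc - turn_cost`) and an all-defect
#' society at the mutual-defection payoff.
#'
#' @param config A [game_config()]; its `turn_cost` is ignored in favour of
#'   the bracket.
#' @param target_class `"rich"`, `"poor"`, or `"all"` (total wealth).
#' @param replicates Monte Carlo replicates per bisection evaluation.
#' @param tolerance Absolute residual-wealth tolerance in tokens; default
#'   0.5% of the class's mean initial wealth.
#' @param bracket Turn-cost interval over which the mean wealth change must
#'   change sign.
#' @param width_floor Stop once the bracket is narrower than this.
#' @return A list of class `farmers_equilibrium`: `turn_cost`, `residual`
#'   (mean wealth change at the returned cost), `bracket` (final), `target_class`,
#'   `evaluations`.
#' @examples
#' cfg <- game_config(rows = 6, cols = 6, rounds = 10,
#'                    strategy_mix = strategy_mix("titfortat"), seed = 1)
#' eq <- find_equilibrium_turn_cost(cfg, "all", replicates = 2)
#' eq$turn_cost  # 1.1: the full benefit of cooperation
#' @export
find_equilibrium_turn_cost <- function(config,
                                       target_class = c("all", "rich", "poor"),
                                       replicates = 100,
                                       tolerance = NULL,
                                       bracket = c(0.5, 1.6),
                                       width_floor = 1e-3) {
  validate_config(config)
  target_class <- match.arg(target_class)
  replicates <- as.integer(replicates)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2], bracket[1] > 0)

  if (is.null(tolerance)) {
    n <- config$rows * config$cols
    mean_w0 <- config$density_poor * config$wealth_poor +
      (1 - config$density_poor) * config$wealth_rich
    class_share <- switch(target_class,
      all = 1,
      poor = config$density_poor * config$wealth_poor / mean_w0,
      rich = (1 - config$density_poor) * config$wealth_rich / mean_w0)
    tolerance <- 0.005 * n * mean_w0 * class_share
  }

  f <- function(cost) {
    cfg <- config
    cfg$turn_cost <- cost
    class_wealth_change(cfg, target_class, replicates, base_seed)
  }
  lo <- bracket[[1]]; hi <- bracket[[2]]
  f_lo <- f(lo); f_hi <- f(hi)
  evals <- 2L
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(paste0("no sign change over bracket [%g, %g]: ",
                        "wealth change %g and %g"), lo, hi, f_lo, f_hi))
  }
  # wealth change decreases in cost, so f(lo) > 0 > f(hi)
  mid <- (lo + hi) / 2; f_mid <- f_lo
  while (hi - lo > width_floor) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    evals <- evals + 1L
    if (abs(f_mid) <= tolerance) break
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
  }
  structure(list(turn_cost = mid, residual = f_mid,
                 bracket = c(lo, hi), tolerance = tolerance,
                 target_class = target_class, evaluations = evals,
                 replicates = replicates),
            class = "farmers_equilibrium")
}

#' @export
print.farmers_equilibrium <- function(x, ...) {
  cat(sprintf(paste0("Wealth-equilibrium turn cost (%s): %.4f\n",
                     "  residual %.4g tokens (tolerance %.4g), bracket [%.4f, %.4f], %d evaluations\n"),
              x$target_class, x$turn_cost, x$residual, x$tolerance,
              x$bracket[1], x$bracket[2], x$evaluations))
  invisible(x)
}

#' Histogram of final wealth by category
#'
#' Bins the final wealth of alive players per (initial class, strategy)
#' category on a common scale (default: unit-token bins over \[0, 50\];
#' the upper limit extends automatically to cover the observed maximum).
#'
#' @param result A [run_simulation()] result.
#' @param bin_width Bin width in tokens (> 0).
#' @param limits Numeric length-2 lower/upper wealth limits of the common
#'   scale.
#' @return A list of class `farmers_histogram`: `breaks` (bin edges,
#'   left-closed bins) and `counts`, a matrix with one row per category.
#' @export
wealth_histogram <- function(result, bin_width = 1, limits = c(0, 50)) {
  stopifnot(inherits(result, "farmers_result"))
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  ag <- result$agents[result$agents$alive, , drop = FALSE]
  top <- max(limits[[2]], if (nrow(ag)) max(ag$wealth) else limits[[2]])
  breaks <- seq(limits[[1]], limits[[1]] +
                  bin_width * ceiling((top - limits[[1]]) / bin_width + 1e-9),
                by = bin_width)
  grid <- category_grid(result$config)
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(breaks) - 1L,
                   dimnames = list(paste(grid$class, grid$strategy), NULL))
  for (j in seq_len(nrow(grid))) {
    w <- ag$wealth[ag$class == grid$class[[j]] &
                     ag$strategy == grid$strategy[[j]]]
    if (length(w)) {
      idx <- findInterval(w, breaks, rightmost.closed = TRUE)
      counts[j, ] <- tabulate(idx, nbins = ncol(counts))
    }
  }
  structure(list(breaks = breaks, counts = counts, categories = grid,
                 bin_width = bin_width),
            class = "farmers_histogram")
}

#' Sweep survival and wealth over a turn-cost grid
#'
#' Runs a Monte Carlo aggregate at each turn cost and returns a tidy table
#' (one row per turn cost x category), plus total die-off per point — the
#' survival-versus-cost curves of the model.
#'
#' @param config A [game_config()].
#' @param turn_costs Numeric vector of turn costs.
#' @param replicates Replicates per point.
#' @return A data frame with columns `turn_cost`, `class`, `strategy`,
#'   `survival_mean`, `survival_se`, `wealth_mean`, `wealth_se`, `dieoff`.
#' @export
run_sweep <- function(config, turn_costs, replicates = 100) {
  out <- vector("list", length(turn_costs))
  for (i in seq_along(turn_costs)) {
    cfg <- config
    cfg$turn_cost <- turn_costs[[i]]
    mc <- run_monte_carlo(cfg, replicates)
    a <- mc$aggregate
    a <- a[, c("class", "strategy", "survival_mean", "survival_se",
               "wealth_mean", "wealth_se")]
    a$turn_cost <- turn_costs[[i]]
    a$dieoff <- dieoff_fraction(mc)
    out[[i]] <- a
  }
  df <- do.call(rbind, out)
  df[, c("turn_cost", "class", "strategy", "survival_mean", "survival_se",
         "wealth_mean", "wealth_se", "dieoff")]
}
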