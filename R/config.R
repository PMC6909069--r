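# Strategy identifiers, in the fixed order used throughout the package and
# by the compiled engine (codes 1..6).
FG_STRATEGIES <- c("titfortat", "subsist", "exploit", "thief", "middle",
                   "always_defect")

#' Named strategy-mix presets
#'
#' `"5strat"` is the equal-weight five-strategy society (tit-for-tat,
#' subsist, exploit, thief, middle); `"3strat"` the equal-weight
#' three-strategy society (tit-for-tat, subsist, exploit); `"titfortat"`
#' and `"defect"` are the pure cooperating and pure always-defect
#' comparator societies.
#'
#' @param name Preset name.
#' @return A named numeric weight vector over the six strategy kinds.
#' @examples
#' strategy_mix("3strat")
#' @export
strategy_mix <- function(name = c("5strat", "3strat", "titfortat", "defect")) {
  name <- match.arg(name)
  w <- stats::setNames(numeric(length(FG_STRATEGIES)), FG_STRATEGIES)
  w[switch(name,
           "5strat" = c("titfortat", "subsist", "exploit", "thief", "middle"),
           "3strat" = c("titfortat", "subsist", "exploit"),
           "titfortat" = "titfortat",
           "defect" = "always_defect")] <- 1
  w
}

#' Farmer's Game simulation configuration
#'
#' Bundles every parameter of a simulation run.  The defaults reproduce the
#' baseline study conditions: a 20 x 20 bordered lattice, 50 rounds, payoffs
#' (1.1, 2.2, 0, 1.0), turn cost 1.07 (near wealth equilibrium), 10%
#' tit-for-tat forgiveness, half the players initially poor with 4 tokens
#' and the rest wealthy with 10, and the equal-weight five-strategy mix.
#'
#' @param payoffs A [payoff_matrix()].
#' @param turn_cost Tokens each player consumes per interaction; positive.
#' @param forgiveness Probability in \[0, 1\] that a tit-for-tat retaliation
#'   is replaced by cooperation.
#' @param rows,cols Lattice dimensions (>= 1).
#' @param rounds Number of rounds; in each round every live edge is played
#'   once, so interior players take 4 turns per round.
#' @param density_poor Probability that a player starts poor.
#' @param wealth_poor,wealth_rich Initial token endowments.  The poor start
#'   with approximately enough to survive one round of four turns.
#' @param subsist_threshold Wealth at or below which a subsist player
#'   defects (survival of the next round in doubt).
#' @param middle_threshold Wealth at or below which a middle player defects
#'   (survival of two rounds in doubt).
#' @param wealth_ratio_trigger Wealth ratio at or above which exploit
#'   (self richer) and thief (opponent richer) defect.
#' @param strategy_mix Named nonnegative weights over the strategy kinds
#'   (`titfortat`, `subsist`, `exploit`, `thief`, `middle`,
#'   `always_defect`); see [strategy_mix()] for presets.  Weights are
#'   normalised internally.
#' @param reconnect Death-reconnection policy: `"clique"` (default)
#'   connects every pair of the dead player's still-alive neighbours —
#'   the literal reading of survivors being "connected to each other" —
#'   at the price of degrees growing as deaths accumulate; `"pair"`
#'   connects them in opposite pairs, preserving degrees (about 4 turns
#'   per round throughout).  See [remove_node_reconnect()] and the
#'   vignette for how the choice shifts heavy-die-off regimes.
#' @param borderless Build a toroidal (wraparound) lattice instead of the
#'   default bordered one; used for edge-effect comparisons.
#' @param seed Integer seed making the run reproducible, or `NULL`.
#'
#' @return An object of class `farmers_config` (validated).
#' @examples
#' cfg <- game_config(seed = 1)
#' cfg3 <- game_config(strategy_mix = strategy_mix("3strat"), seed = 1)
#' @seealso [validate_config()], [run_simulation()], [load_config()]
#' @export
game_config <- function(payoffs = payoff_matrix(),
                        turn_cost = 1.07,
                        forgiveness = 0.10,
                        rows = 20, cols = 20,
                        rounds = 50,
                        density_poor = 0.5,
                        wealth_poor = 4, wealth_rich = 10,
                        subsist_threshold = 4,
                        middle_threshold = 8,
                        wealth_ratio_trigger = 2,
                        strategy_mix = farmersgame::strategy_mix("5strat"),
                        reconnect = c("clique", "pair"),
                        borderless = FALSE,
                        seed = NULL) {
  reconnect <- match.arg(reconnect)
  cfg <- structure(list(
    payoffs = payoffs,
    turn_cost = as.numeric(turn_cost),
    forgiveness = as.numeric(forgiveness),
    rows = as.integer(rows), cols = as.integer(cols),
    rounds = as.integer(rounds),
    density_poor = as.numeric(density_poor),
    wealth_poor = as.numeric(wealth_poor),
    wealth_rich = as.numeric(wealth_rich),
    subsist_threshold = as.numeric(subsist_threshold),
    middle_threshold = as.numeric(middle_threshold),
    wealth_ratio_trigger = as.numeric(wealth_ratio_trigger),
    strategy_mix = strategy_mix,
    reconnect = reconnect,
    borderless = isTRUE(borderless),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "farmers_config")
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the configuration (Prisoner's Dilemma payoff
#' ordering, probability bounds, positive dimensions and cost, nonnegative
#' thresholds, usable strategy weights) and reports *all* violations at
#' once.
#'
#' @param config A `farmers_config` as built by [game_config()].
#' @return The config, invisibly, if valid; otherwise an error listing each
#'   violation by name.
#' @examples
#' cfg <- validate_config(game_config())
#' @export
validate_config <- function(config) {
  if (!inherits(config, "farmers_config")) {
    stop("not a farmers_config; use game_config()")
  }
  errs <- character()
  add <- function(msg) errs[[length(errs) + 1L]] <<- msg

  p <- config$payoffs
  if (!inherits(p, "farmers_payoffs")) {
    add("payoffs: not a payoff_matrix()")
  } else if (!(p$temptation_dc >= p$reward_cc && p$reward_cc >= p$punish_dd &&
               p$punish_dd >= p$sucker_cd)) {
    add("payoffs: PD ordering violated")
  }
  prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      add(paste0(nm, ": probability out of range [0,1]"))
    }
  }
  prob(config$forgiveness, "forgiveness")
  prob(config$density_poor, "density_poor")
  if (config$turn_cost <= 0) add("turn_cost: must be positive")
  for (nm in c("rows", "cols")) {
    v <- config[[nm]]
    if (is.na(v) || v < 1L) add(paste0(nm, ": must be a positive count"))
  }
  if (is.na(config$rounds) || config$rounds < 0L) {
    add("rounds: must be a nonnegative count")
  }
  for (nm in c("wealth_poor", "wealth_rich", "subsist_threshold",
               "middle_threshold", "wealth_ratio_trigger")) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      add(paste0(nm, ": must be a nonnegative number"))
    }
  }
  mix <- config$strategy_mix
  if (is.null(names(mix)) || !all(names(mix) %in% FG_STRATEGIES)) {
    add(paste0("strategy_mix: names must be among ",
               paste(FG_STRATEGIES, collapse = ", ")))
  } else if (any(mix < 0) || sum(mix) <= 0) {
    add("strategy_mix: weights must be nonnegative with positive sum")
  }
  if (!identical(config$reconnect, "pair") &&
      !identical(config$reconnect, "clique")) {
    add("reconnect: must be \"pair\" or \"clique\"")
  }
  if (config$borderless && (config$rows < 3L || config$cols < 3L)) {
    add("borderless: toroidal lattice needs rows, cols >= 3")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

#' @export
print.farmers_config <- function(x, ...) {
  mix <- x$strategy_mix[x$strategy_mix > 0]
  cat(sprintf("Farmer's Game config: %dx%d%s lattice, %d rounds\n",
              x$rows, x$cols, if (x$borderless) " toroidal" else "", x$rounds))
  print(x$payoffs)
  cat(sprintf("  turn cost %.4g, forgiveness %.2f, density_poor %.2f, wealth %g/%g\n",
              x$turn_cost, x$forgiveness, x$density_poor,
              x$wealth_poor, x$wealth_rich))
  cat("  mix:", paste(sprintf("%s=%.3g", names(mix), mix / sum(mix)),
                      collapse = " "),
      if (!is.null(x$seed)) sprintf(" seed=%d", x$seed) else "", "\n")
  invisible(x)
}

# Normalised strategy probabilities in engine order (length 6).
mix_probs <- function(config) {
  w <- stats::setNames(numeric(6L), FG_STRATEGIES)
  w[names(config$strategy_mix)] <- config$strategy_mix
  w / sum(w)
}
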