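#' Initialise a population on the lattice
#'
#' Builds the lattice and assigns each player independently: poor with
#' probability `density_poor` (receiving `wealth_poor` tokens, by default 4
#' — approximately enough to last one round of four turns) else rich
#' (`wealth_rich`, default 10), and a strategy drawn from the normalised
#' `strategy_mix`.  Memories start empty and everyone is alive.
#'
#' The random stream is consumed in a fixed order — all class draws, then
#' all strategy draws, then (during play) one forgiveness draw per
#' retaliation decision — so a seeded run is fully reproducible and the
#' compiled and reference engines see identical populations.
#'
#' @param config A [game_config()].  If `config$seed` is set, the R random
#'   seed is set before any draw.
#' @return An object of class `farmers_population`.
#' @examples
#' pop <- init_population(game_config(rows = 4, cols = 4, seed = 1))
#' table(pop$class)
#' @seealso [run_round()], [run_simulation()]
#' @export
init_population <- function(config) {
  validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- build_lattice(config$rows, config$cols, config$borderless)
  n <- net$n
  cls <- ifelse(stats::runif(n) < config$density_poor, "poor", "rich")
  strat <- sample(FG_STRATEGIES, n, replace = TRUE, prob = mix_probs(config))
  wealth <- ifelse(cls == "poor", config$wealth_poor, config$wealth_rich)
  structure(list(net = net,
                 class = cls,
                 strategy = strat,
                 wealth = wealth,
                 initial_wealth = wealth,
                 memory = replicate(n, list(), simplify = FALSE),
                 death_round = rep(NA_integer_, n),
                 death_wealth = rep(NA_real_, n),
                 config = config,
                 round = 0L),
            class = "farmers_population")
}

#' @export
print.farmers_population <- function(x, ...) {
  cat(sprintf("Farmer's Game population: round %d, %d/%d alive, total wealth %.4g\n",
              x$round, sum(x$net$alive), x$net$n,
              sum(x$wealth[x$net$alive])))
  invisible(x)
}

# Lightweight agent view for decide_move().
agent_view <- function(pop, i) {
  structure(list(id = i, strategy = pop$strategy[[i]], class = pop$class[[i]],
                 wealth = pop$wealth[[i]], alive = pop$net$alive[[i]],
                 memory = pop$memory[[i]]),
            class = "farmers_agent")
}

#' Play one round (reference engine)
#'
#' One round plays every edge between two alive players exactly once, in
#' sorted-edge order, using the edge list as it stood at the start of the
#' round.  For each interaction both players decide simultaneously from
#' pre-interaction state ([decide_move()]), both record the opponent's move
#' ([record_outcome()] semantics), and both receive the net payoff
#' ([pair_payoff()]).  Immediately after the interaction any participant at
#' or below zero wealth dies — it is removed with neighbour reconnection
#' and plays no further interaction this round.  Edges created by
#' reconnection first play in the following round.
#'
#' This is the readable pure-R enactment of the rules; [run_simulation()]
#' uses a compiled engine with identical semantics and random-stream usage.
#'
#' @param population A `farmers_population`.
#' @return A list with `population` (updated) and `ledger`, a one-row data
#'   frame (`round`, `interactions`, `gross`, `cost`, `wealth_delta`,
#'   `deaths`).  The exact identity
#'   `wealth_delta == gross - 2 * turn_cost * interactions` holds every
#'   round.
#' @export
run_round <- function(population) {
  pop <- population
  cfg <- pop$config
  wealth_before <- sum(pop$wealth)
  edges <- lattice_edges(pop$net, alive_only = TRUE)
  gross_sum <- 0
  played <- 0L
  deaths <- integer()
  this_round <- pop$round + 1L
  for (k in seq_len(nrow(edges))) {
    a <- edges$node_a[[k]]; b <- edges$node_b[[k]]
    if (!pop$net$alive[[a]] || !pop$net$alive[[b]]) next
    A <- agent_view(pop, a); B <- agent_view(pop, b)
    move_a <- decide_move(A, B, cfg)
    move_b <- decide_move(B, A, cfg)
    pop$memory[[a]][[as.character(b)]] <- move_b
    pop$memory[[b]][[as.character(a)]] <- move_a
    pay <- pair_payoff(move_a, move_b, cfg$payoffs, cfg$turn_cost)
    pop$wealth[[a]] <- pop$wealth[[a]] + pay$net_a
    pop$wealth[[b]] <- pop$wealth[[b]] + pay$net_b
    gross_sum <- gross_sum + pay$gross_a + pay$gross_b
    played <- played + 1L
    dying <- c(a, b)[c(pop$wealth[[a]] <= 0, pop$wealth[[b]] <= 0)]
    if (length(dying)) {
      pop$net <- kill_nodes(pop$net, dying, cfg$reconnect)
      pop$death_round[dying] <- this_round
      pop$death_wealth[dying] <- pop$wealth[dying]
      deaths <- c(deaths, dying)
    }
  }
  pop$round <- this_round
  ledger <- data.frame(round = this_round,
                       interactions = played,
                       gross = gross_sum,
                       cost = 2 * cfg$turn_cost * played,
                       wealth_delta = sum(pop$wealth) - wealth_before,
                       deaths = length(deaths))
  list(population = pop, ledger = ledger)
}

# All (class x strategy) category labels for the strategies present in the
# mix, in engine order.
category_grid <- function(config) {
  strat <- FG_STRATEGIES[mix_probs(config) > 0]
  expand.grid(class = c("poor", "rich"), strategy = strat,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run a complete Farmer's Game simulation
#'
#' Initialises a population ([init_population()]) and plays
#' `config$rounds` rounds.  Players are classified throughout by their
#' *initial* class and (fixed) strategy, so the fate of each starting
#' category can be tracked; dead players are never replaced.
#'
#' @param config A [game_config()].
#' @param engine `"compiled"` (default, C++ core) or `"reference"` (pure R,
#'   [run_round()] in a loop).  Both consume the random stream identically,
#'   so a seeded run is engine-independent.
#' @return An object of class `farmers_result` with elements
#'   \describe{
#'     \item{summary}{data frame per (initial class x strategy) category:
#'       `initial_count`, `final_count`, `initial_wealth`, `final_wealth`
#'       (alive players only), `survival`.}
#'     \item{agents}{data frame of final per-player state (`id`, `row`,
#'       `col`, `class`, `strategy`, `initial_wealth`, `wealth`, `alive`,
#'       `death_round`).}
#'     \item{series}{long data frame (`round`, `class`, `strategy`,
#'       `alive`, `wealth`) from round 0 to `rounds`.}
#'     \item{deaths}{death log (`round`, `id`, `class`, `strategy`,
#'       `wealth`), wealth at death always <= 0.}
#'     \item{ledger}{per-round interaction/gross/cost accounting.}
#'   }
#' @examples
#' res <- run_simulation(game_config(rows = 8, cols = 8, rounds = 10, seed = 1))
#' res$summary
#' @seealso [run_monte_carlo()], [wealth_histogram()]
#' @export
run_simulation <- function(config, engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  pop <- init_population(config)
  if (engine == "compiled") {
    out <- .fg_run_engine(
      rows = config$rows, cols = config$cols,
      borderless = config$borderless,
      strategy = match(pop$strategy, FG_STRATEGIES),
      cls = match(pop$class, c("poor", "rich")),
      wealth0 = pop$wealth,
      reward_cc = config$payoffs$reward_cc,
      temptation_dc = config$payoffs$temptation_dc,
      sucker_cd = config$payoffs$sucker_cd,
      punish_dd = config$payoffs$punish_dd,
      turn_cost = config$turn_cost,
      forgiveness = config$forgiveness,
      subsist_thr = config$subsist_threshold,
      middle_thr = config$middle_threshold,
      ratio_trig = config$wealth_ratio_trigger,
      rounds = config$rounds,
      reconnect_pair = identical(config$reconnect, "pair"))
    final_wealth <- out$wealth
    alive <- out$alive
    death_round <- out$death_round
    death_wealth <- out$death_wealth
    alive_series <- out$alive_series
    wealth_series <- out$wealth_series
    ledger <- data.frame(round = seq_len(config$rounds),
                         interactions = out$interactions,
                         gross = out$gross,
                         cost = 2 * config$turn_cost * out$interactions,
                         deaths = out$deaths_per_round)
  } else {
    rounds <- config$rounds
    alive_series <- matrix(0, nrow = rounds + 1L, ncol = 12L)
    wealth_series <- matrix(0, nrow = rounds + 1L, ncol = 12L)
    cat_of <- (match(pop$class, c("poor", "rich")) - 1L) * 6L +
      match(pop$strategy, FG_STRATEGIES)
    tally <- function(p, r) {
      for (k in seq_len(12L)) {
        sel <- p$net$alive & cat_of == k
        alive_series[r, k] <<- sum(sel)
        wealth_series[r, k] <<- sum(p$wealth[sel])
      }
    }
    tally(pop, 1L)
    ledgers <- vector("list", rounds)
    for (r in seq_len(rounds)) {
      step <- run_round(pop)
      pop <- step$population
      ledgers[[r]] <- step$ledger
      tally(pop, r + 1L)
    }
    ledger <- do.call(rbind, ledgers)
    final_wealth <- pop$wealth
    alive <- pop$net$alive
    death_round <- pop$death_round
    death_wealth <- pop$death_wealth
  }

  cat_idx <- (match(pop$class, c("poor", "rich")) - 1L) * 6L +
    match(pop$strategy, FG_STRATEGIES)
  grid <- category_grid(config)
  grid_idx <- (match(grid$class, c("poor", "rich")) - 1L) * 6L +
    match(grid$strategy, FG_STRATEGIES)
  summary_df <- grid
  summary_df$initial_count <- vapply(grid_idx, function(k)
    sum(cat_idx == k), integer(1))
  summary_df$final_count <- vapply(grid_idx, function(k)
    sum(alive & cat_idx == k), integer(1))
  summary_df$initial_wealth <- vapply(grid_idx, function(k)
    sum(pop$initial_wealth[cat_idx == k]), numeric(1))
  summary_df$final_wealth <- vapply(grid_idx, function(k)
    sum(final_wealth[alive & cat_idx == k]), numeric(1))
  summary_df$survival <- ifelse(summary_df$initial_count > 0,
                                summary_df$final_count / summary_df$initial_count,
                                NA_real_)

  net0 <- build_lattice(config$rows, config$cols, config$borderless)
  agents <- data.frame(id = seq_len(net0$n),
                       row = net0$coords[, "row"],
                       col = net0$coords[, "col"],
                       class = pop$class,
                       strategy = pop$strategy,
                       initial_wealth = pop$initial_wealth,
                       wealth = final_wealth,
                       alive = alive,
                       death_round = death_round)

  # column k of the series matrices is category (class-1)*6 + strategy
  all_grid <- data.frame(class = rep(c("poor", "rich"), each = 6L),
                         strategy = rep(FG_STRATEGIES, times = 2L))
  keep <- paste(all_grid$class, all_grid$strategy) %in%
    paste(grid$class, grid$strategy)
  series <- data.frame(
    round = rep(0:config$rounds, each = sum(keep)),
    class = rep(all_grid$class[keep], times = config$rounds + 1L),
    strategy = rep(all_grid$strategy[keep], times = config$rounds + 1L),
    alive = as.vector(t(alive_series[, keep, drop = FALSE])),
    wealth = as.vector(t(wealth_series[, keep, drop = FALSE])))

  died <- which(!is.na(death_round))
  deaths <- data.frame(round = death_round[died], id = died,
                       class = pop$class[died], strategy = pop$strategy[died],
                       wealth = death_wealth[died])
  deaths <- deaths[order(deaths$round, deaths$id), , drop = FALSE]
  rownames(deaths) <- NULL

  structure(list(summary = summary_df, agents = agents, series = series,
                 deaths = deaths, ledger = ledger, config = config,
                 engine = engine),
            class = "farmers_result")
}

#' @export
print.farmers_result <- function(x, ...) {
  cat(sprintf("Farmer's Game run: %dx%d, %d rounds, %d/%d alive (engine: %s)\n",
              x$config$rows, x$config$cols, x$config$rounds,
              sum(x$agents$alive), nrow(x$agents), x$engine))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
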