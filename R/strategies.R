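#' Strategy kinds
#'
#' Six decision rules are available, all layered on a memory-one
#' tit-for-tat base:
#'
#' * `titfortat` — classic tit-for-tat with forgiveness.  Cooperate on a
#'   first encounter or when the opponent last cooperated; when the
#'   opponent last defected, retaliate, except that with probability
#'   `forgiveness` the retaliation is replaced by cooperation.
#' * `subsist` — defect whenever own wealth is at or below
#'   `subsist_threshold` (survival of the next round of four turns in
#'   doubt), else play the base rule.
#' * `exploit` — defect when at least `wealth_ratio_trigger` times as
#'   wealthy as the opponent, else base.
#' * `thief` — defect when the opponent is at least `wealth_ratio_trigger`
#'   times as wealthy, else base.
#' * `middle` — defect whenever own wealth is at or below
#'   `middle_threshold` (survival of two rounds in doubt), else base.
#' * `always_defect` — unconditional defection; the non-cooperating
#'   comparator society.
#'
#' Memory is one move per neighbour: each agent stores only the last move
#' it observed from each opponent.  Strategies are fixed for life — there
#' is no imitation, evolution or replacement.
#'
#' @return Character vector of the six strategy names.
#' @examples
#' strategy_kinds()
#' @export
strategy_kinds <- function() FG_STRATEGIES

#' Construct an agent state
#'
#' A light container used by the reference (pure R) engine and by unit
#' tests; the compiled engine keeps the same state in flat vectors.
#'
#' @param id Node id.
#' @param strategy One of [strategy_kinds()].
#' @param class `"poor"` or `"rich"` (initial class; never reassigned).
#' @param wealth Current tokens (real-valued; no rounding anywhere).
#' @param memory Named list mapping neighbour id (as character) to the last
#'   observed move `"C"`/`"D"`; a missing entry means no encounter yet.
#' @return A list of class `farmers_agent`.
#' @export
agent_state <- function(id, strategy, class = c("poor", "rich"),
                        wealth = 4, memory = list()) {
  strategy <- match.arg(strategy, FG_STRATEGIES)
  class <- match.arg(class)
  structure(list(id = as.integer(id), strategy = strategy, class = class,
                 wealth = as.numeric(wealth), alive = TRUE, memory = memory),
            class = "farmers_agent")
}

#' Decide an agent's move against one opponent
#'
#' Applies the agent's strategy rule (see [strategy_kinds()]) given its own
#' wealth, the opponent's current wealth (wealth is mutually visible), and
#' its memory of the opponent's last move.  Threshold triggers use "at or
#' below" for wealth thresholds and "at least" for the wealth-ratio
#' triggers.  The only randomness is the forgiveness draw, consumed from
#' the R random stream exactly when the base rule would retaliate.
#'
#' @param agent A [agent_state()] (fields `strategy`, `wealth`, `memory`).
#' @param opponent An [agent_state()] (fields `id`, `wealth`).
#' @param config A [game_config()].
#' @return `"C"` or `"D"`.
#' @examples
#' cfg <- game_config()
#' a <- agent_state(1, "subsist", "poor", wealth = 4)
#' b <- agent_state(2, "titfortat", "rich", wealth = 10)
#' decide_move(a, b, cfg)  # "D": survival in doubt
#' @export
decide_move <- function(agent, opponent, config) {
  if (!isTRUE(agent$alive) || !isTRUE(opponent$alive)) {
    stop("dead participant in decide_move")
  }
  trigger <- switch(agent$strategy,
    always_defect = TRUE,
    subsist = agent$wealth <= config$subsist_threshold,
    middle  = agent$wealth <= config$middle_threshold,
    exploit = agent$wealth >= config$wealth_ratio_trigger * opponent$wealth,
    thief   = opponent$wealth >= config$wealth_ratio_trigger * agent$wealth,
    titfortat = FALSE)
  if (trigger) return("D")
  last <- agent$memory[[as.character(opponent$id)]]
  if (is.null(last) || identical(last, "C")) return("C")
  # retaliation, unless forgiven
  if (stats::runif(1) < config$forgiveness) "C" else "D"
}

#' Record an observed opponent move
#'
#' Memory-one bookkeeping: the stored move for that neighbour is replaced
#' by the observed one; nothing else changes.  An agent's own move never
#' alters its own memory.
#'
#' @param agent A [agent_state()].
#' @param opponent_id Node id of the neighbour.
#' @param observed `"C"` or `"D"`.
#' @return The updated agent.
#' @export
record_outcome <- function(agent, opponent_id, observed) {
  observed <- match.arg(observed, c("C", "D"))
  agent$memory[[as.character(opponent_id)]] <- observed
  agent
}
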