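#' Construct a Farmer's Game payoff matrix
#'
#' The Farmer's Game is a Prisoner's Dilemma in which two neighbouring
#' players may jointly farm the land between them.  Mutual cooperation
#' yields `reward_cc` tokens to each player; a defector facing a cooperator
#' takes `temptation_dc` while the victim receives `sucker_cd`; mutual
#' defection yields `punish_dd` to each.  The default matrix
#' (1.1, 2.2, 0, 1.0) encodes a 10% cooperation surplus with the defector
#' taking the whole harvest.
#'
#' @param reward_cc Tokens per player under mutual cooperation.
#' @param temptation_dc Tokens to a defector whose opponent cooperates.
#' @param sucker_cd Tokens to a cooperator whose opponent defects.
#' @param punish_dd Tokens per player under mutual defection.
#'
#' @return An object of class `farmers_payoffs`, a named list of the four
#'   gross payoffs.
#'
#' @details The Prisoner's Dilemma ordering
#'   `temptation_dc >= reward_cc >= punish_dd >= sucker_cd` is enforced.
#'   A matrix is *conservative* when `temptation_dc + sucker_cd ==
#'   2 * reward_cc`, i.e. unilateral defection redistributes the harvest
#'   without destroying any of it; see [is_conservative()].  The flag is
#'   always derived, never stored, so non-conservative variants such as
#'   (1.1, 2.0, 0, 1.0) are handled uniformly.
#'
#' @examples
#' payoff_matrix()                       # baseline 1.1 / 2.2|0 / 1.0
#' payoff_matrix(reward_cc = 1.5, temptation_dc = 3.0)
#' @seealso [pair_payoff()], [is_conservative()], [game_config()]
#' @export
payoff_matrix <- function(reward_cc = 1.1, temptation_dc = 2.2,
                          sucker_cd = 0, punish_dd = 1.0) {
  pm <- list(reward_cc = as.numeric(reward_cc),
             temptation_dc = as.numeric(temptation_dc),
             sucker_cd = as.numeric(sucker_cd),
             punish_dd = as.numeric(punish_dd))
  bad <- vapply(pm, function(x) length(x) != 1L || !is.finite(x), logical(1))
  if (any(bad)) {
    stop("payoff entries must be single finite numbers: ",
         paste(names(pm)[bad], collapse = ", "))
  }
  if (!(pm$temptation_dc >= pm$reward_cc &&
        pm$reward_cc >= pm$punish_dd &&
        pm$punish_dd >= pm$sucker_cd)) {
    stop("PD ordering violated: need temptation_dc >= reward_cc >= ",
         "punish_dd >= sucker_cd")
  }
  structure(pm, class = "farmers_payoffs")
}

#' Is a payoff matrix conservative?
#'
#' A payoff pair involving at least one cooperator is conserved when the
#' defector and victim payoffs sum to twice the mutual-cooperation payoff:
#' defection then redistributes the harvest rather than destroying it.
#'
#' @param payoffs A [payoff_matrix()].
#' @param tol Numeric tolerance for the equality test.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_conservative(payoff_matrix())                      # TRUE
#' is_conservative(payoff_matrix(temptation_dc = 2.0))   # FALSE
#' @export
is_conservative <- function(payoffs, tol = 1e-9) {
  stopifnot(inherits(payoffs, "farmers_payoffs"))
  abs(payoffs$temptation_dc + payoffs$sucker_cd - 2 * payoffs$reward_cc) <= tol
}

#' @export
print.farmers_payoffs <- function(x, ...) {
  cat("Farmer's Game payoffs (gross tokens)\n")
  cat(sprintf("  C|C %.4g   D|C %.4g   C|D %.4g   D|D %.4g   [%s]\n",
              x$reward_cc, x$temptation_dc, x$sucker_cd, x$punish_dd,
              if (is_conservative(x)) "conservative" else "non-conservative"))
  invisible(x)
}

#' Settle one pairwise interaction
#'
#' Looks up the gross payoff of each player from the move pair and subtracts
#' the per-interaction consumption cost ("the players must eat") to give net
#' wealth changes.
#'
#' @param move_a,move_b Moves, `"C"` (cooperate) or `"D"` (defect).
#' @param payoffs A [payoff_matrix()].
#' @param turn_cost Tokens consumed by each player for this interaction
#'   (a positive consumption amount; it is subtracted).
#'
#' @return A named list with `gross_a`, `gross_b`, `net_a`, `net_b`.
#'
#' @examples
#' pair_payoff("C", "C", payoff_matrix(), 1.07)  # net 0.03 each
#' pair_payoff("D", "C", payoff_matrix(), 1.07)  # defector grosses 2.2
#' @export
pair_payoff <- function(move_a, move_b, payoffs = payoff_matrix(),
                        turn_cost = 1.07) {
  stopifnot(inherits(payoffs, "farmers_payoffs"))
  move_a <- match.arg(move_a, c("C", "D"))
  move_b <- match.arg(move_b, c("C", "D"))
  gross <- function(mine, theirs) {
    if (mine == "C") {
      if (theirs == "C") payoffs$reward_cc else payoffs$sucker_cd
    } else {
      if (theirs == "C") payoffs$temptation_dc else payoffs$punish_dd
    }
  }
  ga <- gross(move_a, move_b)
  gb <- gross(move_b, move_a)
  list(gross_a = ga, gross_b = gb,
       net_a = ga - turn_cost, net_b = gb - turn_cost)
}
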