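# Straight-line enactment of the game rules for tiny lattices, written
# directly from the rule statements and independent of the package's
# engine code paths.  Deterministic (forgiveness = 0 only).
#
# strategies/classes/wealth0 are vectors over row-major node ids.
oracle_sim <- function(rows, cols, strategies, classes, wealth0,
                       reward = 1.1, temptation = 2.2, sucker = 0,
                       punish = 1.0, cost = 1.07, rounds = 3,
                       subsist_thr = 4, middle_thr = 8, ratio = 2,
                       policy = "clique") {
  n <- rows * cols
  # adjacency matrix of the bordered 4-neighbour grid
  A <- matrix(FALSE, n, n)
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    i <- r * cols + c + 1
    if (r > 0)        A[i, (r - 1) * cols + c + 1] <- TRUE
    if (r < rows - 1) A[i, (r + 1) * cols + c + 1] <- TRUE
    if (c > 0)        A[i, r * cols + c] <- TRUE
    if (c < cols - 1) A[i, r * cols + c + 2] <- TRUE
  }
  wealth <- wealth0
  alive <- rep(TRUE, n)
  mem <- matrix(NA_character_, n, n)  # mem[i, j]: last move i saw from j
  death_round <- rep(NA_integer_, n)

  choose_move <- function(i, j) {
    s <- strategies[i]
    if (s == "always_defect") return("D")
    if (s == "subsist" && wealth[i] <= subsist_thr) return("D")
    if (s == "middle" && wealth[i] <= middle_thr) return("D")
    if (s == "exploit" && wealth[i] >= ratio * wealth[j]) return("D")
    if (s == "thief" && wealth[j] >= ratio * wealth[i]) return("D")
    last <- mem[i, j]
    if (is.na(last) || last == "C") "C" else "D"   # no forgiveness
  }
  gross <- function(mine, theirs) {
    if (mine == "C" && theirs == "C") reward
    else if (mine == "C") sucker
    else if (theirs == "C") temptation
    else punish
  }

  for (rd in seq_len(rounds)) {
    # live edges at round start, lexicographic
    edges <- which(A & upper.tri(A), arr.ind = TRUE)
    edges <- edges[alive[edges[, 1]] & alive[edges[, 2]], , drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      if (!alive[i] || !alive[j]) next
      mi <- choose_move(i, j); mj <- choose_move(j, i)
      mem[i, j] <- mj; mem[j, i] <- mi
      wealth[i] <- wealth[i] + gross(mi, mj) - cost
      wealth[j] <- wealth[j] + gross(mj, mi) - cost
      dead_now <- c(i, j)[c(wealth[i] <= 0, wealth[j] <= 0)]
      if (length(dead_now)) {
        nb <- lapply(dead_now, function(d) which(A[d, ]))
        alive[dead_now] <- FALSE
        death_round[dead_now] <- rd
        for (d in dead_now) { A[d, ] <- FALSE; A[, d] <- FALSE }
        for (m in seq_along(dead_now)) {
          live_nb <- sort(nb[[m]][alive[nb[[m]]]])
          q <- length(live_nb)
          if (q < 2) next
          if (policy == "clique") {
            for (a in live_nb) for (b in live_nb) if (a < b) {
              A[a, b] <- TRUE; A[b, a] <- TRUE
            }
          } else {  # nested pairing: first with last, second with second-last
            for (p in seq_len(q %/% 2)) {
              a <- live_nb[p]; b <- live_nb[q + 1 - p]
              A[a, b] <- TRUE; A[b, a] <- TRUE
            }
          }
        }
      }
    }
  }
  list(wealth = wealth, alive = alive, death_round = death_round)
}

# Shorthand configs used across tests.
small_config <- function(...) {
  game_config(rows = 6, cols = 6, rounds = 10, seed = 1, ...)
}
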