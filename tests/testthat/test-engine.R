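test_that("population initialisation follows the configured distribution", {
  cfg <- game_config(density_poor = 1, rows = 5, cols = 5, seed = 2)
  pop <- init_population(cfg)
  expect_true(all(pop$wealth == 4))

  cfg2 <- game_config(seed = 11)
  pop2 <- init_population(cfg2)
  n_poor <- sum(pop2$class == "poor")
  # Binomial(400, 0.5): stay within 4 standard deviations of 200
  expect_true(abs(n_poor - 200) < 4 * sqrt(400 * 0.25))

  pop3 <- init_population(cfg2)
  expect_identical(pop2$class, pop3$class)
  expect_identical(pop2$strategy, pop3$strategy)
})

test_that("all-defect society at turn cost 1.0 is in exact stasis", {
  cfg <- game_config(turn_cost = 1.0, rounds = 25,
                     strategy_mix = strategy_mix("defect"), seed = 4)
  res <- run_simulation(cfg)
  expect_identical(res$agents$wealth, res$agents$initial_wealth)
  expect_equal(nrow(res$deaths), 0)
  h <- wealth_histogram(res)
  expect_equal(sum(colSums(h$counts) > 0), 2)  # only the 4 and 10 bins
  occupied <- which(colSums(h$counts) > 0)
  expect_equal(h$breaks[occupied], c(4, 10))
})

test_that("all-defect society above the mutual-defection payoff dies on schedule", {
  # poor interior agent: 4 interactions/round at net -0.2 -> dead in round 5
  cfg <- game_config(turn_cost = 1.2, rounds = 10, density_poor = 1,
                     strategy_mix = strategy_mix("defect"), seed = 4)
  res <- run_simulation(cfg)
  interior <- res$agents$row > 0 & res$agents$row < 19 &
    res$agents$col > 0 & res$agents$col < 19
  expect_true(all(res$agents$death_round[interior] == 5))
})

test_that("the per-round wealth ledger identity is exact", {
  cfg <- game_config(rows = 6, cols = 6, rounds = 8, turn_cost = 1.12,
                     seed = 8)
  pop <- init_population(cfg)
  for (r in 1:8) {
    total_before <- sum(pop$wealth)
    step <- run_round(pop)
    pop <- step$population
    led <- step$ledger
    expect_equal(sum(pop$wealth) - total_before,
                 led$gross - 2 * cfg$turn_cost * led$interactions,
                 tolerance = 1e-9)
    expect_identical(led$cost, 2 * cfg$turn_cost * led$interactions)
  }
  # same identity from the compiled engine's ledger and series
  res <- run_simulation(cfg)
  expect_equal(res$ledger$cost, 2 * cfg$turn_cost * res$ledger$interactions)
})

test_that("seeded runs are bitwise reproducible", {
  cfg <- game_config(rows = 8, cols = 8, rounds = 15, seed = 21)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$agents, b$agents)
  expect_identical(a$summary, b$summary)
  expect_identical(a$series, b$series)
})

test_that("compiled and reference engines agree bit-for-bit", {
  for (seed in c(1, 2, 3)) {
    cfg <- game_config(rows = 5, cols = 5, rounds = 10, turn_cost = 1.1,
                       forgiveness = 0.3, seed = seed,
                       reconnect = if (seed == 2) "clique" else "pair")
    a <- run_simulation(cfg, engine = "compiled")
    b <- run_simulation(cfg, engine = "reference")
    expect_identical(a$agents$wealth, b$agents$wealth)
    expect_identical(a$agents$alive, b$agents$alive)
    expect_equal(a$deaths, b$deaths)
    expect_equal(a$series, b$series)
  }
})

test_that("engine matches a straight-line enactment of the rules", {
  # 2x2 lattice, forgiveness 0, 3 rounds: fully deterministic
  strategies <- c("titfortat", "subsist", "exploit", "thief")
  classes <- c("rich", "poor", "rich", "poor")
  wealth0 <- c(10, 4, 10, 4)
  expected <- oracle_sim(2, 2, strategies, classes, wealth0, rounds = 3)

  cfg <- game_config(rows = 2, cols = 2, rounds = 3, forgiveness = 0, seed = 1)
  pop <- init_population(cfg)
  pop$strategy <- strategies
  pop$class <- classes
  pop$wealth <- wealth0
  pop$initial_wealth <- wealth0
  for (r in 1:3) pop <- run_round(pop)$population
  expect_equal(pop$wealth, expected$wealth)
  expect_equal(pop$net$alive, expected$alive)

  # a lethal configuration on 3x3, still deterministic
  strategies9 <- c("titfortat", "always_defect", "titfortat",
                   "subsist", "titfortat", "middle",
                   "exploit", "thief", "titfortat")
  classes9 <- rep(c("poor", "rich", "poor"), 3)
  wealth09 <- ifelse(classes9 == "poor", 4, 10)
  expected9 <- oracle_sim(3, 3, strategies9, classes9, wealth09,
                          cost = 1.15, rounds = 12)
  cfg9 <- game_config(rows = 3, cols = 3, rounds = 12, forgiveness = 0,
                      turn_cost = 1.15, seed = 1)
  pop9 <- init_population(cfg9)
  pop9$strategy <- strategies9
  pop9$class <- classes9
  pop9$wealth <- wealth09
  pop9$initial_wealth <- wealth09
  for (r in 1:12) pop9 <- run_round(pop9)$population
  expect_true(any(!expected9$alive))  # the scenario does kill someone
  expect_equal(pop9$wealth, expected9$wealth)
  expect_equal(pop9$net$alive, expected9$alive)
  expect_equal(pop9$death_round, expected9$death_round)
})

test_that("dead players never interact again and die at nonpositive wealth", {
  cfg <- game_config(rows = 8, cols = 8, rounds = 30, turn_cost = 1.12,
                     seed = 5)
  res <- run_simulation(cfg)
  expect_gt(nrow(res$deaths), 0)
  expect_true(all(res$deaths$wealth <= 0))
  # alive counts never increase
  totals <- tapply(res$series$alive, res$series$round, sum)
  expect_true(all(diff(totals[order(as.integer(names(totals)))]) <= 0))
  # a dead agent's wealth is frozen at its death value
  dead <- res$agents[!res$agents$alive, ]
  expect_true(all(dead$wealth <= 0))
})

test_that("all tit-for-tat at turn cost 1.1 holds total wealth constant", {
  cfg <- game_config(turn_cost = 1.1, strategy_mix = strategy_mix("titfortat"),
                     seed = 6)
  res <- run_simulation(cfg)
  expect_equal(nrow(res$deaths), 0)
  totals <- tapply(res$series$wealth, res$series$round, sum)
  expect_true(all(abs(totals - totals[[1]]) < 1e-9))
})
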