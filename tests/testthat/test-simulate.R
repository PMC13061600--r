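spec3 <- game_spec(3)

test_that("fixed-level opponents reduce to their defining behaviours", {
  # fresh block: attractions uniform, level-0 policy is uniform
  op <- make_agent("fixed_level", opponent_spec(0, lapse = 0), spec3)
  expect_equal(agent_policy(op), rep(1 / 3, 3))
  # a level-0 opponent repeats its own frequent action
  op <- make_agent("fixed_level",
                   opponent_spec(0, beta = 50, lapse = 0), spec3)
  for (t in 1:10) op <- agent_learn(op, 0, sample(0:2, 1))
  expect_equal(which.max(agent_policy(op)), 1L)
  expect_gt(max(agent_policy(op)), 0.99)
  # full lapse: uniform regardless of level and history
  op <- make_agent("fixed_level", opponent_spec(2, lapse = 1), spec3)
  for (t in 1:10) op <- agent_learn(op, sample(0:2, 1), sample(0:2, 1))
  expect_equal(agent_policy(op), rep(1 / 3, 3))
})

test_that("identical seeds reproduce identical experiments", {
  s1 <- simulate_experiment(2, "chase", seed = 42)
  s2 <- simulate_experiment(2, "chase", seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(2, "chase", seed = 43)
  expect_false(identical(s1$action_self, s3$action_self))
})

test_that("default design matches the scanner experiment layout", {
  sims <- simulate_experiment(3, "chase", seed = 9)
  expect_equal(nrow(sims), 3 * 6 * 40)  # six 40-trial blocks each
  for (p in 1:3) {
    d <- sims[sims$participant == p, ]
    sched <- d$opponent_level[!duplicated(d$block)]
    expect_equal(sort(sched), c(0, 0, 1, 1, 2, 2))
    expect_true(all(diff(sched) != 0))  # no immediate repetitions
  }
  # payoffs consistent with the payoff matrix
  pm <- payoff_matrix(spec3)
  expect_equal(sims$payoff_self,
               pm[cbind(sims$action_self + 1, sims$action_opp + 1)])
  expect_equal(sims$payoff_opp,
               pm[cbind(sims$action_opp + 1, sims$action_self + 1)])
})

test_that("empty cohort yields an empty collection", {
  sims <- simulate_experiment(0, "chase", seed = 1)
  expect_equal(nrow(sims), 0L)
})

test_that("degenerate parameter sampler gives every agent the same parameters", {
  pars <- list(alpha = 0.3, beta = 5, gamma = 10, lambda = 1, kappa = 3)
  sims <- simulate_experiment(3, "chase", params = pars, seed = 2)
  gen <- attr(sims, "params")
  expect_equal(nrow(gen), 3L)
  expect_true(all(gen$alpha == 0.3) && all(gen$kappa == 3))
})

test_that("uniform play earns nothing on average in the zero-sum game", {
  set.seed(77)
  pays <- replicate(30, {
    a <- make_agent("uniform", list(), spec3)
    o <- make_agent("fixed_level", opponent_spec(1), spec3)
    mean(play_block(a, o, 40, spec3)$payoff_self)
  })
  expect_lt(abs(mean(pays)), 0.05)
})

test_that("an adaptive depth-3 agent beats every fixed-level opponent", {
  set.seed(88)
  for (lev in 0:2) {
    pays <- replicate(6, {
      a <- make_agent("chase", list(alpha = 0.3, beta = 8, gamma = 20,
                                    lambda = 1, kappa = 3), spec3)
      o <- make_agent("fixed_level", opponent_spec(lev), spec3)
      mean(play_block(a, o, 40, spec3)$payoff_self)
    })
    expect_gt(mean(pays), 0)
  }
})

test_that("block starts are statistically fresh", {
  # trial 1 of every block is sampled from uniform policies on both
  # sides: the empirical first-trial action distribution is uniform
  sims <- simulate_experiment(30, "chase", seed = 123)
  first <- sims$action_self[sims$trial == 1]
  tab <- tabulate(first + 1L, 3) / length(first)
  expect_true(all(abs(tab - 1 / 3) < 0.08))
})

test_that("session round trip through CSV and sidecar is lossless", {
  sims <- simulate_experiment(2, "chase", seed = 31)
  path <- tempfile(fileext = ".csv")
  write_sessions(sims, path)
  back <- read_sessions(path)
  expect_equal(as.data.frame(sims), as.data.frame(back),
               ignore_attr = TRUE)
  expect_equal(attr(back, "model"), "chase")
  # schema violations are caught and name the offender
  bad <- as.data.frame(sims)
  bad$action_self[5] <- 3L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_sessions(path), "out of range")
  bad <- as.data.frame(sims)
  bad$payoff_self[7] <- 99
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_sessions(path), "row 7")
})
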