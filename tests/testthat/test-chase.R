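pm3 <- payoff_matrix(game_spec(3))

test_that("softmax choice rule matches hand calculation and limits", {
  expect_equal(softmax_policy(c(1, 0, 0), 1),
               c(0.57611688, 0.21194156, 0.21194156), tolerance = 1e-7)
  expect_equal(softmax_policy(c(3, -2, 7), 0), rep(1 / 3, 3))
  expect_equal(softmax_policy(c(1, 0, 0), 500), c(1, 0, 0),
               tolerance = 1e-12)
  expect_error(softmax_policy(c(1, 0), -1), "non-negative")
})

test_that("attraction delta rule matches hand calculation and boundaries", {
  a <- rep(1 / 3, 3)
  expect_equal(update_attractions(a, 1, 0.5), c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(update_attractions(a, 2, 0), a)
  expect_equal(update_attractions(a, 0, 1), c(1, 0, 0))
  expect_equal(sum(update_attractions(a, 1, 0.37)), 1)
  expect_error(update_attractions(a, 0, 1.2), "alpha")
})

test_that("recursive level policies reproduce the worked reasoning example", {
  # opponent history concentrated on paper (action 1)
  attr <- list(a_self = c(0, 1, 0), a_opp = c(0, 1, 0))
  b <- 400
  # anticipating the opponent repeats paper, a level-1 player answers
  # scissors; a level-2 player expects that answer and plays rock
  expect_equal(which.max(level_policy(1, attr, "self_play", pm3, b)), 3L)
  expect_equal(which.max(level_policy(2, attr, "self_play", pm3, b)), 1L)
  # level 0 is the plain softmax of the reference history
  expect_equal(level_policy(0, attr, "self_play", pm3, 2),
               softmax_policy(attr$a_self, 2))
  expect_equal(level_policy(0, attr, "opponent_prediction", pm3, 2),
               softmax_policy(attr$a_opp, 2))
  # beta = 0 flattens any level
  for (k in 0:3)
    expect_equal(level_policy(k, attr, "self_play", pm3, 0), rep(1 / 3, 3))
})

test_that("best-response cycle has period n_actions", {
  attr <- list(a_self = c(1, 0, 0), a_opp = c(1, 0, 0))
  b <- 400
  seen <- sapply(0:5, function(k)
    which.max(level_policy(k, attr, "self_play", pm3, b)))
  expect_equal(sort(unique(seen[1:3])), 1:3)    # visits all actions
  expect_equal(seen[4:6], seen[1:3])            # period 3
  pm4 <- payoff_matrix(game_spec(4))
  attr4 <- list(a_self = c(1, 0, 0, 0), a_opp = c(1, 0, 0, 0))
  seen4 <- sapply(0:7, function(k)
    which.max(level_policy(k, attr4, "self_play", pm4, b)))
  expect_equal(seen4[5:8], seen4[1:4])          # period 4
})

test_that("level likelihood scores the observed action under each level", {
  attr <- list(a_self = rep(1 / 3, 3), a_opp = c(1, 0, 0))
  b <- 100
  # a level-0 opponent repeats their frequent action (rock)
  L <- level_likelihood(0, attr, 2, pm3, b)
  expect_equal(length(L), 2L)
  expect_gt(L[1], 0.99)
  expect_lt(L[2], 0.4)
  # single-level case and uninformative limit
  expect_length(level_likelihood(1, attr, 1, pm3, 5), 1L)
  expect_equal(level_likelihood(2, attr, 3, pm3, 0), rep(1 / 3, 3))
})

test_that("likelihood distortion matches hand softmax and limits", {
  expect_equal(distort_likelihood(c(0.8, 0.2), 0), c(0.5, 0.5))
  expect_equal(distort_likelihood(c(0.8, 0.2), 1),
               c(0.64565631, 0.35434369), tolerance = 1e-7)
  expect_equal(distort_likelihood(rep(0.25, 4), 17), rep(0.25, 4))
  expect_error(distort_likelihood(c(0.5, 0.5), -2), "non-negative")
})

test_that("Bayes update renormalizes and handles degenerate cases", {
  expect_equal(bayes_update(c(0.5, 0.5), c(0.8, 0.2)), c(0.8, 0.2))
  b <- c(0.3, 0.7)
  expect_equal(bayes_update(b, c(0.5, 0.5)), b)
  expect_equal(bayes_update(c(1, 0), c(0.2, 0.8)), c(1, 0))
  expect_error(bayes_update(c(1, 0), c(0, 1)), "degenerate")
})

test_that("belief-update KL matches hand value and is non-negative", {
  expect_equal(belief_update_kl(c(0.8, 0.2), c(0.5, 0.5)),
               0.19274475, tolerance = 1e-7)
  expect_equal(belief_update_kl(c(0.3, 0.7), c(0.3, 0.7)), 0)
  set.seed(42)
  for (i in 1:20) {
    p <- as.vector(stats::rgamma(3, 1)); p <- p / sum(p)
    q <- as.vector(stats::rgamma(3, 1)); q <- q / sum(q)
    expect_gte(belief_update_kl(p, q), 0)
  }
  expect_error(belief_update_kl(c(0.5, 0.5), c(1, 0)), "divergence")
})

test_that("integrated policy marginalizes predictions and best responds", {
  preds <- rbind(c(1, 0, 0), c(0, 1, 0))  # level 0 rock, level 1 paper
  ip <- integrated_policy(c(0.5, 0.5), preds, pm3, 300)
  expect_equal(ip$predicted_opp, c(0.5, 0.5, 0))
  # against 50/50 rock/paper, paper wins or ties: clear best response
  expect_equal(which.max(ip$own_policy), 2L)
  ip0 <- integrated_policy(c(0.2, 0.8), preds, pm3, 0)
  expect_equal(ip0$own_policy, rep(1 / 3, 3))
  # one-hot beliefs: straight best response
  ip1 <- integrated_policy(c(1, 0), preds, pm3, 300)
  expect_equal(which.max(ip1$own_policy), 2L)  # paper beats rock
})

test_that("choice value and prediction error match hand expectations", {
  expect_equal(choice_value(1, c(1, 0, 0), pm3), 1)
  for (a in 0:2) expect_equal(choice_value(a, rep(1 / 3, 3), pm3), 0)
  pm_l2 <- scale_losses(pm3, 2)
  # scissors against 50/50 rock/paper: 0.5 * (-2) + 0.5 * (+1)
  expect_equal(choice_value(2, c(0.5, 0.5, 0), pm_l2), -0.5)
  expect_equal(action_prediction_error(0, c(1, 0, 0)), 0)
  expect_equal(action_prediction_error(2, rep(1 / 3, 3)), 2 / 3)
  expect_equal(action_prediction_error(0, c(0.8, 0.1, 0.1)), 0.2,
               tolerance = 1e-12)
})

test_that("first trial of a block reflects fully uniform state", {
  p <- chase_params(alpha = 0.3, beta = 4, gamma = 8, lambda = 1.5,
                    kappa = 3L)
  st <- chase_init(p, 3)
  expect_equal(st$belief, rep(1 / 3, 3))
  res <- chase_step(st, 0, 2, p, pm3)
  expect_equal(res$deriv$predicted_opp, rep(1 / 3, 3))
  expect_equal(res$deriv$ape, 2 / 3)
  expect_equal(res$deriv$own_policy, rep(1 / 3, 3))
  expect_equal(res$deriv$modal_level_response, 1L)
})

test_that("beta = 0 collapses the session likelihood to the chance level", {
  set.seed(7)
  d <- random_session(40)
  p <- list(alpha = 0.3, beta = 0, gamma = 5, lambda = 1, kappa = 3)
  expect_equal(chase_loglik(d, p, game_spec()), -40 * log(3),
               tolerance = 1e-10)
})

test_that("session likelihood is invariant to consistent action relabeling", {
  set.seed(11)
  d <- random_session(30, n_blocks = 2L)
  p <- random_chase_params()
  ll <- chase_loglik(d, p, game_spec())
  # rotate all labels by one step: the circular game maps onto itself
  d2 <- d
  d2$action_self <- (d$action_self + 1L) %% 3L
  d2$action_opp <- (d$action_opp + 1L) %% 3L
  expect_equal(chase_loglik(d2, p, game_spec()), ll, tolerance = 1e-10)
})

test_that("production filter matches the literal-equation oracle", {
  set.seed(101)
  spec <- game_spec()
  for (i in 1:5) {
    d <- random_session(10)
    p <- random_chase_params()
    orc <- oracle_chase_block(d$action_self, d$action_opp, p$alpha,
                              p$beta, p$gamma, p$lambda, p$kappa, pm3)
    expect_equal(chase_loglik(d, p, spec), orc$loglik, tolerance = 1e-10)
    regs <- chase_regressors(d, p, spec)
    expect_equal(regs$cv, orc$cv, tolerance = 1e-10)
    expect_equal(regs$ape, orc$ape, tolerance = 1e-10)
    expect_equal(regs$bu, orc$bu, tolerance = 1e-10)
  }
})

test_that("beliefs and policies stay normalized on fuzzed trajectories", {
  set.seed(5)
  spec <- game_spec()
  for (i in 1:10) {
    p <- do.call(chase_params, random_chase_params())
    st <- chase_init(p, 3)
    for (t in 1:15) {
      res <- chase_step(st, sample(0:2, 1), sample(0:2, 1), p, pm3)
      expect_equal(sum(res$state$belief), 1, tolerance = 1e-12)
      expect_equal(sum(res$deriv$own_policy), 1, tolerance = 1e-12)
      expect_equal(sum(res$deriv$predicted_opp), 1, tolerance = 1e-12)
      expect_gte(res$deriv$bu, 0)
      st <- res$state
    }
  }
})

test_that("zero level-sensitivity freezes beliefs and nulls every update", {
  set.seed(9)
  p <- chase_params(alpha = 0.4, beta = 6, gamma = 0, lambda = 1,
                    kappa = 3L)
  st <- chase_init(p, 3)
  for (t in 1:20) {
    res <- chase_step(st, sample(0:2, 1), sample(0:2, 1), p, pm3)
    expect_equal(res$deriv$bu, 0, tolerance = 1e-15)
    expect_equal(res$state$belief, rep(1 / 3, 3))
    st <- res$state
  }
})

test_that("belief updates grow with level-evidence sensitivity", {
  # fixed informative likelihood, increasing gamma
  L <- c(0.7, 0.2, 0.1)
  prior <- rep(1 / 3, 3)
  bus <- sapply(c(0, 1, 3, 8, 20), function(g)
    belief_update_kl(bayes_update(prior, distort_likelihood(L, g)), prior))
  expect_true(all(diff(bus) >= -1e-14))
  expect_equal(bus[1], 0)
})
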