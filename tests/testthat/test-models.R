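pm3 <- payoff_matrix(game_spec(3))
spec3 <- game_spec(3)

test_that("RL value update matches hand calculation and boundaries", {
  q <- c(0, 0, 0)
  expect_equal(rl_update(q, 0, 1, 0.5), c(0.5, 0, 0))
  expect_equal(rl_update(c(0.4, 0.2, 0), 1, -1, 0), c(0.4, 0.2, 0))
  # literal vector form decays unchosen entries toward zero
  expect_equal(rl_update(c(0.4, 0.2, 0.1), 0, 1, 0.5),
               c(0.7, 0.1, 0.05))
  # chosen-entry-only variant leaves the others untouched
  expect_equal(rl_update(c(0.4, 0.2, 0.1), 0, 1, 0.5,
                         decay_unchosen = FALSE),
               c(0.7, 0.2, 0.1))
})

test_that("random play yields the chance-level likelihood for every model", {
  set.seed(12)
  d <- random_session(40, n_blocks = 2L)
  blocks <- chaser:::split_blocks(d)
  reg <- chase_models()
  lls <- c(
    reg$rl$loglik(blocks, pm3, c(alpha = 0.4, beta = 0), NA),
    reg$fp$loglik(blocks, pm3, c(alpha = 0.4, beta = 0), NA),
    reg$ewa$loglik(blocks, pm3,
                   c(delta = 0.5, phi = 0.8, rho = 0.6, beta = 0), NA),
    reg$stewa$loglik(blocks, pm3, c(beta = 0), NA),
    reg$tomk$loglik(blocks, pm3, c(alpha = 0.4, beta = 0), 2L))
  for (ll in lls) expect_equal(ll, -80 * log(3), tolerance = 1e-10)
})

test_that("EWA experience and attraction updates match hand calculations", {
  up <- ewa_update(c(0, 0, 0), 1, 0, pm3[, 2], delta = 0.5, phi = 0.9,
                   rho = 0.9)
  expect_equal(up$n, 1.9)  # n' = rho * n + 1
  # phi = 0, n = 0 start: pure latest-payoff attraction, bracket * pvec
  pv <- pm3[, 1]  # opponent played rock
  up0 <- ewa_update(c(0.2, 0.1, 0), 0, 0, pv, delta = 0.3, phi = 0,
                    rho = 0.5)
  expect_equal(up0$a, (0.3 + 0.7 * c(1, 0, 0)) * pv / 1)
  # delta = 1: full foregone-payoff (fictitious-play-like) update
  up1 <- ewa_update(c(0, 0, 0), 0, 0, pv, delta = 1, phi = 1, rho = 1)
  expect_equal(up1$a, pv)
  # delta = 0: only the realized payoff enters
  up2 <- ewa_update(c(0, 0, 0), 0, 1, pv, delta = 0, phi = 1, rho = 1)
  expect_equal(up2$a, c(0, pv[2], 0))
})

test_that("EWA with no foregone learning tracks a rescaled RL rule", {
  # delta = 0, rho = 0 pins the experience-equivalent at 1, giving
  # a' = phi * a + I(own) * pay. With phi = 1 - alpha this is the RL
  # delta rule on attractions scaled by 1/alpha, so the policies agree
  # once the EWA temperature is rescaled by alpha.
  set.seed(31)
  d <- random_session(60)
  blocks <- chaser:::split_blocks(d)
  reg <- chase_models()
  a <- 0.35
  ll_ewa <- reg$ewa$loglik(blocks, pm3,
                           c(delta = 0, phi = 1 - a, rho = 0,
                             beta = a * 3), NA)
  ll_rl <- reg$rl$loglik(blocks, pm3, c(alpha = a, beta = 3), NA)
  expect_equal(ll_ewa, ll_rl, tolerance = 1e-10)
})

test_that("self-tuning EWA change detector behaves at its limits", {
  # stationary opponent, window covering everything: no surprise
  expect_equal(stewa_phi(rep(0L, 30), 3, window = 30L), 1)
  # window-1 detector after a sudden novel action: phi near its minimum
  phi_switch <- stewa_phi(c(rep(0L, 30), 2L), 3)
  expect_lt(phi_switch, 0.1)
  # repeated same action with window 1: h concentrates, surprise shrinks
  expect_gt(stewa_phi(rep(1L, 50), 3), 0.99)
})

test_that("self-tuning EWA attention selects weakly better actions", {
  pv <- pm3[, 1]  # vs rock: rock 0, paper +1, scissors -1
  # realized payoff maximal (played paper): only the chosen action learns
  expect_equal(stewa_delta(pv, 1), c(0, 1, 0))
  # realized payoff minimal (played scissors): every action learns
  expect_equal(stewa_delta(pv, 2), c(1, 1, 1))
  expect_equal(stewa_delta(pv, 0), c(1, 1, 0))
})

test_that("ToMk confidence updates follow the delta rule with lowest-level credit", {
  # correct prediction: c' = 0.8 * 0.5 + 0.2
  expect_equal(tomk_confidence_update(0.5, list(1L), 1L, 0.2), 0.6)
  # incorrect prediction: decay only
  expect_equal(tomk_confidence_update(0.5, list(1L), 2L, 0.2), 0.4)
  # two levels predict the same observed action: only the lowest gains,
  # the higher stays constant
  cf <- tomk_confidence_update(c(0.5, 0.5), list(0L, 0L), 0L, 0.2)
  expect_equal(cf, c(0.6, 0.5))
  # lower level wrong, higher right: lower decays, higher gains
  cf2 <- tomk_confidence_update(c(0.5, 0.5), list(1L, 0L), 0L, 0.2)
  expect_equal(cf2, c(0.4, 0.6))
})

test_that("ToMk compiled filter matches the R step implementation", {
  set.seed(44)
  for (k in 0:3) {
    d <- random_session(25)
    blocks <- chaser:::split_blocks(d)
    ll_cpp <- tomk_filter_cpp(blocks, pm3, 0.3, 4, k, 0.8, 0.5)$loglik
    ag <- make_agent("tomk", list(alpha = 0.3, beta = 4, k = k), spec3)
    ll_r <- 0
    for (t in seq_len(nrow(d))) {
      pol <- agent_policy(ag)
      expect_equal(sum(pol), 1, tolerance = 1e-12)
      ll_r <- ll_r + log(max(pol[d$action_self[t] + 1], 1e-12))
      ag <- agent_learn(ag, d$action_self[t], d$action_opp[t])
    }
    expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
  }
})

test_that("all agent policies are valid distributions on random play", {
  set.seed(55)
  agents <- list(
    make_agent("chase", list(alpha = 0.3, beta = 5, gamma = 10,
                             lambda = 1.5, kappa = 3), spec3),
    make_agent("rl", list(alpha = 0.3, beta = 4), spec3),
    make_agent("fp", list(alpha = 0.3, beta = 4), spec3),
    make_agent("ewa", list(delta = 0.6, phi = 0.8, rho = 0.7, beta = 3),
               spec3),
    make_agent("stewa", list(beta = 3), spec3),
    make_agent("tomk", list(alpha = 0.3, beta = 4, k = 2), spec3),
    make_agent("fixed_level", opponent_spec(1), spec3),
    make_agent("uniform", list(), spec3))
  for (t in 1:12) {
    for (i in seq_along(agents)) {
      pol <- agent_policy(agents[[i]])
      expect_equal(sum(pol), 1, tolerance = 1e-12)
      expect_true(all(pol >= 0))
      agents[[i]] <- agent_learn(agents[[i]], sample(0:2, 1),
                                 sample(0:2, 1))
    }
  }
})

test_that("parameter counts feeding AIC match the model definitions", {
  reg <- chase_models()
  counts <- vapply(reg, function(m) m$n_params, integer(1))
  expect_equal(counts[["chase"]], 5L)
  expect_equal(counts[["rl"]], 2L)
  expect_equal(counts[["fp"]], 2L)
  expect_equal(counts[["ewa"]], 4L)
  expect_equal(counts[["stewa"]], 1L)
  expect_equal(counts[["tomk"]], 3L)
})
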