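#' Fixed-level artificial opponent specification
#'
#' The artificial opponents use the same attraction learning and
#' recursive reasoning as the adaptive agent but are fixed to one level
#' of sophistication (k = 0, 1 or 2) and perform no belief updating.
#' Their noise is parameterised by an inverse temperature and a lapse
#' rate (probability of a uniformly random action); the defaults were
#' chosen so that a low-noise depth-3 adaptive agent attains positive
#' scores against all three levels while the opponents remain
#' informative about their strategy.
#'
#' @param level Fixed reasoning level (0, 1 or 2; any k >= 0 accepted).
#' @param alpha Attraction update rate.
#' @param beta Inverse softmax temperature.
#' @param lapse Lapse probability in `[0, 1]`.
#' @return List of class `opponent_spec`.
#' @export
opponent_spec <- function(level, alpha = 0.3, beta = 3, lapse = 0.25) {
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("opponent level must be >= 0")
  if (lapse < 0 || lapse > 1) stop("lapse must lie in [0, 1]")
  structure(list(level = level, alpha = alpha, beta = beta, lapse = lapse),
            class = "opponent_spec")
}

#' Create a playable agent
#'
#' Uniform interface over all candidate models plus the fixed-level
#' artificial opponents and a uniform-random baseline. An agent holds
#' its own state (always initialised fresh, as at a block start) and is
#' advanced with [agent_learn()]; [agent_policy()] returns its current
#' action distribution. Both actions passed to [agent_learn()] are in
#' the agent's own frame (`own` = the agent's action).
#'
#' @param model One of `"chase"`, `"rl"`, `"fp"`, `"ewa"`, `"stewa"`,
#'   `"tomk"`, `"fixed_level"`, `"uniform"`.
#' @param params Named list/vector of the model's parameters (for
#'   `"fixed_level"`, an [opponent_spec()]).
#' @param spec A [game_spec()].
#' @return An object of class `game_agent`.
#' @export
make_agent <- function(model, params = list(), spec = game_spec()) {
  pi <- payoff_matrix(spec)
  n <- spec$n_actions
  params <- as.list(params)
  state <- switch(
    model,
    chase = chase_init(do.call(chase_params, params), n),
    fp = chase_init(chase_params(alpha = params$alpha, beta = params$beta,
                                 gamma = 0, lambda = 1, kappa = 1L), n),
    rl = list(q = rowMeans(pi)),
    ewa = list(a = rowMeans(pi), n = 0),
    stewa = list(a = rowMeans(pi), n = 0, opp_hist = integer(0)),
    tomk = list(attr = attraction_pair(n),
                conf = rep(0.5, max(params$k, 0L))),
    fixed_level = list(attr = attraction_pair(n)),
    uniform = list(),
    stop("unknown model: ", model))
  structure(list(model = model, params = params, spec = spec, pi = pi,
                 state = state),
            class = "game_agent")
}

#' Current action distribution of an agent
#' @param agent A [make_agent()] object.
#' @return Probability vector over the agent's actions.
#' @export
agent_policy <- function(agent) {
  p <- agent$params
  s <- agent$state
  n <- agent$spec$n_actions
  switch(
    agent$model,
    chase = , fp = {
      cp <- if (agent$model == "fp")
        chase_params(alpha = p$alpha, beta = p$beta, gamma = 0, lambda = 1,
                     kappa = 1L)
      else do.call(chase_params, p)
      pis <- scale_losses(agent$pi, cp$lambda)
      preds <- t(vapply(0:(cp$kappa - 1L), function(k)
        level_policy(k, s$attr, "opponent_prediction", pis, cp$beta),
        numeric(n)))
      integrated_policy(s$belief, preds, pis, cp$beta)$own_policy
    },
    rl = softmax_policy(s$q, p$beta),
    ewa = softmax_policy(s$a, p$beta),
    stewa = softmax_policy(s$a, p$beta),
    tomk = softmax_policy(
      tomk_ev(s$attr$a_self, s$attr$a_opp, s$conf, p$k, agent$pi)$ev,
      p$beta),
    fixed_level = {
      base <- level_policy(p$level, s$attr, "self_play", agent$pi, p$beta)
      (1 - p$lapse) * base + p$lapse / n
    },
    uniform = rep(1 / n, n))
}

#' Advance an agent after one trial
#' @param agent A [make_agent()] object.
#' @param own,opp 0-indexed actions in the agent's own frame.
#' @return The updated agent.
#' @export
agent_learn <- function(agent, own, opp) {
  p <- agent$params
  s <- agent$state
  pvec <- agent$pi[, opp + 1L]
  agent$state <- switch(
    agent$model,
    chase = chase_step(s, own, opp, do.call(chase_params, p), agent$pi)$state,
    fp = chase_step(s, own, opp,
                    chase_params(alpha = p$alpha, beta = p$beta, gamma = 0,
                                 lambda = 1, kappa = 1L), agent$pi)$state,
    rl = list(q = rl_update(s$q, own, agent$pi[own + 1L, opp + 1L],
                            p$alpha)),
    ewa = {
      up <- ewa_update(s$a, s$n, own, pvec, p$delta, p$phi, p$rho)
      list(a = up$a, n = up$n)
    },
    stewa = {
      hist <- c(s$opp_hist, opp)
      phi <- stewa_phi(hist, length(pvec))
      dvec <- stewa_delta(pvec, own)
      n1 <- phi * s$n + 1
      list(a = (phi * s$n * s$a + dvec * pvec) / n1, n = n1,
           opp_hist = hist)
    },
    tomk = {
      ev <- tomk_ev(s$attr$a_self, s$attr$a_opp, s$conf, p$k, agent$pi)
      conf <- tomk_confidence_update(s$conf, ev$opp_argmax, opp, p$alpha)
      list(attr = list(
        a_self = update_attractions(s$attr$a_self, own, p$alpha),
        a_opp = update_attractions(s$attr$a_opp, opp, p$alpha)),
        conf = conf)
    },
    fixed_level = list(attr = list(
      a_self = update_attractions(s$attr$a_self, own, p$alpha),
      a_opp = update_attractions(s$attr$a_opp, opp, p$alpha))),
    uniform = s)
  agent
}

#' Play one block between two agents
#'
#' Both sides start freshly initialised. Each trial, both policies are
#' computed from the pre-trial states, actions are sampled
#' simultaneously, payoffs are read from the raw payoff matrix and both
#' agents learn from the pair of observed actions. No information leaks:
#' each side's policy at trial t depends only on the history through
#' t - 1.
#'
#' @param agent,opponent [make_agent()] objects (fresh).
#' @param n_trials Number of trials (default 40).
#' @param spec A [game_spec()].
#' @return Data frame with one row per trial: `trial`, `action_self`,
#'   `action_opp`, `payoff_self`, `payoff_opp` (actions 0-indexed; the
#'   "self" side is `agent`).
#' @export
play_block <- function(agent, opponent, n_trials = 40L,
                       spec = game_spec()) {
  pi <- payoff_matrix(spec)
  n <- spec$n_actions
  a1 <- integer(n_trials); a2 <- integer(n_trials)
  p1 <- numeric(n_trials); p2 <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    pol1 <- agent_policy(agent)
    pol2 <- agent_policy(opponent)
    a1[t] <- sample.int(n, 1L, prob = pol1) - 1L
    a2[t] <- sample.int(n, 1L, prob = pol2) - 1L
    out <- round_outcome(a1[t], a2[t], pi)
    p1[t] <- out[["payoff_self"]]; p2[t] <- out[["payoff_opp"]]
    agent <- agent_learn(agent, a1[t], a2[t])
    opponent <- agent_learn(opponent, a2[t], a1[t])
  }
  data.frame(trial = seq_len(n_trials), action_self = a1, action_opp = a2,
             payoff_self = p1, payoff_opp = p2)
}

#' Counterbalanced opponent-level schedule
#'
#' Each of the given levels appears `reps` times, in a random order with
#' no immediate repetitions of the same opponent type.
#'
#' @param levels Opponent levels (default 0:2).
#' @param reps Repetitions per level (default 2, i.e. six blocks).
#' @return Integer vector of levels, one per block.
#' @export
block_schedule <- function(levels = 0:2, reps = 2L) {
  pool <- rep(levels, reps)
  repeat {
    sched <- sample(pool)
    if (all(diff(sched) != 0)) return(sched)
  }
}

#' Default CHASE parameter sampler
#'
#' Draws plausible generating parameters for synthetic participants:
#' alpha ~ U(0.05, 0.6), beta ~ U(1, 10), gamma ~ U(1, 30),
#' lambda ~ U(0.5, 3), kappa ~ {1: 0.1, 2: 0.1, 3: 0.8} (most
#' participants mentalize at the maximum depth).
#'
#' @param n Number of parameter sets.
#' @return Data frame with one row per synthetic participant.
#' @export
sample_chase_params <- function(n) {
  data.frame(alpha = stats::runif(n, 0.05, 0.6),
             beta = stats::runif(n, 1, 10),
             gamma = stats::runif(n, 1, 30),
             lambda = stats::runif(n, 0.5, 3),
             kappa = sample(1:3, n, replace = TRUE,
                            prob = c(0.1, 0.1, 0.8)))
}

#' Simulate a full synthetic experiment
#'
#' Reproduces the fMRI-style design by default: each synthetic
#' participant plays six 40-trial blocks against fixed-level artificial
#' opponents (levels 0, 1 and 2, twice each, in a counterbalanced order
#' with no immediate repetitions), with all agent and opponent state
#' reset at every block start. The master seed deterministically spawns
#' one seed per participant, making every session replayable.
#'
#' @param n_participants Number of synthetic participants.
#' @param model Generating model name (see [make_agent()]).
#' @param params Either `NULL` (CHASE: drawn from
#'   [sample_chase_params()]; other models: drawn from their registry
#'   grid ranges), a single named list applied to everyone, or a data
#'   frame with one row per participant.
#' @param spec A [game_spec()].
#' @param opponents Named defaults passed to [opponent_spec()]
#'   (`alpha`, `beta`, `lapse`).
#' @param n_trials Trials per block.
#' @param levels,reps Block schedule (see [block_schedule()]).
#' @param seed Master seed.
#' @return Data frame (one row per trial) with columns `participant`,
#'   `block`, `trial`, `opponent_level`, `action_self`, `action_opp`,
#'   `payoff_self`, `payoff_opp`; attributes `params` (generating
#'   parameters), `seeds`, `model` and `spec`.
#' @export
simulate_experiment <- function(n_participants, model = "chase",
                                params = NULL, spec = game_spec(),
                                opponents = list(), n_trials = 40L,
                                levels = 0:2, reps = 2L, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  if (is.null(params)) {
    params <- if (model == "chase") sample_chase_params(n_participants)
      else default_param_table(model, n_participants)
  } else if (!is.data.frame(params)) {
    params <- as.data.frame(params)[rep(1L, n_participants), , drop = FALSE]
  }
  if (n_participants == 0L)
    return(structure(data.frame(), params = params, seeds = seeds,
                     model = model, spec = spec))
  odef <- utils::modifyList(list(alpha = 0.3, beta = 3, lapse = 0.25),
                            opponents)
  res <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(seeds[p])
    sched <- block_schedule(levels, reps)
    blocks <- vector("list", length(sched))
    for (b in seq_along(sched)) {
      ag <- make_agent(model, as.list(params[p, , drop = FALSE]), spec)
      op <- make_agent("fixed_level",
                       opponent_spec(sched[b], alpha = odef$alpha,
                                     beta = odef$beta, lapse = odef$lapse),
                       spec)
      d <- play_block(ag, op, n_trials, spec)
      d$participant <- p
      d$block <- b
      d$opponent_level <- sched[b]
      blocks[[b]] <- d
    }
    res[[p]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, res)
  out <- out[, c("participant", "block", "trial", "opponent_level",
                 "action_self", "action_opp", "payoff_self", "payoff_opp")]
  structure(out, params = params, seeds = seeds, model = model, spec = spec)
}

# Generating-parameter table for non-CHASE models: uniform draws over the
# registry grid ranges (used by the model-recovery harness).
default_param_table <- function(model, n) {
  if (model == "uniform") return(data.frame(row.names = seq_len(n)))
  reg <- chase_models()[[model]]
  if (is.null(reg)) stop("unknown model: ", model)
  cols <- lapply(reg$grid, function(g) stats::runif(n, min(g), max(g)))
  out <- as.data.frame(cols)
  if (!is.null(reg$discrete))
    out[[reg$discrete$name]] <- sample(reg$discrete$values, n,
                                       replace = TRUE)
  out
}
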