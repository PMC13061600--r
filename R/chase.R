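#' CHASE model parameters
#'
#' Bundles the five free parameters of the adaptive-mentalization agent:
#' `alpha` (attraction update rate in (0,1), an inverse forgetting rate),
#' `beta` (inverse softmax temperature >= 0, behavioural/reasoning noise),
#' `gamma` (sensitivity to evidence about the opponent's level, >= 0),
#' `lambda` (multiplicative weight on loss payoffs, >= 0) and
#' `kappa` (maximum depth of mentalization, integer >= 1; the agent holds
#' beliefs over opponent levels `0 .. kappa-1`).
#'
#' @param alpha,beta,gamma,lambda,kappa See description.
#' @return A named list of class `chase_params`.
#' @export
chase_params <- function(alpha = 0.3, beta = 5, gamma = 10, lambda = 1,
                         kappa = 3L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (beta < 0)   stop("beta must be non-negative")
  if (gamma < 0)  stop("gamma must be non-negative")
  if (lambda < 0) stop("lambda must be non-negative")
  kappa <- as.integer(kappa)
  if (is.na(kappa) || kappa < 1L) stop("kappa must be an integer >= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda = lambda, kappa = kappa),
            class = "chase_params")
}

#' Numerically stabilised softmax choice rule
#'
#' Converts a vector of attractions or expected payoffs into choice
#' probabilities proportional to `exp(temp * x)`. `temp = 0` yields the
#' uniform distribution; large `temp` approaches the argmax.
#'
#' @param x Numeric vector.
#' @param temp Inverse temperature, >= 0.
#' @return A probability vector summing to 1.
#' @export
softmax_policy <- function(x, temp) {
  if (temp < 0) stop("inverse temperature must be non-negative")
  z <- temp * x
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Delta-rule attraction update
#'
#' Markovian update of an attraction (recency-weighted action frequency)
#' vector after observing a chosen action: `a' = a + alpha * (I(chosen) - a)`
#' with `I` the one-hot indicator. Starting from the uniform vector the
#' entries stay in `[0, 1]` and keep summing to 1.
#'
#' @param a Attraction vector.
#' @param chosen 0-indexed observed action.
#' @param alpha Update rate in `[0, 1]`.
#' @return Updated attraction vector.
#' @export
update_attractions <- function(a, chosen, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  ind <- numeric(length(a))
  ind[chosen + 1L] <- 1
  a + alpha * (ind - a)
}

#' Fresh attraction pair
#'
#' Both the self-history and the opponent-history attraction vectors are
#' reset to the uniform distribution at the start of every block.
#'
#' @param n_actions Number of actions.
#' @return List with elements `a_self` and `a_opp`.
#' @export
attraction_pair <- function(n_actions) {
  u <- rep(1 / n_actions, n_actions)
  list(a_self = u, a_opp = u)
}

#' Level-k recursive policy
#'
#' Computes the action distribution of a level-`k` player by starting
#' from nonstrategic (level-0) play and applying `k` steps of noisy best
#' response: `p <- softmax(pi %*% p | beta)`.
#'
#' Which history seeds level-0 play follows the parity rule: odd levels
#' are other-referential, even levels self-referential. When predicting
#' the opponent (`perspective = "opponent_prediction"`), an even-level
#' opponent starts from their own history (`a_opp`) and an odd-level
#' opponent from the focal player's history (`a_self`); for
#' `perspective = "self_play"` the roles are mirrored.
#'
#' @param k Level, integer >= 0.
#' @param attr An [attraction_pair()] from the focal player's viewpoint.
#' @param perspective `"self_play"` (the focal player acts at level `k`)
#'   or `"opponent_prediction"` (the focal player simulates a level-`k`
#'   opponent).
#' @param pi Payoff matrix (loss-scaled if the agent scales losses).
#' @param beta Inverse temperature used both for the level-0 seed and
#'   each best-response step.
#' @return Probability vector over the target player's actions.
#' @export
level_policy <- function(k, attr, perspective = c("self_play",
                                                  "opponent_prediction"),
                         pi, beta) {
  perspective <- match.arg(perspective)
  if (k < 0) stop("level k must be >= 0")
  even <- (k %% 2L) == 0L
  base <- if (perspective == "opponent_prediction") {
    if (even) attr$a_opp else attr$a_self
  } else {
    if (even) attr$a_self else attr$a_opp
  }
  p <- softmax_policy(base, beta)
  if (k > 0) for (i in seq_len(k)) p <- softmax_policy(drop(pi %*% p), beta)
  p
}

#' Likelihood of an observed opponent action under each level
#'
#' For each opponent level `k = 0 .. kappa-1`, the probability that a
#' level-`k` opponent (simulated via [level_policy()] with
#' `perspective = "opponent_prediction"`) would have chosen the observed
#' action.
#'
#' @param a_obs 0-indexed observed opponent action.
#' @param attr Attraction pair (pre-trial state).
#' @param kappa Number of levels entertained (>= 1).
#' @param pi Loss-scaled payoff matrix.
#' @param beta Inverse temperature.
#' @return Numeric vector of length `kappa`.
#' @export
level_likelihood <- function(a_obs, attr, kappa, pi, beta) {
  vapply(0:(kappa - 1L), function(k) {
    level_policy(k, attr, "opponent_prediction", pi, beta)[a_obs + 1L]
  }, numeric(1))
}

#' Sensitivity-distorted level evidence
#'
#' Passes the level likelihood through a softmax with inverse temperature
#' `gamma`, the agent's sensitivity to evidence about the opponent's
#' level. `gamma = 0` flattens the evidence entirely (no learning about
#' the level); large `gamma` sharpens it toward the most likely level.
#'
#' @param L Likelihood vector over levels.
#' @param gamma Sensitivity, >= 0.
#' @return Probability vector over levels.
#' @export
distort_likelihood <- function(L, gamma) {
  if (gamma < 0) stop("gamma must be non-negative")
  softmax_policy(L, gamma)
}

#' Bayesian belief update over opponent levels
#'
#' @param b Prior belief vector (sums to 1).
#' @param l_hat Distorted likelihood vector, same length.
#' @return Posterior `b' = l_hat * b / sum(l_hat * b)`.
#' @export
bayes_update <- function(b, l_hat) {
  stopifnot(length(b) == length(l_hat))
  w <- l_hat * b
  s <- sum(w)
  if (s <= 0) stop("degenerate belief update: all posterior mass is zero")
  w / s
}

#' Belief-update magnitude (KL divergence, nats)
#'
#' Kullback-Leibler divergence from the prior to the posterior belief,
#' `sum(post * log(post / prior))` with `0 * log 0 = 0`, natural log.
#' This is the trial-wise adaptive-mentalization signal (BU).
#'
#' @param b_post,b_prior Probability vectors; `b_prior` must give positive
#'   mass wherever `b_post` does.
#' @return Non-negative scalar.
#' @export
belief_update_kl <- function(b_post, b_prior) {
  stopifnot(length(b_post) == length(b_prior))
  pos <- b_post > 0
  if (any(pos & b_prior <= 0))
    stop("infinite divergence: posterior mass where prior is zero")
  max(sum(b_post[pos] * log(b_post[pos] / b_prior[pos])), 0)
}

#' Belief-weighted opponent prediction and noisy best response
#'
#' Marginalises the per-level opponent predictions over the belief
#' distribution, then forms the noisy best response to the integrated
#' prediction.
#'
#' @param b Belief vector over levels.
#' @param per_level_pred Matrix (levels x actions) of opponent-action
#'   distributions, one row per level.
#' @param pi Loss-scaled payoff matrix.
#' @param beta Inverse temperature.
#' @return List with `predicted_opp` (marginal opponent prediction) and
#'   `own_policy` (softmax over expected payoffs).
#' @export
integrated_policy <- function(b, per_level_pred, pi, beta) {
  predicted_opp <- drop(b %*% per_level_pred)
  own_policy <- softmax_policy(drop(pi %*% predicted_opp), beta)
  list(predicted_opp = predicted_opp, own_policy = own_policy)
}

#' Expected payoff of the chosen action (choice value, CV)
#'
#' @param own_action 0-indexed chosen action.
#' @param predicted_opp Belief-integrated opponent prediction.
#' @param pi Loss-scaled payoff matrix.
#' @return Scalar expected payoff.
#' @export
choice_value <- function(own_action, predicted_opp, pi) {
  drop(pi %*% predicted_opp)[own_action + 1L]
}

#' Action prediction error (APE)
#'
#' One minus the predicted probability of the opponent's observed action.
#'
#' @param observed_opp 0-indexed observed opponent action.
#' @param predicted_opp Opponent prediction (probability vector).
#' @return Scalar in `[0, 1]`.
#' @export
action_prediction_error <- function(observed_opp, predicted_opp) {
  1 - predicted_opp[observed_opp + 1L]
}

#' Initialise CHASE agent state for a fresh block
#'
#' All prior belief variables (attractions, level beliefs) are reset to
#' uniform distributions at every block start.
#'
#' @param params A [chase_params()] object.
#' @param n_actions Number of actions in the game.
#' @return A `chase_state` list with `attr` and `belief`.
#' @export
chase_init <- function(params, n_actions) {
  structure(list(attr = attraction_pair(n_actions),
                 belief = rep(1 / params$kappa, params$kappa)),
            class = "chase_state")
}

#' One CHASE trial: policy, feedback processing, learning
#'
#' Runs a full trial of the CHASE agent, in the model's order of
#' computation: (i) per-level opponent predictions and the integrated
#' noisy best response are computed from the pre-trial state (this policy
#' is what the likelihood of the agent's own action and CV are based on);
#' (ii) on feedback, the APE is read off the prediction, the level
#' likelihood of the observed opponent action is built from the pre-trial
#' attractions, distorted by `gamma` and folded into the level belief by
#' Bayes rule (the KL divergence of that update is BU); (iii) both
#' attraction vectors are updated with the two observed actions.
#'
#' State must never be carried across block boundaries; call
#' [chase_init()] at each block start.
#'
#' @param state `chase_state` from [chase_init()] or a previous step.
#' @param own_action,opp_action 0-indexed actions played this trial.
#' @param params [chase_params()].
#' @param pi Unscaled payoff matrix; loss scaling with `params$lambda` is
#'   applied internally.
#' @return List `state` (post-trial) and `deriv`, the trial derivatives:
#'   `cv`, `ape`, `bu`, `p_own_action`, `own_policy`, `predicted_opp`,
#'   `modal_level_response` (argmax-belief level + 1, pre-update belief,
#'   ties toward the lower level).
#' @export
chase_step <- function(state, own_action, opp_action, params, pi) {
  pis <- scale_losses(pi, params$lambda)
  kap <- params$kappa
  preds <- t(vapply(0:(kap - 1L), function(k)
    level_policy(k, state$attr, "opponent_prediction", pis, params$beta),
    numeric(nrow(pi))))
  ip <- integrated_policy(state$belief, preds, pis, params$beta)

  cv <- choice_value(own_action, ip$predicted_opp, pis)
  ape <- action_prediction_error(opp_action, ip$predicted_opp)
  modal <- which.max(state$belief)  # which.max breaks ties toward lower level

  L <- level_likelihood(opp_action, state$attr, kap, pis, params$beta)
  l_hat <- distort_likelihood(L, params$gamma)
  b_post <- bayes_update(state$belief, l_hat)
  bu <- belief_update_kl(b_post, state$belief)

  attr2 <- list(
    a_self = update_attractions(state$attr$a_self, own_action, params$alpha),
    a_opp  = update_attractions(state$attr$a_opp, opp_action, params$alpha))

  new_state <- structure(list(attr = attr2, belief = b_post,
                              last_likelihood = L, last_distorted = l_hat,
                              last_bu = bu),
                         class = "chase_state")
  deriv <- list(cv = cv, ape = ape, bu = bu,
                p_own_action = ip$own_policy[own_action + 1L],
                own_policy = ip$own_policy,
                predicted_opp = ip$predicted_opp,
                modal_level_response = modal)  # modal = argmax level + 1
  list(state = new_state, deriv = deriv)
}

#' Session log likelihood of the CHASE model
#'
#' Sum over trials of the log probability the agent's integrated policy
#' assigned to the action actually played, with the full state reset to
#' uniform at every block start. One parameter set is used across all of
#' a participant's blocks; the model is agnostic to opponent identity.
#' Per-trial probabilities are floored at 1e-12 before the log.
#'
#' @param sessions A session data frame (see [simulate_experiment()] /
#'   [read_sessions()]) for a single participant, with columns `block`,
#'   `action_self`, `action_opp`.
#' @param params [chase_params()] or a named vector with `alpha`, `beta`,
#'   `gamma`, `lambda`, `kappa`.
#' @param spec A [game_spec()].
#' @return Scalar log likelihood (<= 0).
#' @export
chase_loglik <- function(sessions, params, spec) {
  pi <- payoff_matrix(spec)
  p <- as.list(params)
  out <- chase_filter_cpp(
    split_blocks(sessions), pi,
    p$alpha, p$beta, p$gamma, p$lambda, as.integer(p$kappa),
    FALSE)
  out$loglik
}

#' Trial-wise model-derived regressors
#'
#' Runs the CHASE filter over a participant's sessions and returns the
#' tidy trial-by-trial table of model-derived quantities used as
#' parametric modulators: choice value (CV), action prediction error
#' (APE), belief update (BU, KL divergence in nats) plus its
#' within-participant z-score `bu_z` (z-scoring happens only here, at the
#' export layer), and the modal level response (argmax-belief level + 1).
#'
#' @inheritParams chase_loglik
#' @return A data frame with one row per trial: `participant`, `block`,
#'   `trial`, `cv`, `ape`, `bu`, `bu_z`, `modal_level_response`.
#' @export
chase_regressors <- function(sessions, params, spec) {
  pi <- payoff_matrix(spec)
  p <- as.list(params)
  blocks <- split_blocks(sessions)
  out <- chase_filter_cpp(blocks, pi, p$alpha, p$beta, p$gamma, p$lambda,
                          as.integer(p$kappa), TRUE)
  bu <- out$bu
  bu_z <- if (stats::sd(bu) > 0) (bu - mean(bu)) / stats::sd(bu) else bu * 0
  data.frame(
    participant = sessions$participant[1L],
    block = sessions$block,
    trial = sessions$trial,
    cv = out$cv, ape = out$ape, bu = bu, bu_z = bu_z,
    modal_level_response = out$modal)
}

# Split a single-participant session data frame into a list of
# two-column integer matrices (own, opp), one per block, in block order.
split_blocks <- function(sessions) {
  stopifnot(all(c("block", "action_self", "action_opp") %in%
                  names(sessions)))
  lapply(split(sessions, sessions$block), function(d)
    cbind(as.integer(d$action_self), as.integer(d$action_opp)))
}
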