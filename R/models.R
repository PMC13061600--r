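#' Candidate model registry
#'
#' Returns the registry of candidate models under a uniform interface.
#' Each entry carries the model's free-parameter specification (names,
#' transforms between the natural and unconstrained optimisation scale,
#' default grid-search values), any discrete parameter enumerated
#' exhaustively at fit time, the number of free parameters feeding AIC,
#' and a session log-likelihood function.
#'
#' Models:
#' \describe{
#'   \item{chase}{Adaptive cognitive-hierarchy agent; free parameters
#'     alpha, beta, gamma, lambda plus the discrete mentalization depth
#'     kappa (5 parameters).}
#'   \item{rl}{Delta-rule reinforcement learning on own payoffs
#'     (alpha, beta).}
#'   \item{fp}{Fictitious play: best response to recency-weighted
#'     opponent action frequencies; identical to CHASE with kappa = 1
#'     (alpha, beta).}
#'   \item{ewa}{Experience-weighted attraction with foregone-payoff
#'     weight delta and forgetting rates phi, rho (delta, phi, rho,
#'     beta).}
#'   \item{stewa}{Self-tuning EWA; only beta is free.}
#'   \item{tomk}{Confidence-based theory-of-mind model with fixed own
#'     level k, enumerated over 0..3 (alpha, beta, k).}
#' }
#'
#' @param k_max Maximum CHASE mentalization depth enumerated at fit time.
#' @return Named list of model definitions.
#' @export
chase_models <- function(k_max = 3L) {
  list(
    chase = list(
      name = "chase",
      par_names = c("alpha", "beta", "gamma", "lambda"),
      bounds = list(alpha = c(0, 1), beta = c(0, 20), gamma = c(0, 30),
                    lambda = c(0, 5)),
      grid = list(alpha = c(0.1, 0.3, 0.5), beta = c(2, 6),
                  gamma = c(2, 8, 25), lambda = c(0.8, 1.5)),
      discrete = list(name = "kappa", values = seq_len(k_max)),
      n_params = 5L,
      loglik = function(blocks, pi, par, discrete) {
        chase_filter_cpp(blocks, pi, par[["alpha"]], par[["beta"]],
                         par[["gamma"]], par[["lambda"]],
                         as.integer(discrete), FALSE)$loglik
      }),
    rl = list(
      name = "rl",
      par_names = c("alpha", "beta"),
      bounds = list(alpha = c(0, 1), beta = c(0, 20)),
      grid = list(alpha = c(0.1, 0.3, 0.6), beta = c(1, 3, 8)),
      discrete = NULL,
      n_params = 2L,
      loglik = function(blocks, pi, par, discrete) {
        rl_loglik_cpp(blocks, pi, par[["alpha"]], par[["beta"]], TRUE)
      }),
    fp = list(
      name = "fp",
      par_names = c("alpha", "beta"),
      bounds = list(alpha = c(0, 1), beta = c(0, 20)),
      grid = list(alpha = c(0.1, 0.3, 0.6), beta = c(1, 3, 8)),
      discrete = NULL,
      n_params = 2L,
      loglik = function(blocks, pi, par, discrete) {
        chase_filter_cpp(blocks, pi, par[["alpha"]], par[["beta"]],
                         0, 1, 1L, FALSE)$loglik
      }),
    ewa = list(
      name = "ewa",
      par_names = c("delta", "phi", "rho", "beta"),
      bounds = list(delta = c(0, 1), phi = c(0, 1), rho = c(0, 1),
                    beta = c(0, 20)),
      grid = list(delta = c(0.2, 0.8), phi = c(0.3, 0.9),
                  rho = c(0.3, 0.9), beta = c(1, 4)),
      discrete = NULL,
      n_params = 4L,
      loglik = function(blocks, pi, par, discrete) {
        ewa_loglik_cpp(blocks, pi, par[["delta"]], par[["phi"]],
                       par[["rho"]], par[["beta"]])
      }),
    stewa = list(
      name = "stewa",
      par_names = "beta",
      bounds = list(beta = c(0, 20)),
      grid = list(beta = c(0.5, 2, 6)),
      discrete = NULL,
      n_params = 1L,
      loglik = function(blocks, pi, par, discrete) {
        stewa_loglik_cpp(blocks, pi, par[["beta"]], 1L)
      }),
    tomk = list(
      name = "tomk",
      par_names = c("alpha", "beta"),
      bounds = list(alpha = c(0, 1), beta = c(0, 20)),
      grid = list(alpha = c(0.1, 0.3, 0.6), beta = c(1, 3, 8)),
      discrete = list(name = "k", values = 0:3),
      n_params = 3L,
      loglik = function(blocks, pi, par, discrete) {
        tomk_filter_cpp(blocks, pi, par[["alpha"]], par[["beta"]],
                        as.integer(discrete), 0.8, 0.5)$loglik
      })
  )
}

#' Reinforcement-learning value update
#'
#' Literal delta-rule on action values: `q' = q + alpha * (payoff * I(a)
#' - q)`, so unchosen values decay toward zero. With
#' `decay_unchosen = FALSE` only the chosen entry is updated (the
#' alternative reading of the indicator form).
#'
#' @param q Value vector (initialised at the expected payoff against a
#'   uniformly random opponent; all zeros in the zero-sum game).
#' @param chosen 0-indexed chosen action.
#' @param payoff Realized payoff.
#' @param alpha Learning rate in `[0, 1]`.
#' @param decay_unchosen Logical, see description.
#' @return Updated value vector.
#' @export
rl_update <- function(q, chosen, payoff, alpha, decay_unchosen = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (decay_unchosen) {
    ind <- numeric(length(q))
    ind[chosen + 1L] <- payoff
    q + alpha * (ind - q)
  } else {
    q[chosen + 1L] <- q[chosen + 1L] + alpha * (payoff - q[chosen + 1L])
    q
  }
}

#' Experience-weighted attraction update
#'
#' One EWA step: experience `n' = rho * n + 1` and attractions
#' `a' = (phi * n * a + (delta + (1 - delta) * I(own)) * pvec) / n'`,
#' where `pvec` is the foregone-payoff vector (payoff of every own
#' action against the observed opponent action). The denominator is the
#' post-update experience `n'`.
#'
#' @param a Attraction vector.
#' @param n Experience-equivalent (>= 0, initialised at 0).
#' @param own 0-indexed own action.
#' @param pvec Foregone-payoff vector `pi[, opp + 1]`.
#' @param delta Foregone-payoff weight in `[0, 1]`.
#' @param phi,rho Forgetting rates in `[0, 1]`.
#' @return List with updated `a` and `n`.
#' @export
ewa_update <- function(a, n, own, pvec, delta, phi, rho) {
  n1 <- rho * n + 1
  w <- delta + (1 - delta) * (seq_along(a) == own + 1L)
  list(a = (phi * n * a + w * pvec) / n1, n = n1)
}

#' Self-tuning EWA change detector
#'
#' Surprise-index forgetting rate `phi(t) = 1 - 0.5 * sum((h - r)^2)`
#' comparing cumulative opponent-action frequencies `h` against the
#' recent-window frequencies `r` (window defaults to the single most
#' recent opponent action). A perfectly stationary opponent gives
#' `phi = 1` (no forgetting); a sudden switch to a novel action after a
#' long history drives `phi` toward its minimum.
#'
#' @param opp_history Integer vector of 0-indexed opponent actions,
#'   including the current trial.
#' @param n_actions Number of actions.
#' @param window Recent-window length.
#' @return `phi(t)` in `[0, 1]`.
#' @export
stewa_phi <- function(opp_history, n_actions, window = 1L) {
  t <- length(opp_history)
  h <- tabulate(opp_history + 1L, n_actions) / t
  w <- min(window, t)
  r <- tabulate(opp_history[(t - w + 1L):t] + 1L, n_actions) / w
  1 - 0.5 * sum((h - r)^2)
}

#' Self-tuning EWA attention vector
#'
#' `delta_j(t) = 1` if the foregone payoff of own action `j` weakly
#' exceeds the realized payoff, else 0; the chosen action always counts
#' fully.
#'
#' @param pvec Foregone-payoff vector against the observed opponent
#'   action.
#' @param own 0-indexed own action.
#' @return 0/1 attention vector.
#' @export
stewa_delta <- function(pvec, own) {
  realized <- pvec[own + 1L]
  d <- as.numeric(pvec >= realized)
  d[own + 1L] <- 1
  d
}

# ---- ToMk internals (R mirror of the compiled filter) -----------------

# EV chains for a ToMk agent of level k. Returns the agent's final EV
# vector and, per opponent level 0..k-1, the argmax set of the opponent's
# simulated EV (used both for the best-response mixing and for the
# confidence credit assignment).
tomk_ev <- function(a_self, a_opp, conf, k, pi, c_opp = 0.8) {
  ev_me <- drop(pi %*% a_opp)
  ev_opp <- drop(pi %*% a_self)
  ev_me_sim <- ev_me
  opp_argmax <- vector("list", max(k, 0L))
  amax <- function(ev) which(ev >= max(ev) - 1e-12)
  onehot_split <- function(set, n) { p <- numeric(n); p[set] <- 1 / length(set); p }
  n <- nrow(pi)
  if (k > 0) for (j in seq_len(k)) {
    set <- amax(ev_opp)
    opp_argmax[[j]] <- set - 1L
    br <- drop(pi %*% onehot_split(set, n))
    ev_me_new <- conf[j] * br + (1 - conf[j]) * ev_me
    p_me <- onehot_split(amax(ev_me_sim), n)
    br_opp <- drop(pi %*% p_me)
    ev_opp <- c_opp * br_opp + (1 - c_opp) * ev_opp
    ev_me_sim <- c_opp * br + (1 - c_opp) * ev_me_sim
    ev_me <- ev_me_new
  }
  list(ev = ev_me, opp_argmax = opp_argmax)
}

#' ToMk confidence update with lowest-level credit assignment
#'
#' After observing the opponent's action, every level whose argmax
#' prediction covers the action is "able to explain" it. Credit (a
#' positive delta-rule update) goes only to the lowest explaining level;
#' higher explaining levels keep their confidence; all other levels
#' decay (`c' = (1 - alpha) * c`).
#'
#' @param conf Confidence vector (own levels 1..k).
#' @param opp_argmax List of 0-indexed argmax sets, one per opponent
#'   level 0..k-1.
#' @param opp_action 0-indexed observed opponent action.
#' @param alpha Update rate.
#' @return Updated confidence vector.
#' @export
tomk_confidence_update <- function(conf, opp_argmax, opp_action, alpha) {
  k <- length(conf)
  if (k == 0L) return(conf)
  matched <- vapply(opp_argmax, function(s) opp_action %in% s, logical(1))
  lowest <- if (any(matched)) which(matched)[1L] else 0L
  for (j in seq_len(k)) {
    if (matched[j] && j > lowest) next
    conf[j] <- (1 - alpha) * conf[j] + alpha * as.numeric(j == lowest)
  }
  conf
}
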