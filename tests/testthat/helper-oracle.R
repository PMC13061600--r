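# Literal per-equation transcription of the adaptive-mentalization agent,
# written independently of the package implementation: plain loops, no
# shared helpers. Used as the brute-force oracle the production filter is
# checked against.

oracle_softmax <- function(x, temp) {
  e <- exp(temp * x - max(temp * x))
  e / sum(e)
}

# One whole block, trial by trial. Returns the full latent trajectory.
oracle_chase_block <- function(own, opp, alpha, beta, gamma, lambda,
                               kappa, pi_raw) {
  n <- nrow(pi_raw)
  pi_s <- pi_raw
  pi_s[pi_s == -1] <- -lambda
  a_self <- rep(1 / n, n)
  a_opp <- rep(1 / n, n)
  b <- rep(1 / kappa, kappa)
  T_ <- length(own)
  out <- list(loglik = 0, cv = numeric(T_), ape = numeric(T_),
              bu = numeric(T_), beliefs = matrix(NA_real_, T_, kappa))
  for (t in seq_len(T_)) {
    # per-level opponent predictions (parity: even levels start from the
    # opponent's own history, odd levels from mine)
    preds <- matrix(NA_real_, kappa, n)
    for (k in 0:(kappa - 1)) {
      p <- if (k %% 2 == 0) oracle_softmax(a_opp, beta)
           else oracle_softmax(a_self, beta)
      if (k > 0) for (i in 1:k) p <- oracle_softmax(as.vector(pi_s %*% p), beta)
      preds[k + 1, ] <- p
    }
    pred_opp <- as.vector(t(preds) %*% b)
    ev <- as.vector(pi_s %*% pred_opp)
    pol <- oracle_softmax(ev, beta)
    out$loglik <- out$loglik + log(max(pol[own[t] + 1], 1e-12))
    out$cv[t] <- ev[own[t] + 1]
    out$ape[t] <- 1 - pred_opp[opp[t] + 1]
    # level likelihood of the observed opponent action, distorted, Bayes
    L <- preds[, opp[t] + 1]
    l_hat <- oracle_softmax(L, gamma)
    post <- l_hat * b / sum(l_hat * b)
    out$bu[t] <- sum(ifelse(post > 0, post * log(post / b), 0))
    out$beliefs[t, ] <- post
    b <- post
    # attraction deltas
    i_self <- as.numeric(seq_len(n) == own[t] + 1)
    i_opp <- as.numeric(seq_len(n) == opp[t] + 1)
    a_self <- a_self + alpha * (i_self - a_self)
    a_opp <- a_opp + alpha * (i_opp - a_opp)
  }
  out
}

# random session generator used across tests
random_session <- function(n_trials, n_blocks = 1L, n_actions = 3L,
                           participant = 1L) {
  data.frame(
    participant = participant,
    block = rep(seq_len(n_blocks), each = n_trials),
    trial = rep(seq_len(n_trials), n_blocks),
    action_self = sample(0:(n_actions - 1L), n_trials * n_blocks,
                         replace = TRUE),
    action_opp = sample(0:(n_actions - 1L), n_trials * n_blocks,
                        replace = TRUE))
}

random_chase_params <- function() {
  list(alpha = runif(1, 0.05, 0.6), beta = runif(1, 1, 10),
       gamma = runif(1, 1, 30), lambda = runif(1, 0.5, 3),
       kappa = sample(1:3, 1))
}
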