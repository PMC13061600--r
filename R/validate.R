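#' Parameter recovery for the CHASE model
#'
#' Simulates a cohort of CHASE agents on the fixed-level-opponent design
#' (by default six 40-trial blocks, opponent levels 0/1/2 twice each),
#' refits the model to every synthetic participant and correlates
#' generating with recovered parameters (Pearson; the discrete depth
#' kappa is treated as ordinal).
#'
#' @param n_participants Number of synthetic participants (default 48).
#' @param spec A [game_spec()].
#' @param seed Master seed (controls parameter draws and gameplay).
#' @param k_max Maximum depth enumerated at fit time.
#' @param settings A [fit_settings()] list.
#' @param params Optional generating-parameter data frame (default:
#'   drawn from [sample_chase_params()]).
#' @param ... Passed to [simulate_experiment()] (e.g. `n_trials`,
#'   `opponents`).
#' @return Object of class `recovery_report`: `correlations` (named, one
#'   per parameter), `generating` and `recovered` data frames, `n_failed`
#'   (fits excluded), and the config echo.
#' @export
parameter_recovery <- function(n_participants = 48L, spec = game_spec(),
                               seed = 1L, k_max = 3L,
                               settings = fit_settings(),
                               params = NULL, ...) {
  sims <- simulate_experiment(n_participants, "chase", params = params,
                              spec = spec, seed = seed, ...)
  gen <- attr(sims, "params")
  pn <- c("alpha", "beta", "gamma", "lambda", "kappa")
  rec <- as.data.frame(matrix(NA_real_, n_participants, length(pn),
                              dimnames = list(NULL, pn)))
  failed <- 0L
  for (p in seq_len(n_participants)) {
    f <- tryCatch(
      fit_participant(sims[sims$participant == p, ], "chase", spec,
                      k_max, settings),
      error = function(e) NULL)
    if (is.null(f)) { failed <- failed + 1L; next }
    rec[p, ] <- f$estimates[pn]
  }
  ok <- stats::complete.cases(rec)
  cors <- vapply(pn, function(nm) {
    keep <- ok
    # gamma only shapes behaviour when beliefs span several levels
    # (kappa = 1 agents hold a single-level belief and never express it)
    if (nm == "gamma") keep <- ok & gen$kappa > 1
    g <- gen[[nm]][keep]; r <- rec[[nm]][keep]
    if (stats::sd(g) == 0 || stats::sd(r) == 0) return(NA_real_)
    stats::cor(g, r)
  }, numeric(1))
  structure(list(correlations = cors, generating = gen, recovered = rec,
                 n_failed = failed,
                 config = list(n_participants = n_participants,
                               seed = seed, k_max = k_max)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (", x$config$n_participants, " agents",
      if (x$n_failed) paste0(", ", x$n_failed, " failed fits excluded"),
      ")\n", sep = "")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Model recovery (confusion matrix)
#'
#' Simulates data from every candidate model, fits every candidate model
#' to each simulation and tallies which model wins (lowest AIC). Rows of
#' the confusion matrix are the generating model, columns the
#' best-fitting model; entries are proportions of simulations won and
#' rows sum to 1.
#'
#' @param n_sims Simulations per generating model.
#' @param models Character vector of model names (generators and
#'   fitted candidates).
#' @param spec A [game_spec()].
#' @param seed Master seed.
#' @param k_max,settings Fitting controls.
#' @param ... Passed to [simulate_experiment()].
#' @return Object of class `confusion_matrix`: the proportion matrix
#'   plus the per-simulation best-fit table.
#' @export
model_recovery <- function(n_sims = 20L,
                           models = names(chase_models()),
                           spec = game_spec(), seed = 1L, k_max = 3L,
                           settings = fit_settings(), ...) {
  cm <- matrix(0, length(models), length(models),
               dimnames = list(generator = models, best_fit = models))
  detail <- list()
  for (gi in seq_along(models)) {
    gmod <- models[gi]
    sims <- simulate_experiment(n_sims, gmod, spec = spec,
                                seed = seed + gi, ...)
    fits <- fit_dataset(sims, models, spec, k_max, settings)
    for (p in unique(fits$participant)) {
      fp <- fits[fits$participant == p, ]
      win <- fp$model[which.min(fp$aic)]
      cm[gmod, win] <- cm[gmod, win] + 1
      detail[[length(detail) + 1L]] <- data.frame(
        generator = gmod, sim = p, best_fit = win)
    }
  }
  cm <- cm / rowSums(cm)
  structure(list(matrix = cm, detail = do.call(rbind, detail)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Model recovery confusion matrix (rows: generator)\n")
  print(round(x$matrix, 3))
  invisible(x)
}

# Noise-free (argmax) level-k own-action policy with uniform tie
# splitting; parity rule as in level_policy with beta -> infinity.
hard_level_policy <- function(k, attr, pi) {
  amax_split <- function(v) {
    p <- numeric(length(v))
    set <- which(v >= max(v) - 1e-12)
    p[set] <- 1 / length(set)
    p
  }
  p <- amax_split(if (k %% 2L == 0L) attr$a_self else attr$a_opp)
  if (k > 0) for (i in seq_len(k)) p <- amax_split(drop(pi %*% p))
  p
}

# Per-trial fractional credit of each candidate response level: the
# probability the noise-free level-k policy (given the running history)
# assigns to the action actually played. Ties share credit, so a
# uniformly random player earns 1/n_actions in expectation.
level_credit_matrix <- function(block, levels, alpha, pi) {
  n <- nrow(pi)
  attr <- attraction_pair(n)
  credit <- matrix(0, nrow(block), length(levels))
  for (t in seq_len(nrow(block))) {
    for (li in seq_along(levels))
      credit[t, li] <- hard_level_policy(levels[li], attr,
                                         pi)[block$action_self[t] + 1L]
    attr$a_self <- update_attractions(attr$a_self, block$action_self[t],
                                      alpha)
    attr$a_opp <- update_attractions(attr$a_opp, block$action_opp[t],
                                     alpha)
  }
  credit
}

#' Posterior predictive check: stylized best-response curves
#'
#' For every trial position within a block, the frequency with which
#' actions match the noise-free best response of the correct level
#' against the block's opponent (level k opponents call for a level-(k+1)
#' response), relative to chance (1/n_actions), together with the
#' collapsed frequency of the alternative level responses. Matching is
#' computed against the running game history with argmax (noise-free)
#' level policies and uniform tie credit.
#'
#' @param logs Session data frame with `opponent_level` labels.
#' @param spec A [game_spec()].
#' @param levels Candidate response levels scored (default 1:3).
#' @param alpha Attraction rate of the reference history tracker.
#' @return Data frame: `opponent_level`, `trial`, `correct`
#'   (chance-corrected correct-level frequency) and `alternative`
#'   (chance-corrected mean frequency of the other levels).
#' @export
posterior_predictive_check <- function(logs, spec = game_spec(),
                                       levels = 1:3, alpha = 0.3) {
  pi <- payoff_matrix(spec)
  n <- spec$n_actions
  acc <- list()
  for (p in unique(logs$participant)) {
    dp <- logs[logs$participant == p, ]
    for (b in unique(dp$block)) {
      blk <- dp[dp$block == b, ]
      cred <- level_credit_matrix(blk, levels, alpha, pi)
      correct_level <- blk$opponent_level[1L] + 1L
      ci <- match(correct_level, levels)
      acc[[length(acc) + 1L]] <- data.frame(
        opponent_level = blk$opponent_level[1L],
        trial = blk$trial,
        correct = if (is.na(ci)) NA_real_ else cred[, ci],
        alternative = rowMeans(cred[, setdiff(seq_along(levels), ci),
                                    drop = FALSE]))
    }
  }
  d <- do.call(rbind, acc)
  agg <- stats::aggregate(cbind(correct, alternative) ~ opponent_level +
                            trial, d, mean)
  agg$correct <- agg$correct - 1 / n
  agg$alternative <- agg$alternative - 1 / n
  agg[order(agg$opponent_level, agg$trial), ]
}

#' Trial-level strategy assignment via a permutation null
#'
#' Credits each trial's action to candidate response levels with
#' noise-free (argmax) level policies on the running history, smooths
#' the credits with a trailing window, and labels a trial with the
#' highest-scoring level whose window score exceeds the 95th percentile
#' of a within-block permutation null (the participant's own actions
#' shuffled within block, credits recomputed). Trials where no level
#' clears its threshold stay unassigned (`NA`).
#'
#' @param session Single-participant session data frame.
#' @param spec A [game_spec()].
#' @param levels Candidate levels (default 1:3).
#' @param alpha Attraction rate of the reference history tracker.
#' @param window Trailing window length (trials).
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Seed for the permutations.
#' @param threshold Null quantile (default 0.95).
#' @return Data frame: `block`, `trial`, `level` (assigned or `NA`),
#'   `score` of the winning level; attribute `thresholds`.
#' @export
level_assignment <- function(session, spec = game_spec(), levels = 1:3,
                             alpha = 0.3, window = 10L, n_perm = 1000L,
                             seed = 1L, threshold = 0.95) {
  if (n_perm < 100L)
    warning("n_perm < 100 gives an unstable permutation null")
  pi <- payoff_matrix(spec)
  set.seed(seed)
  roll <- function(x, w) {
    cs <- cumsum(x)
    t <- seq_along(x)
    lo <- pmax(t - w + 1L, 1L)
    (cs - c(0, cs)[lo]) / (t - lo + 1L)
  }
  out <- list()
  null_scores <- vector("list", length(levels))
  real_scores <- list()
  blocks <- unique(session$block)
  for (b in blocks) {
    blk <- session[session$block == b, ]
    cred <- level_credit_matrix(blk, levels, alpha, pi)
    sc <- apply(cred, 2L, roll, w = window)
    real_scores[[as.character(b)]] <- sc
    for (r in seq_len(n_perm)) {
      pb <- blk
      pb$action_self <- sample(blk$action_self)
      pc <- level_credit_matrix(pb, levels, alpha, pi)
      psc <- apply(pc, 2L, roll, w = window)
      for (li in seq_along(levels))
        null_scores[[li]] <- c(null_scores[[li]], psc[, li])
    }
  }
  thr <- vapply(null_scores, stats::quantile, numeric(1),
                probs = threshold, names = FALSE)
  for (b in blocks) {
    blk <- session[session$block == b, ]
    sc <- real_scores[[as.character(b)]]
    lev <- rep(NA_integer_, nrow(blk))
    best <- numeric(nrow(blk))
    for (t in seq_len(nrow(blk))) {
      pass <- which(sc[t, ] > thr)
      if (length(pass)) {
        w <- pass[which.max(sc[t, pass])]
        lev[t] <- levels[w]
        best[t] <- sc[t, w]
      } else best[t] <- max(sc[t, ])
    }
    out[[length(out) + 1L]] <- data.frame(block = b, trial = blk$trial,
                                          level = lev, score = best)
  }
  structure(do.call(rbind, out),
            thresholds = stats::setNames(thr, levels))
}

#' Belief-update time course
#'
#' Mean and dispersion of the (within-participant z-scored) belief
#' update across participants at each within-block trial position, plus
#' one least-squares slope of BU on trial index per participant.
#'
#' @param regressors Data frame from [chase_regressors()] (stacked over
#'   participants), with columns `participant`, `trial`, `bu_z`.
#' @return List with `curve` (data frame `trial`, `mean`, `sd`) and
#'   `slopes` (named numeric, one per participant).
#' @export
bu_timecourse <- function(regressors) {
  curve <- stats::aggregate(bu_z ~ trial, regressors,
                            function(x) c(mean = mean(x), sd = stats::sd(x)))
  curve <- data.frame(trial = curve$trial, mean = curve$bu_z[, "mean"],
                      sd = curve$bu_z[, "sd"])
  parts <- unique(regressors$participant)
  slopes <- vapply(parts, function(p) {
    d <- regressors[regressors$participant == p, ]
    if (stats::sd(d$bu_z) == 0) return(0)
    unname(stats::coef(stats::lm(bu_z ~ trial, d))[2L])
  }, numeric(1))
  list(curve = curve, slopes = stats::setNames(slopes, parts))
}
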