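#' Akaike information criterion
#'
#' @param loglik Maximised log likelihood.
#' @param n_params Number of free parameters.
#' @return `2 * n_params - 2 * loglik`.
#' @export
aic <- function(loglik, n_params) 2 * n_params - 2 * loglik

# natural <-> unconstrained transforms: every continuous parameter is
# mapped onto a documented plausible range (lo, hi) through a logistic,
# so the optimiser works on an unconstrained scale but cannot run onto
# the flat likelihood plateaus outside the identifiable range.
to_unconstrained <- function(x, bounds) {
  stats::qlogis((x - bounds[1L]) / (bounds[2L] - bounds[1L]))
}
to_natural <- function(x, bounds) {
  bounds[1L] + (bounds[2L] - bounds[1L]) * stats::plogis(x)
}

#' Fitting settings
#'
#' @param n_polish Number of best grid points polished by quasi-Newton
#'   optimisation per discrete-parameter value.
#' @param maxit Maximum BFGS iterations per polish.
#' @param reltol Relative convergence tolerance on the objective.
#' @param extra_starts Optional list of additional natural-scale start
#'   points (named lists), appended to the grid.
#' @return List of settings.
#' @export
fit_settings <- function(n_polish = 2L, maxit = 100L, reltol = 1e-8,
                         extra_starts = NULL) {
  list(n_polish = n_polish, maxit = maxit, reltol = reltol,
       extra_starts = extra_starts)
}

#' Maximum-likelihood fit of one model to one participant
#'
#' One parameter set is fitted across all of a participant's blocks and
#' opponents. Continuous parameters are optimised on an unconstrained
#' scale (range-logistic transforms onto the documented plausible
#' ranges, see [chase_models()]) by an initial grid search whose best
#' points are polished with BFGS; discrete
#' parameters (the CHASE depth kappa, the ToMk level k) are enumerated
#' exhaustively and the best continuous fit per value retained. All
#' model state resets at every block start.
#'
#' @param sessions Single-participant session data frame (columns
#'   `block`, `action_self`, `action_opp`).
#' @param model Model name in [chase_models()].
#' @param spec A [game_spec()].
#' @param k_max Maximum CHASE depth enumerated.
#' @param settings A [fit_settings()] list.
#' @return Object of class `chase_fit`: `model`, `estimates` (named,
#'   natural scale, including any discrete parameter), `loglik`, `aic`,
#'   `n_params`, `diagnostics` (convergence flag, number of starts, best
#'   grid point, per-discrete-value logliks).
#' @export
fit_participant <- function(sessions, model, spec = game_spec(),
                            k_max = 3L, settings = fit_settings()) {
  reg <- chase_models(k_max)[[model]]
  if (is.null(reg)) stop("unknown model: ", model)
  blocks <- split_blocks(sessions)
  pi <- payoff_matrix(spec)
  bounds <- reg$bounds
  pn <- reg$par_names

  grid <- expand.grid(reg$grid, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(settings$extra_starts))
    grid <- rbind(grid, do.call(rbind, lapply(settings$extra_starts,
                                              function(s)
                                                as.data.frame(s[pn]))))
  disc_vals <- if (is.null(reg$discrete)) NA else reg$discrete$values

  best <- NULL
  per_disc <- numeric(0)
  for (dv in disc_vals) {
    nll <- function(theta) {
      par <- stats::setNames(
        mapply(to_natural, theta, bounds[pn]), pn)
      ll <- reg$loglik(blocks, pi, par, dv)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    g_theta <- lapply(seq_len(nrow(grid)), function(i)
      mapply(to_unconstrained, as.numeric(grid[i, pn]), bounds[pn]))
    g_val <- vapply(g_theta, nll, numeric(1))
    ord <- order(g_val)
    cand <- list(par = g_theta[[ord[1L]]], value = g_val[ord[1L]],
                 convergence = NA_integer_)
    for (i in ord[seq_len(min(settings$n_polish, length(ord)))]) {
      opt <- tryCatch(
        stats::optim(g_theta[[i]], nll, method = "BFGS",
                     control = list(maxit = settings$maxit,
                                    reltol = settings$reltol)),
        error = function(e) NULL)
      if (!is.null(opt) && opt$value < cand$value)
        cand <- list(par = opt$par, value = opt$value,
                     convergence = opt$convergence)
    }
    per_disc <- c(per_disc, -cand$value)
    if (is.null(best) || cand$value < best$value) {
      best <- cand
      best$disc <- dv
      best$grid_best <- as.numeric(grid[ord[1L], pn])
    }
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fit failure: no finite likelihood found for model ", model)

  est <- stats::setNames(mapply(to_natural, best$par, bounds[pn]), pn)
  if (!is.null(reg$discrete)) est[reg$discrete$name] <- best$disc
  ll <- -best$value
  structure(list(
    model = model,
    estimates = est,
    loglik = ll,
    aic = aic(ll, reg$n_params),
    n_params = reg$n_params,
    diagnostics = list(
      converged = identical(best$convergence, 0L) || is.na(best$convergence),
      n_starts = nrow(grid),
      best_grid_point = stats::setNames(best$grid_best, pn),
      per_discrete_loglik = if (is.null(reg$discrete)) NULL else
        stats::setNames(per_disc, disc_vals))),
    class = "chase_fit")
}

#' @export
print.chase_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  cat("Estimates:\n")
  print(round(x$estimates, 4))
  cat(sprintf("logLik = %.3f, AIC = %.3f (%d parameters)\n",
              x$loglik, x$aic, x$n_params))
  invisible(x)
}

#' Fit several models to every participant of a dataset
#'
#' @param sessions Multi-participant session data frame (column
#'   `participant` distinguishes individuals).
#' @param models Character vector of model names.
#' @inheritParams fit_participant
#' @return Data frame with one row per participant x model: `participant`,
#'   `model`, `loglik`, `aic`, `n_params`, and `par_<name>` columns for
#'   the estimates.
#' @export
fit_dataset <- function(sessions, models = names(chase_models()),
                        spec = game_spec(), k_max = 3L,
                        settings = fit_settings()) {
  parts <- unique(sessions$participant)
  rows <- list()
  for (p in parts) {
    d <- sessions[sessions$participant == p, ]
    for (m in models) {
      f <- fit_participant(d, m, spec, k_max, settings)
      row <- data.frame(participant = p, model = m, loglik = f$loglik,
                        aic = f$aic, n_params = f$n_params)
      for (nm in names(f$estimates))
        row[[paste0("par_", nm)]] <- unname(f$estimates[nm])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    allcols <- unique(unlist(lapply(rows, names)))
    r[setdiff(allcols, names(r))] <- NA
    r[allcols]
  }))
  rownames(out) <- NULL
  out
}

#' Log-evidence matrix from fit results
#'
#' Builds the participant x model matrix of approximate log model
#' evidence, `-AIC / 2`, consumed by [vb_bms()].
#'
#' @param fits Data frame from [fit_dataset()].
#' @return Numeric matrix, rows = participants, columns = models.
#' @export
evidence_matrix <- function(fits) {
  parts <- unique(fits$participant)
  models <- unique(fits$model)
  m <- matrix(NA_real_, length(parts), length(models),
              dimnames = list(as.character(parts), models))
  for (i in seq_len(nrow(fits)))
    m[as.character(fits$participant[i]), fits$model[i]] <-
      -fits$aic[i] / 2
  if (anyNA(m)) stop("evidence matrix has missing participant/model cells")
  m
}
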