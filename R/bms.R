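#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over per-participant log model evidence
#' (approximated upstream as -AIC/2; see [evidence_matrix()]). Model
#' frequencies in the population get a Dirichlet prior with unit counts;
#' participant-wise model responsibilities and the Dirichlet posterior
#' are iterated to convergence. Reported are the posterior counts
#' `alpha`, expected model frequencies, exceedance probabilities (EP;
#' Monte-Carlo over the Dirichlet posterior), the Bayesian omnibus risk
#' (BOR; posterior probability of the equal-frequency null, from the
#' variational free energies of the alternative and the null) and the
#' protected exceedance probabilities
#' `PXP = EP * (1 - BOR) + BOR / M`.
#'
#' @param evidence Numeric matrix, rows = participants, columns = models,
#'   entries = log model evidence. At least two columns.
#' @param alpha0 Prior Dirichlet count per model (default 1).
#' @param n_samples Monte-Carlo samples for EP (default 1e5).
#' @param seed Seed for the EP sampling.
#' @param max_iter,tol Convergence controls on the alpha vector.
#' @return Object of class `bms_result`: `alpha`, `expected_freq`, `ep`,
#'   `bor`, `pxp`, `iterations`, `converged`, `responsibilities`.
#' @export
vb_bms <- function(evidence, alpha0 = 1, n_samples = 1e5L, seed = 1L,
                   max_iter = 500L, tol = 1e-8) {
  evidence <- as.matrix(evidence)
  if (ncol(evidence) < 2L) stop("need at least two models")
  if (any(!is.finite(evidence))) stop("evidence entries must be finite")
  n <- nrow(evidence); M <- ncol(evidence)
  a0 <- rep(alpha0, M)
  alpha <- a0 + n / M
  u <- matrix(1 / M, n, M)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    lw <- sweep(evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1L, max)
    u <- exp(lw); u <- u / rowSums(u)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new
      converged <- TRUE; break }
    alpha <- alpha_new
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("vb_bms did not converge in ", max_iter, " iterations")

  ep <- exceedance_probability(alpha, n_samples, seed)
  bor <- bayesian_omnibus_risk(evidence, u, alpha, a0)
  pxp <- ep * (1 - bor) + bor / M
  structure(list(alpha = stats::setNames(alpha, colnames(evidence)),
                 expected_freq = stats::setNames(alpha / sum(alpha),
                                                 colnames(evidence)),
                 ep = stats::setNames(ep, colnames(evidence)),
                 bor = bor,
                 pxp = stats::setNames(pxp, colnames(evidence)),
                 iterations = iter, converged = converged,
                 responsibilities = u),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  tab <- rbind(alpha = x$alpha, freq = x$expected_freq, EP = x$ep,
               PXP = x$pxp)
  print(round(tab, 4))
  cat(sprintf("BOR = %.4f (%d iterations%s)\n", x$bor, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# Monte-Carlo exceedance probabilities from a Dirichlet posterior.
exceedance_probability <- function(alpha, n_samples = 1e5L, seed = 1L) {
  M <- length(alpha)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- matrix(stats::rgamma(n_samples * M, shape = rep(alpha,
                                                       each = n_samples)),
              n_samples, M)
  win <- max.col(g, ties.method = "random")
  tabulate(win, M) / n_samples
}

# Variational free energy of the random-effects model minus that of the
# equal-frequency null; BOR = 1 / (1 + exp(F1 - F0)).
bayesian_omnibus_risk <- function(evidence, u, alpha, a0) {
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) + sum((alpha - a0) * elog_r)
  upos <- u[u > 0]
  f1 <- sum(u * sweep(evidence, 2L, elog_r, "+")) - sum(upos * log(upos)) -
    kl_dir
  # null: fixed equal frequencies; exact log evidence
  M <- ncol(evidence)
  mx <- apply(evidence, 1L, max)
  f0 <- sum(mx + log(rowMeans(exp(evidence - mx))))
  1 / (1 + exp(f1 - f0))
}
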