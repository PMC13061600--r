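#' Define a rock-paper-scissors-style game
#'
#' Games are circular-dominance matching games with `n_actions` actions
#' arranged on a circle: each action beats the action exactly one step
#' behind it and loses to the action one step ahead, so dominance is
#' circular and nontransitive. Actions are 0-indexed internally; session
#' files may use 1-indexed on-screen labels, which the readers convert.
#'
#' @param n_actions Number of actions (3 or 4 in the experiments; any
#'   integer >= 3 is accepted).
#' @param zero_sum Logical; if `TRUE` wins pay +1 and losses -1 (ties 0).
#'   If `FALSE` losses are replaced by `loss_payoff`.
#' @param loss_payoff Payoff of a lost round in the non-zero-sum variant
#'   (default 0: win +1, tie 0, loss 0).
#' @param label Free-text variant label.
#' @return An object of class `game_spec`.
#' @examples
#' g <- game_spec(3)
#' payoff_matrix(g)
#' @export
game_spec <- function(n_actions = 3L, zero_sum = TRUE, loss_payoff = 0,
                      label = NULL) {
  n_actions <- as.integer(n_actions)
  if (is.na(n_actions) || n_actions < 3L)
    stop("invalid game spec: n_actions must be an integer >= 3")
  if (is.null(label))
    label <- sprintf("%d-action %s", n_actions,
                     if (zero_sum) "zero-sum" else "non-zero-sum")
  structure(
    list(n_actions = n_actions, zero_sum = isTRUE(zero_sum),
         loss_payoff = loss_payoff, label = label),
    class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat("Game:", x$label, "\n")
  invisible(x)
}

#' Build the payoff matrix of a circular-dominance game
#'
#' Row i / column j holds the payoff of playing action i against action j
#' (0-indexed actions map to row/column i+1). In the zero-sum variant
#' entry (i, j) is +1 when i is one step ahead of j on the circle
#' (`i == (j + 1) mod n`), -1 when j is one step ahead of i, and 0
#' otherwise. The non-zero-sum variant replaces every -1 by the spec's
#' `loss_payoff`.
#'
#' @param spec A [game_spec()].
#' @return An `n x n` numeric matrix with attribute `lambda_applied`
#'   (`NULL` until [scale_losses()] is used).
#' @export
payoff_matrix <- function(spec) {
  stopifnot(inherits(spec, "game_spec"))
  n <- spec$n_actions
  i <- matrix(0:(n - 1L), n, n)
  j <- t(i)
  pm <- matrix(0, n, n)
  pm[i == (j + 1L) %% n] <- 1
  pm[j == (i + 1L) %% n] <- -1
  if (!spec$zero_sum)
    pm[pm == -1] <- spec$loss_payoff
  attr(pm, "lambda_applied") <- NULL
  pm
}

#' Scale the loss entries of a payoff matrix
#'
#' Rescales the influence of losses in an agent's internal payoff matrix:
#' every -1 entry becomes -lambda, all other entries are unchanged.
#' `lambda = 1` leaves the matrix untouched; `lambda = 0` produces a
#' loss-blind agent. The scaled matrix is used inside the agent's
#' recursive reasoning, level likelihood, integrated response and choice
#' value; raw payoffs are what the game itself pays out.
#'
#' @param pi A payoff matrix from [payoff_matrix()].
#' @param lambda Non-negative loss weight.
#' @return The scaled matrix, with `lambda_applied` recorded.
#' @export
scale_losses <- function(pi, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0)
    stop("lambda must be a single non-negative number")
  pi[pi == -1] <- -lambda
  attr(pi, "lambda_applied") <- lambda
  pi
}

#' Resolve one round of the game
#'
#' @param a_self,a_opp 0-indexed actions of the two players.
#' @param pi The (unscaled) payoff matrix.
#' @return Named numeric vector `c(payoff_self, payoff_opp)`; the
#'   opponent's payoff is read from the opponent-perspective entry
#'   `pi[a_opp, a_self]`.
#' @export
round_outcome <- function(a_self, a_opp, pi) {
  n <- nrow(pi)
  if (a_self < 0L || a_self >= n || a_opp < 0L || a_opp >= n)
    stop("action index out of range [0, ", n - 1L, "]")
  c(payoff_self = pi[a_self + 1L, a_opp + 1L],
    payoff_opp  = pi[a_opp + 1L, a_self + 1L])
}
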