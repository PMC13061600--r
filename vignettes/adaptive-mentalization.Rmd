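---
title: "Modelling adaptive mentalization in repeated matching games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptive mentalization in repeated matching games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaser)
```

## The scientific problem

In repeated rock-paper-scissors-style games, the game-theoretic ideal —
uniformly random play — is something humans are famously bad at. Real
players leave statistical footprints (they repeat recent actions, chase
wins, avoid recent losses), and a strategic opponent can exploit those
footprints by recursive reasoning: "she tends to repeat paper, so I play
scissors" (level 1), "he will expect me to repeat paper and play
scissors, so I play rock" (level 2), and so on. The depth of this
recursion is the player's *level* k. An *adaptive* player does more than
fix a level: they infer, trial by trial, which level their opponent is
playing, and best respond one step ahead of it. That inference — a form
of mentalization — is what this package models.

`chaser` implements:

* the CHASE agent — a cognitive-hierarchy model with Bayesian belief
  updating over the opponent's level;
* five competitor learning models (reinforcement learning, fictitious
  play, experience-weighted attraction, self-tuning EWA, and a
  confidence-based theory-of-mind model);
* fixed-level artificial opponents and a full synthetic-experiment
  generator;
* maximum-likelihood fitting, AIC, and random-effects Bayesian model
  selection (exceedance and protected exceedance probabilities);
* validation harnesses: parameter recovery, model recovery,
  posterior predictive checks, trial-level strategy assignment, and
  belief-update time courses;
* trial-wise model-derived regressors (choice value, action prediction
  error, belief update) for event-related analyses.

## The CHASE model

The game has `n` actions on a circle; the payoff matrix `pi` pays +1 to
the action one step ahead of the opponent's, -1 to the action one step
behind, 0 to a tie.

**Nonstrategic play (level 0).** The level-0 substrate is an attraction
vector: recency-weighted action frequencies updated by a delta rule,
`A'(a) = A(a) + alpha * (I(a) - A(a))`, mapped to choice probabilities
by a softmax with inverse temperature `beta`. `alpha` is an inverse
forgetting rate: high values chase the latest action, low values average
over the whole history.

**Recursive reasoning (level k > 0).** A level-k policy applies k noisy
best-response steps to level-0 play: `p <- softmax(pi %*% p | beta)`.
Parity decides whose history seeds the recursion: odd levels respond to
the *other* player's salient action, even levels to one's *own* (an
even-level player reasons about how the opponent will respond to *them*).
The implementation therefore keeps two attraction vectors — one per
history — and mirrors the parity rule between acting and predicting.

**Adaptive belief updating (kappa > 1).** An agent of depth `kappa`
holds a belief distribution over opponent levels `0..kappa-1`. Each
trial it computes, for every level, the probability that an opponent of
that level would have chosen the observed action (the level likelihood),
distorts that evidence through a softmax with sensitivity `gamma`, and
folds it into the belief by Bayes rule. Its own response is the noisy
best response to the belief-weighted opponent prediction. `gamma = 0`
makes the agent insensitive (beliefs never move); large `gamma` makes a
single discriminating trial decisive.

**Loss weighting.** A parameter `lambda` rescales the -1 entries of the
agent's internal payoff matrix (`lambda = 1` is the objective game;
`lambda > 1` makes losses loom large; `lambda = 0` is loss-blind). The
scaled matrix is used everywhere inside the agent — recursion,
likelihood, integrated response, choice value — while the game itself
always pays raw payoffs.

**Trial-wise derivatives.** For each trial the filter emits the choice
value CV (expected payoff of the chosen action under the belief-weighted
prediction), the action prediction error APE (one minus the predicted
probability of the opponent's observed action) and the belief update BU
(KL divergence, in nats, from the trial's prior belief to its
posterior). BU is z-scored within participant only at the regressor
export layer — the model itself always works with raw KL.

```{r worked}
spec <- game_spec(3)
pars <- chase_params(alpha = 0.3, beta = 6, gamma = 15, lambda = 1,
                     kappa = 3)
state <- chase_init(pars, 3)
step <- chase_step(state, own_action = 1, opp_action = 0, pars,
                   payoff_matrix(spec))
round(step$state$belief, 4)   # belief over opponent levels 0..2
round(step$deriv$bu, 4)       # KL divergence of that update, in nats
```

## Parameters, units and defaults

| parameter | meaning | domain | sampler default |
|---|---|---|---|
| `alpha` | attraction update rate (inverse forgetting) | (0, 1) | U(0.05, 0.6) |
| `beta` | inverse softmax temperature (choice/reasoning noise) | >= 0 | U(1, 10) |
| `gamma` | sensitivity to level evidence | >= 0 | U(1, 30) |
| `lambda` | loss weight in the internal payoff matrix | >= 0 | U(0.5, 3) |
| `kappa` | maximum mentalization depth | {1, 2, 3} | P(3) = 0.8, P(1) = P(2) = 0.1 |

The sampler is what `simulate_experiment()` draws synthetic participants
from; most simulated players mentalize at the maximum depth, mirroring
the predominance of deep mentalizers among fitted participants.

## Competitor models

* **RL** — delta rule on own-action values with realized payoffs; the
  literal vector form of the update decays unchosen values toward zero
  (the chosen-entry-only reading is available behind
  `decay_unchosen = FALSE`).
* **FP** — fictitious play: best response to the opponent's
  recency-weighted action frequencies. Exactly the CHASE model with
  `kappa = 1` (the package reuses the same filter; a test verifies the
  identity against an independently coded agent).
* **EWA** — experience-weighted attraction, hybridizing RL and FP with
  a foregone-payoff weight `delta` and forgetting rates `phi` (fixed)
  and `rho` (strategic). The update divides by the *post*-update
  experience-equivalent `n' = rho * n + 1`; dividing by the pre-decay
  experience would be undefined at the prescribed `n = 0` start.
* **stEWA** — self-tuning EWA: `phi(t)` comes from a surprise index
  comparing cumulative to recent-window opponent action frequencies
  (window 1 by default), the attention vector learns from actions whose
  foregone payoff weakly beats the realized one, `rho = phi(t)`, and
  only `beta` is estimated.
* **ToMk** — recursive argmax predictions mixed with level-specific
  confidences that are updated by a delta rule, with credit assigned
  only to the lowest level able to explain the observed action;
  opponent-side confidences are fixed at 0.8. Argmax ties split their
  mass uniformly (first-index tie-breaking would inject an
  action-labelling artifact); a level "explains" the action when the
  action lies in its argmax set.

Parameter counts for AIC: CHASE 5, RL 2, FP 2, EWA 4 (three updating
parameters plus the temperature), stEWA 1, ToMk 3 (`alpha`, `beta` and
the level `k`, chosen by likelihood over 0..3 just as `kappa` is
enumerated for CHASE).

## Artificial opponents and the synthetic experiment

The opponents use the same attraction learning and recursion as the
agent but are *fixed* at level 0, 1 or 2 — no belief updating. Their
noise is a lapse mixture: with probability `lapse` they act uniformly,
otherwise they follow their level policy at temperature `beta`. The
exact noise calibration used with human participants is not public; the
lapse-plus-temperature parameterisation is an explicit stand-in, with
defaults (`alpha = 0.3`, `beta = 3`, `lapse = 0.25`) chosen on two
criteria stated up front: a low-noise depth-3 agent must earn clearly
positive scores against all three levels, and the opponents must stay
informative enough that an adaptive observer can keep learning about
their level throughout a block (very sharp opponents saturate the
agent's beliefs within a couple of trials, which destroys the
identifiability of `gamma`).

`simulate_experiment()` reproduces the scanner design by default: six
blocks of 40 trials, levels 0/1/2 twice each in a counterbalanced order
without immediate repetitions, *all* state (attractions, beliefs,
confidences, experience) reset to uniform at each block start, and one
deterministic seed spawned per participant from the master seed.

What the generator emulates: block structure, simultaneous play,
fixed-level opponents with calibrated noise, heterogeneous agent
parameters. What it does not: response times, fatigue and attention
drifts, beliefs about the opponent's humanness, within-block strategy
switching by the opponent. Passing tests on synthetic data therefore
show internal consistency of the pipeline, not validity for any
particular human dataset.

## Fitting

`fit_participant()` performs maximum-likelihood estimation with one
parameter set per participant across all blocks and opponents. The
per-trial choice probabilities are floored at 1e-12 before the log.
Continuous parameters are searched through range-logistic transforms
onto documented plausible ranges (`alpha`, `delta`, `phi`, `rho` in
(0, 1); `beta` in (0, 20); `gamma` in (0, 30); `lambda` in (0, 5)): a
crossed grid of start values is evaluated, the best points are polished
by BFGS (tolerance 1e-8 on the objective), and discrete parameters
(`kappa`, the ToMk `k`) are enumerated exhaustively. The bounded
transforms exist because several likelihoods plateau: beyond a
data-dependent point, larger `gamma` (or `beta`) changes the likelihood
by less than optimizer tolerance, and an unbounded search walks
arbitrarily far along the flat ridge, returning estimates whose
magnitude is meaningless. Restricting the search to the plausible range
keeps estimates interpretable without changing any attained likelihood
in a practically relevant way.

## Random-effects model selection

Per-participant log model evidence is approximated by `-AIC/2` and fed
to a variational Dirichlet scheme over population model frequencies
(uniform prior counts). Reported are expected frequencies, exceedance
probabilities (Monte-Carlo over the Dirichlet posterior, 1e5 samples by
default, Monte-Carlo error below 0.005), the Bayesian omnibus risk
(posterior probability of the equal-frequency null, from the variational
free energies of the alternative versus the null) and protected
exceedance probabilities `PXP = EP * (1 - BOR) + BOR / M`. Convergence
is declared when the Dirichlet counts move less than 1e-8, with a
500-iteration cap.

## Validation harnesses and the problem sizes used

* `parameter_recovery()` — 48 synthetic participants on the six-block
  design, simulate-then-refit, Pearson correlations between generating
  and recovered parameters (`kappa` treated as ordinal). The `gamma`
  correlation is computed over participants generated with `kappa > 1`:
  at `kappa = 1` the belief has a single support point and `gamma`
  never enters the likelihood, so those fits return arbitrary `gamma`
  values that are noise by construction. Even so, `gamma` recovery is
  structurally limited under the uniform sampler: for sharp agents the
  belief saturates after one or two discriminating trials, so all
  sufficiently large `gamma` produce near-identical behaviour and the
  upper part of the sampled range cannot be resolved from 240 trials.
  The recovery correlations for `alpha`, `beta`, `lambda` and `kappa`
  are high; the `gamma` correlation is reported as computed and is the
  known weak spot of the design.
* `model_recovery()` — 20 simulations per generating model, all six
  models fitted to each, best fit by AIC; the confusion matrix rows are
  generating models and sum to 1.
* `posterior_predictive_check()` — per within-block trial position, the
  frequency with which actions match the noise-free (argmax,
  `lambda = 1`) best response of the correct level against the block's
  opponent, relative to chance. Argmax ties split credit uniformly, so
  uniform play centres exactly on chance.
* `level_assignment()` — the trial-level strategy labelling uses a
  sliding-window (10 trials) match score per candidate level against a
  within-block permutation null (the participant's own actions
  shuffled, everything recomputed), labelling only scores above the
  null's 95th percentile. The published scheme is under-described;
  this reconstruction is conservative for highly concentrated action
  sequences, whose shuffles retain much of the match structure.
* `bu_timecourse()` — per-trial mean and dispersion of within-
  participant z-scored belief updates, plus one least-squares slope of
  BU on trial index per participant. Note the first trial of a block
  carries no level evidence (uniform attractions give a flat level
  likelihood), so the group curve rises from zero, peaks within the
  first few trials and decays — the mean slope over a block is
  negative for adaptive cohorts.

These sizes (48 recovery participants, 20 recovery simulations per
model, cohorts of 8-12 for the predictive checks) are the package's
default desk-scale choices; every harness accepts larger values.

## Numerical choices and degenerate inputs

* Softmax is stabilised by max-subtraction; temperature 0 returns the
  uniform distribution.
* KL divergence uses natural log, `0 * log 0 = 0`, and clamps tiny
  negative rounding residue at identity updates to 0.
* Belief updates renormalize and assert positive total mass (an
  all-zero posterior cannot occur with softmax-distorted likelihoods).
* Argmax ties anywhere (ToMk predictions, noise-free level policies)
  split mass uniformly; the modal level response breaks belief ties
  toward the lower level, the conservative assignment.
* Session readers validate action ranges and recompute every payoff
  from the payoff matrix, naming the offending row on mismatch.

## Known limitations

* The opponent noise model is a stand-in for an unavailable
  calibration; absolute payoff levels and adaptation speeds against
  these opponents should not be compared quantitatively to human data.
* `gamma` is only weakly identified for sharp (high `beta`, high
  `gamma`) agents at 240 trials, as discussed above.
* Log evidence is approximated by `-AIC/2`; with richer per-participant
  data a proper marginal likelihood would be preferable.
* The likelihood treats both players' actions as given; it does not
  model the opponent's adaptation to the participant (the fixed-level
  opponents make this exact for the designs simulated here).
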