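# The hybrid instrumental/Pavlovian learner: a Rescorla-Wagner stimulus-value
# tracker plus standard Q-learning on stimulus-action pairs, combined in a
# softmax choice rule with a Go-bias and a Pavlovian bias that couples the
# learned stimulus value to action initiation.

#' Agent parameters of the Go/NoGo learner
#'
#' Four parameters govern a subject's behavior in one block: the learning
#' rate `alpha` (delta-rule step size, in (0,1)), the softmax temperature
#' `beta` (> 0; action weights are divided by it, so larger values mean more
#' random choice), the Pavlovian bias `pi` (scales the learned stimulus value
#' into the Go weight: positive values promote approach to reward-predictive
#' cards and inhibition for loss-predictive ones), and the Go-bias `b_go`
#' (valence-independent additive tendency to respond).
#'
#' @param alpha learning rate, strictly inside (0, 1).
#' @param beta temperature, strictly positive.
#' @param pi Pavlovian bias, any real.
#' @param b_go Go-bias, any real.
#' @return an object of class `agent_params`.
#' @examples
#' agent_params(alpha = 0.2, beta = 2.7, pi = 0.6, b_go = 0.3)
#' @export
agent_params <- function(alpha, beta, pi = 0, b_go = 0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0)
    stop("`beta` must be strictly positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, pi = pi, b_go = b_go),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("Go/NoGo agent: alpha = %.3f, beta = %.3f, pi = %.3f, b_go = %.3f\n",
              x$alpha, x$beta, x$pi, x$b_go))
  invisible(x)
}

#' Learner state
#'
#' Running stimulus values `V(s)` and action values `Q(a|s)`, all initialized
#' at zero at the start of each block (each block introduces four new cards,
#' so no stimulus knowledge carries over).
#'
#' @param cards card labels tracked by the learner.
#' @return a list with named numeric vectors `V`, `Q_go`, `Q_nogo`.
#' @export
learner_state <- function(cards = CARD_LEVELS) {
  z <- setNames(numeric(length(cards)), cards)
  list(V = z, Q_go = z, Q_nogo = z)
}

#' Action weights for one card
#'
#' `W(Go) = Q(Go|s) + b_go + pi * V(s)` and `W(NoGo) = Q(NoGo|s)`: the
#' Pavlovian term perturbs only the Go weight, in proportion to the card's
#' learned value.
#'
#' @param state a [learner_state()].
#' @param card a single card label present in the state.
#' @param params an [agent_params()] object.
#' @return named numeric vector `c(go = , nogo = )`.
#' @export
action_weights <- function(state, card, params) {
  if (!card %in% names(state$V))
    stop("unknown card: ", card, call. = FALSE)
  c(go = unname(state$Q_go[card] + params$b_go + params$pi * state$V[card]),
    nogo = unname(state$Q_nogo[card]))
}

#' Probability of a Go response
#'
#' Two-option softmax with temperature `beta`, computed as the logistic of
#' the scaled weight difference: `P(Go) = logistic((W_go - W_nogo) / beta)`.
#' `P(Go) + P(NoGo) = 1` by construction.
#'
#' @param w_go,w_nogo action weights.
#' @param beta temperature, > 0.
#' @return probability of Go (vectorized).
#' @examples
#' p_go(1, 0, 1)  # 0.731...
#' @export
p_go <- function(w_go, w_nogo, beta) {
  if (any(beta <= 0)) stop("`beta` must be strictly positive", call. = FALSE)
  plogis((w_go - w_nogo) / beta)
}

#' Delta-rule update of the stimulus value
#'
#' `V(s) <- V(s) + alpha * (r - V(s))`; applied on every trial regardless of
#' the action taken. Other cards are untouched.
#'
#' @inheritParams action_weights
#' @param reward scaled feedback r.
#' @param alpha learning rate in (0, 1].
#' @return the updated state.
#' @export
update_stimulus_value <- function(state, card, reward, alpha) {
  if (!card %in% names(state$V)) stop("unknown card: ", card, call. = FALSE)
  state$V[card] <- state$V[card] + alpha * (reward - state$V[card])
  state
}

#' Delta-rule update of the chosen action's value
#'
#' Only `Q(a|s)` of the action actually taken for the shown card is updated.
#'
#' @inheritParams update_stimulus_value
#' @param action `"go"` or `"nogo"`.
#' @return the updated state.
#' @export
update_action_value <- function(state, card, action, reward, alpha) {
  if (!card %in% names(state$V)) stop("unknown card: ", card, call. = FALSE)
  slot <- if (action == "go") "Q_go" else "Q_nogo"
  state[[slot]][card] <- state[[slot]][card] +
    alpha * (reward - state[[slot]][card])
  state
}

#' Simulate a generative agent on a standard session
#'
#' Convenience wrapper: builds fresh block schedules and runs the agent as a
#' HighControl subject (contingency-driven outcomes in every block).
#'
#' @param params an [agent_params()] object or a list of one per block.
#' @param n_blocks,n_reps,contingency session geometry (defaults: 2 blocks of
#'   4 x 40 trials at 70/30 contingency).
#' @param reward_scale points-to-reward conversion (default 0.1).
#' @param seed integer seed.
#' @return trial records, as from [run_session()].
#' @export
simulate_agent <- function(params, n_blocks = 2L, n_reps = 40L,
                           contingency = 0.7, reward_scale = 0.1, seed) {
  seeds <- derive_seeds(seed, n_blocks + 1L)
  schedules <- lapply(seq_len(n_blocks), function(b)
    make_block_schedule(n_reps, contingency, seed = seeds[b], block = b))
  run_session("agent", "high", "sham", params, schedules,
              reward_scale = reward_scale, seed = seeds[n_blocks + 1L])
}

#' Negative log-likelihood of recorded choices
#'
#' Replays the learner over a subject's recorded trials (values reset at each
#' block boundary) and accumulates `-log P(a_t | history)` under the softmax
#' choice rule. The reward entering the value updates is the delivered
#' (Go-cost-inclusive) feedback times `reward_scale`.
#'
#' @param params an [agent_params()] object.
#' @param records trial records for a single subject (one or more blocks),
#'   ordered by trial within block.
#' @param reward_scale points-to-reward conversion (default 0.1).
#' @return the NLL; 0 for an empty record set.
#' @export
negative_log_likelihood <- function(params, records, reward_scale = 0.1) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  if (length(unique(records$subject_id)) > 1L)
    stop("records must belong to a single subject", call. = FALSE)
  seg <- records_to_segments(records, reward_scale)
  k <- length(seg$start)
  sum(gng_nll_segments(seg$card, seg$go, seg$reward, seg$start, seg$end,
                       rep(params$alpha, k), rep(params$beta, k),
                       rep(params$pi, k), rep(params$b_go, k)))
}

# Flatten ordered trial records into the C++ segment layout (one segment per
# block, values reset at each segment start).
records_to_segments <- function(records, reward_scale) {
  ord <- order(records$block, records$trial)
  records <- records[ord, , drop = FALSE]
  check_cards(records$card)
  blocks <- unique(records$block)
  start <- end <- integer(length(blocks))
  for (i in seq_along(blocks)) {
    idx <- which(records$block == blocks[i])
    start[i] <- min(idx); end[i] <- max(idx)
  }
  list(card = match(records$card, CARD_LEVELS),
       go = as.integer(records$response == "go"),
       reward = records$delivered_points * reward_scale,
       start = start, end = end)
}

#' Subject-wise maximum-likelihood fit
#'
#' Fits `alpha`, `beta`, `pi`, `b_go` for a single subject by minimizing the
#' replay NLL, optimizing on an unconstrained scale (logit for alpha, log for
#' beta) with multiple restarts.
#'
#' @inheritParams negative_log_likelihood
#' @param n_starts number of random restarts.
#' @param seed seed for the restart jitter.
#' @return list with `params` ([agent_params()]), `nll`, and `convergence`.
#' @export
fit_subject_ml <- function(records, reward_scale = 0.1, n_starts = 5L,
                           seed = 1L) {
  seg <- records_to_segments(records, reward_scale)
  k <- length(seg$start)
  obj <- function(theta) {
    a <- plogis(theta[1]); b <- exp(min(max(theta[2], -10), 10))
    sum(gng_nll_segments(seg$card, seg$go, seg$reward, seg$start, seg$end,
                         rep(a, k), rep(b, k), rep(theta[3], k),
                         rep(theta[4], k)))
  }
  starts <- local_seed(seed, {
    m <- matrix(rnorm(4L * n_starts, 0, 0.8), n_starts, 4L)
    m[1, ] <- 0
    m
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 1000L))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  list(params = agent_params(alpha = plogis(theta[1]),
                             beta = exp(min(max(theta[2], -10), 10)),
                             pi = theta[3], b_go = theta[4]),
       nll = best$value, convergence = best$convergence)
}
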