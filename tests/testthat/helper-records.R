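# Builders for synthetic trial-record fixtures used across the tests.

all_cards <- c("go_win", "nogo_win", "go_avoid", "nogo_avoid")

# A balanced block of 4 x n_reps trials with a fixed response policy.
# `respond` maps a card label to "go"/"nogo"; outcomes follow the stated
# contingency deterministically (favorable on every trial by default).
policy_block_records <- function(respond, n_reps = 40L, block = 1L,
                                 favorable = TRUE) {
  card <- rep(all_cards, each = n_reps)
  response <- vapply(card, respond, character(1))
  fav <- rep(favorable, length.out = length(card))
  base <- resolve_outcome(card, response, fav)
  data.frame(
    subject_id = "t1", control = "high", tdcs = "sham",
    block = block, trial = seq_along(card), card = card,
    response = response, base_points = base,
    delivered_points = apply_go_cost(base, response),
    correct = response == card_required(card),
    stringsAsFactors = FALSE
  )
}

always_go <- function(card) "go"
always_nogo <- function(card) "nogo"
pavlovian_policy <- function(card) {
  if (card_valence(card) == "win") "go" else "nogo"
}
instrumental_policy <- function(card) card_required(card)

# Straight-line re-implementation of the choice model used as an independent
# likelihood oracle: explicit per-trial loop with named locals, no shared
# code with the package internals.
oracle_nll <- function(params, records, reward_scale = 0.1) {
  records <- records[order(records$block, records$trial), ]
  total <- 0
  for (b in unique(records$block)) {
    rb <- records[records$block == b, ]
    V <- c(go_win = 0, nogo_win = 0, go_avoid = 0, nogo_avoid = 0)
    Q <- matrix(0, 2, 4, dimnames = list(c("go", "nogo"), names(V)))
    for (t in seq_len(nrow(rb))) {
      s <- rb$card[t]
      w_go <- Q["go", s] + params$b_go + params$pi * V[s]
      w_nogo <- Q["nogo", s]
      p_go_t <- exp(w_go / params$beta) /
        (exp(w_go / params$beta) + exp(w_nogo / params$beta))
      chosen <- rb$response[t]
      p_chosen <- if (chosen == "go") p_go_t else 1 - p_go_t
      total <- total - log(p_chosen)
      r <- rb$delivered_points[t] * reward_scale
      V[s] <- V[s] + params$alpha * (r - V[s])
      Q[chosen, s] <- Q[chosen, s] + params$alpha * (r - Q[chosen, s])
    }
  }
  total
}
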