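# Task engine for the orthogonalized Go/NoGo task: schedules, probabilistic
# feedback with a Go-cost, and the card-specific yoked replay that removes
# outcome controllability in block 1 of LowControl sessions.

#' Card types of the orthogonalized Go/NoGo task
#'
#' The task crosses outcome valence (Win cards can pay +10 or 0; Avoid cards
#' pay 0 or -10) with the required instrumental response (Go or NoGo), giving
#' four card types. A card is Pavlovian-congruent when the required response
#' matches the Pavlovian tendency (approach reward, withhold under threat):
#' Go-to-Win and NoGo-to-Avoid.
#'
#' @return `card_types()` returns a data.frame with one row per card type and
#'   columns `card`, `valence`, `required_action` and `congruent`.
#' @examples
#' card_types()
#' @export
card_types <- function() {
  data.frame(
    card = CARD_LEVELS,
    valence = card_valence(CARD_LEVELS),
    required_action = card_required(CARD_LEVELS),
    congruent = card_congruent(CARD_LEVELS),
    stringsAsFactors = FALSE
  )
}

CARD_LEVELS <- c("go_win", "nogo_win", "go_avoid", "nogo_avoid")
RESPONSE_LEVELS <- c("go", "nogo")
CONTROL_LEVELS <- c("high", "low")
TDCS_LEVELS <- c("sham", "stim")

check_cards <- function(card) {
  bad <- !card %in% CARD_LEVELS
  if (any(bad))
    stop("unknown card label(s): ", paste(unique(card[bad]), collapse = ", "),
         call. = FALSE)
  invisible(card)
}

#' @rdname card_types
#' @param card character vector of card labels (`"go_win"`, `"nogo_win"`,
#'   `"go_avoid"`, `"nogo_avoid"`).
#' @export
card_valence <- function(card) {
  check_cards(card)
  ifelse(grepl("win$", card), "win", "avoid")
}

#' @rdname card_types
#' @export
card_required <- function(card) {
  check_cards(card)
  ifelse(grepl("^go_", card), "go", "nogo")
}

#' @rdname card_types
#' @export
card_congruent <- function(card) {
  # congruent iff the instrumental requirement matches the Pavlovian tendency
  (card_valence(card) == "win") == (card_required(card) == "go")
}

#' Build one block's trial schedule
#'
#' Generates a uniformly shuffled sequence of `4 * n_reps` trials (each card
#' type repeated `n_reps` times) and marks on which trials the correct
#' response leads to the favorable outcome. With the default fixed-proportion
#' mode each card carries exactly `round(contingency * n_reps)` favorable
#' trials, so a 70/30 response-feedback contingency is realized exactly;
#' `mode = "bernoulli"` instead draws each flag independently.
#'
#' @param n_reps repetitions per card type (40 in the standard two-block,
#'   160-trial design).
#' @param contingency probability that the correct response produces the good
#'   outcome (0.7 in the standard design).
#' @param seed integer seed; the schedule is a pure function of its arguments.
#' @param block block number stored in the schedule (1 or 2).
#' @param mode `"fixed"` (exact per-card proportion) or `"bernoulli"`.
#' @return data.frame with columns `block`, `trial`, `card`, `favorable`.
#' @examples
#' sched <- make_block_schedule(40, 0.7, seed = 1)
#' table(sched$card, sched$favorable)
#' @export
make_block_schedule <- function(n_reps, contingency, seed, block = 1L,
                                mode = c("fixed", "bernoulli")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 ||
      n_reps != round(n_reps))
    stop("`n_reps` must be a positive integer", call. = FALSE)
  if (!is.numeric(contingency) || contingency < 0 || contingency > 1)
    stop("`contingency` must lie in [0, 1]", call. = FALSE)
  n_reps <- as.integer(n_reps)
  card <- rep(CARD_LEVELS, each = n_reps)
  local_seed(seed, {
    if (mode == "fixed") {
      n_fav <- as.integer(round(contingency * n_reps))
      fav_per_card <- c(rep(TRUE, n_fav), rep(FALSE, n_reps - n_fav))
      favorable <- rep(fav_per_card, times = 4L)
    } else {
      favorable <- runif(length(card)) < contingency
    }
    ord <- sample.int(length(card))
    data.frame(
      block = as.integer(block),
      trial = seq_along(card),
      card = card[ord],
      favorable = favorable[ord],
      stringsAsFactors = FALSE
    )
  })
}

#' Resolve the base outcome of a trial
#'
#' The good outcome (+10 for Win cards, 0 for Avoid cards) is delivered iff
#' the correctness of the response matches the trial's favorable flag; the bad
#' outcome is 0 for Win cards and -10 for Avoid cards. Vectorized.
#'
#' @param card card label(s).
#' @param response `"go"` or `"nogo"`.
#' @param favorable logical; `TRUE` when the correct response yields the good
#'   outcome on this trial.
#' @return integer base points in \{-10, 0, +10\}, before the Go-cost.
#' @examples
#' resolve_outcome("go_win", "go", TRUE)     # +10
#' resolve_outcome("go_avoid", "nogo", TRUE) # -10 would need favorable FALSE:
#' resolve_outcome("go_avoid", "nogo", FALSE)
#' @export
resolve_outcome <- function(card, response, favorable) {
  check_cards(card)
  if (!all(response %in% RESPONSE_LEVELS))
    stop("`response` must be 'go' or 'nogo'", call. = FALSE)
  correct <- response == card_required(card)
  good <- correct == favorable
  win <- card_valence(card) == "win"
  as.integer(ifelse(win, ifelse(good, 10L, 0L), ifelse(good, 0L, -10L)))
}

#' Apply the Go-cost to a base outcome
#'
#' Any outcome that follows an active (Go) response is penalized by one point,
#' so +10 / 0 / -10 become 9 / -1 / -11; NoGo outcomes are unchanged.
#'
#' @param base_points integer base outcome(s) in \{-10, 0, +10\}.
#' @param response `"go"` or `"nogo"`.
#' @return delivered points after the Go-cost.
#' @examples
#' apply_go_cost(c(10, 0, -10), "go")  # 9 -1 -11
#' @export
apply_go_cost <- function(base_points, response) {
  if (!all(base_points %in% c(-10L, 0L, 10L)))
    stop("`base_points` must be -10, 0 or +10", call. = FALSE)
  if (!all(response %in% RESPONSE_LEVELS))
    stop("`response` must be 'go' or 'nogo'", call. = FALSE)
  as.integer(base_points - (response == "go"))
}

#' Build card-specific yoked outcome streams from a source subject's block 1
#'
#' For the low-controllability manipulation, a LowControl subject replays the
#' outcomes earned by a paired HighControl subject in block 1, card by card:
#' the source's delivered outcomes are recorded with the Go-cost removed (a
#' Go-preceded 9 is stored as 10) and re-randomized in order within each card
#' label. When replayed, the target's own response determines only the
#' Go-cost, never the base outcome, which severs the response-outcome
#' contingency while matching reward/loss frequencies within the pair.
#'
#' @param source_block1 trial records (data.frame in the standard trial-table
#'   dialect) of the source subject's first block.
#' @param seed integer seed for the per-card re-randomization.
#' @return an object of class `yoked_streams`: a list of base-outcome vectors,
#'   one per card label.
#' @export
build_yoked_streams <- function(source_block1, seed) {
  x <- source_block1
  if (!all(c("card", "response", "delivered_points") %in% names(x)))
    stop("source records must contain card, response, delivered_points",
         call. = FALSE)
  counts <- table(factor(x$card, levels = CARD_LEVELS))
  if (length(unique(as.integer(counts))) != 1L || any(counts == 0L))
    stop("incomplete source block: each card must appear the same number ",
         "of times (got ", paste(counts, collapse = "/"), ")", call. = FALSE)
  base <- as.integer(x$delivered_points + (x$response == "go"))
  if (!all(base %in% c(-10L, 0L, 10L)))
    stop("source outcomes inconsistent with the Go-cost rule", call. = FALSE)
  streams <- local_seed(seed, {
    lapply(split(base, factor(x$card, levels = CARD_LEVELS)),
           function(v) v[sample.int(length(v))])
  })
  structure(streams, class = "yoked_streams", n_reps = as.integer(counts[1]))
}

#' Simulate one subject's task session
#'
#' Threads a learning agent through one or more block schedules, resolving
#' outcomes trial by trial. HighControl sessions draw outcomes from the
#' schedule's contingency in every block; LowControl sessions replace the
#' block-1 base outcome with the next item of the card's yoked stream
#' (regardless of the response), applying only the Go-cost to the subject's
#' own choices.
#'
#' @param subject_id subject identifier stored in the records.
#' @param control `"high"` or `"low"` outcome controllability group.
#' @param tdcs `"sham"` or `"stim"` stimulation arm.
#' @param agent either an [agent_params()] object (used in every block), a
#'   list of one per block, or a `function(card)` returning the probability of
#'   a Go response (a fixed policy, useful for closed-form checks).
#' @param schedules a list of block schedules from [make_block_schedule()]
#'   (or a single schedule data.frame).
#' @param yoked a `yoked_streams` object, required when `control = "low"`.
#' @param reward_scale factor converting delivered points to the learner's
#'   reward units (default 0.1: +10 points enter the update as +1).
#' @param seed integer seed; per-block substreams are derived from it.
#' @return data.frame of trial records in the standard dialect.
#' @export
run_session <- function(subject_id, control, tdcs, agent, schedules,
                        yoked = NULL, reward_scale = 0.1, seed) {
  control <- match.arg(control, CONTROL_LEVELS)
  tdcs <- match.arg(tdcs, TDCS_LEVELS)
  if (is.data.frame(schedules)) schedules <- split(schedules, schedules$block)
  n_blocks <- length(schedules)
  if (control == "low" && is.null(yoked))
    stop("LowControl sessions require a `yoked` stream for block 1",
         call. = FALSE)
  block_seeds <- derive_seeds(seed, n_blocks)
  agents <- if (is.function(agent) || inherits(agent, "agent_params"))
    rep(list(agent), n_blocks) else agent
  if (length(agents) != n_blocks)
    stop("`agent` must supply one parameter set per block", call. = FALSE)
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    stream <- if (control == "low" && b == 1L) yoked else NULL
    out[[b]] <- simulate_block(agents[[b]], schedules[[b]], stream,
                               reward_scale, block_seeds[b])
  }
  rec <- do.call(rbind, out)
  data.frame(subject_id = subject_id, control = control, tdcs = tdcs,
             rec, stringsAsFactors = FALSE, row.names = NULL)
}

# One block: sequential choice, outcome resolution, value updates.
simulate_block <- function(agent, schedule, yoked, reward_scale, seed) {
  n <- nrow(schedule)
  card <- schedule$card
  check_cards(card)
  required <- card_required(card)
  use_model <- !is.function(agent)
  if (use_model && !inherits(agent, "agent_params"))
    stop("`agent` must be an agent_params object or a policy function",
         call. = FALSE)
  pos <- setNames(rep(0L, 4L), CARD_LEVELS)  # yoked stream cursors
  V <- Qg <- Qn <- setNames(numeric(4L), CARD_LEVELS)
  response <- character(n)
  base <- integer(n)
  local_seed(seed, {
    u <- runif(n)
    for (t in seq_len(n)) {
      cd <- card[t]
      p <- if (use_model) {
        plogis((Qg[cd] + agent$b_go + agent$pi * V[cd] - Qn[cd]) / agent$beta)
      } else {
        agent(cd)
      }
      go <- u[t] < p
      response[t] <- if (go) "go" else "nogo"
      if (is.null(yoked)) {
        base[t] <- resolve_outcome(cd, response[t], schedule$favorable[t])
      } else {
        pos[cd] <- pos[cd] + 1L
        if (pos[cd] > length(yoked[[cd]]))
          stop("internal consistency error: yoked stream exhausted for card ",
               cd, call. = FALSE)
        base[t] <- yoked[[cd]][pos[cd]]
      }
      delivered <- base[t] - go
      if (use_model) {
        r <- delivered * reward_scale
        V[cd] <- V[cd] + agent$alpha * (r - V[cd])
        if (go) Qg[cd] <- Qg[cd] + agent$alpha * (r - Qg[cd])
        else    Qn[cd] <- Qn[cd] + agent$alpha * (r - Qn[cd])
      }
    }
  })
  data.frame(
    block = schedule$block,
    trial = schedule$trial,
    card = card,
    response = response,
    base_points = base,
    delivered_points = as.integer(base - (response == "go")),
    correct = response == required,
    stringsAsFactors = FALSE
  )
}
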