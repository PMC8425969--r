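# Hierarchical Bayesian estimation of the learner's parameters. Each of the
# four model parameters gets a group-level linear predictor over block,
# controllability, stimulation and all their interactions (dummy coding,
# HighControl-Sham block 1 as reference cell), plus a subject random
# intercept shared across blocks. Links: logit for alpha, log for beta,
# identity for pi and b_go. Sampling is an adaptive Metropolis-within-Gibbs
# scheme on the non-centered parameterization, with the replay likelihood
# evaluated in compiled code.

PARAM_NAMES <- c("alpha", "beta", "pi", "b_go")
DESIGN_TERMS <- c("intercept", "block", "control", "tdcs",
                  "block:control", "block:tdcs", "control:tdcs",
                  "block:control:tdcs")

#' Group-level design row
#'
#' Dummy (reference-cell) coding with HighControl-Sham, block 1 as the
#' reference: `block` = 1 for block 2, `control` = 1 for LowControl,
#' `tdcs` = 1 for the stimulated arm; interaction columns are products of
#' their parents.
#'
#' @param control `"high"` or `"low"` (vectorized).
#' @param tdcs `"sham"` or `"stim"`.
#' @param block 1 or 2.
#' @return a matrix with one row per input and the eight design columns.
#' @examples
#' build_design("low", "stim", 2)  # all regressors 1
#' @export
build_design <- function(control, tdcs, block) {
  if (!all(control %in% CONTROL_LEVELS)) stop("unknown control label",
                                              call. = FALSE)
  if (!all(tdcs %in% TDCS_LEVELS)) stop("unknown tdcs label", call. = FALSE)
  if (!all(block %in% c(1L, 2L))) stop("unknown block label", call. = FALSE)
  b <- as.numeric(block == 2)
  cc <- as.numeric(control == "low")
  s <- as.numeric(tdcs == "stim")
  m <- cbind(1, b, cc, s, b * cc, b * s, cc * s, b * cc * s)
  colnames(m) <- DESIGN_TERMS
  m
}

#' Map linked-scale predictors to natural-scale parameters
#'
#' Inverse-logit for the learning rate, exponential for the temperature,
#' identity for the Pavlovian bias and Go-bias.
#'
#' @param eta named numeric vector (or 4-column matrix) of linear predictors
#'   in the order alpha, beta, pi, b_go.
#' @return a list (or data.frame, for matrix input) of natural-scale values.
#' @examples
#' transform_to_natural(c(alpha = 0, beta = 0, pi = 0.5, b_go = -0.2))
#' @export
transform_to_natural <- function(eta) {
  if (is.matrix(eta)) {
    data.frame(alpha = plogis(eta[, 1]), beta = exp(eta[, 2]),
               pi = eta[, 3], b_go = eta[, 4])
  } else {
    list(alpha = unname(plogis(eta[1])), beta = unname(exp(eta[2])),
         pi = unname(eta[3]), b_go = unname(eta[4]))
  }
}

#' MCMC configuration
#'
#' The replication-scale default follows the study conventions for this model
#' family: six chains, 1000 warmup and 1000 retained draws each, and an
#' automated Gelman-Rubin screen at 1.05. [desk_mcmc_config()] is the reduced
#' configuration used by the test-bench and recovery runs (2 chains x 300/300).
#'
#' @param n_chains number of chains.
#' @param warmup adaptation iterations per chain (discarded).
#' @param draws retained iterations per chain.
#' @param rhat_threshold convergence screening threshold.
#' @param seed integer seed; chain seeds are derived from it.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 6L, warmup = 1000L, draws = 1000L,
                        rhat_threshold = 1.05, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), rhat_threshold = rhat_threshold,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
desk_mcmc_config <- function(seed) {
  mcmc_config(n_chains = 2L, warmup = 300L, draws = 300L, seed = seed)
}

#' Narrowest (highest-density) posterior interval
#'
#' Scans all contiguous windows of the sorted draws containing
#' `ceiling(mass * n)` points and returns the narrowest one. For unimodal
#' posteriors this is the usual HDI; a zero-width interval (all draws equal)
#' is returned with attribute `degenerate = TRUE`.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass interval mass (default 0.95).
#' @return named vector `c(lower = , upper = )`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) == 0L) stop("`draws` must be non-empty", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("`mass` must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  k <- min(n, max(2L, ceiling(mass * n)))
  if (n < 2L) {
    out <- c(lower = x[1], upper = x[1])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lo <- 1:(n - k + 1L)
  widths <- x[lo + k - 1L] - x[lo]
  i <- lo[which.min(widths)]
  out <- c(lower = x[i], upper = x[i + k - 1L])
  if (out[1] == out[2]) attr(out, "degenerate") <- TRUE
  out
}

#' Evidence ratio for the sign of a coefficient
#'
#' Posterior odds in the favored direction: with `p = P(b > 0)` the ratio is
#' `p / (1 - p)` when positive values dominate and `(1 - p) / p` otherwise;
#' `Inf` when every draw lies on one side.
#'
#' @param p_positive posterior probability that the coefficient is positive.
#' @return list with `value` and `direction` (`"positive"`/`"negative"`).
#' @examples
#' evidence_ratio(27 / 28)  # 27, positive
#' @export
evidence_ratio <- function(p_positive) {
  if (p_positive < 0 || p_positive > 1)
    stop("`p_positive` must be a probability", call. = FALSE)
  if (p_positive >= 0.5) {
    list(value = if (p_positive == 1) Inf else p_positive / (1 - p_positive),
         direction = "positive")
  } else {
    list(value = if (p_positive == 0) Inf else (1 - p_positive) / p_positive,
         direction = "negative")
  }
}

#' Summarize posterior draws of one coefficient
#'
#' Posterior mean, 95% HDI, `P(b > 0)` and the evidence ratio in the favored
#' direction.
#'
#' @param draws numeric vector of draws (length >= 2).
#' @param mass HDI mass.
#' @return one-row data.frame.
#' @export
summarize_coefficient <- function(draws, mass = 0.95) {
  if (length(draws) < 2L) stop("need at least two draws", call. = FALSE)
  h <- hdi(draws, mass)
  p <- mean(draws > 0)
  er <- evidence_ratio(p)
  data.frame(mean = mean(draws), sd = sd(draws),
             hdi_low = unname(h[1]), hdi_high = unname(h[2]),
             p_positive = p, evidence_ratio = er$value,
             er_direction = er$direction, stringsAsFactors = FALSE)
}

#' Gelman-Rubin convergence statistic
#'
#' Classic potential-scale-reduction factor over parallel chains, floored at
#' 1 (values below 1 are sampling noise). Two identical chains give exactly
#' 1; chains exploring different regions give values well above the 1.05
#' screening threshold.
#'
#' @param x matrix of draws, iterations x chains.
#' @return the R-hat value.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L || ncol(x) < 2L) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2L, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

# ---------------------------------------------------------------------------
# Hierarchical fit

#' Fit the hierarchical model to a trial table
#'
#' Estimates, for each of the four learner parameters, eight group-level
#' coefficients (intercept, block, controllability, stimulation and all
#' interactions; dummy coding, HighControl-Sham block 1 reference), a
#' subject-level standard deviation, and subject random intercepts shared
#' across blocks. Priors are Normal(0, 1) on the coefficients (linked scale)
#' and Half-Normal(1) on the subject SDs. Sampling is adaptive
#' Metropolis-within-Gibbs on the non-centered parameterization with the
#' likelihood replayed in compiled code; after sampling, every monitored
#' group-level quantity is screened with the split-chain Gelman-Rubin
#' statistic and a convergence warning names any quantity above the
#' threshold.
#'
#' @param trials trial table in the standard dialect (>= 2 subjects).
#' @param config an [mcmc_config()].
#' @param reward_scale points-to-reward conversion used in the likelihood.
#' @param progress print per-chain progress.
#' @return an object of class `gng_fit` with elements `draws` (array
#'   iterations x chains x quantity), `rhat`, `subject_params` (posterior-mean
#'   natural-scale parameters per subject-block), `config`.
#' @export
fit_hierarchical <- function(trials, config, reward_scale = 0.1,
                             progress = FALSE) {
  if (!inherits(config, "mcmc_config")) stop("`config` must be an mcmc_config",
                                             call. = FALSE)
  prep <- prepare_fit_data(trials, reward_scale)
  if (prep$n_subjects < 2L)
    stop("hierarchical fit requires at least 2 subjects", call. = FALSE)
  one_cat <- tapply(prep$go, prep$seg_subject[prep$trial_seg],
                    function(g) length(unique(g)) == 1L)
  if (all(one_cat))
    warning("every subject produced a single response category; ",
            "subject-level parameters are weakly identified", call. = FALSE)

  qty_names <- c(as.vector(outer(DESIGN_TERMS, PARAM_NAMES,
                                 function(t, p) paste(p, t, sep = ":"))),
                 paste0("sigma_", PARAM_NAMES))
  chain_seeds <- derive_seeds(config$seed, config$n_chains + 1L)
  init_eta <- pooled_ml_init(prep, chain_seeds[config$n_chains + 1L])
  chains <- vector("list", config$n_chains)
  subj_acc <- 0
  for (ch in seq_len(config$n_chains)) {
    if (progress) message("chain ", ch, "/", config$n_chains)
    chains[[ch]] <- run_mwg_chain(prep, config$warmup, config$draws,
                                  chain_seeds[ch], init_eta)
    subj_acc <- subj_acc + chains[[ch]]$subject_sum
  }
  draws <- array(NA_real_, dim = c(config$draws, config$n_chains,
                                   length(qty_names)),
                 dimnames = list(NULL, NULL, qty_names))
  for (ch in seq_len(config$n_chains)) draws[, ch, ] <- chains[[ch]]$draws

  rh <- apply(draws, 3L, rhat)
  bad <- names(rh)[is.finite(rh) & rh > config$rhat_threshold]
  if (length(bad) > 0L)
    warning("convergence screening failed (R-hat > ",
            config$rhat_threshold, ") for: ", paste(bad, collapse = ", "),
            call. = FALSE)

  subj_mean <- subj_acc / (config$n_chains * config$draws)
  subject_params <- data.frame(
    subject_id = prep$subjects$subject_id[prep$seg_subject],
    control = prep$subjects$control[prep$seg_subject],
    tdcs = prep$subjects$tdcs[prep$seg_subject],
    block = prep$seg_block,
    alpha = subj_mean[, 1], beta = subj_mean[, 2],
    pi = subj_mean[, 3], b_go = subj_mean[, 4],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(draws = draws, rhat = rh, subject_params = subject_params,
                 config = config, reward_scale = reward_scale,
                 n_subjects = prep$n_subjects),
            class = "gng_fit")
}

# Flatten a trial table into per-subject-block segments with design rows.
prepare_fit_data <- function(trials, reward_scale) {
  req <- c("subject_id", "control", "tdcs", "block", "trial", "card",
           "response", "delivered_points")
  miss <- setdiff(req, names(trials))
  if (length(miss) > 0L)
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trials <- trials[order(trials$subject_id, trials$block, trials$trial), ,
                   drop = FALSE]
  subjects <- unique(trials[, c("subject_id", "control", "tdcs")])
  rownames(subjects) <- NULL
  key <- paste(trials$subject_id, trials$block)
  seg_keys <- unique(key)
  nseg <- length(seg_keys)
  start <- end <- seg_block <- integer(nseg)
  seg_subject <- integer(nseg)
  for (i in seq_len(nseg)) {
    idx <- which(key == seg_keys[i])
    start[i] <- min(idx); end[i] <- max(idx)
    seg_block[i] <- trials$block[start[i]]
    seg_subject[i] <- match(trials$subject_id[start[i]],
                            subjects$subject_id)
  }
  X <- build_design(subjects$control[seg_subject],
                    subjects$tdcs[seg_subject], seg_block)
  list(card = match(trials$card, CARD_LEVELS),
       go = as.integer(trials$response == "go"),
       reward = trials$delivered_points * reward_scale,
       reward_points = trials$delivered_points,
       reward_scale = reward_scale,
       start = start, end = end, X = X,
       seg_subject = seg_subject, seg_block = seg_block,
       trial_seg = rep(seq_len(nseg), times = end - start + 1L),
       subjects = subjects, n_subjects = nrow(subjects))
}

# Segment NLL given the (nseg x 4) matrix of linked-scale predictors.
seg_nll_eta <- function(prep, eta) {
  gng_nll_segments(prep$card, prep$go, prep$reward, prep$start, prep$end,
                   plogis(eta[, 1]), exp(pmin(pmax(eta[, 2], -20), 20)),
                   eta[, 3], eta[, 4])
}

# Linked-scale starting point for the group intercepts: coordinate descent
# over a coarse grid of population-level values (subject effects at zero).
# Deterministic and robust at short series lengths, where subject-wise ML is
# unstable; cuts the burn-in distance and keeps chains off the shallow
# alpha/beta trade-off ridge. Each chain then jitters around it.
pooled_ml_init <- function(prep, seed) {
  grids <- list(qlogis(c(0.05, 0.1, 0.2, 0.35, 0.5, 0.7)),
                log(c(0.5, 1, 2, 3.5, 6, 10)),
                c(-0.6, 0, 0.3, 0.6, 1.2),
                c(-1, -0.5, 0, 0.3, 0.8))
  eta0 <- c(0, 0, 0, 0)
  total_nll <- function(e) {
    eta <- matrix(e, length(prep$start), 4L, byrow = TRUE)
    sum(seg_nll_eta(prep, eta))
  }
  for (pass in 1:2) {
    for (p in 1:4) {
      vals <- vapply(grids[[p]], function(v) {
        e <- eta0; e[p] <- v; total_nll(e)
      }, numeric(1))
      eta0[p] <- grids[[p]][which.min(vals)]
    }
  }
  eta0
}

# One adaptive Metropolis-within-Gibbs chain. Non-centered subject effects:
# eta_p(seg) = X %*% B[p, ] + sigma_p * Z[p, subject(seg)]. Component-wise
# random-walk proposals with Robbins-Monro scale adaptation during warmup
# (target acceptance 0.44); subject effects are updated in one vectorized
# sweep per parameter, which is valid because the likelihood factorizes over
# subjects given the group-level state. Each recorded iteration performs
# `n_scans` full Gibbs scans, trading walltime for mixing.
run_mwg_chain <- function(prep, warmup, draws, seed, init_eta = rep(0, 4L),
                          n_scans = 2L) {
  local_seed(seed, {
    n_sub <- prep$n_subjects
    nseg <- length(prep$start)
    B <- matrix(rnorm(32L, 0, 0.05), 4L, 8L)
    B[, 1L] <- B[, 1L] + init_eta
    log_sigma <- rep(log(0.5), 4L)
    Z <- matrix(rnorm(4L * n_sub, 0, 0.5), 4L, n_sub)
    ls_B <- matrix(log(0.1), 4L, 8L)
    ls_S <- rep(log(0.2), 4L)
    ls_Z <- matrix(log(0.3), 4L, n_sub)
    ls_T <- rep(log(0.2), 4L)
    ls_R <- rep(log(0.2), 4L)
    # running moments of B for the joint (Haario-style) coefficient proposal
    ls_J <- rep(log(1), 4L)
    cov_mean <- matrix(0, 4L, 8L)
    cov_S <- array(0, c(4L, 8L, 8L))
    cov_n <- 0L
    cov_chol <- vector("list", 4L)

    eta <- matrix(0, nseg, 4L)
    for (p in 1:4)
      eta[, p] <- prep$X %*% B[p, ] + exp(log_sigma[p]) * Z[p, prep$seg_subject]
    cur_nll <- seg_nll_eta(prep, eta)

    total <- warmup + draws
    out <- matrix(NA_real_, draws, 36L)
    subject_sum <- matrix(0, nseg, 4L)

    for (iter in seq_len(total)) {
      adapt <- iter <= warmup
      gam <- min(0.25, 2 / sqrt(iter))

      for (scan in seq_len(n_scans)) {
      # group-level coefficients
      for (p in 1:4) {
        for (j in 1:8) {
          prop <- B[p, j] + rnorm(1L, 0, exp(ls_B[p, j]))
          eta_new <- eta
          eta_new[, p] <- eta[, p] + prep$X[, j] * (prop - B[p, j])
          nll_new <- seg_nll_eta(prep, eta_new)
          la <- sum(cur_nll) - sum(nll_new) +
            dnorm(prop, 0, 1, log = TRUE) - dnorm(B[p, j], 0, 1, log = TRUE)
          if (is.finite(la) && log(runif(1L)) < la) {
            B[p, j] <- prop; eta <- eta_new; cur_nll <- nll_new
          }
          if (adapt)
            ls_B[p, j] <- ls_B[p, j] +
              gam * (min(1, exp(min(la, 0, na.rm = TRUE))) - 0.44)
        }
      }

      # joint coefficient update along the warmup-estimated posterior
      # covariance: cuts across the ridges (e.g. intercept vs arm contrast)
      # that component-wise walks traverse slowly
      for (p in 1:4) {
        if (is.null(cov_chol[[p]])) next
        step <- exp(ls_J[p]) * (2.38 / sqrt(8)) *
          drop(crossprod(cov_chol[[p]], rnorm(8L)))
        propB <- B[p, ] + step
        eta_new <- eta
        eta_new[, p] <- eta[, p] + drop(prep$X %*% step)
        nll_new <- seg_nll_eta(prep, eta_new)
        la <- sum(cur_nll) - sum(nll_new) +
          sum(dnorm(propB, 0, 1, log = TRUE) - dnorm(B[p, ], 0, 1, log = TRUE))
        if (is.finite(la) && log(runif(1L)) < la) {
          B[p, ] <- propB; eta <- eta_new; cur_nll <- nll_new
        }
        if (adapt)
          ls_J[p] <- ls_J[p] + gam * (min(1, exp(min(la, 0, na.rm = TRUE))) - 0.25)
      }

      # subject-level standard deviations (half-normal prior, log-scale walk)
      for (p in 1:4) {
        prop_ls <- log_sigma[p] + rnorm(1L, 0, exp(ls_S[p]))
        eta_new <- eta
        eta_new[, p] <- eta[, p] +
          (exp(prop_ls) - exp(log_sigma[p])) * Z[p, prep$seg_subject]
        nll_new <- seg_nll_eta(prep, eta_new)
        la <- sum(cur_nll) - sum(nll_new) +
          dnorm(exp(prop_ls), 0, 1, log = TRUE) + prop_ls -
          dnorm(exp(log_sigma[p]), 0, 1, log = TRUE) - log_sigma[p]
        if (is.finite(la) && log(runif(1L)) < la) {
          log_sigma[p] <- prop_ls; eta <- eta_new; cur_nll <- nll_new
        }
        if (adapt)
          ls_S[p] <- ls_S[p] + gam * (min(1, exp(min(la, 0, na.rm = TRUE))) - 0.44)
      }

      # subject random intercepts, vectorized accept/reject per subject
      for (p in 1:4) {
        propz <- Z[p, ] + rnorm(n_sub, 0, exp(ls_Z[p, ]))
        eta_new <- eta
        eta_new[, p] <- eta[, p] +
          exp(log_sigma[p]) * (propz - Z[p, ])[prep$seg_subject]
        nll_new <- seg_nll_eta(prep, eta_new)
        old_by_sub <- rowsum(cur_nll, prep$seg_subject)[, 1]
        new_by_sub <- rowsum(nll_new, prep$seg_subject)[, 1]
        la <- old_by_sub - new_by_sub +
          dnorm(propz, 0, 1, log = TRUE) - dnorm(Z[p, ], 0, 1, log = TRUE)
        acc <- is.finite(la) & log(runif(n_sub)) < la
        if (any(acc)) {
          Z[p, acc] <- propz[acc]
          seg_acc <- acc[prep$seg_subject]
          eta[seg_acc, p] <- eta_new[seg_acc, p]
          cur_nll[seg_acc] <- nll_new[seg_acc]
        }
        if (adapt)
          ls_Z[p, ] <- ls_Z[p, ] +
            gam * (pmin(1, exp(pmin(la, 0))) - 0.44)
      }

      # Interweaving moves. Both leave every linear predictor (and hence the
      # likelihood) unchanged, so they are evaluated on the priors alone;
      # they decorrelate the intercept from the subject effects and the
      # subject SD from their scale, which component-wise walks mix slowly.
      for (p in 1:4) {
        # translation: shift the intercept, absorb it in the subject effects
        delta <- rnorm(1L, 0, exp(ls_T[p]))
        sg <- exp(log_sigma[p])
        z_new <- Z[p, ] - delta / sg
        la <- dnorm(B[p, 1L] + delta, 0, 1, log = TRUE) -
          dnorm(B[p, 1L], 0, 1, log = TRUE) +
          sum(dnorm(z_new, 0, 1, log = TRUE) -
                dnorm(Z[p, ], 0, 1, log = TRUE))
        if (is.finite(la) && log(runif(1L)) < la) {
          B[p, 1L] <- B[p, 1L] + delta
          Z[p, ] <- z_new
        }
        if (adapt)
          ls_T[p] <- ls_T[p] + gam * (min(1, exp(min(la, 0, na.rm = TRUE))) - 0.44)

        # rescaling: change the SD, shrink/stretch the effects to compensate
        eps <- rnorm(1L, 0, exp(ls_R[p]))
        ls_new <- log_sigma[p] + eps
        z_new <- Z[p, ] * exp(-eps)
        la <- dnorm(exp(ls_new), 0, 1, log = TRUE) + ls_new -
          dnorm(exp(log_sigma[p]), 0, 1, log = TRUE) - log_sigma[p] +
          sum(dnorm(z_new, 0, 1, log = TRUE) -
                dnorm(Z[p, ], 0, 1, log = TRUE)) - n_sub * eps
        if (is.finite(la) && log(runif(1L)) < la) {
          log_sigma[p] <- ls_new
          Z[p, ] <- z_new
        }
        if (adapt)
          ls_R[p] <- ls_R[p] + gam * (min(1, exp(min(la, 0, na.rm = TRUE))) - 0.44)
      }
      }  # scans

      if (adapt) {
        cov_n <- cov_n + 1L
        for (p in 1:4) {
          d0 <- B[p, ] - cov_mean[p, ]
          cov_mean[p, ] <- cov_mean[p, ] + d0 / cov_n
          cov_S[p, , ] <- cov_S[p, , ] + outer(d0, B[p, ] - cov_mean[p, ])
        }
        if (cov_n >= 50L && cov_n %% 25L == 0L) {
          for (p in 1:4) {
            C <- cov_S[p, , ] / (cov_n - 1L) + diag(1e-8, 8L)
            cov_chol[[p]] <- tryCatch(chol(C), error = function(e) NULL)
          }
        }
      }

      if (!adapt) {
        d <- iter - warmup
        out[d, ] <- c(t(B), exp(log_sigma))
        subject_sum <- subject_sum +
          cbind(plogis(eta[, 1]), exp(pmin(pmax(eta[, 2], -20), 20)),
                eta[, 3], eta[, 4])
      }
    }
    list(draws = out, subject_sum = subject_sum)
  })
}

#' @export
print.gng_fit <- function(x, ...) {
  cat("Hierarchical Go/NoGo model fit\n")
  cat(sprintf("  subjects: %d   chains: %d   draws/chain: %d\n",
              x$n_subjects, x$config$n_chains, x$config$draws))
  cat(sprintf("  max R-hat (group level): %.3f\n",
              max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary table of a hierarchical fit
#'
#' One row per monitored group-level quantity: posterior mean, 95% HDI,
#' `P(b > 0)`, evidence ratio and R-hat.
#'
#' @param object a `gng_fit`.
#' @param mass HDI mass.
#' @param ... unused.
#' @return data.frame with one row per coefficient.
#' @export
summary.gng_fit <- function(object, mass = 0.95, ...) {
  qn <- dimnames(object$draws)[[3]]
  rows <- lapply(seq_along(qn), function(i) {
    s <- summarize_coefficient(as.vector(object$draws[, , i]), mass)
    cbind(data.frame(coefficient = qn[i], stringsAsFactors = FALSE), s,
          data.frame(rhat = unname(object$rhat[i])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format posterior draws
#'
#' @param fit a `gng_fit`.
#' @return data.frame with columns `coefficient`, `chain`, `draw`, `value`,
#'   suitable for CSV persistence.
#' @export
fit_draws <- function(fit) {
  d <- fit$draws
  qn <- dimnames(d)[[3]]
  n_it <- dim(d)[1]; n_ch <- dim(d)[2]
  data.frame(
    coefficient = rep(qn, each = n_it * n_ch),
    chain = rep(rep(seq_len(n_ch), each = n_it), times = length(qn)),
    draw = rep(seq_len(n_it), times = n_ch * length(qn)),
    value = as.vector(d),
    stringsAsFactors = FALSE
  )
}

#' Summarize a long-format draws table
#'
#' Rebuilds per-coefficient posterior summaries (mean, HDI, P(b>0), evidence
#' ratio) from a table as written by [fit_draws()].
#'
#' @param draws_df data.frame with columns `coefficient`, `chain`, `draw`,
#'   `value`.
#' @param mass HDI mass.
#' @return data.frame, one row per coefficient.
#' @export
summarize_draws_table <- function(draws_df, mass = 0.95) {
  pieces <- split(draws_df$value, draws_df$coefficient)
  out <- do.call(rbind, lapply(names(pieces), function(nm) {
    cbind(data.frame(coefficient = nm, stringsAsFactors = FALSE),
          summarize_coefficient(pieces[[nm]], mass))
  }))
  rownames(out) <- NULL
  out
}
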