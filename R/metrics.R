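# Model-free behavioral statistics for the Go/NoGo task: the Pavlovian
# performance index and its two sub-measures, accuracy and percent-Go tables,
# mixed between-within ANOVA with partial eta squared, Bonferroni adjustment,
# and Cohen's d with BCa bootstrap confidence intervals.

#' Reward-based invigoration
#'
#' The fraction of all Go responses that occurred on Win-valence trials:
#' `#(Go on Win) / #(Go)`. Undefined (`NA`) when the subject made no Go
#' response at all; on a balanced block 0.5 is the neutral baseline.
#'
#' @param records trial records of one subject-block.
#' @return a fraction in \[0, 1\], or `NA`.
#' @export
invigoration <- function(records) {
  go <- records$response == "go"
  if (!any(go)) return(NA_real_)
  sum(go & card_valence(records$card) == "win") / sum(go)
}

#' Punishment-based suppression
#'
#' Mirror image of [invigoration()]: the fraction of all NoGo responses made
#' on Avoid-valence trials. `NA` when no NoGo response was produced.
#'
#' @inheritParams invigoration
#' @return a fraction in \[0, 1\], or `NA`.
#' @export
suppression <- function(records) {
  ng <- records$response == "nogo"
  if (!any(ng)) return(NA_real_)
  sum(ng & card_valence(records$card) == "avoid") / sum(ng)
}

#' Pavlovian performance index
#'
#' The mean of reward-based invigoration and punishment-based suppression;
#' `NA` if either sub-measure is undefined.
#'
#' @inheritParams invigoration
#' @return the PPI, or `NA`.
#' @export
ppi <- function(records) {
  iv <- invigoration(records)
  sp <- suppression(records)
  if (is.na(iv) || is.na(sp)) return(NA_real_)
  (iv + sp) / 2
}

#' Per-subject behavioral summary
#'
#' PPI and its sub-measures for every subject x block in a trial table.
#'
#' @param trials trial table in the standard dialect.
#' @return data.frame with one row per subject x block: `invigoration`,
#'   `suppression`, `ppi`, `n_go`, `n_nogo`.
#' @export
behavioral_summary <- function(trials) {
  pieces <- split(trials, list(trials$subject_id, trials$block), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(subject_id = d$subject_id[1], control = d$control[1],
               tdcs = d$tdcs[1], block = d$block[1],
               invigoration = invigoration(d), suppression = suppression(d),
               ppi = ppi(d),
               n_go = sum(d$response == "go"),
               n_nogo = sum(d$response == "nogo"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$subject_id, out$block), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Accuracy and percent-Go per card type
#'
#' Response accuracy (fraction of trials on which the response matched the
#' card's required action) and the percentage of Go responses, per subject,
#' block and card type, with the card's valence and Pavlovian congruency
#' attached.
#'
#' @param trials trial table in the standard dialect.
#' @return data.frame with one row per subject x block x card.
#' @export
accuracy_percgo <- function(trials) {
  pieces <- split(trials,
                  list(trials$subject_id, trials$block, trials$card),
                  drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(subject_id = d$subject_id[1], control = d$control[1],
               tdcs = d$tdcs[1], block = d$block[1], card = d$card[1],
               valence = card_valence(d$card[1]),
               congruent = card_congruent(d$card[1]),
               accuracy = mean(d$correct),
               perc_go = mean(d$response == "go"),
               n_trials = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$subject_id, out$block, out$card), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mixed between-within ANOVA
#'
#' Classical univariate mixed-design ANOVA on a balanced table (one value per
#' subject and within-cell), with one between-subject factor and up to three
#' two-level within-subject factors. F ratios use the appropriate error
#' stratum (subject, or subject x within-interaction); with two-level within
#' factors sphericity holds exactly and no correction is needed. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` within each stratum.
#'
#' @param data data.frame in long format.
#' @param dv name of the numeric response column.
#' @param subject name of the subject identifier column.
#' @param between name of the between-subject factor column (or `NULL`).
#' @param within character vector of within-subject factor columns.
#' @return data.frame with columns `effect`, `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `degenerate`.
#' @export
mixed_anova <- function(data, dv, subject, between = NULL, within) {
  for (v in c(dv, subject, between, within))
    if (!v %in% names(data)) stop("column not found: ", v, call. = FALSE)
  if (anyNA(data[[dv]]))
    stop("missing values in `", dv, "` for subject(s): ",
         paste(unique(data[[subject]][is.na(data[[dv]])]), collapse = ", "),
         call. = FALSE)
  d <- data
  d$.subj <- factor(d[[subject]])
  for (v in c(between, within)) d[[v]] <- factor(d[[v]])
  # completeness: every subject must fill every within-cell exactly once
  cell <- interaction(d[, within, drop = FALSE], drop = FALSE)
  tab <- table(d$.subj, cell)
  bad <- rownames(tab)[apply(tab, 1L, function(r) any(r != 1L))]
  if (length(bad) > 0L)
    stop("unbalanced design: subject(s) with missing or duplicated cells: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(.subj/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- aov(form, data = d)
  res <- lapply(summary(fit), function(s) as.data.frame(s[[1]]))
  out <- do.call(rbind, lapply(res, function(tabl) {
    nm <- trimws(rownames(tabl))
    is_res <- nm == "Residuals"
    if (!any(is_res) || all(is_res)) return(NULL)
    ss_err <- tabl[is_res, "Sum Sq"]
    df_err <- tabl[is_res, "Df"]
    eff <- tabl[!is_res, , drop = FALSE]
    data.frame(effect = trimws(rownames(eff)),
               F = eff[, "Sum Sq"] / eff[, "Df"] / (ss_err / df_err),
               df_num = eff[, "Df"], df_den = df_err,
               p = pf(eff[, "Sum Sq"] / eff[, "Df"] / (ss_err / df_err),
                      eff[, "Df"], df_err, lower.tail = FALSE),
               partial_eta_sq = eff[, "Sum Sq"] /
                 (eff[, "Sum Sq"] + ss_err),
               degenerate = ss_err < sqrt(.Machine$double.eps),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' Multiplies raw p-values by the family size, capping at 1.
#'
#' @param p raw p-value(s).
#' @param family number of comparisons in the family.
#' @return adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, family) {
  if (family < 1L) stop("`family` must be >= 1", call. = FALSE)
  pmin(p * family, 1)
}

#' Unpaired Cohen's d
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled standard deviation over
#' both samples. Antisymmetric in its arguments.
#'
#' @param a,b numeric samples.
#' @return Cohen's d (NaN when the pooled variance is zero).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Cohen's d with a BCa bootstrap confidence interval
#'
#' The effect size used in estimation ("Cumming") plots: unpaired Cohen's d
#' with a bias-corrected and accelerated bootstrap interval over stratified
#' resamples (resampling within each group). Deterministic given `seed`.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param mass confidence mass (default 0.95).
#' @param seed integer seed.
#' @return an object of class `effect_size`: list with `d`, `ci_low`,
#'   `ci_high`, `n_boot`, `mass`, `seed`, `degenerate`.
#' @examples
#' cohens_d_bca(rnorm(25), rnorm(25, 0.5), n_boot = 500, seed = 1)
#' @export
cohens_d_bca <- function(a, b, n_boot = 5000L, mass = 0.95, seed) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  d <- cohens_d(a, b)
  dat <- data.frame(x = c(a, b), g = rep(1:2, c(length(a), length(b))))
  if (!is.finite(d)) {
    return(structure(list(d = d, ci_low = NA_real_, ci_high = NA_real_,
                          n_boot = n_boot, mass = mass, seed = seed,
                          degenerate = TRUE), class = "effect_size"))
  }
  stat <- function(dd, i) {
    x <- dd$x[i]
    cohens_d(x[dd$g == 1], x[dd$g == 2])
  }
  ci <- local_seed(seed, {
    bt <- boot::boot(dat, stat, R = n_boot, strata = dat$g)
    tryCatch(boot::boot.ci(bt, conf = mass, type = "bca")$bca[4:5],
             error = function(e) NULL)
  })
  degenerate <- is.null(ci)
  if (degenerate) ci <- c(d, d)
  structure(list(d = d, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 mass = mass, seed = seed, degenerate = degenerate),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f, %d%% BCa CI [%.3f, %.3f] (%d resamples)\n",
              x$d, round(100 * x$mass), x$ci_low, x$ci_high, x$n_boot))
  if (x$degenerate) cat("  (degenerate bootstrap distribution)\n")
  invisible(x)
}

#' Estimation-plot comparisons against a shared control group
#'
#' Computes Cohen's d with BCa intervals for each non-control group against a
#' shared control group (the design used to compare the three intervention
#' arms against HighControl-Sham), from a per-subject table of one value
#' each.
#'
#' @param values numeric vector, one value per subject.
#' @param groups group label per subject.
#' @param control_group label of the shared control group.
#' @param n_boot,mass,seed passed to [cohens_d_bca()].
#' @return data.frame with one row per comparison (`group`, `d`, `ci_low`,
#'   `ci_high`).
#' @export
estimation_vs_control <- function(values, groups, control_group,
                                  n_boot = 5000L, mass = 0.95, seed) {
  if (!control_group %in% groups)
    stop("control group not present: ", control_group, call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  ctrl <- values[groups == control_group]
  others <- setdiff(unique(groups), control_group)
  seeds <- derive_seeds(seed, length(others))
  out <- do.call(rbind, lapply(seq_along(others), function(i) {
    es <- cohens_d_bca(values[groups == others[i]], ctrl, n_boot = n_boot,
                       mass = mass, seed = seeds[i])
    data.frame(group = others[i], control = control_group, d = es$d,
               ci_low = es$ci_low, ci_high = es$ci_high,
               degenerate = es$degenerate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Combined group label
#'
#' Collapses the controllability and stimulation factors into the four-level
#' group factor used in the between-subject analyses (e.g. `"high_sham"`).
#'
#' @param control `"high"`/`"low"` vector.
#' @param tdcs `"sham"`/`"stim"` vector.
#' @return character vector of group labels.
#' @export
group_label <- function(control, tdcs) paste(control, tdcs, sep = "_")
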