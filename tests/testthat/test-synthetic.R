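test_that("zero coefficients produce the identity-transform parameters", {
  cf <- matrix(0, 4, 8, dimnames = dimnames(generating_coefficients()))
  cfg <- cohort_config(n_per_group = c(high_sham = 3L, high_stim = 3L,
                                       low_sham = 3L, low_stim = 3L),
                       coefficients = cf,
                       subject_sd = c(alpha = 0, beta = 0, pi = 0, b_go = 0),
                       seed = 1)
  tr <- draw_subject_parameters(cfg)
  expect_true(all(tr$params$alpha == 0.5))
  expect_true(all(tr$params$beta == 1))
  expect_true(all(tr$params$pi == 0))
  expect_true(all(tr$params$b_go == 0))
})

test_that("a block x control coefficient moves the right cell means", {
  cf <- generating_coefficients("none")
  cf["pi", "block:control"] <- 1.5
  cfg <- cohort_config(n_per_group = c(high_sham = 40L, high_stim = 40L,
                                       low_sham = 40L, low_stim = 40L),
                       coefficients = cf,
                       subject_sd = c(alpha = 0.1, beta = 0.1, pi = 0.1,
                                      b_go = 0.1),
                       seed = 2)
  p <- draw_subject_parameters(cfg)$params
  diff_by <- function(ctl) {
    b2 <- p$pi[p$control == ctl & p$block == 2]
    b1 <- p$pi[p$control == ctl & p$block == 1]
    mean(b2 - b1)
  }
  expect_gt(diff_by("low"), diff_by("high") + 1)
})

test_that("subject-level SD scales the between-subject spread", {
  base <- cohort_config(n_per_group = c(high_sham = 250L, high_stim = 250L,
                                        low_sham = 250L, low_stim = 250L),
                        subject_sd = c(alpha = 0.2, beta = 0.2, pi = 0.2,
                                       b_go = 0.2),
                        seed = 3)
  wide <- cohort_config(n_per_group = base$n_per_group,
                        subject_sd = c(alpha = 1, beta = 1, pi = 1,
                                       b_go = 1),
                        seed = 3)
  a1 <- draw_subject_parameters(base)$params$alpha
  a2 <- draw_subject_parameters(wide)$params$alpha
  expect_gt(var(a2), var(a1))
})

test_that("cohort generation is deterministic with the study structure", {
  cfg <- cohort_config(n_per_group = c(high_sham = 3L, high_stim = 3L,
                                       low_sham = 3L, low_stim = 3L),
                       n_reps = 5L, seed = 99)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$truth$params, co2$truth$params)
  expect_equal(nrow(co1$trials), 12L * 2L * 20L)
  expect_identical(behavioral_summary(co1$trials),
                   behavioral_summary(co2$trials))
})

test_that("yoked pairs share per-card reward/loss frequencies in block 1", {
  cfg <- cohort_config(n_per_group = c(high_sham = 3L, high_stim = 3L,
                                       low_sham = 3L, low_stim = 3L),
                       n_reps = 10L, seed = 17)
  co <- generate_cohort(cfg)
  tr <- co$trials
  for (arm in c("sham", "stim")) {
    lows <- unique(tr$subject_id[tr$control == "low" & tr$tdcs == arm])
    highs <- unique(tr$subject_id[tr$control == "high" & tr$tdcs == arm])
    for (k in seq_along(lows)) {
      lo1 <- tr[tr$subject_id == lows[k] & tr$block == 1, ]
      hi1 <- tr[tr$subject_id == highs[k] & tr$block == 1, ]
      for (cd in all_cards)
        expect_equal(table(lo1$base_points[lo1$card == cd]),
                     table(hi1$base_points[hi1$card == cd]))
    }
  }
})

test_that("oversized LowControl arms recycle sources with a warning", {
  cfg <- cohort_config(n_per_group = c(high_sham = 2L, high_stim = 2L,
                                       low_sham = 3L, low_stim = 2L),
                       n_reps = 5L, seed = 23)
  expect_warning(generate_cohort(cfg), "recycling")
})

test_that("the default layout reproduces the 103-subject arithmetic", {
  cfg <- cohort_config(seed = 1)
  subs <- pavbias:::cohort_subjects(cfg)
  expect_equal(nrow(subs), 103L)
  expect_equal(sum(subs$control == "low" & subs$tdcs == "stim"), 27L)
  # 103 subjects x 320 trials would give 32,960 rows
  expect_equal(nrow(subs) * 2L * 4L * cfg$n_reps, 32960L)
})

test_that("simulated PPI increases with the generating Pavlovian bias", {
  ppis <- vapply(c(-1, 0.5, 2.5), function(pv) {
    rec <- simulate_agent(agent_params(0.3, 1, pv, 0), n_blocks = 1L,
                          n_reps = 250L, seed = 31)
    ppi(rec)
  }, numeric(1))
  expect_true(all(diff(ppis) > 0))
})

test_that("a positive Pavlovian intercept lifts group PPI above 0.5", {
  cf <- generating_coefficients("none")
  cf["pi", "intercept"] <- 1.5
  cf["beta", "intercept"] <- log(0.5)
  cfg <- cohort_config(n_per_group = c(high_sham = 6L, high_stim = 6L,
                                       low_sham = 0L, low_stim = 0L),
                       coefficients = cf, n_reps = 40L, seed = 41)
  co <- generate_cohort(cfg)
  bs <- behavioral_summary(co$trials)
  expect_gt(mean(bs$ppi[bs$block == 1]), 0.5)
})

test_that("low-control cohorts show the reduced-Go-bias signature", {
  cfg <- cohort_config(n_per_group = c(high_sham = 8L, high_stim = 8L,
                                       low_sham = 8L, low_stim = 8L),
                       coefficients = generating_coefficients("full"),
                       seed = 53)
  co <- generate_cohort(cfg)
  bs <- behavioral_summary(co$trials)
  b1 <- bs[bs$block == 1, ]
  # the strong negative Go-bias effect under low control in block 1
  expect_lt(mean(b1$n_go[b1$control == "low"]),
            mean(b1$n_go[b1$control == "high"]))
})

test_that("ground truth round-trips through CSV", {
  cfg <- cohort_config(n_per_group = c(high_sham = 2L, high_stim = 2L,
                                       low_sham = 2L, low_stim = 2L),
                       n_reps = 5L, seed = 61)
  tr <- draw_subject_parameters(cfg)
  path <- tempfile(fileext = ".csv")
  write.csv(tr$params, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back, tr$params, tolerance = 1e-12)
  unlink(path)
})
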