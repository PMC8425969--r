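test_that("design rows dummy-code the reference cell and products", {
  expect_equal(unname(build_design("high", "sham", 1)[1, ]),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(build_design("low", "stim", 2)[1, ]),
               rep(1, 8))
  r <- build_design("low", "sham", 2)[1, ]
  expect_equal(unname(r[c("block", "control", "block:control")]), c(1, 1, 1))
  expect_equal(unname(r[c("tdcs", "block:tdcs", "control:tdcs",
                          "block:control:tdcs")]), c(0, 0, 0, 0))
  expect_error(build_design("medium", "sham", 1), "control")
})

test_that("link functions map the linear predictors to natural ranges", {
  nat <- transform_to_natural(c(alpha = 0, beta = 0, pi = 0.5, b_go = -0.2))
  expect_equal(nat$alpha, 0.5)
  expect_equal(nat$beta, 1)
  expect_equal(nat$pi, 0.5)
  expect_equal(nat$b_go, -0.2)
  expect_equal(transform_to_natural(c(-1.3863, 0, 0, 0))$alpha, 0.2,
               tolerance = 1e-4)
})

test_that("hdi returns the narrowest window of the requested mass", {
  x <- seq(0, 1, length.out = 1000)
  h <- hdi(x, 0.95)
  expect_equal(unname(h[2] - h[1]), 0.95, tolerance = 2e-3)

  # a spiked sample pulls the interval onto the spike, not the tails
  spiked <- c(rnorm(900, 0, 0.1), runif(100, -10, 10))
  hs <- hdi(spiked, 0.9)
  expect_lt(hs[2] - hs[1],
            diff(quantile(spiked, c(0.05, 0.95))) + 1e-9)
  expect_gte(mean(spiked >= hs[1] & spiked <= hs[2]), 0.9)

  # degenerate draws yield a flagged zero-width interval
  hd <- hdi(rep(3, 50))
  expect_equal(as.numeric(hd), c(3, 3))
  expect_true(attr(hd, "degenerate"))

  # symmetric unimodal draws: HDI close to the equal-tailed interval
  set.seed(1)
  z <- rnorm(20000)
  hz <- hdi(z, 0.95)
  et <- quantile(z, c(0.025, 0.975))
  expect_equal(unname(hz), unname(et), tolerance = 0.05)
  expect_error(hdi(numeric(0)), "non-empty")
  expect_error(hdi(1:10, mass = 1.2), "mass")
})

test_that("evidence ratios are the posterior odds of the favored sign", {
  er <- evidence_ratio(27 / 28)
  expect_equal(er$value, 27)
  expect_equal(er$direction, "positive")
  expect_equal(evidence_ratio(0.5)$value, 1)
  expect_equal(evidence_ratio(0)$value, Inf)
  expect_equal(evidence_ratio(0)$direction, "negative")
  # strictly increasing in p on the positive side
  ps <- seq(0.5, 0.99, by = 0.07)
  vals <- vapply(ps, function(p) evidence_ratio(p)$value, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("coefficient summaries report mean, HDI, P(b>0) and ER", {
  draws <- c(rep(-0.1, 1), rep(0.2, 27))
  s <- summarize_coefficient(draws)
  expect_equal(s$p_positive, 27 / 28)
  expect_equal(s$evidence_ratio, 27)
  neg <- summarize_coefficient(seq(-3, -1, length.out = 40))
  expect_equal(neg$evidence_ratio, Inf)
  expect_equal(neg$er_direction, "negative")
  expect_error(summarize_coefficient(1), "two draws")
})

test_that("split R-hat is 1 for identical chains and large for split ones", {
  x <- matrix(rnorm(400), 200, 2)
  same <- cbind(x[, 1], x[, 1])
  expect_equal(rhat(same), 1, tolerance = 1e-10)
  apart <- cbind(rnorm(200, 0), rnorm(200, 6))
  expect_gt(rhat(apart), 1.5)
})

test_that("a small hierarchical fit runs, converges structurally and is deterministic", {
  cfg <- cohort_config(
    n_per_group = c(high_sham = 3L, high_stim = 3L, low_sham = 3L,
                    low_stim = 3L),
    n_reps = 10L, seed = 314)
  co <- generate_cohort(cfg)
  mc <- mcmc_config(n_chains = 2L, warmup = 80L, draws = 60L, seed = 9)
  fit1 <- suppressWarnings(fit_hierarchical(co$trials, mc))
  expect_s3_class(fit1, "gng_fit")
  expect_equal(dim(fit1$draws), c(60L, 2L, 36L))
  expect_equal(nrow(fit1$subject_params), 24L)  # 12 subjects x 2 blocks
  expect_true(all(fit1$subject_params$alpha > 0 &
                    fit1$subject_params$alpha < 1))
  expect_true(all(fit1$subject_params$beta > 0))
  sm <- summary(fit1)
  expect_equal(nrow(sm), 36L)
  expect_true(all(sm$hdi_low < sm$hdi_high))

  fit2 <- suppressWarnings(fit_hierarchical(co$trials, mc))
  expect_identical(fit1$draws, fit2$draws)

  expect_error(fit_hierarchical(co$trials[co$trials$subject_id == "hsh01", ],
                                mc), "2 subjects")
})

test_that("a null Pavlovian bias is recovered as such", {
  cf <- generating_coefficients("none")
  cf["pi", "intercept"] <- 0
  cf["beta", "intercept"] <- log(0.5)
  cf["alpha", "intercept"] <- qlogis(0.35)
  cfg <- cohort_config(
    n_per_group = c(high_sham = 5L, high_stim = 5L, low_sham = 0L,
                    low_stim = 0L),
    coefficients = cf,
    subject_sd = c(alpha = 0.5, beta = 0.5, pi = 0, b_go = 0.5),
    n_reps = 20L, seed = 2718)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(
    fit_hierarchical(co$trials,
                     mcmc_config(n_chains = 2L, warmup = 150L, draws = 150L,
                                 seed = 4)))
  s <- summary(fit)
  pi0 <- s[s$coefficient == "pi:intercept", ]
  expect_true(pi0$hdi_low <= 0 && 0 <= pi0$hdi_high)
})

test_that("hierarchical estimates shrink relative to subject-wise ML", {
  co <- generate_cohort(recovery_cohort_config(seed = 99, n_per_arm = 5L))
  fit <- suppressWarnings(
    fit_hierarchical(co$trials,
                     mcmc_config(n_chains = 2L, warmup = 150L, draws = 150L,
                                 seed = 5)))
  subs <- unique(co$trials$subject_id)
  ml <- t(vapply(subs, function(s) {
    m <- fit_subject_ml(co$trials[co$trials$subject_id == s, ], seed = 1)
    c(m$params$pi, m$params$b_go)
  }, numeric(2)))
  hb <- fit$subject_params[fit$subject_params$block == 1, ]
  hb <- hb[match(subs, hb$subject_id), ]
  expect_lt(var(hb$pi), var(ml[, 1]))
  expect_lt(var(hb$b_go), var(ml[, 2]))
})

test_that("long-format draws round-trip into identical summaries", {
  cfg <- cohort_config(
    n_per_group = c(high_sham = 2L, high_stim = 2L, low_sham = 2L,
                    low_stim = 2L),
    n_reps = 8L, seed = 11)
  co <- generate_cohort(cfg)
  fit <- suppressWarnings(
    fit_hierarchical(co$trials,
                     mcmc_config(n_chains = 2L, warmup = 40L, draws = 40L,
                                 seed = 3)))
  long <- fit_draws(fit)
  expect_equal(nrow(long), 40L * 2L * 36L)
  s1 <- summary(fit)
  s2 <- summarize_draws_table(long)
  s2 <- s2[match(s1$coefficient, s2$coefficient), ]
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$hdi_low, s2$hdi_low)
})
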