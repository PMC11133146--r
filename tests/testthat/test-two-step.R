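test_that("configuration and parameter objects validate", {
  expect_error(two_step_config(common_transition_prob = 0.4), "0.5")
  expect_error(two_step_config(drift_bounds = c(0, 0.75)), "lower")
  expect_error(hybrid_params(alpha = 1.2), "alpha")
  expect_error(hybrid_params(w_mb = -1), "nonnegative")
})

test_that("simulated transitions are consistent and reproducible", {
  tr <- simulate_two_step(hybrid_params(), two_step_config(n_trials = 500),
                          seed = 61)
  tr2 <- simulate_two_step(hybrid_params(), two_step_config(n_trials = 500),
                           seed = 61)
  expect_identical(tr, tr2)
  # state follows choice and transition deterministically
  expect_identical(tr$state2,
                   ifelse(tr$transition == "common", tr$choice1,
                          3L - tr$choice1))
  expect_true(all(tr$reward %in% 0:1))
})

test_that("indifferent parameters produce uniform choices", {
  p0 <- hybrid_params(alpha = 0.5, w_mb = 0, w_mf1 = 0, w_mf2 = 0,
                      persev = 0)
  tr <- simulate_two_step(p0, two_step_config(n_trials = 10000), seed = 62)
  expect_lt(abs(mean(tr$choice1 == 1) - 0.5), 0.02)
  expect_lt(abs(mean(tr$choice2 == 1) - 0.5), 0.02)
  # uniform policies give exactly n * 2 * log(1/2)
  expect_equal(hybrid_loglik(p0, tr), nrow(tr) * 2 * log(0.5))
})

test_that("the likelihood matches a hand-stepped forward trace", {
  p <- hybrid_params(alpha = 0.5, w_mb = 1, w_mf1 = 1, w_mf2 = 1,
                     persev = 0.5)
  trials <- data.frame(
    trial = 1:3,
    choice1 = c(1L, 1L, 2L),
    transition = c("common", "common", "rare"),
    state2 = c(1L, 1L, 1L),
    choice2 = c(1L, 2L, 1L),
    reward = c(1L, 0L, 1L),
    rt1 = 0.5, rt2 = 0.5, missed = FALSE)
  # manual trace with alpha = 0.5, lambda = 1:
  # t1: all values zero -> p = 1/4; then Q2[1,1] = 0.5, QMF1[1] = 0.5
  # t2: QMB = (0.35, 0.15), v1 = (1.35, 0.15) incl. perseverance,
  #     stage-2 values (0.5, 0); then QMF1[1] = 0.25, Q2[1,2] = 0
  # t3: QMB = (0.35, 0.15), v1 = (1.10, 0.15), stage-2 values (0.5, 0)
  expected <- 2 * log(0.5) +
    log(stats::plogis(1.35 - 0.15)) + log(stats::plogis(0 - 0.5)) +
    log(stats::plogis(0.15 - 1.10)) + log(stats::plogis(0.5 - 0))
  expect_equal(hybrid_loglik(p, trials), expected)
})

test_that("per-trial choice probabilities are normalized (enumeration)", {
  p <- hybrid_params(alpha = 0.6, w_mb = 2, w_mf1 = 1.5, w_mf2 = 3,
                     persev = -0.4)
  base <- data.frame(trial = 1L, choice1 = 1L, transition = "common",
                     state2 = 1L, choice2 = 2L, reward = 1L,
                     rt1 = 0.5, rt2 = 0.5, missed = FALSE)
  ll1 <- hybrid_loglik(p, base)
  total <- 0
  for (c1 in 1:2) for (c2 in 1:2) {
    t2 <- data.frame(trial = 2L, choice1 = c1, transition = "common",
                     state2 = c1, choice2 = c2, reward = 0L,
                     rt1 = 0.5, rt2 = 0.5, missed = FALSE)
    total <- total + exp(hybrid_loglik(p, rbind(base, t2)))
  }
  expect_equal(total, exp(ll1))
})

test_that("the likelihood is invariant to a consistent relabeling", {
  p <- hybrid_params(alpha = 0.35, w_mb = 2.5, w_mf1 = 1, w_mf2 = 2,
                     persev = 0.2)
  tr <- simulate_two_step(p, two_step_config(n_trials = 300), seed = 63)
  flipped <- tr
  flipped$choice1 <- 3L - tr$choice1
  flipped$state2 <- 3L - tr$state2
  expect_equal(hybrid_loglik(p, flipped), hybrid_loglik(p, tr))
})

test_that("missed trials are skipped without touching the learner state", {
  p <- hybrid_params()
  tr <- simulate_two_step(p, two_step_config(n_trials = 100), seed = 64)
  ll <- hybrid_loglik(p, tr)
  miss_row <- tr[1, ]
  miss_row$missed <- TRUE
  tr_aug <- rbind(tr[1:50, ], miss_row, tr[51:100, ])
  expect_equal(hybrid_loglik(p, tr_aug), ll)
  expect_error(hybrid_loglik(list(alpha = NA, w_mb = 1, w_mf1 = 1,
                                  w_mf2 = 1, persev = 0), tr), "finite")
})

test_that("MAP estimation recovers the generating weights", {
  truth <- hybrid_params(alpha = 0.4, w_mb = 3, w_mf1 = 1, w_mf2 = 4,
                         persev = 0.3)
  tr <- simulate_two_step(truth, two_step_config(n_trials = 2000), seed = 65)
  fit <- fit_map(tr, n_starts = 5, seed = 65)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$w_mb - 3) / 3, 0.3)
  expect_lt(abs(fit$params$w_mf1 - 1) / 1, 0.3)
  expect_lt(abs(fit$params$alpha - 0.4), 0.15)
})

test_that("MAP approaches maximum likelihood as priors flatten", {
  truth <- hybrid_params(alpha = 0.5, w_mb = 2, w_mf1 = 1.5, w_mf2 = 3,
                         persev = 0)
  tr <- simulate_two_step(truth, two_step_config(n_trials = 800), seed = 66)
  flat <- list(logdens = function(par) 0,
               sample = freeoperant:::default_hybrid_priors()$sample)
  wide <- list(logdens = function(par) {
    sum(dnorm(par[2:5], 0, 1e4, log = TRUE))
  }, sample = flat$sample)
  f_ml <- fit_map(tr, priors = flat, n_starts = 5, seed = 1)
  f_wide <- fit_map(tr, priors = wide, n_starts = 5, seed = 1)
  expect_equal(unlist(f_wide$params[1:5]), unlist(f_ml$params[1:5]),
               tolerance = 0.02)
})

test_that("degenerate inputs are rejected", {
  tr <- simulate_two_step(hybrid_params(), two_step_config(n_trials = 60),
                          seed = 67)
  tr$missed <- TRUE
  expect_error(fit_map(tr), "at least 50")
})

test_that("engagement exclusion filters flag the defined violations", {
  tr <- simulate_two_step(hybrid_params(), two_step_config(n_trials = 200),
                          seed = 68)
  expect_true(two_step_exclusions(tr, 0.65, 0.05)$included)
  trm <- tr
  trm$missed[1:22] <- TRUE  # 11% missed
  em <- two_step_exclusions(trm)
  expect_false(em$included)
  expect_identical(em$reasons, "missed")
  trk <- tr
  trk$choice1 <- c(rep(1L, 190), rep(2L, 10))  # 95% same key
  ek <- two_step_exclusions(trk)
  expect_false(ek$included)
  expect_true("same_key" %in% ek$reasons)
  # implausibly fast responding relative to the cohort
  trf <- tr
  trf$rt1 <- trf$rt1 / 10
  trf$rt2 <- trf$rt2 / 10
  ef <- two_step_exclusions(trf, cohort_rt_mean = 0.65, cohort_rt_sd = 0.05)
  expect_false(ef$included)
  expect_true("fast_rt" %in% ef$reasons)
})

test_that("model-based agents show the reward-by-transition stay signature", {
  cfg <- two_step_config(n_trials = 2000)
  mb <- simulate_two_step(hybrid_params(w_mb = 5, w_mf1 = 0, persev = 0),
                          cfg, seed = 69)
  mf <- simulate_two_step(hybrid_params(w_mb = 0, w_mf1 = 5, persev = 0),
                          cfg, seed = 69)
  g_mb <- stay_switch_glm(mb)
  g_mf <- stay_switch_glm(mf)
  int_mb <- stats::coef(g_mb)["prev_reward:prev_common"]
  int_mf <- stats::coef(g_mf)["prev_reward:prev_common"]
  expect_gt(int_mb, int_mf)
  expect_gt(int_mb, 0.2)
  # the model-free agent instead carries a strong reward main effect
  expect_gt(stats::coef(g_mf)["prev_reward"], 0.2)
})
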