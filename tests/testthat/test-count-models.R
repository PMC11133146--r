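test_that("family variance formulas evaluate directly", {
  expect_identical(family_variance("nb2", 10, 5), 30)
  expect_identical(family_variance("nb1", 10, 2), 30)
  expect_identical(family_variance("poisson", 10), 10)
})

test_that("Poisson quadrature fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  d <- simulate_count_data(m_per_group = 10, sigma = 0.6, family = "poisson",
                           seed = 31)
  own <- fit_mixed_count(d, "poisson")
  ref <- lme4::glmer(entries ~ manipulation * group + (1 | participant_id),
                     d, stats::poisson(), nAGQ = 15)
  expect_equal(unname(coef(own)), unname(lme4::fixef(ref)), tolerance = 1e-3)
  # absolute log-likelihood scale cross-checked against the Laplace fit
  # (lme4 reports nAGQ > 1 deviances without the normalizing constants)
  ref_laplace <- lme4::glmer(entries ~ manipulation * group +
                               (1 | participant_id), d, stats::poisson(),
                             nAGQ = 1)
  expect_gte(own$logLik, as.numeric(stats::logLik(ref_laplace)) - 1e-4)
  expect_lt(own$logLik - as.numeric(stats::logLik(ref_laplace)), 0.5)
  expect_equal(own$sigma_id, sqrt(unlist(lme4::VarCorr(ref))[[1]]),
               tolerance = 1e-3)
  expect_equal(unname(own$se), unname(sqrt(diag(as.matrix(stats::vcov(ref))))),
               tolerance = 1e-2)
})

test_that("negative binomial and OLRE fits agree with an independent fitter", {
  skip_if_not_installed("glmmTMB")
  d <- simulate_count_data(m_per_group = 15, sigma = 0.6, family = "nb2",
                           disp = 3, seed = 32)
  d$manip_only <- NULL
  for (fam in c("nb1", "nb2")) {
    own <- fit_mixed_count(d, fam, formula = entries ~ manipulation)
    ref <- glmmTMB::glmmTMB(
      entries ~ manipulation + (1 | participant_id), d,
      family = if (fam == "nb1") glmmTMB::nbinom1() else glmmTMB::nbinom2())
    expect_equal(unname(coef(own)), unname(glmmTMB::fixef(ref)$cond),
                 tolerance = 0.02)
    # adaptive quadrature should do at least as well as the Laplace fit
    expect_gte(own$logLik, as.numeric(stats::logLik(ref)) - 0.05)
    expect_equal(own$dispersion, glmmTMB::sigma(ref), tolerance = 0.05)
  }
  d$obs <- factor(seq_len(nrow(d)))
  own <- fit_mixed_count(d, "olre", formula = entries ~ manipulation)
  ref <- glmmTMB::glmmTMB(entries ~ manipulation + (1 | participant_id) +
                            (1 | obs), d, family = stats::poisson())
  expect_equal(unname(coef(own)), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 0.02)
  expect_gte(own$logLik, as.numeric(stats::logLik(ref)) - 0.05)
})

test_that("NB fits collapse to the Poisson fit as dispersion vanishes", {
  d <- simulate_count_data(m_per_group = 10, sigma = 0.5, family = "poisson",
                           seed = 33)
  pois <- fit_mixed_count(d, "poisson", formula = entries ~ manipulation)
  p <- length(coef(pois))
  # evaluate the NB1/NB2 marginal log-likelihood at the Poisson optimum with
  # dispersion pinned near its boundary
  X <- stats::model.matrix(~ manipulation, d)
  id <- as.integer(factor(d$participant_id))
  m <- max(id)
  gh <- freeoperant:::gh_rule(15)
  warm <- new.env()
  Xb <- drop(X %*% coef(pois))
  ll_nb1 <- freeoperant:::agq_loglik("nb1", d$entries, Xb, id, m,
                                     pois$sigma_id, 1e-6, gh, warm)
  warm2 <- new.env()
  ll_nb2 <- freeoperant:::agq_loglik("nb2", d$entries, Xb, id, m,
                                     pois$sigma_id, 1e6, gh, warm2)
  expect_equal(ll_nb1, pois$logLik, tolerance = 1e-3)
  expect_equal(ll_nb2, pois$logLik, tolerance = 1e-3)
})

test_that("mixed-model coefficients are recovered within 3 standard errors", {
  d <- simulate_count_data(m_per_group = 67, sigma = 0.6, family = "poisson",
                           seed = 34)
  truth <- attr(d, "beta")
  fit <- fit_mixed_count(d, "poisson")
  expect_true(all(is.finite(fit$se)))
  expect_true(all(abs(coef(fit) - truth) <= 3 * fit$se))
})

test_that("dispersion ratio matches its defining arithmetic", {
  r <- dispersion_ratio(4545, df = 389)
  expect_equal(r$ratio, 11.683, tolerance = 1e-4)
  expect_lt(r$p, 0.001)
  expect_error(dispersion_ratio(10, df = 0), "positive")
})

test_that("dispersion ratio is near 1 for equidispersed data and flags overdispersion", {
  # calibration regime: low shrinkage (small random effect, modest counts),
  # where conditional Pearson residuals carry close to their nominal df
  beta_small <- c(1.5, -0.8, -0.1, -0.2, -0.3, 0.3, 0, 0.4, 0)
  d <- simulate_count_data(m_per_group = 45, beta = beta_small, sigma = 0.1,
                           family = "poisson", seed = 35)
  fit <- fit_mixed_count(d, "poisson", hessian = FALSE)
  r <- dispersion_ratio(fit)
  expect_identical(r$df, nrow(d) - 9L - 1L)
  expect_gt(r$ratio, 0.8)
  expect_lt(r$ratio, 1.2)
  # strongly overdispersed (NB1, variance ~ 11x the mean) data
  d2 <- simulate_count_data(m_per_group = 45, sigma = 0.6, family = "nb1",
                            disp = 10, seed = 36)
  fit2 <- fit_mixed_count(d2, "poisson", hessian = FALSE)
  expect_gt(dispersion_ratio(fit2)$ratio, 5)
  # a zero-residual fit has ratio 0
  fit2$pearson_resid[] <- 0
  expect_identical(dispersion_ratio(fit2)$ratio, 0)
})

test_that("interaction tests expose the 4-df block and simple contrasts", {
  d <- simulate_count_data(m_per_group = 20, sigma = 0.5, family = "poisson",
                           seed = 37)
  fit <- fit_mixed_count(d, "poisson")
  it <- interaction_tests(fit)
  expect_identical(it$overall$df, 4L)
  expect_gt(it$overall$chisq, 0)
  expect_identical(nrow(it$contrasts), 5L)
  # the simulated devaluation-by-extensive interactions are strong and positive
  dev_rows <- grep("devaluation x extensive", it$contrasts$contrast)[1:2]
  expect_true(all(it$contrasts$estimate[dev_rows] > 0))
  expect_true(all(it$contrasts$p[dev_rows] < 0.05))
  # zeroing the interaction coefficients collapses the statistic to zero
  fit0 <- fit
  fit0$coefficients[grep(":", names(fit0$coefficients))] <- 0
  expect_equal(interaction_tests(fit0)$overall$chisq, 0)
})

test_that("the interaction test keeps its size on null data", {
  # no interaction in truth: devaluation and group effects but no product term
  beta0 <- c(3.5, -1.5, -0.2, -0.4, -0.6, 0, 0, 0, 0)
  rej <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    d <- simulate_count_data(m_per_group = 12, beta = beta0, sigma = 0.5,
                             family = "poisson", seed = 500 + i)
    fit <- fit_mixed_count(d, "poisson")
    p <- interaction_tests(fit)$overall$p
    if (is.finite(p) && p < 0.05) rej <- rej + 1
  }
  # binomial(60, 0.05): observing more than 9 rejections is implausible
  expect_lte(rej, 9)
})

test_that("leave-one-out selection handles trivial inputs", {
  d <- simulate_count_data(m_per_group = 8, sigma = 0.4, family = "nb1",
                           disp = 3, seed = 38)
  sel <- loocv_select(d, families = "nb1", nodes = 9)
  expect_identical(sel$winner, "nb1")
  expect_true(is.finite(sel$mse["nb1"]))
  # constant counts are predicted (almost) exactly by any family
  dc <- d
  dc$entries <- 7L
  selc <- loocv_select(dc, families = "nb1",
                       formula = entries ~ 1, nodes = 9)
  expect_lt(selc$mse["nb1"], 1e-3)
})
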