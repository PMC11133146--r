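#' Two-step task configuration
#'
#' The sequential decision task used to dissociate model-based from
#' model-free learning: each stage-1 action commonly (probability 0.7) leads
#' to one of two second-stage states and rarely (0.3) to the other, with
#' the mapping reversed between the two actions. Each second-stage action
#' pays a unit reward with a probability that drifts across trials as a
#' Gaussian random walk with reflecting bounds.
#'
#' @param common_transition_prob Probability of the common transition.
#' @param n_trials Trials per session.
#' @param drift_sd Step SD of the reward-probability random walk.
#' @param drift_bounds Reflecting bounds of the reward probabilities.
#' @param p_miss Probability a simulated trial is missed (no response).
#' @return A `two_step_config` list.
#' @export
two_step_config <- function(common_transition_prob = 0.7,
                            n_trials = 200,
                            drift_sd = 0.025,
                            drift_bounds = c(0.25, 0.75),
                            p_miss = 0) {
  if (common_transition_prob <= 0.5 || common_transition_prob >= 1) {
    stop("common_transition_prob must be in (0.5, 1)", call. = FALSE)
  }
  if (drift_bounds[1] <= 0 || drift_bounds[2] >= 1 ||
      drift_bounds[1] >= drift_bounds[2]) {
    stop("drift_bounds must satisfy 0 < lower < upper < 1", call. = FALSE)
  }
  cfg <- list(common_transition_prob = common_transition_prob,
              n_trials = n_trials, drift_sd = drift_sd,
              drift_bounds = drift_bounds, p_miss = p_miss)
  class(cfg) <- "two_step_config"
  cfg
}

#' Hybrid model-based/model-free parameters
#'
#' The five-parameter hybrid reinforcement-learning model: one learning
#' rate, separate stage-1 model-based and model-free weights, a stage-2
#' model-free weight, and a perseverance (stage-1 choice stickiness) term.
#' The stage-1 model-free update backs up the obtained outcome with
#' eligibility `lambda` (fixed at 1 by default, so the single learning rate
#' carries the reward signal to stage 1).
#'
#' @param alpha Learning rate in (0, 1).
#' @param w_mb Stage-1 model-based weight (>= 0; inverse-temperature scale).
#' @param w_mf1 Stage-1 model-free weight (>= 0).
#' @param w_mf2 Stage-2 model-free weight (>= 0).
#' @param persev Perseverance: additive stickiness on repeating the
#'   previous stage-1 choice.
#' @param lambda Eligibility of the stage-2 prediction error in the stage-1
#'   model-free update.
#' @return A `hybrid_params` list.
#' @export
hybrid_params <- function(alpha = 0.4, w_mb = 3, w_mf1 = 1, w_mf2 = 4,
                          persev = 0.3, lambda = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (w_mb < 0 || w_mf1 < 0 || w_mf2 < 0) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  if (!all(is.finite(c(alpha, w_mb, w_mf1, w_mf2, persev, lambda)))) {
    stop("parameters must be finite", call. = FALSE)
  }
  p <- list(alpha = alpha, w_mb = w_mb, w_mf1 = w_mf1, w_mf2 = w_mf2,
            persev = persev, lambda = lambda)
  class(p) <- "hybrid_params"
  p
}

softmax2 <- function(v) {
  ev <- exp(v - max(v))
  ev / sum(ev)
}

#' Simulate a two-step task session from the hybrid model
#'
#' The agent's own softmax policies generate both choices: stage 1 from
#' `w_mb * Q_MB + w_mf1 * Q_MF1 + persev * repeat`, stage 2 from
#' `w_mf2 * Q2[state, ]`. Transitions are Bernoulli with the common
#' probability; rewards follow the drifting reward probabilities.
#'
#' @param params A [hybrid_params()].
#' @param config A [two_step_config()].
#' @param seed Integer seed.
#' @return Data frame of trials: `trial`, `choice1`, `transition`,
#'   `state2`, `choice2`, `reward`, `rt1`, `rt2`, `missed`.
#' @export
simulate_two_step <- function(params = hybrid_params(),
                              config = two_step_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_trials
  pc <- config$common_transition_prob
  bounds <- config$drift_bounds
  P <- matrix(runif(4, bounds[1], bounds[2]), 2, 2)  # state x action
  Q2 <- matrix(0, 2, 2)
  QMF1 <- c(0, 0)
  prev1 <- 0L
  out <- data.frame(trial = seq_len(n), choice1 = NA_integer_,
                    transition = NA_character_, state2 = NA_integer_,
                    choice2 = NA_integer_, reward = NA_integer_,
                    rt1 = NA_real_, rt2 = NA_real_, missed = FALSE)
  for (t in seq_len(n)) {
    if (config$p_miss > 0 && runif(1) < config$p_miss) {
      out$missed[t] <- TRUE
      P <- drift_probs(P, config)
      next
    }
    QMB <- c(pc * max(Q2[1, ]) + (1 - pc) * max(Q2[2, ]),
             (1 - pc) * max(Q2[1, ]) + pc * max(Q2[2, ]))
    v1 <- params$w_mb * QMB + params$w_mf1 * QMF1
    if (prev1 > 0) v1[prev1] <- v1[prev1] + params$persev
    c1 <- sample.int(2L, 1L, prob = softmax2(v1))
    common <- runif(1) < pc
    s2 <- if (common) c1 else 3L - c1
    c2 <- sample.int(2L, 1L, prob = softmax2(params$w_mf2 * Q2[s2, ]))
    r <- as.integer(runif(1) < P[s2, c2])
    # learning
    d1 <- Q2[s2, c2] - QMF1[c1]
    QMF1[c1] <- QMF1[c1] + params$alpha * d1
    d2 <- r - Q2[s2, c2]
    Q2[s2, c2] <- Q2[s2, c2] + params$alpha * d2
    QMF1[c1] <- QMF1[c1] + params$alpha * params$lambda * d2
    prev1 <- c1
    out$choice1[t] <- c1
    out$transition[t] <- if (common) "common" else "rare"
    out$state2[t] <- s2
    out$choice2[t] <- c2
    out$reward[t] <- r
    out$rt1[t] <- rlnorm(1, log(0.7), 0.3)
    out$rt2[t] <- rlnorm(1, log(0.6), 0.3)
    P <- drift_probs(P, config)
  }
  out
}

drift_probs <- function(P, config) {
  P <- P + rnorm(4, 0, config$drift_sd)
  lo <- config$drift_bounds[1]
  hi <- config$drift_bounds[2]
  # reflecting bounds
  P[P < lo] <- 2 * lo - P[P < lo]
  P[P > hi] <- 2 * hi - P[P > hi]
  pmin(pmax(P, lo), hi)
}

#' Log-likelihood of two-step choices under the hybrid model
#'
#' Forward recursion over trials: stage-2 action values are updated by the
#' reward prediction error with the learning rate; stage-1 model-free values
#' back up the obtained stage-2 value (and, with eligibility `lambda`, the
#' stage-2 prediction error); model-based stage-1 values combine the fixed
#' transition probabilities (0.7/0.3) with the best stage-2 action in each
#' state. Missed trials contribute nothing and trigger no updates. Returns
#' the summed log probability of the observed choices at both stages.
#'
#' @param params A [hybrid_params()] (or a named list with its fields).
#' @param trials A trial data frame as produced by [simulate_two_step()].
#' @param common_transition_prob The (known) common-transition probability
#'   used by the model-based evaluator.
#' @return Scalar log-likelihood.
#' @export
hybrid_loglik <- function(params, trials, common_transition_prob = 0.7) {
  if (!all(is.finite(unlist(params[c("alpha", "w_mb", "w_mf1", "w_mf2",
                                     "persev")])))) {
    stop("non-finite parameter", call. = FALSE)
  }
  lambda <- if (is.null(params$lambda)) 1 else params$lambda
  pc <- common_transition_prob
  alpha <- params$alpha
  w_mb <- params$w_mb
  w_mf1 <- params$w_mf1
  w_mf2 <- params$w_mf2
  persev <- params$persev
  # stage-2 action values Q2[state, action] and stage-1 model-free values
  # kept as scalars for speed; the recursion is inherently sequential
  q11 <- 0; q12 <- 0; q21 <- 0; q22 <- 0
  m1 <- 0; m2 <- 0
  prev1 <- 0L
  ll <- 0
  ch1 <- trials$choice1
  ch2 <- trials$choice2
  st2 <- trials$state2
  rew <- trials$reward
  missed <- trials$missed
  for (t in seq_len(nrow(trials))) {
    if (missed[t]) next
    mx1 <- if (q11 > q12) q11 else q12
    mx2 <- if (q21 > q22) q21 else q22
    v1 <- w_mb * (pc * mx1 + (1 - pc) * mx2) + w_mf1 * m1
    v2 <- w_mb * ((1 - pc) * mx1 + pc * mx2) + w_mf1 * m2
    if (prev1 == 1L) v1 <- v1 + persev
    else if (prev1 == 2L) v2 <- v2 + persev
    c1 <- ch1[t]
    ll <- ll + stats::plogis(if (c1 == 1L) v1 - v2 else v2 - v1,
                             log.p = TRUE)
    s <- st2[t]
    c2 <- ch2[t]
    qa <- if (s == 1L) q11 else q21
    qb <- if (s == 1L) q12 else q22
    ll <- ll + stats::plogis(w_mf2 * (if (c2 == 1L) qa - qb else qb - qa),
                             log.p = TRUE)
    qc <- if (c2 == 1L) qa else qb
    mf <- if (c1 == 1L) m1 else m2
    mf <- mf + alpha * (qc - mf)
    d2 <- rew[t] - qc
    qc_new <- qc + alpha * d2
    if (s == 1L) { if (c2 == 1L) q11 <- qc_new else q12 <- qc_new }
    else { if (c2 == 1L) q21 <- qc_new else q22 <- qc_new }
    mf <- mf + alpha * lambda * d2
    if (c1 == 1L) m1 <- mf else m2 <- mf
    prev1 <- c1
  }
  ll
}

default_hybrid_priors <- function() {
  list(
    logdens = function(par) {
      stats::dbeta(par[1], 2, 2, log = TRUE) +
        sum(dnorm(par[2:4], 0, 5, log = TRUE)) +
        dnorm(par[5], 0, 2, log = TRUE)
    },
    sample = function() {
      c(alpha = runif(1, 0.1, 0.9), w_mb = abs(rnorm(1, 0, 3)),
        w_mf1 = abs(rnorm(1, 0, 3)), w_mf2 = abs(rnorm(1, 0, 3)),
        persev = rnorm(1, 0, 1))
    }
  )
}

#' MAP estimation of the hybrid model
#'
#' Maximizes log-likelihood plus weakly-informative log-priors (Beta(2, 2)
#' on the learning rate, half-normal SD 5 on the weights via box bounds,
#' normal SD 2 on perseverance) with bounded quasi-Newton (L-BFGS-B) from
#' multiple random starts; the best start is returned.
#'
#' @param trials Trial data frame (>= 50 valid trials).
#' @param priors List with `logdens(par)` and `sample()` in the order
#'   (alpha, w_mb, w_mf1, w_mf2, persev); `NULL` for the defaults. Pass a
#'   flat `logdens` for maximum likelihood.
#' @param n_starts Number of random initializations.
#' @param seed Integer seed for the starts.
#' @param common_transition_prob Known common-transition probability.
#' @return A `hybrid_fit`: `params` ([hybrid_params()] at the optimum),
#'   `log_posterior`, `logLik` at the optimum, per-start results and
#'   convergence info.
#' @export
fit_map <- function(trials, priors = NULL, n_starts = 10, seed = 1L,
                    common_transition_prob = 0.7) {
  valid <- sum(!trials$missed)
  if (valid < 50) stop("need at least 50 valid trials", call. = FALSE)
  if (is.null(priors)) priors <- default_hybrid_priors()
  set.seed(seed)
  obj <- function(par) {
    p <- list(alpha = par[1], w_mb = par[2], w_mf1 = par[3], w_mf2 = par[4],
              persev = par[5], lambda = 1)
    -(hybrid_loglik(p, trials, common_transition_prob) + priors$logdens(par))
  }
  lower <- c(1e-3, 0, 0, 0, -10)
  upper <- c(1 - 1e-3, 20, 20, 20, 10)
  starts <- lapply(seq_len(n_starts), function(i) {
    s <- priors$sample()
    pmin(pmax(s, lower + 1e-6), upper - 1e-6)
  })
  results <- lapply(starts, function(s) {
    tryCatch(optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e9)),
             error = function(e) NULL)
  })
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    out <- list(params = NULL, converged = FALSE, starts = results,
                message = "all starts failed")
    class(out) <- "hybrid_fit"
    return(out)
  }
  vals <- vapply(results[ok], function(r) r$value, numeric(1))
  best <- results[ok][[which.min(vals)]]
  par <- best$par
  params <- hybrid_params(alpha = par[1], w_mb = par[2], w_mf1 = par[3],
                          w_mf2 = par[4], persev = par[5])
  out <- list(params = params,
              log_posterior = -best$value,
              logLik = hybrid_loglik(params, trials, common_transition_prob),
              converged = best$convergence == 0,
              n_starts = n_starts,
              n_ok = sum(ok),
              starts = results)
  class(out) <- "hybrid_fit"
  out
}

#' @export
print.hybrid_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("Hybrid model fit: FAILED (", x$message, ")\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf(
    "Hybrid MB/MF fit: alpha %.3f, w_mb %.2f, w_mf1 %.2f, w_mf2 %.2f, persev %.2f\n",
    p$alpha, p$w_mb, p$w_mf1, p$w_mf2, p$persev))
  cat(sprintf("  log posterior %.2f (%d/%d starts ok)\n",
              x$log_posterior, x$n_ok, x$n_starts))
  invisible(x)
}

#' Two-step engagement exclusion filters
#'
#' Flags a participant for exclusion when they missed more than 10% of
#' trials, when their mean response time lies more than 2 SD below or above
#' the cohort mean, or when more than 90% of stage-1 presses used the same
#' key.
#'
#' @param trials The participant's trial data frame.
#' @param cohort_rt_mean,cohort_rt_sd Cohort summary of per-participant
#'   mean response times for the SD criterion (omit to skip it).
#' @param max_missed,max_same_key Criterion thresholds.
#' @return List with `included` and a character vector of `reasons`.
#' @export
two_step_exclusions <- function(trials, cohort_rt_mean = NULL,
                                cohort_rt_sd = NULL, max_missed = 0.10,
                                max_same_key = 0.90) {
  reasons <- character(0)
  missed_frac <- mean(trials$missed)
  if (missed_frac > max_missed) reasons <- c(reasons, "missed")
  ok <- !trials$missed
  if (!is.null(cohort_rt_mean) && !is.null(cohort_rt_sd) &&
      is.finite(cohort_rt_mean) && is.finite(cohort_rt_sd) && any(ok)) {
    rt <- mean(c(trials$rt1[ok], trials$rt2[ok]), na.rm = TRUE)
    if (rt < cohort_rt_mean - 2 * cohort_rt_sd) reasons <- c(reasons, "fast_rt")
    if (rt > cohort_rt_mean + 2 * cohort_rt_sd) reasons <- c(reasons, "slow_rt")
  }
  if (any(ok)) {
    same <- max(table(factor(trials$choice1[ok], levels = 1:2))) / sum(ok)
    if (same > max_same_key) reasons <- c(reasons, "same_key")
  }
  list(included = length(reasons) == 0, reasons = reasons,
       missed_fraction = missed_frac)
}

#' Stay/switch signature analysis
#'
#' The classic two-step diagnostic: a logistic regression of staying with
#' the previous stage-1 choice on the previous trial's reward, transition
#' type and their interaction. Model-based control manifests as a
#' reward-by-transition interaction; model-free control as a reward main
#' effect.
#'
#' @param trials Trial data frame.
#' @return The fitted `glm` object.
#' @export
stay_switch_glm <- function(trials) {
  t2 <- trials[!trials$missed, ]
  n <- nrow(t2)
  if (n < 3) stop("too few valid trials", call. = FALSE)
  d <- data.frame(
    stay = as.integer(t2$choice1[-1] == t2$choice1[-n]),
    prev_reward = ifelse(t2$reward[-n] == 1, 1, -1),
    prev_common = ifelse(t2$transition[-n] == "common", 1, -1))
  stats::glm(stay ~ prev_reward * prev_common, data = d,
             family = stats::binomial())
}

#' Simulate-and-refit parameter recovery study
#'
#' Draws parameter vectors from the priors, simulates a session from each,
#' refits by MAP, and reports per-parameter rank correlations between true
#' and recovered values — the standard check that the likelihood carries
#' information about the model-based and model-free weights at the study's
#' trial counts.
#'
#' @param n_draws Number of simulated agents.
#' @param n_trials Trials per agent.
#' @param n_starts MAP restarts per agent.
#' @param seed Integer seed.
#' @param config A [two_step_config()] (its `n_trials` is overridden).
#' @return List with `truth` and `recovered` data frames and `rank_cor`.
#' @export
recovery_study <- function(n_draws = 30, n_trials = 1000, n_starts = 5,
                           seed = 1L, config = two_step_config()) {
  set.seed(seed)
  config$n_trials <- n_trials
  draw <- function() {
    hybrid_params(alpha = runif(1, 0.2, 0.8),
                  w_mb = runif(1, 0, 6),
                  w_mf1 = runif(1, 0, 6),
                  w_mf2 = runif(1, 1, 8),
                  persev = runif(1, -1, 1))
  }
  truths <- replicate(n_draws, draw(), simplify = FALSE)
  seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  rec <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    trials <- simulate_two_step(truths[[i]], config, seed = seeds[i])
    fit <- fit_map(trials, n_starts = n_starts, seed = seeds[i],
                   common_transition_prob = config$common_transition_prob)
    rec[[i]] <- fit$params
  }
  fields <- c("alpha", "w_mb", "w_mf1", "w_mf2", "persev")
  truth_df <- as.data.frame(lapply(fields, function(f)
    vapply(truths, `[[`, numeric(1), f)))
  rec_df <- as.data.frame(lapply(fields, function(f)
    vapply(rec, `[[`, numeric(1), f)))
  names(truth_df) <- names(rec_df) <- fields
  rank_cor <- vapply(fields, function(f)
    stats::cor(truth_df[[f]], rec_df[[f]], method = "spearman"), numeric(1))
  list(truth = truth_df, recovered = rec_df, rank_cor = rank_cor)
}
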