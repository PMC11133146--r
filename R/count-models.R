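#' @importFrom stats dnorm dpois dnbinom glm model.matrix nlminb pchisq pnorm
#'   poisson coef logLik quantile median pf sd var optim residuals
NULL

gh_rule <- function(n) {
  gq <- statmod::gauss.quad(n, kind = "hermite")
  list(x = gq$nodes, logw = log(gq$weights) + gq$nodes^2)
}

logsumexp_rows <- function(m) {
  K <- ncol(m)
  mx <- m[, 1]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, m[, k])
  s <- exp(m[, 1] - mx)
  for (k in seq_len(K)[-1]) s <- s + exp(m[, k] - mx)
  mx + log(s)
}

# observation log-likelihood and derivatives wrt the linear predictor
obs_loglik <- function(family, y, eta, disp) {
  mu <- exp(eta)
  switch(family,
    poisson = dpois(y, mu, log = TRUE),
    nb1 = dnbinom(y, size = mu / disp, mu = mu, log = TRUE),
    nb2 = dnbinom(y, size = disp, mu = mu, log = TRUE),
    stop("unknown family"))
}

obs_score <- function(family, y, eta, disp) {
  mu <- exp(eta)
  switch(family,
    poisson = list(d1 = y - mu, d2 = -mu),
    nb1 = {
      u <- mu / disp
      dldmu <- (digamma(y + u) - digamma(u) - log1p(disp)) / disp
      d2ldmu2 <- (trigamma(y + u) - trigamma(u)) / disp^2
      list(d1 = mu * dldmu, d2 = mu * dldmu + mu^2 * d2ldmu2)
    },
    nb2 = {
      th <- disp
      dldmu <- y / mu - (y + th) / (mu + th)
      d2ldmu2 <- -y / mu^2 + (y + th) / (mu + th)^2
      list(d1 = mu * dldmu, d2 = mu * dldmu + mu^2 * d2ldmu2)
    },
    stop("unknown family"))
}

# conditional modes of the participant random intercept: damped Newton with
# a per-participant monotone line search (the NB1 curvature can misbehave
# far from the mode)
find_modes <- function(family, y, Xb, id, m, sigma2, disp, b0) {
  b <- b0
  H_of <- function(b) {
    rowsum(obs_loglik(family, y, Xb + b[id], disp), id)[, 1] -
      b^2 / (2 * sigma2)
  }
  H <- H_of(b)
  tol_g <- 1e-9 * (1 + max(y))
  for (it in 1:100) {
    sc <- obs_score(family, y, Xb + b[id], disp)
    g1 <- rowsum(sc$d1, id)[, 1] - b / sigma2
    if (max(abs(g1)) < tol_g) break
    g2 <- pmin(rowsum(sc$d2, id)[, 1] - 1 / sigma2, -1e-10)
    step <- pmax(pmin(-g1 / g2, 2), -2)
    for (half in 1:15) {
      b_new <- b + step
      H_new <- H_of(b_new)
      worse <- H_new < H - 1e-11 * (1 + abs(H))
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
    H <- H_new
  }
  sc <- obs_score(family, y, Xb + b[id], disp)
  curv <- pmin(rowsum(sc$d2, id)[, 1] - 1 / sigma2, -1e-10)
  list(b = b, scale = 1 / sqrt(-curv))
}

# log marginal likelihood by adaptive Gauss-Hermite quadrature
agq_loglik <- function(family, y, Xb, id, m, sigma, disp, gh, warm_env) {
  sigma2 <- sigma^2
  b0 <- if (!is.null(warm_env$b) && length(warm_env$b) == m) warm_env$b
        else numeric(m)
  modes <- find_modes(family, y, Xb, id, m, sigma2, disp, b0)
  warm_env$b <- modes$b
  K <- length(gh$x)
  n <- length(y)
  # b values at shifted/scaled nodes: m x K
  bk <- outer(modes$scale * sqrt(2), gh$x) + modes$b
  eta_mat <- Xb + bk[id, , drop = FALSE]
  ll <- matrix(obs_loglik(family, y, as.vector(eta_mat), disp), n, K)
  h <- rowsum(ll, id) + dnorm(bk, 0, sigma, log = TRUE)
  lm_i <- log(sqrt(2) * modes$scale) +
    logsumexp_rows(sweep(h, 2, gh$logw, "+"))
  sum(lm_i)
}

# --- OLRE: Poisson with an extra observation-level normal intercept -------

# log m(y | a) = log \int Pois(y | exp(a + u)) N(u; 0, tau^2) du  (adaptive GH)
# returns also d/da log m when deriv = TRUE
olre_obs_logm <- function(y, a, tau, gh, deriv = FALSE) {
  tau2 <- tau^2
  # start at the prior-shrunk approximate mode (lambda ~ y), so Newton
  # converges in a few steps even for extreme linear predictors
  u <- pmax(pmin((log(pmax(y, 0.3)) - a) * tau2 / (1 + tau2), 15), -15)
  tol_g <- 1e-9 * (1 + max(y))
  for (it in 1:60) {
    elam <- exp(a + u)
    g1 <- y - elam - u / tau2
    if (max(abs(g1)) < tol_g) break
    u <- u + pmax(pmin(g1 / (elam + 1 / tau2), 2), -2)
  }
  elam <- exp(a + u)
  scl <- 1 / sqrt(elam + 1 / tau2)
  K <- length(gh$x)
  uk <- outer(scl * sqrt(2), gh$x) + u
  lamk <- a + uk
  elamk <- exp(lamk)
  hw <- y * lamk - elamk - lgamma(y + 1) -
    uk * uk / (2 * tau2) - (log(2 * pi) / 2 + log(tau)) +
    rep(gh$logw, each = length(a))
  logm <- log(sqrt(2) * scl) + logsumexp_rows(hw)
  out <- list(logm = logm)
  if (deriv) {
    w <- exp(hw - logm + log(sqrt(2) * scl))  # posterior weights, rows sum ~1
    e1 <- rowSums(w * elamk)
    e2 <- rowSums(w * elamk * elamk)
    out$d1 <- y - e1
    # d^2 log m / da^2 = -E[e^lambda] + Var(e^lambda); cap below zero so the
    # Newton mode search keeps a descent direction
    out$d2 <- pmin(-e1 + (e2 - e1 * e1), -1e-8)
  }
  out
}

agq_loglik_olre <- function(y, Xb, id, m, sigma, tau, gh, gh_in, warm_env) {
  sigma2 <- sigma^2
  # modes are solved to a tight tolerance so the objective stays a smooth
  # function of the parameters (finite-difference gradients rely on this);
  # the warm start only shortens the Newton path
  b <- if (!is.null(warm_env$b) && length(warm_env$b) == m) warm_env$b
       else numeric(m)
  om <- olre_obs_logm(y, Xb + b[id], tau, gh_in, deriv = TRUE)
  H <- rowsum(om$logm, id)[, 1] - b^2 / (2 * sigma2)
  tol_g <- 1e-9 * (1 + max(y))
  for (it in 1:40) {
    g1 <- rowsum(om$d1, id)[, 1] - b / sigma2
    g2 <- rowsum(om$d2, id)[, 1] - 1 / sigma2
    if (max(abs(g1)) < tol_g) break
    step <- pmax(pmin(g1 / g2, 2), -2)
    for (half in 1:12) {
      b_new <- b - step
      om_new <- olre_obs_logm(y, Xb + b_new[id], tau, gh_in, deriv = TRUE)
      H_new <- rowsum(om_new$logm, id)[, 1] - b_new^2 / (2 * sigma2)
      worse <- H_new < H - 1e-11 * (1 + abs(H))
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; om <- om_new; break }
    b <- b_new
    om <- om_new
    H <- H_new
  }
  warm_env$b <- b  # conditional modes, reused for fitted values
  curv <- rowsum(om$d2, id)[, 1] - 1 / sigma2
  scl <- 1 / sqrt(-curv)
  K <- length(gh$x)
  n <- length(y)
  bk <- outer(scl * sqrt(2), gh$x) + b
  a_mat <- Xb + bk[id, , drop = FALSE]
  lm_obs <- matrix(olre_obs_logm(y, as.vector(a_mat), tau, gh_in)$logm, n, K)
  h <- rowsum(lm_obs, id) + dnorm(bk, 0, sigma, log = TRUE)
  sum(log(sqrt(2) * scl) + logsumexp_rows(sweep(h, 2, gh$logw, "+")))
}

#' Fit a mixed-effects count regression by adaptive quadrature
#'
#' Fits `entries ~ manipulation * group + (1 | participant)` (or any fixed
#' formula supplied) by maximizing the marginal likelihood, integrating the
#' participant random intercept with adaptive Gauss-Hermite quadrature.
#' Supported conditional families: `poisson`; `nb1` (negative binomial with
#' linear, "quasi-Poisson" variance `mu * (1 + alpha)`); `nb2` (quadratic
#' variance `mu + mu^2 / theta`); and `olre`, a Poisson model with an
#' additional observation-level normal random intercept (the obervation
#' effect is itself integrated by an inner adaptive quadrature).
#'
#' @param data A [count_dataset()] (or any data frame with the response,
#'   fixed-effect covariates and a `participant_id` column).
#' @param family `"poisson"`, `"olre"`, `"nb1"` or `"nb2"`.
#' @param formula Fixed-effects formula (response on the left).
#' @param nodes Quadrature nodes for the participant integral (and the
#'   observation-level integral under `olre`).
#' @param start Optional start values (full parameter vector on the internal
#'   scale: fixed effects, `log sigma`, then `log` dispersion if any).
#' @param hessian Compute observed-information standard errors.
#' @return A `mixed_count_fit` with fixed-effect estimates and standard
#'   errors on the log scale, the random-intercept SD, the dispersion
#'   parameter, the marginal log-likelihood, conditional fitted means and
#'   Pearson residuals.
#' @export
fit_mixed_count <- function(data, family = c("poisson", "olre", "nb1", "nb2"),
                            formula = entries ~ manipulation * group,
                            nodes = 15, start = NULL, hessian = TRUE,
                            control = list(eval.max = 2000, iter.max = 1000)) {
  family <- match.arg(family)
  data <- droplevels(as.data.frame(data))
  X <- model.matrix(formula, data)
  y <- data[[as.character(formula[[2]])]]
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be nonnegative counts", call. = FALSE)
  }
  id_f <- factor(data$participant_id)
  id <- as.integer(id_f)
  m <- nlevels(id_f)
  p <- ncol(X)
  gh <- gh_rule(nodes)
  gh_in <- gh_rule(max(9, min(nodes, 11)))
  warm_env <- new.env(parent = emptyenv())

  has_disp <- family %in% c("nb1", "nb2", "olre")
  negll <- function(par) {
    beta <- par[1:p]
    sigma <- exp(par[p + 1])
    disp <- if (has_disp) exp(par[p + 2]) else NULL
    Xb <- drop(X %*% beta)
    ll <- tryCatch({
      if (family == "olre") {
        agq_loglik_olre(y, Xb, id, m, sigma, disp, gh, gh_in, warm_env)
      } else {
        agq_loglik(family, y, Xb, id, m, sigma, disp, gh, warm_env)
      }
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (is.null(start)) {
    g0 <- glm(formula, data = data, family = poisson())
    beta0 <- coef(g0)
    beta0[!is.finite(beta0)] <- 0
    disp0 <- switch(family,
      poisson = NULL,
      nb1 = log(max(mean(residuals(g0, "pearson")^2) - 1, 0.5)),
      nb2 = log(5),
      olre = log(0.7))
    start <- c(beta0, log(0.5), disp0)
  }
  n_par <- p + 1 + as.integer(has_disp)
  lower <- c(rep(-Inf, p), -6, if (has_disp) -6)
  upper <- c(rep(Inf, p), 3, if (has_disp) if (family == "olre") 3 else 6)
  opt <- nlminb(start, negll, lower = lower, upper = upper,
                control = control)
  par <- opt$par
  beta <- par[1:p]
  names(beta) <- colnames(X)
  sigma <- unname(exp(par[p + 1]))
  disp <- if (has_disp) unname(exp(par[p + 2])) else NULL

  vc <- matrix(NA_real_, n_par, n_par)
  se <- rep(NA_real_, p)
  if (hessian) {
    H <- tryCatch(numDeriv::hessian(negll, par), error = function(e) NULL)
    if (!is.null(H)) {
      vc_try <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc_try) && all(diag(vc_try)[1:p] > 0)) {
        vc <- vc_try
        se <- sqrt(diag(vc)[1:p])
      }
    }
  }

  # conditional fitted values and Pearson residuals
  Xb <- drop(X %*% beta)
  if (family == "olre") {
    negll(par)  # refresh conditional modes at the optimum
    b <- warm_env$b
    mu <- exp(Xb + b[id] + disp^2 / 2)
    vfun <- mu + (exp(disp^2) - 1) * mu^2
  } else {
    modes <- find_modes(family, y, Xb, id, m, sigma^2, disp, numeric(m))
    b <- modes$b
    mu <- exp(Xb + b[id])
    vfun <- switch(family,
      poisson = mu,
      nb1 = mu * (1 + disp),
      nb2 = mu + mu^2 / disp)
  }
  pearson <- (y - mu) / sqrt(vfun)
  df_resid <- length(y) - p - 1L - as.integer(family == "olre")

  fit <- list(family = family,
              coefficients = beta,
              se = se,
              vcov = vc[1:p, 1:p, drop = FALSE],
              sigma_id = sigma,
              dispersion = disp,
              logLik = -opt$objective,
              fitted = mu,
              ranef = stats::setNames(b, levels(id_f)),
              pearson_resid = pearson,
              df_residual = df_resid,
              n_obs = length(y),
              n_participants = m,
              nodes = nodes,
              formula = formula,
              data = data,
              X = X,
              converged = opt$convergence == 0,
              message = opt$message,
              par = par)
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  class(fit) <- "mixed_count_fit"
  fit
}

#' @export
print.mixed_count_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects count model (%s), %d obs / %d participants\n",
              x$family, x$n_obs, x$n_participants))
  cat(sprintf("  logLik %.2f; random-intercept SD %.3f", x$logLik, x$sigma_id))
  if (!is.null(x$dispersion)) {
    cat(sprintf("; dispersion %s = %.3f",
                switch(x$family, nb1 = "alpha", nb2 = "theta", olre = "tau"),
                x$dispersion))
  }
  cat("\nFixed effects (log scale):\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * pnorm(-abs(tab$z))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.mixed_count_fit <- function(object, ...) object$coefficients

#' @export
logLik.mixed_count_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par), class = "logLik")
}

#' @export
vcov.mixed_count_fit <- function(object, ...) object$vcov

#' Mean-variance relation of the supported count families
#'
#' @param family `"poisson"`, `"nb1"` or `"nb2"`.
#' @param mu Conditional mean.
#' @param disp Dispersion parameter (`alpha` for nb1, `theta` for nb2).
#' @return The conditional variance.
#' @export
#' @examples
#' family_variance("nb1", 10, 2)  # 30
#' family_variance("nb2", 10, 5)  # 30
family_variance <- function(family, mu, disp = NULL) {
  switch(family,
    poisson = mu,
    nb1 = mu * (1 + disp),
    nb2 = mu + mu^2 / disp,
    stop("unknown family"))
}

#' Overdispersion diagnostic (Pearson dispersion ratio)
#'
#' Ratio of the sum of squared Pearson residuals to the residual degrees of
#' freedom, with an upper-tail chi-square test. A ratio near 1 indicates
#' equidispersion; large values indicate the conditional family understates
#' the variance.
#'
#' @param x A `mixed_count_fit`, or a numeric Pearson chi-square statistic.
#' @param df Residual degrees of freedom (when `x` is numeric).
#' @return List with `ratio`, `pearson_chi2`, `df` and `p`.
#' @export
#' @examples
#' dispersion_ratio(4545, df = 389)$ratio
dispersion_ratio <- function(x, df = NULL) {
  if (inherits(x, "mixed_count_fit")) {
    chi2 <- sum(x$pearson_resid^2)
    df <- x$df_residual
  } else {
    chi2 <- x
    if (is.null(df)) stop("df required", call. = FALSE)
  }
  if (df <= 0) stop("residual df must be positive", call. = FALSE)
  list(ratio = chi2 / df, pearson_chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Leave-one-out cross-validated model selection
#'
#' For each candidate family, refits the mixed count model with one unit
#' held out at a time, predicts the held-out count and scores the family by
#' mean squared prediction error; the family with the lowest MSE wins.
#' `granularity = "observation"` leaves out single observations (predicting
#' them from the participant's conditional mode re-estimated from their
#' remaining observations); `"participant"` leaves out whole participants
#' (predicting from the population distribution of the intercept).
#'
#' @param data A [count_dataset()].
#' @param families Candidate families.
#' @param granularity `"observation"` or `"participant"`.
#' @param formula Fixed-effects formula.
#' @param nodes Quadrature nodes.
#' @param fold_rel_tol Relative convergence tolerance for the warm-started
#'   fold refits (the full fit always uses the default tolerance).
#' @return List with `mse` (named per family), `winner`, `failed` families
#'   and per-family prediction vectors.
#' @export
loocv_select <- function(data, families = c("olre", "nb1", "nb2"),
                         granularity = c("observation", "participant"),
                         formula = entries ~ manipulation * group,
                         nodes = 15, fold_rel_tol = 1e-6) {
  granularity <- match.arg(granularity)
  data <- droplevels(as.data.frame(data))
  y <- data[[as.character(formula[[2]])]]
  n <- nrow(data)
  mse <- stats::setNames(rep(NA_real_, length(families)), families)
  preds <- list()
  failed <- character(0)
  for (fam in families) {
    full <- tryCatch(
      fit_mixed_count(data, fam, formula, nodes, hessian = FALSE),
      error = function(e) NULL)
    if (is.null(full)) {
      failed <- c(failed, fam)
      warning(sprintf("family %s failed on the full data; excluded", fam))
      next
    }
    folds <- if (granularity == "observation") {
      lapply(seq_len(n), function(i) i)
    } else {
      split(seq_len(n), data$participant_id)
    }
    pred <- rep(NA_real_, n)
    ok <- TRUE
    for (fold in folds) {
      train <- data[-fold, , drop = FALSE]
      fit <- tryCatch(
        fit_mixed_count(train, fam, formula, nodes, start = full$par,
                        hessian = FALSE,
                        control = list(eval.max = 150, iter.max = 60,
                                       rel.tol = fold_rel_tol)),
        error = function(e) NULL)
      if (is.null(fit) || !all(is.finite(fit$coefficients))) {
        ok <- FALSE
        break
      }
      Xh <- model.matrix(formula, data[fold, , drop = FALSE])
      eta <- drop(Xh %*% fit$coefficients)
      extra <- if (fam == "olre") fit$dispersion^2 / 2 else 0
      if (granularity == "observation" &&
          as.character(data$participant_id[fold]) %in% names(fit$ranef)) {
        bi <- fit$ranef[as.character(data$participant_id[fold])]
        pred[fold] <- exp(eta + bi + extra)
      } else {
        pred[fold] <- exp(eta + fit$sigma_id^2 / 2 + extra)
      }
    }
    if (!ok) {
      failed <- c(failed, fam)
      warning(sprintf("family %s failed on a fold; excluded", fam))
      next
    }
    preds[[fam]] <- pred
    mse[fam] <- mean((y - pred)^2)
  }
  if (all(is.na(mse))) stop("no family produced LOOCV predictions",
                            call. = FALSE)
  list(mse = mse, winner = names(which.min(mse)), failed = failed,
       predictions = preds, granularity = granularity)
}

#' Interaction and simple-effect tests for the factorial count model
#'
#' Computes the overall Wald chi-square on the group-by-manipulation
#' interaction block (4 df in the full 3x3 design), the simple interaction
#' contrasts comparing the devaluation-versus-pre-devaluation-control change
#' across group pairs, and the simple group effects on the pre-devaluation
#' (reference) day.
#'
#' @param fit A `mixed_count_fit` of the factorial model.
#' @return List with `overall` (`chisq`, `df`, `p`) and `contrasts` (data
#'   frame of estimates, standard errors, z and p values).
#' @export
interaction_tests <- function(fit) {
  stopifnot(inherits(fit, "mixed_count_fit"))
  cf <- fit$coefficients
  V <- fit$vcov
  int_idx <- grep(":", names(cf))
  if (length(int_idx) == 0) stop("model has no interaction terms",
                                 call. = FALSE)
  ci <- cf[int_idx]
  Vi <- V[int_idx, int_idx, drop = FALSE]
  W <- tryCatch(drop(t(ci) %*% solve(Vi, ci)), error = function(e) NA_real_)
  overall <- list(chisq = W, df = length(int_idx),
                  p = pchisq(W, length(int_idx), lower.tail = FALSE))

  contrast <- function(label, L) {
    est <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    z <- est / se
    data.frame(contrast = label, estimate = est, se = se, z = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  unit <- function(name) {
    L <- numeric(length(cf))
    L[match(name, names(cf))] <- 1
    L
  }
  rows <- list()
  dev_ext <- "manipulationdevaluation:groupextensive"
  dev_par <- "manipulationdevaluation:groupextensive_parallel"
  if (dev_ext %in% names(cf)) {
    rows <- c(rows, list(contrast("devaluation x extensive vs short",
                                  unit(dev_ext))))
  }
  if (dev_par %in% names(cf)) {
    rows <- c(rows, list(contrast("devaluation x extensive_parallel vs short",
                                  unit(dev_par))))
  }
  if (all(c(dev_ext, dev_par) %in% names(cf))) {
    rows <- c(rows, list(contrast("devaluation x extensive vs extensive_parallel",
                                  unit(dev_ext) - unit(dev_par))))
  }
  for (g in c("groupextensive", "groupextensive_parallel")) {
    if (g %in% names(cf)) {
      rows <- c(rows, list(contrast(sprintf("pre-devaluation day: %s vs short",
                                            sub("group", "", g)), unit(g))))
    }
  }
  list(overall = overall, contrasts = do.call(rbind, rows))
}
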