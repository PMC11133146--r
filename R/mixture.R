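#' Univariate Gaussian mixture fit by EM
#'
#' Fits a k-component Gaussian mixture to a sample (here, behavioral
#' adaptation indices within a training group) by expectation-maximization
#' with multiple random restarts, a variance floor guarding against
#' degenerate components, and a log-likelihood convergence tolerance.
#' BIC is `-2 logLik + p log n` with `p = 3k - 1` free parameters.
#'
#' @param x Numeric sample (n >= 10).
#' @param k Number of components (1 or 2 in the study design; any small k
#'   is accepted).
#' @param n_starts Random restarts.
#' @param var_floor Lower bound on component variances.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap.
#' @return A `mixture_fit`: component `means`, `vars`, `weights`,
#'   `logLik`, `BIC`, `responsibilities` and the cluster `assignment`.
#' @export
fit_mixture <- function(x, k = 1, n_starts = 20, var_floor = 1e-4,
                        tol = 1e-8, max_iter = 500) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1) {
    mu <- mean(x)
    v <- max(mean((x - mu)^2), var_floor)  # ML variance
    ll <- sum(dnorm(x, mu, sqrt(v), log = TRUE))
    fit <- list(k = 1L, means = mu, vars = v, weights = 1,
                logLik = ll, BIC = -2 * ll + 2 * log(n),
                responsibilities = matrix(1, n, 1),
                assignment = rep(1L, n), converged = TRUE)
    class(fit) <- "mixture_fit"
    return(fit)
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    mu <- sort(sample(x, k))
    v <- rep(max(var(x) / k, var_floor), k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        log(w[j]) + dnorm(x, mu[j], sqrt(v[j]), log = TRUE),
        numeric(n))
      mx <- apply(dens, 1, max)
      lse <- mx + log(rowSums(exp(dens - mx)))
      r <- exp(dens - lse)
      ll <- sum(lse)
      if (abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      nk <- colSums(r)
      if (any(nk < 1e-8)) break  # empty component; restart
      w <- nk / n
      mu <- colSums(r * x) / nk
      v <- pmax(colSums(r * (outer(x, mu, "-"))^2) / nk, var_floor)
    }
    if (is.null(best) || ll > best$logLik) {
      best <- list(mu = mu, v = v, w = w, logLik = ll, r = r,
                   converged = converged)
    }
  }
  ord <- order(best$mu)
  p <- 3 * k - 1
  fit <- list(k = as.integer(k),
              means = best$mu[ord], vars = best$v[ord],
              weights = best$w[ord],
              logLik = best$logLik,
              BIC = -2 * best$logLik + p * log(n),
              responsibilities = best$r[, ord, drop = FALSE],
              assignment = max.col(best$r[, ord, drop = FALSE]),
              converged = best$converged)
  class(fit) <- "mixture_fit"
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d (BIC %.2f)\n", x$k, x$BIC))
  tab <- data.frame(weight = x$weights, mean = x$means, sd = sqrt(x$vars))
  print(round(tab, 4))
  invisible(x)
}

#' Select the number of latent subgroups by BIC
#'
#' Fits mixtures with each candidate number of components and returns the
#' one with the lowest BIC — the study's criterion for deciding whether a
#' training group's adaptation-index distribution is better explained by
#' one cluster or by two latent (goal-directed and habitual) subgroups.
#'
#' @param x Numeric sample.
#' @param k_values Candidate component counts.
#' @param ... Passed to [fit_mixture()].
#' @return List with `k` (the winner), `fits` and `bic` per candidate.
#' @export
select_k <- function(x, k_values = c(1, 2), ...) {
  fits <- lapply(k_values, function(k) fit_mixture(x, k, ...))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  names(bic) <- names(fits) <- paste0("k", k_values)
  list(k = k_values[which.min(bic)], fits = fits, bic = bic)
}
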