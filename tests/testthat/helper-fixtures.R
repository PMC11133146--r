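# shared fixtures, built in code and memoized for the session

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a light agent: low rates keep simulation fast while preserving structure
light_params <- function(...) {
  agent_params(sessions_per_day = 3,
               entries_per_session = list(mean = 5, size = 2),
               ...)
}

# small two-group cohort with a habitual subgroup only under extensive training
fixture_cohort <- function() {
  memo("cohort_small", {
    dist <- default_params_distribution(
      sessions_per_day = 3, entries_per_session = list(mean = 5, size = 2))
    simulate_cohort(c(short = 12, extensive = 12), dist, seed = 2024)
  })
}

# simulate a factorial count dataset from a known mixed count model
simulate_count_data <- function(m_per_group = 20, beta = NULL, sigma = 0.6,
                                family = "poisson", disp = NULL, seed = 1) {
  set.seed(seed)
  groups <- c("short", "extensive", "extensive_parallel")
  m <- m_per_group * length(groups)
  id <- sprintf("p%03d", seq_len(m))
  d <- expand.grid(participant_id = id,
                   manipulation = c("control_pre", "devaluation",
                                    "control_post"),
                   stringsAsFactors = FALSE)
  d$group <- rep(groups, each = m_per_group)[match(d$participant_id, id)]
  d$manipulation <- factor(d$manipulation,
                           levels = c("control_pre", "devaluation",
                                      "control_post"))
  d$group <- factor(d$group, levels = groups)
  X <- stats::model.matrix(~ manipulation * group, d)
  if (is.null(beta)) {
    beta <- c(3.7, -2.1, -0.2, -0.35, -0.8, 0.67, 0.05, 0.85, 0.04)
  }
  b <- stats::rnorm(m, 0, sigma)
  eta <- drop(X %*% beta) + b[match(d$participant_id, id)]
  mu <- exp(eta)
  d$entries <- switch(family,
    poisson = stats::rpois(nrow(d), mu),
    nb1 = stats::rnbinom(nrow(d), size = mu / disp, mu = mu),
    nb2 = stats::rnbinom(nrow(d), size = disp, mu = mu))
  attr(d, "beta") <- beta
  attr(d, "sigma") <- sigma
  d
}
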