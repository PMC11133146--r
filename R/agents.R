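#' Generative parameters of a synthetic participant
#'
#' A synthetic participant emits entries in self-initiated micro-sessions:
#' the daily number of sessions is Poisson, session start times are uniform
#' within a waking window, entries per session follow a shifted negative
#' binomial, and within-session inter-entry gaps are bounded strictly below
#' the 300-s sessionization threshold by construction. Daily intensity is
#' scaled by a per-participant engagement multiplier; cohort-level
#' heterogeneity in that multiplier is what makes daily counts heavily
#' overdispersed across participants.
#'
#' On manipulation days, entries after the manipulation entry are thinned:
#' each is retained with probability `1 - devaluation_sensitivity` after a
#' devaluation message (`1 - control_sensitivity` after a control message),
#' so the expected post-manipulation count equals `(1 - s)` times the
#' matched valued-day expectation. Sensitivity 1 is full goal-directed
#' adaptation; 0 is pure habit.
#'
#' @param sessions_per_day Poisson mean of the daily session count (before
#'   the engagement multiplier).
#' @param entries_per_session List with `mean` (>= 1) and `size`: entries per
#'   session are `1 + NegBin(mu = mean - 1, size)`.
#' @param within_session_gap List with `min`, `shape`, `scale`, `max`:
#'   gaps are `min + Gamma(shape, scale)` seconds, capped at `max` (< 300).
#' @param session_start_window Waking-hours interval (clock hours).
#' @param devaluation_sensitivity Thinning fraction `s` in \[0, 1\] applied to
#'   post-devaluation entries.
#' @param control_sensitivity Same for control manipulations (default 0).
#' @param cave_policy List with `p_valued`, `p_devalued` (per-pile press
#'   probabilities given the warehouse state) and `max_targets` (piles
#'   reachable within the cave window).
#' @param day_drift Multiplicative daily trend on entry intensity (1 =
#'   stationary).
#' @param rate_multiplier Per-participant engagement multiplier (cohort
#'   simulation draws it from a capped lognormal).
#' @param comply Enforce the minimum-daily-entries floor by construction.
#' @return An `agent_params` object.
#' @export
agent_params <- function(sessions_per_day = 7,
                         entries_per_session = list(mean = 7.64, size = 2),
                         within_session_gap = list(min = 10, shape = 2,
                                                   scale = 25, max = 295),
                         session_start_window = c(8, 23),
                         devaluation_sensitivity = 0.9,
                         control_sensitivity = 0,
                         cave_policy = list(p_valued = 0.55, p_devalued = 0.25,
                                            max_targets = 15),
                         day_drift = 1,
                         rate_multiplier = 1,
                         comply = TRUE) {
  p <- list(sessions_per_day = sessions_per_day,
            entries_per_session = entries_per_session,
            within_session_gap = within_session_gap,
            session_start_window = session_start_window,
            devaluation_sensitivity = devaluation_sensitivity,
            control_sensitivity = control_sensitivity,
            cave_policy = cave_policy,
            day_drift = day_drift,
            rate_multiplier = rate_multiplier,
            comply = comply)
  class(p) <- "agent_params"
  validate_agent_params(p)
  p
}

validate_agent_params <- function(p) {
  stopifnot(inherits(p, "agent_params"))
  s <- p$devaluation_sensitivity
  if (!is.numeric(s) || s < 0 || s > 1) {
    stop("devaluation_sensitivity must be in [0, 1]", call. = FALSE)
  }
  if (p$control_sensitivity < 0 || p$control_sensitivity > 1) {
    stop("control_sensitivity must be in [0, 1]", call. = FALSE)
  }
  if (p$sessions_per_day <= 0 || p$rate_multiplier <= 0 || p$day_drift <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  if (p$entries_per_session$mean < 1) {
    stop("entries_per_session mean must be >= 1", call. = FALSE)
  }
  gap <- p$within_session_gap
  if (gap$min <= 0 || gap$max >= 300 || gap$min > gap$max) {
    stop("within-session gaps must lie strictly inside (0, 300) seconds",
         call. = FALSE)
  }
  invisible(p)
}

# planned entry timestamps for one day, in seconds since experiment start
plan_day_entries <- function(day, params, config) {
  w0 <- (day - 1) * 86400 + params$session_start_window[1] * 3600
  w1 <- (day - 1) * 86400 + params$session_start_window[2] * 3600
  lambda <- params$sessions_per_day * params$rate_multiplier *
    params$day_drift^(day - 1)
  n_sessions <- max(1L, rpois(1, lambda))
  eps <- params$entries_per_session
  session_sizes <- 1L + rnbinom(n_sessions, mu = eps$mean - 1, size = eps$size)
  if (params$comply && sum(session_sizes) < config$min_daily_entries) {
    session_sizes[n_sessions] <- session_sizes[n_sessions] +
      config$min_daily_entries - sum(session_sizes)
  }
  starts <- sort(runif(n_sessions, w0, w1))
  gap <- params$within_session_gap
  ts <- numeric(0)
  prev_end <- -Inf
  kept_sizes <- integer(0)
  for (i in seq_len(n_sessions)) {
    s0 <- max(starts[i], prev_end + 300)  # keep sessions separated
    if (s0 > w1 && length(ts) > 0) next
    gaps <- pmin(gap$min + rgamma(session_sizes[i] - 1L, shape = gap$shape,
                                  scale = gap$scale), gap$max)
    tt <- s0 + c(0, cumsum(gaps))
    ts <- c(ts, tt)
    kept_sizes <- c(kept_sizes, session_sizes[i])
    prev_end <- tt[length(tt)]
  }
  if (params$comply && length(ts) < config$min_daily_entries) {
    need <- config$min_daily_entries - length(ts)
    gaps <- pmin(gap$min + rgamma(need, shape = gap$shape, scale = gap$scale),
                 gap$max)
    ts <- c(ts, ts[length(ts)] + cumsum(gaps))
  }
  ts
}

#' Simulate one participant's full entry log
#'
#' Generates session-clustered entry timestamps for every day of the group
#' schedule, thins post-manipulation entries according to the agent's
#' devaluation/control sensitivity, and replays the stream through the task
#' state machine, including the cave mini-task after each confirmed
#' manipulation message.
#'
#' @param params An [agent_params()].
#' @param schedule A [schedule_for_group()] calendar.
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical logs.
#' @param participant_id Identifier stored in the log.
#' @param group Label stored in the log (defaults to the schedule's group).
#' @return A `participant_log`: list with `participant_id`, `group`,
#'   `params`, `events` (one row per entry with the entry-event fields),
#'   `cave_results` (one row per manipulation) and the schedule/config used.
#' @export
simulate_participant <- function(params, schedule = schedule_for_group("short"),
                                 config = task_config(), seed = 1L,
                                 participant_id = "p1",
                                 group = schedule$group) {
  validate_agent_params(params)
  set.seed(seed)
  manip_ord <- config$manipulation_entry
  all_ts <- list()
  for (day in seq_len(schedule$n_days)) {
    ts <- plan_day_entries(day, params, config)
    manip <- schedule$calendar[day]
    if (manip != "none" && length(ts) > manip_ord) {
      s_eff <- if (manip == "devaluation") params$devaluation_sensitivity
               else params$control_sensitivity
      post <- seq_along(ts) > manip_ord
      keep <- !post | (runif(length(ts)) >= s_eff)
      ts <- ts[keep]
    }
    all_ts[[day]] <- ts
  }
  timestamps <- unlist(all_ts)

  state <- init_participant_state(participant_id, config, schedule)
  events <- vector("list", length(timestamps))
  caves <- list()
  for (i in seq_along(timestamps)) {
    res <- process_entry(state, timestamps[i], confirm = TRUE)
    state <- res$state
    events[[i]] <- res$event
    ev <- res$event
    if (ev$manipulation_shown != "none" &&
        ev$daily_ordinal == manip_ord &&
        config$manipulation_check_mode == "cave") {
      pol <- params$cave_policy
      p_press <- if (ev$manipulation_shown == "devaluation")
        pol$p_devalued else pol$p_valued
      n_piles <- rbinom(1, min(pol$max_targets, config$cave_n_piles), p_press)
      n_rocks <- rbinom(1, 2, 0.25)  # occasional mispresses
      targets <- c(rep("pile", n_piles), rep("rock", n_rocks))
      cave <- run_cave(state$warehouse_status, targets, config)
      state$gold_total <- state$gold_total + cave$gold_delta
      caves[[length(caves) + 1]] <- data.frame(
        participant_id = participant_id, day_index = ev$day_index,
        manipulation = ev$manipulation_shown, presses = cave$presses,
        piles_collected = cave$piles_collected, gold_delta = cave$gold_delta,
        stringsAsFactors = FALSE)
    }
  }
  log <- list(participant_id = participant_id,
              group = group,
              params = params,
              events = do.call(rbind, events),
              cave_results = if (length(caves)) do.call(rbind, caves) else
                data.frame(),
              schedule = schedule,
              config = config,
              seed = seed)
  class(log) <- "participant_log"
  log
}

#' @export
print.participant_log <- function(x, ...) {
  cat(sprintf("Participant log '%s' (%s group): %d entries over %d days\n",
              x$participant_id, x$group, nrow(x$events), x$schedule$n_days))
  invisible(x)
}

#' Default cohort parameter distribution
#'
#' Returns a sampler `function(group)` producing [agent_params()] draws that
#' emulate the study cohort: per-participant engagement multipliers from a
#' lognormal (sdlog 1.4) capped at 15, which reproduces daily-entry
#' descriptives of roughly median 53.5, mean 122 and SD 180 at the default
#' session process; goal-directed devaluation sensitivity (Beta(15, 2)) for
#' everyone in the short training group; and, in the extensive training
#' groups, a latent mixture of a goal-directed and a habitual
#' (Beta(1.5, 12)) subgroup so that extensive training yields the
#' two-cluster adaptation-index structure.
#'
#' @param habitual_fraction Probability that an extensive-training agent is
#'   drawn from the habitual subgroup.
#' @param goal_beta,habitual_beta Beta shape pairs for the two
#'   devaluation-sensitivity subpopulations; the goal-directed default is
#'   calibrated so the simulated short-group adaptation index averages
#'   about 0.47.
#' @param rate_sdlog,rate_cap Lognormal spread and cap of the engagement
#'   multiplier.
#' @param ... Overrides passed on to [agent_params()].
#' @return A function mapping a group name to one `agent_params` draw.
#' @export
default_params_distribution <- function(habitual_fraction = 0.5,
                                        goal_beta = c(14, 3.5),
                                        habitual_beta = c(1.5, 12),
                                        rate_sdlog = 1.4, rate_cap = 15,
                                        ...) {
  dots <- list(...)
  function(group) {
    habitual <- group != "short" && runif(1) < habitual_fraction
    shp <- if (habitual) habitual_beta else goal_beta
    args <- c(list(
      devaluation_sensitivity = rbeta(1, shp[1], shp[2]),
      rate_multiplier = min(rlnorm(1, 0, rate_sdlog), rate_cap)
    ), dots)
    do.call(agent_params, args)
  }
}

#' Simulate a full experimental cohort
#'
#' @param n_per_group Named integer vector of group sizes; names must be
#'   group identifiers accepted by [schedule_for_group()]. The study's
#'   cohort sizes (45/45/43) are the default.
#' @param params_distribution A `function(group)` returning one
#'   [agent_params()] draw, e.g. [default_params_distribution()].
#' @param config A [task_config()].
#' @param seed Master seed; per-participant seeds are derived from it, so the
#'   whole cohort is reproducible.
#' @return A list of `participant_log` objects with class `cohort`.
#' @export
simulate_cohort <- function(n_per_group = c(short = 45, extensive = 45,
                                            extensive_parallel = 43),
                            params_distribution = default_params_distribution(),
                            config = task_config(), seed = 1L) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("short", "extensive", "extensive_parallel"))) {
    stop("n_per_group must be named with valid group names", call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1", call. = FALSE)
  if (!is.function(params_distribution)) {
    stop("params_distribution must be a function(group)", call. = FALSE)
  }
  set.seed(seed)
  n_total <- sum(n_per_group)
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  draws <- list()
  groups <- rep(names(n_per_group), n_per_group)
  for (g in seq_along(groups)) draws[[g]] <- params_distribution(groups[g])
  logs <- vector("list", n_total)
  idx <- 0L
  for (g in seq_along(groups)) {
    idx <- idx + 1L
    grp <- groups[g]
    logs[[idx]] <- simulate_participant(
      draws[[g]], schedule_for_group(grp), config, seed = seeds[idx],
      participant_id = sprintf("%s_%02d", grp,
                               sum(groups[seq_len(g)] == grp)),
      group = grp)
  }
  class(logs) <- "cohort"
  logs
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x, function(l) l$group, character(1))
  cat("Simulated cohort:", length(x), "participants (",
      paste(sprintf("%s: %d", names(table(groups)), table(groups)),
            collapse = ", "), ")\n")
  invisible(x)
}
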