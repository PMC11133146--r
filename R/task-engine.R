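#' @importFrom stats rbinom runif rexp rpois rnbinom rlnorm rgamma rbeta rnorm
NULL

day_of_timestamp <- function(timestamp, config) {
  as.integer(floor((timestamp - config$day_boundary_hour * 3600) / 86400) + 1)
}

#' Initialise the per-participant task state
#'
#' @param participant_id Identifier carried into every emitted event.
#' @param config A [task_config()].
#' @param schedule A [schedule_for_group()] calendar.
#' @return A `participant_state` list tracking the current day, the daily
#'   entry ordinal, the failure streak, the warehouse, pending manipulation
#'   messages and cumulative gold.
#' @export
init_participant_state <- function(participant_id, config = task_config(),
                                   schedule = schedule_for_group("short")) {
  state <- list(
    participant_id = participant_id,
    config = config,
    schedule = schedule,
    day_index = 0L,
    daily_ordinal = 0L,
    failure_streak = 0L,
    warehouse_status = "empty_start",
    gold_today = 0,
    gold_total = 0,
    message_pending = FALSE,
    pending_message = "none",
    manip_confirmed = FALSE,
    pattern_gold_ordinals = integer(0),
    ri_next_available = if (config$schedule_kind == "random_interval")
      rexp(1, 1 / config$ri_mean_interval) else Inf,
    last_timestamp = -Inf
  )
  class(state) <- "participant_state"
  state
}

warehouse_valued <- function(state) state$warehouse_status != "full"

#' Draw the outcome of a single entry
#'
#' Applies, in order of precedence: the fixed daily pattern (under
#' `"rock_gold"`, the first daily entry is forced to a rock and the second to
#' gold; under `"random_two_of_five"`, the pre-drawn gold ordinals among the
#' first five are forced), the failure guarantee (a streak of
#' `guarantee_after_failures` consecutive rocks forces gold), and otherwise a
#' Bernoulli draw with `reward_probability`.
#'
#' @param daily_ordinal 1-based entry count within the current day.
#' @param failure_streak Number of consecutive rocks preceding this entry.
#' @param config A [task_config()].
#' @param pattern_gold_ordinals Ordinals forced to gold under the
#'   `"random_two_of_five"` pattern (drawn once per day).
#' @return `"gold"` or `"rock"`.
#' @export
#' @examples
#' draw_outcome(7, failure_streak = 6)  # guaranteed gold
draw_outcome <- function(daily_ordinal, failure_streak, config = task_config(),
                         pattern_gold_ordinals = integer(0)) {
  if (daily_ordinal < 1) stop("daily_ordinal must be >= 1", call. = FALSE)
  if (failure_streak < 0) stop("failure_streak must be >= 0", call. = FALSE)
  if (config$fixed_daily_pattern == "rock_gold") {
    if (daily_ordinal == 1) return("rock")
    if (daily_ordinal == 2) return("gold")
  } else if (config$fixed_daily_pattern == "random_two_of_five" &&
             daily_ordinal <= 5) {
    return(if (daily_ordinal %in% pattern_gold_ordinals) "gold" else "rock")
  }
  if (failure_streak >= config$guarantee_after_failures) return("gold")
  if (runif(1) < config$reward_probability) "gold" else "rock"
}

advance_day <- function(state, new_day) {
  state$day_index <- as.integer(new_day)
  state$daily_ordinal <- 0L
  state$warehouse_status <- "empty_start"
  state$gold_today <- 0
  state$message_pending <- FALSE
  state$pending_message <- "none"
  state$manip_confirmed <- FALSE
  state$pattern_gold_ordinals <-
    if (state$config$fixed_daily_pattern == "random_two_of_five")
      sample.int(5L, 2L) else integer(0)
  state
}

#' Process one app entry through the task state machine
#'
#' Advances the experimental day when the timestamp crosses the day boundary
#' (emptying the warehouse), increments the daily ordinal, raises the
#' scheduled warehouse message on the manipulation entry (re-raising it on
#' subsequent entries until confirmed), applies outcome masking from the
#' masking ordinal onward on manipulation days, draws the outcome, and
#' settles the gold account: the entry cost is always deducted and the reward
#' is credited only while the warehouse can still store gold.
#'
#' @param state A `participant_state`.
#' @param timestamp Seconds since experiment start (nondecreasing within a
#'   participant; the day boundary clock offset is taken from the config).
#' @param confirm Whether the participant confirms a manipulation message
#'   shown on this entry (simulated agents confirm immediately).
#' @return A list with `event` (one-row data frame of the entry event) and
#'   `state` (the updated state).
#' @export
process_entry <- function(state, timestamp, confirm = TRUE) {
  stopifnot(inherits(state, "participant_state"))
  config <- state$config
  if (timestamp < state$last_timestamp) {
    stop(sprintf("out-of-order timestamp for participant %s",
                 state$participant_id), call. = FALSE)
  }
  day <- day_of_timestamp(timestamp, config)
  if (day > state$schedule$n_days) {
    stop(sprintf("entry on day %d beyond the %d-day schedule", day,
                 state$schedule$n_days), call. = FALSE)
  }
  if (day > state$day_index) state <- advance_day(state, day)
  state$last_timestamp <- timestamp
  state$daily_ordinal <- state$daily_ordinal + 1L
  ord <- state$daily_ordinal
  manip_today <- state$schedule$calendar[state$day_index]

  phase <- "pre_manipulation"
  if (manip_today != "none" && state$manip_confirmed &&
      ord > config$manipulation_entry) {
    phase <- "under_manipulation"
  }

  shown <- "none"
  if (manip_today != "none" && ord == config$manipulation_entry) {
    # message first raised; warehouse status changes as the message appears
    state$warehouse_status <-
      if (manip_today == "devaluation") "full" else "half_full"
    state$message_pending <- TRUE
    state$pending_message <- manip_today
  }
  if (state$message_pending) {
    shown <- state$pending_message
    if (confirm) {
      state$message_pending <- FALSE
      state$manip_confirmed <- TRUE
    }
  }

  masked <- manip_today != "none" && ord >= config$masking_start_entry

  if (config$schedule_kind == "random_interval") {
    if (timestamp >= state$ri_next_available) {
      outcome <- "gold"
      state$ri_next_available <- timestamp +
        rexp(1, 1 / config$ri_mean_interval)
    } else {
      outcome <- "rock"
    }
    # the fixed pattern and guarantee are layered on top of availability
    forced <- draw_outcome_forced(ord, state$failure_streak, config,
                                  state$pattern_gold_ordinals)
    if (!is.na(forced)) outcome <- forced
  } else {
    outcome <- draw_outcome(ord, state$failure_streak, config,
                            state$pattern_gold_ordinals)
  }
  state$failure_streak <-
    if (outcome == "gold") 0L else state$failure_streak + 1L

  credit <- 0
  if (outcome == "gold" && warehouse_valued(state)) {
    credit <- config$reward_magnitude
    state$gold_today <- state$gold_today + credit
  }
  gold_delta <- credit - config$entry_cost
  if (config$aversive_outcomes && outcome == "rock" &&
      runif(1) < config$aversive_probability) {
    gold_delta <- gold_delta - config$aversive_magnitude
  }
  state$gold_total <- state$gold_total + gold_delta

  event <- data.frame(
    participant_id = state$participant_id,
    timestamp = timestamp,
    day_index = state$day_index,
    daily_ordinal = ord,
    outcome = outcome,
    masked = masked,
    manipulation_shown = shown,
    gold_delta = gold_delta,
    phase = phase,
    sequence_completed = TRUE,
    stringsAsFactors = FALSE
  )
  list(event = event, state = state)
}

# forced outcomes only (pattern/guarantee); NA when the schedule draw decides
draw_outcome_forced <- function(ord, streak, config, pattern_gold_ordinals) {
  if (config$fixed_daily_pattern == "rock_gold") {
    if (ord == 1) return("rock")
    if (ord == 2) return("gold")
  } else if (config$fixed_daily_pattern == "random_two_of_five" && ord <= 5) {
    return(if (ord %in% pattern_gold_ordinals) "gold" else "rock")
  }
  if (streak >= config$guarantee_after_failures) return("gold")
  NA_character_
}

#' Generate a cave layout
#'
#' @param config A [task_config()].
#' @return Character vector of `"pile"`/`"rock"` targets in random screen
#'   order, with exactly `cave_n_piles` piles and `cave_n_rocks` rocks.
#' @export
generate_cave_layout <- function(config = task_config()) {
  sample(c(rep("pile", config$cave_n_piles), rep("rock", config$cave_n_rocks)))
}

#' Run the cave manipulation-check mini-task
#'
#' Each press costs `cave_press_cost` gold units; every pressed pile is worth
#' `cave_pile_value` units, credited only while the warehouse is not full
#' (piles are worthless after devaluation). Presses on rocks never credit.
#'
#' @param warehouse_status `"empty_start"`, `"half_full"` or `"full"`.
#' @param press_targets Character vector of pressed targets (`"pile"` /
#'   `"rock"`), in press order.
#' @param config A [task_config()].
#' @return A list with `presses`, `piles_collected` and `gold_delta`.
#' @export
#' @examples
#' run_cave("half_full", c("pile"))$gold_delta  # 15 - 10 = 5
run_cave <- function(warehouse_status, press_targets, config = task_config()) {
  stopifnot(warehouse_status %in% c("empty_start", "half_full", "full"))
  press_targets <- as.character(press_targets)
  if (!all(press_targets %in% c("pile", "rock"))) {
    stop("press_targets must be 'pile' or 'rock'", call. = FALSE)
  }
  piles <- sum(press_targets == "pile")
  if (piles > config$cave_n_piles) {
    stop("more pile presses than piles present", call. = FALSE)
  }
  presses <- length(press_targets)
  valued <- warehouse_status != "full"
  gold_delta <- -presses * config$cave_press_cost +
    piles * config$cave_pile_value * as.numeric(valued)
  list(presses = presses, piles_collected = piles, gold_delta = gold_delta)
}
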