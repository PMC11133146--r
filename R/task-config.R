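#' Task configuration for the gold-planet free-operant paradigm
#'
#' Builds the full set of tunable task parameters. The defaults reproduce the
#' published study: a one-gold-unit entry cost, a 15-unit reward delivered
#' with probability 1/3 per entry (VR-3), a guaranteed reward after six
#' consecutive failures, a fixed daily pattern (first daily entry a rock,
#' second a gold find), outcome masking from the third daily entry on
#' manipulation days, the warehouse manipulation message on the fifth daily
#' entry, a five-entry daily compliance floor, a 05:00 day boundary, and a
#' cave mini-task with 15 gold piles and 15 rocks where each press costs 10
#' units and each pile is worth 15.
#'
#' @param entry_cost Gold units deducted on every entry.
#' @param reward_magnitude Gold units credited for a gold find while the
#'   warehouse can still store gold.
#' @param reward_probability Per-entry probability of finding gold under the
#'   variable-ratio schedule.
#' @param guarantee_after_failures Number of consecutive rocks after which
#'   the next entry is guaranteed to yield gold. `Inf` disables the rule.
#' @param fixed_daily_pattern One of `"rock_gold"` (first daily entry forced
#'   to rock, second forced to gold), `"random_two_of_five"` (two randomly
#'   chosen entries among the first five forced to gold) or `"none"`.
#' @param masking_start_entry Daily ordinal from which outcomes are hidden on
#'   manipulation days.
#' @param manipulation_entry Daily ordinal on which the warehouse message
#'   (devaluation or control) is shown on manipulation days.
#' @param min_daily_entries Compliance floor: minimum entries per day.
#' @param day_boundary_hour Clock hour at which the experimental day rolls
#'   over and the warehouse is emptied.
#' @param cave_duration Seconds available for free gold collection.
#' @param cave_press_cost Gold units paid per press inside the cave.
#' @param cave_pile_value Gold units per collected pile (credited only while
#'   the warehouse is not full).
#' @param cave_n_piles,cave_n_rocks Cave layout composition.
#' @param manipulation_check_mode `"cave"` (mini-task) or `"status_question"`
#'   (explicit warehouse-status prompt).
#' @param devaluation_reminder Show a reminder message after post-devaluation
#'   entries.
#' @param schedule_kind `"ratio"` (default, VR) or `"random_interval"` (a
#'   reward becomes available after an exponentially distributed interval and
#'   is delivered on the next entry).
#' @param ri_mean_interval Mean of the exponential availability interval, in
#'   seconds, for the random-interval schedule.
#' @param aversive_outcomes Enable gold losses on non-rewarded entries.
#' @param aversive_magnitude Gold units lost when an aversive outcome fires.
#' @param aversive_probability Probability that a rock entry is aversive.
#'
#' @return An object of class `task_config` (a validated named list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$reward_probability
task_config <- function(entry_cost = 1,
                        reward_magnitude = 15,
                        reward_probability = 1 / 3,
                        guarantee_after_failures = 6,
                        fixed_daily_pattern = c("rock_gold", "random_two_of_five", "none"),
                        masking_start_entry = 3,
                        manipulation_entry = 5,
                        min_daily_entries = 5,
                        day_boundary_hour = 5,
                        cave_duration = 5,
                        cave_press_cost = 10,
                        cave_pile_value = 15,
                        cave_n_piles = 15,
                        cave_n_rocks = 15,
                        manipulation_check_mode = c("cave", "status_question"),
                        devaluation_reminder = FALSE,
                        schedule_kind = c("ratio", "random_interval"),
                        ri_mean_interval = 3600,
                        aversive_outcomes = FALSE,
                        aversive_magnitude = 0,
                        aversive_probability = 0) {
  fixed_daily_pattern <- match.arg(fixed_daily_pattern)
  manipulation_check_mode <- match.arg(manipulation_check_mode)
  schedule_kind <- match.arg(schedule_kind)
  cfg <- list(
    entry_cost = entry_cost,
    reward_magnitude = reward_magnitude,
    reward_probability = reward_probability,
    guarantee_after_failures = guarantee_after_failures,
    fixed_daily_pattern = fixed_daily_pattern,
    masking_start_entry = masking_start_entry,
    manipulation_entry = manipulation_entry,
    min_daily_entries = min_daily_entries,
    day_boundary_hour = day_boundary_hour,
    cave_duration = cave_duration,
    cave_press_cost = cave_press_cost,
    cave_pile_value = cave_pile_value,
    cave_n_piles = cave_n_piles,
    cave_n_rocks = cave_n_rocks,
    manipulation_check_mode = manipulation_check_mode,
    devaluation_reminder = devaluation_reminder,
    schedule_kind = schedule_kind,
    ri_mean_interval = ri_mean_interval,
    aversive_outcomes = aversive_outcomes,
    aversive_magnitude = aversive_magnitude,
    aversive_probability = aversive_probability
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!num1(cfg$reward_probability) ||
      cfg$reward_probability < 0 || cfg$reward_probability > 1) {
    stop("reward_probability must be in [0, 1]", call. = FALSE)
  }
  for (f in c("entry_cost", "reward_magnitude", "cave_press_cost",
              "cave_pile_value", "aversive_magnitude", "ri_mean_interval")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("%s must be a nonnegative number", f), call. = FALSE)
    }
  }
  if (!(num1(cfg$guarantee_after_failures)) || cfg$guarantee_after_failures < 1) {
    stop("guarantee_after_failures must be >= 1", call. = FALSE)
  }
  if (cfg$masking_start_entry >= cfg$manipulation_entry) {
    stop("masking_start_entry must precede manipulation_entry", call. = FALSE)
  }
  if (cfg$min_daily_entries < 0 || cfg$cave_n_piles < 0 || cfg$cave_n_rocks < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (cfg$aversive_probability < 0 || cfg$aversive_probability > 1) {
    stop("aversive_probability must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Free-operant task configuration\n")
  cat(sprintf("  entry cost %g, reward %g with p = %.4g (%s schedule)\n",
              x$entry_cost, x$reward_magnitude, x$reward_probability,
              x$schedule_kind))
  cat(sprintf("  guarantee after %g failures; daily pattern: %s\n",
              x$guarantee_after_failures, x$fixed_daily_pattern))
  cat(sprintf("  masking from entry %d; manipulation at entry %d; floor %d/day\n",
              x$masking_start_entry, x$manipulation_entry, x$min_daily_entries))
  cat(sprintf("  cave: %d piles / %d rocks, press cost %g, pile value %g\n",
              x$cave_n_piles, x$cave_n_rocks, x$cave_press_cost,
              x$cave_pile_value))
  invisible(x)
}

#' Manipulation calendar for an experimental group
#'
#' Returns the training-duration group schedules: the short training group
#' runs 4 days with a control manipulation on days 2 and 4 and outcome
#' devaluation on day 3; the extensive training groups run 11 days with
#' controls on days 9 and 11 and devaluation on day 10; the parallel variant
#' adds control manipulations on days 2-4, chronologically parallel to the
#' short group's manipulation days.
#'
#' @param group `"short"`, `"extensive"` or `"extensive_parallel"`.
#' @return A `group_schedule` object with fields `group`, `n_days`,
#'   `calendar` (character vector indexed by day: `"none"`, `"control"` or
#'   `"devaluation"`) and `devaluation_day`.
#' @export
#' @examples
#' schedule_for_group("short")$calendar
schedule_for_group <- function(group = c("short", "extensive", "extensive_parallel")) {
  group <- match.arg(group)
  if (group == "short") {
    n_days <- 4L
    calendar <- rep("none", n_days)
    calendar[c(2, 4)] <- "control"
    calendar[3] <- "devaluation"
  } else {
    n_days <- 11L
    calendar <- rep("none", n_days)
    calendar[c(9, 11)] <- "control"
    calendar[10] <- "devaluation"
    if (group == "extensive_parallel") calendar[2:4] <- "control"
  }
  out <- list(group = group, n_days = n_days, calendar = calendar,
              devaluation_day = which(calendar == "devaluation"))
  class(out) <- "group_schedule"
  out
}

#' @export
print.group_schedule <- function(x, ...) {
  cat(sprintf("Group schedule '%s': %d days\n", x$group, x$n_days))
  manip <- which(x$calendar != "none")
  cat(sprintf("  day %2d: %s\n", manip, x$calendar[manip]), sep = "")
  invisible(x)
}

#' Disable all warehouse manipulations in a schedule
#'
#' Convenience used to obtain matched valued-day baselines: the calendar is
#' replaced by `"none"` on every day.
#'
#' @param schedule A `group_schedule`.
#' @return The schedule with an all-`"none"` calendar.
#' @export
without_manipulations <- function(schedule) {
  stopifnot(inherits(schedule, "group_schedule"))
  schedule$calendar[] <- "none"
  schedule$devaluation_day <- integer(0)
  schedule
}
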