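test_that("task configuration validates its invariants", {
  expect_error(task_config(reward_probability = 1.2), "reward_probability")
  expect_error(task_config(entry_cost = -1), "entry_cost")
  expect_error(task_config(guarantee_after_failures = 0), "guarantee")
  expect_error(task_config(masking_start_entry = 5, manipulation_entry = 5),
               "precede")
})

test_that("outcome draw honors the fixed pattern and the failure guarantee", {
  cfg <- task_config()
  set.seed(1)
  expect_identical(draw_outcome(7, failure_streak = 6, cfg), "gold")
  expect_identical(draw_outcome(1, failure_streak = 0, cfg), "rock")
  expect_identical(draw_outcome(1, failure_streak = 6, cfg), "rock")
  expect_identical(draw_outcome(2, failure_streak = 3, cfg), "gold")
  expect_error(draw_outcome(0, 0, cfg), "ordinal")
  expect_error(draw_outcome(3, -1, cfg), "streak")
})

test_that("long-run gold frequency matches the variable-ratio probability", {
  cfg <- task_config(fixed_daily_pattern = "none",
                     guarantee_after_failures = Inf)
  set.seed(42)
  draws <- replicate(1e5, draw_outcome(3, 0, cfg))
  expect_lt(abs(mean(draws == "gold") - 1 / 3), 0.01)
})

test_that("the guarantee bounds the failure streak in simulated streams", {
  cfg <- task_config(fixed_daily_pattern = "none")
  set.seed(7)
  streak <- 0L
  max_streak <- 0L
  for (i in 1:50000) {
    out <- draw_outcome(3, streak, cfg)
    streak <- if (out == "gold") 0L else streak + 1L
    max_streak <- max(max_streak, streak)
  }
  expect_lte(max_streak, cfg$guarantee_after_failures)
})

test_that("group schedules match the study calendars", {
  s <- schedule_for_group("short")
  expect_identical(s$n_days, 4L)
  expect_identical(s$calendar, c("none", "control", "devaluation", "control"))
  e <- schedule_for_group("extensive")
  expect_identical(e$n_days, 11L)
  expect_identical(which(e$calendar == "devaluation"), 10L)
  expect_identical(which(e$calendar == "control"), c(9L, 11L))
  p <- schedule_for_group("extensive_parallel")
  expect_identical(which(p$calendar == "control"), c(2L, 3L, 4L, 9L, 11L))
  expect_identical(which(p$calendar == "devaluation"), 10L)
  expect_identical(sum(s$calendar == "devaluation"), 1L)
  expect_error(schedule_for_group("weekend"))
})

entry_stream <- function(state, hours) {
  events <- list()
  for (h in hours) {
    res <- process_entry(state, h * 3600)
    state <- res$state
    events[[length(events) + 1]] <- res$event
  }
  list(events = do.call(rbind, events), state = state)
}

test_that("the manipulation entry raises the message, masks outcomes and fills the warehouse", {
  cfg <- task_config()
  sch <- schedule_for_group("short")
  state <- init_participant_state("p", cfg, sch)
  # day 3 is the devaluation day; hours from 05:00-day arithmetic
  d3 <- 2 * 24 + 8  # 08:00 on day 3
  set.seed(5)
  res <- entry_stream(state, d3 + (0:6) / 4)
  ev <- res$events
  expect_identical(ev$day_index, rep(3L, 7))
  expect_identical(ev$masked, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(ev$manipulation_shown[5], "devaluation")
  expect_identical(ev$manipulation_shown[6], "none")
  expect_identical(res$state$warehouse_status, "full")
  expect_identical(ev$phase, c(rep("pre_manipulation", 5),
                               rep("under_manipulation", 2)))
  # post-devaluation gold is never credited: delta is always -entry_cost
  expect_true(all(ev$gold_delta[5:7] == -cfg$entry_cost))
})

test_that("rewards are credited on valued days and after control messages", {
  cfg <- task_config()
  sch <- schedule_for_group("short")
  state <- init_participant_state("p", cfg, sch)
  set.seed(5)
  res <- entry_stream(state, 8 + (0:1) / 4)  # day 1, no manipulation
  ev <- res$events
  expect_identical(ev$outcome, c("rock", "gold"))
  expect_identical(ev$gold_delta, c(-1, 14))
  expect_false(any(ev$masked))
  # control day: message at entry 5, warehouse half full, gold still credited
  state2 <- init_participant_state("q", cfg, sch)
  set.seed(6)
  res2 <- entry_stream(state2, 24 + 8 + (0:5) / 4)  # day 2 = control
  expect_identical(res2$events$manipulation_shown[5], "control")
  expect_identical(res2$state$warehouse_status, "half_full")
  gold_rows <- res2$events$outcome == "gold"
  expect_true(all(res2$events$gold_delta[gold_rows] == 14))
})

test_that("an unconfirmed manipulation message reappears until confirmed", {
  cfg <- task_config()
  sch <- schedule_for_group("short")
  state <- init_participant_state("p", cfg, sch)
  set.seed(8)
  t0 <- (2 * 24 + 8) * 3600
  for (i in 0:3) state <- process_entry(state, t0 + i * 60)$state
  r5 <- process_entry(state, t0 + 4 * 60, confirm = FALSE)
  expect_identical(r5$event$manipulation_shown, "devaluation")
  r6 <- process_entry(r5$state, t0 + 5 * 60, confirm = FALSE)
  expect_identical(r6$event$manipulation_shown, "devaluation")
  expect_identical(r6$event$phase, "pre_manipulation")  # not yet confirmed
  r7 <- process_entry(r6$state, t0 + 6 * 60, confirm = TRUE)
  expect_identical(r7$event$manipulation_shown, "devaluation")
  r8 <- process_entry(r7$state, t0 + 7 * 60)
  expect_identical(r8$event$manipulation_shown, "none")
  expect_identical(r8$event$phase, "under_manipulation")
})

test_that("timestamps must be nondecreasing and within the schedule", {
  cfg <- task_config()
  state <- init_participant_state("p", cfg, schedule_for_group("short"))
  state <- process_entry(state, 10 * 3600)$state
  expect_error(process_entry(state, 9 * 3600), "out-of-order")
  expect_error(process_entry(state, 10 * 24 * 3600), "beyond")
})

test_that("gold accounting is conserved and masking does not alter outcomes", {
  cfg <- task_config()
  sch <- schedule_for_group("short")
  state <- init_participant_state("p", cfg, sch)
  set.seed(9)
  res <- entry_stream(state, 2 * 24 + 8 + (0:19) / 4)  # 20 entries, deval day
  ev <- res$events
  credits <- ev$gold_delta + cfg$entry_cost
  expect_identical(sum(credits), res$state$gold_today)
  # masked gold finds before the manipulation entry are still credited
  pre <- ev$daily_ordinal < cfg$manipulation_entry
  expect_true(all(credits[pre & ev$outcome == "gold"] == cfg$reward_magnitude))
  expect_true(all(credits[ev$daily_ordinal >= cfg$manipulation_entry] == 0))
})

test_that("disabling manipulations keeps every entry pre-manipulation and valued", {
  cfg <- task_config()
  sch <- without_manipulations(schedule_for_group("short"))
  state <- init_participant_state("p", cfg, sch)
  set.seed(10)
  res <- entry_stream(state, rep(c(8, 32, 56, 80), each = 6) + (0:5) / 4)
  expect_true(all(res$events$phase == "pre_manipulation"))
  expect_true(all(res$events$manipulation_shown == "none"))
  gold <- res$events$outcome == "gold"
  expect_true(all(res$events$gold_delta[gold] == 14))
})

test_that("the day boundary rolls the warehouse over and resets ordinals", {
  cfg <- task_config()
  sch <- schedule_for_group("short")
  state <- init_participant_state("p", cfg, sch)
  set.seed(11)
  r1 <- entry_stream(state, c(28.0, 28.1))  # day 1 (04:00 is still day 0's tail)
  expect_identical(r1$events$day_index, c(1L, 1L))
  r2 <- process_entry(r1$state, (24 + 6) * 3600)  # 06:00 next day
  expect_identical(r2$event$day_index, 2L)
  expect_identical(r2$event$daily_ordinal, 1L)
  expect_identical(r2$event$outcome, "rock")
})

test_that("cave presses cost gold and piles pay only while the warehouse is valued", {
  cfg <- task_config()
  expect_identical(run_cave("full", rep("pile", 3), cfg)$gold_delta, -30)
  expect_identical(run_cave("half_full", "pile", cfg)$gold_delta, 5)
  r <- run_cave("half_full", c("pile", "rock", "rock"), cfg)
  expect_identical(r$presses, 3L)
  expect_identical(r$piles_collected, 1L)
  expect_identical(r$gold_delta, 15 - 30)
  expect_error(run_cave("half_full", rep("pile", 16), cfg), "more pile")
  set.seed(3)
  layout <- generate_cave_layout(cfg)
  expect_identical(sum(layout == "pile"), 15L)
  expect_identical(sum(layout == "rock"), 15L)
})

test_that("the random-interval schedule delivers on the first entry after availability", {
  cfg <- task_config(schedule_kind = "random_interval",
                     ri_mean_interval = 600,
                     fixed_daily_pattern = "none",
                     guarantee_after_failures = Inf)
  sch <- without_manipulations(schedule_for_group("short"))
  set.seed(12)
  state <- init_participant_state("p", cfg, sch)
  res <- entry_stream(state, 8 + (0:99) / 2)  # every 30 min over day 1
  golds <- sum(res$events$outcome == "gold")
  expect_gt(golds, 0)
  # availability-gated: cannot out-earn one reward per interval on average
  expect_lt(golds, 100)
})
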