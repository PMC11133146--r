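#' Behavioral adaptation index
#'
#' The goal-directedness statistic
#' \deqn{(\sqrt{\mu_{valued}} - \sqrt{devalued}) /
#'       (\sqrt{\mu_{valued}} + \sqrt{devalued})}
#' where \eqn{\mu_{valued}} is the mean of the entry counts under the control
#' manipulations on the days before and after outcome devaluation and
#' `devalued` is the count under the devaluation manipulation. The square
#' root downweights inflated counts. The index lies in \[-1, 1\]: 1 means no
#' habitual (devalued) entries at all, values near 0 mean responding
#' insensitive to outcome value.
#'
#' @param valued_pre Entries under manipulation on the control day before
#'   devaluation.
#' @param valued_post Same for the control day after devaluation.
#' @param devalued Entries under manipulation on the devaluation day.
#' @return An `adaptation_index` object: list with the inputs, `mu_valued`
#'   and `value`.
#' @export
#' @examples
#' adaptation_index(16, 16, 4)$value  # (4 - 2) / (4 + 2)
adaptation_index <- function(valued_pre, valued_post, devalued) {
  if (any(c(valued_pre, valued_post, devalued) < 0)) {
    stop("entry counts must be nonnegative", call. = FALSE)
  }
  mu_valued <- (valued_pre + valued_post) / 2
  if (mu_valued == 0 && devalued == 0) {
    stop("adaptation index undefined: no valued and no devalued entries",
         call. = FALSE)
  }
  value <- (sqrt(mu_valued) - sqrt(devalued)) /
    (sqrt(mu_valued) + sqrt(devalued))
  out <- list(valued_pre = valued_pre, valued_post = valued_post,
              devalued = devalued, mu_valued = mu_valued, value = value)
  class(out) <- "adaptation_index"
  out
}

#' @export
print.adaptation_index <- function(x, ...) {
  cat(sprintf("Adaptation index %.3f (valued %g/%g, devalued %g)\n",
              x$value, x$valued_pre, x$valued_post, x$devalued))
  invisible(x)
}

#' Partition a timestamp stream into self-initiated sessions
#'
#' Consecutive entries closer than `threshold` seconds belong to the same
#' session; a gap of `threshold` or more (strictly "not less than") starts a
#' new one.
#'
#' @param timestamps Sorted numeric vector of entry times in seconds.
#' @param threshold Sessionization gap in seconds (default 300).
#' @return A `session_set`: list with `sessions` (list of timestamp runs),
#'   `n_sessions` and `session_id` (per input timestamp).
#' @export
#' @examples
#' sessionize(c(0, 100, 399, 1000))$n_sessions  # gap of 601 splits once
sessionize <- function(timestamps, threshold = 300) {
  if (is.unsorted(timestamps)) stop("timestamps must be sorted", call. = FALSE)
  n <- length(timestamps)
  if (n == 0) {
    out <- list(sessions = list(), n_sessions = 0L, session_id = integer(0),
                threshold = threshold)
    class(out) <- "session_set"
    return(out)
  }
  gaps <- diff(timestamps)
  session_id <- cumsum(c(1L, as.integer(gaps >= threshold)))
  out <- list(sessions = split(timestamps, session_id),
              n_sessions = max(session_id),
              session_id = session_id,
              threshold = threshold)
  class(out) <- "session_set"
  out
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("%d session(s) over %d entries (threshold %g s)\n",
              x$n_sessions, length(x$session_id), x$threshold))
  invisible(x)
}

#' Entries under manipulation, per manipulation day
#'
#' Counts, for each manipulation day in a log, the entries committed after
#' the manipulation message was confirmed (the study's main dependent
#' variable; the manipulation entry itself is excluded).
#'
#' @param log A `participant_log`.
#' @return Data frame with `participant_id`, `day_index`, `manipulation` and
#'   `entries`.
#' @export
entries_under_manipulation <- function(log) {
  ev <- log$events
  days <- which(log$schedule$calendar != "none")
  out <- lapply(days, function(d) {
    data.frame(participant_id = log$participant_id,
               day_index = d,
               manipulation = log$schedule$calendar[d],
               entries = sum(ev$day_index == d & ev$phase == "under_manipulation"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Main-manipulation entry counts in long format
#'
#' Extracts, for each participant, the entries under manipulation on the
#' three main manipulation days (control on the day before devaluation,
#' devaluation day, control on the day after) — the dataset modelled by the
#' mixed-effects count regressions. Week-1 parallel controls are not part of
#' this triplet.
#'
#' @param cohort A list of `participant_log` objects.
#' @return A `count_dataset` data frame with columns `participant_id`,
#'   `group`, `manipulation` (factor: `control_pre`, `devaluation`,
#'   `control_post`) and `entries`, one row per participant and level.
#' @export
count_dataset <- function(cohort) {
  rows <- lapply(cohort, function(log) {
    dev <- log$schedule$devaluation_day
    if (length(dev) != 1) return(NULL)
    ev <- log$events
    cnt <- function(d) sum(ev$day_index == d & ev$phase == "under_manipulation")
    data.frame(participant_id = log$participant_id,
               group = log$group,
               manipulation = c("control_pre", "devaluation", "control_post"),
               entries = c(cnt(dev - 1), cnt(dev), cnt(dev + 1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group,
                      levels = c("short", "extensive", "extensive_parallel"))
  out$group <- droplevels(out$group)
  out$manipulation <- factor(out$manipulation,
                             levels = c("control_pre", "devaluation",
                                        "control_post"))
  class(out) <- c("count_dataset", "data.frame")
  out
}

#' Engagement indices for one participant
#'
#' Computes the engagement measures used to probe habit expression: entries
#' on the first day, average daily entries excluding the devaluation day
#' (with a variant excluding all manipulation days), the average number of
#' daily self-initiated sessions and average entries per session, and the
#' baseline count of entries following the control manipulation on the
#' pre-devaluation day.
#'
#' @param log A `participant_log`.
#' @param threshold Sessionization threshold in seconds.
#' @return One-row data frame of indices.
#' @export
engagement_indices <- function(log, threshold = 300) {
  ev <- log$events
  if (nrow(ev) == 0) stop("log contains no entries", call. = FALSE)
  n_days <- log$schedule$n_days
  dev_day <- log$schedule$devaluation_day
  manip_days <- which(log$schedule$calendar != "none")
  daily <- tabulate(ev$day_index, nbins = n_days)

  keep_days <- setdiff(seq_len(n_days), dev_day)
  keep_days_all <- setdiff(seq_len(n_days), manip_days)
  sess_daily <- vapply(seq_len(n_days), function(d) {
    ss <- sessionize(ev$timestamp[ev$day_index == d], threshold)
    ss$n_sessions
  }, integer(1))
  entries_per_session <- ifelse(sess_daily > 0, daily / sess_daily, NA_real_)

  dev <- if (length(dev_day)) dev_day else NA_integer_
  baseline <- if (!is.na(dev)) {
    sum(ev$day_index == dev - 1 & ev$phase == "under_manipulation")
  } else NA_integer_

  data.frame(
    participant_id = log$participant_id,
    group = log$group,
    first_day_entries = daily[1],
    avg_daily_entries = mean(daily[keep_days]),
    avg_daily_entries_no_manip = if (length(keep_days_all))
      mean(daily[keep_days_all]) else NA_real_,
    daily_sessions_avg = mean(sess_daily),
    entries_per_session_avg = mean(entries_per_session, na.rm = TRUE),
    baseline_entries_pre_devaluation = baseline,
    stringsAsFactors = FALSE
  )
}

#' Proportion of still-valued entries
#'
#' `still_valued / (still_valued + devalued)`: the share of a participant's
#' post-manipulation entries that occurred while the outcome still had value
#' (pre-devaluation control day) relative to the devaluation day.
#'
#' @param still_valued Entries under the pre-devaluation control.
#' @param devalued Entries under devaluation.
#' @return Fraction in \[0, 1\].
#' @export
devalued_proportion <- function(still_valued, devalued) {
  if (still_valued < 0 || devalued < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (still_valued + devalued == 0) {
    stop("proportion undefined when both counts are zero", call. = FALSE)
  }
  still_valued / (still_valued + devalued)
}

#' Daily-compliance exclusion filter
#'
#' A participant is retained only if every experimental day has at least
#' `min_daily_entries` entries.
#'
#' @param log A `participant_log`.
#' @param config A [task_config()] supplying the floor.
#' @return List with `included` and `first_violation_day` (NA when included).
#' @export
exclusion_filter <- function(log, config = log$config) {
  daily <- tabulate(log$events$day_index, nbins = log$schedule$n_days)
  bad <- which(daily < config$min_daily_entries)
  list(included = length(bad) == 0,
       first_violation_day = if (length(bad)) bad[1] else NA_integer_)
}

#' Lower/upper quartile membership of baseline engagement
#'
#' Splits participants into the lower and upper quartiles of a baseline
#' count (entries following the control manipulation on the pre-devaluation
#' day). By default the split is computed separately within each training
#' group; `within_group = FALSE` pools all participants. Quartiles use
#' linear-interpolation sample quantiles; membership is `<= Q1` / `>= Q3`.
#'
#' @param baseline Named or plain numeric vector of baseline counts.
#' @param group Factor/character of group membership, parallel to
#'   `baseline`.
#' @param within_group Compute quartiles separately per group.
#' @return Data frame with `baseline`, `group`, `quartile` (`"lower"`,
#'   `"upper"` or NA for the middle half) and a `degenerate` flag set when a
#'   stratum's Q1 equals its Q3.
#' @export
quartile_groups <- function(baseline, group = rep("all", length(baseline)),
                            within_group = TRUE) {
  group <- as.character(group)
  if (!within_group) group <- rep("all", length(baseline))
  out <- data.frame(baseline = baseline, group = group,
                    quartile = NA_character_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) < 4) {
      stop(sprintf("stratum '%s' has fewer than 4 participants", g),
           call. = FALSE)
    }
    q <- stats::quantile(baseline[i], c(0.25, 0.75), type = 7, names = FALSE)
    if (q[1] == q[2]) {
      out$degenerate[i] <- TRUE
      next
    }
    out$quartile[i][baseline[i] <= q[1]] <- "lower"
    out$quartile[i][baseline[i] >= q[2]] <- "upper"
  }
  out
}

#' Per-participant metrics table for a cohort
#'
#' Combines engagement indices, inclusion status and the behavioral
#' adaptation index into the per-participant table consumed by the
#' regression analyses.
#'
#' @param cohort A list of `participant_log` objects.
#' @param threshold Sessionization threshold in seconds.
#' @return Data frame, one row per participant.
#' @export
cohort_metrics <- function(cohort, threshold = 300) {
  counts <- count_dataset(cohort)
  rows <- lapply(cohort, function(log) {
    eng <- engagement_indices(log, threshold)
    cc <- counts[counts$participant_id == log$participant_id, ]
    idx <- tryCatch(adaptation_index(
      cc$entries[cc$manipulation == "control_pre"],
      cc$entries[cc$manipulation == "control_post"],
      cc$entries[cc$manipulation == "devaluation"])$value,
      error = function(e) NA_real_)
    filt <- exclusion_filter(log)
    eng$adaptation_index <- idx
    eng$included <- filt$included
    eng
  })
  do.call(rbind, rows)
}
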