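#' Calibrate shock intensities from the maximum endurable current
#'
#' The differential-conditioning task uses two fixed fractions of each
#' participant's maximum endurable current: the low-intensity stimulus (LS) is
#' 50% and the high-intensity stimulus (HS) is 90% of the maximum.
#'
#' @param max_current Maximum endurable current in mA (single positive number).
#' @return An object of class `stim_calibration`: a list with elements
#'   `max_current`, `ls_current` (0.5 x max) and `hs_current` (0.9 x max),
#'   all in mA.
#' @export
#' @examples
#' calibrate_intensities(3.0) # LS = 1.5 mA, HS = 2.7 mA
calibrate_intensities <- function(max_current) {
  check_scalar_number(max_current, "max_current", positive = TRUE)
  out <- list(
    max_current = max_current,
    ls_current = 0.5 * max_current,
    hs_current = 0.9 * max_current
  )
  class(out) <- "stim_calibration"
  out
}

#' @export
print.stim_calibration <- function(x, ...) {
  cat(sprintf(
    "Stimulus calibration: max %.3g mA -> LS %.3g mA (50%%), HS %.3g mA (90%%)\n",
    x$max_current, x$ls_current, x$hs_current
  ))
  invisible(x)
}

# Shared per-trial timing (seconds): sound, delay, shock.
SOUND_DUR <- 5
DELAY_DUR <- 5
SHOCK_DUR <- 5

trial_frame <- function(condition, rest_dur, lead_in) {
  n <- length(condition)
  cue <- ifelse(condition %in% c("LF-LS", "LF-HS"), "LF", "HF")
  shock <- ifelse(condition %in% c("LF-LS", "HF-LS"), "LS", "HS")
  matched <- condition %in% c("LF-LS", "HF-HS")
  trial_len <- SOUND_DUR + DELAY_DUR + SHOCK_DUR + rest_dur
  onset <- lead_in + cumsum(c(0, head(trial_len, -1)))
  data.frame(
    trial = seq_len(n),
    cue = factor(cue, levels = CUE_LEVELS),
    shock = factor(shock, levels = SHOCK_LEVELS),
    condition = factor(condition, levels = CONDITION_LEVELS),
    matched = matched,
    sound_onset = onset,
    sound_dur = SOUND_DUR,
    delay_dur = DELAY_DUR,
    shock_dur = SHOCK_DUR,
    rest_dur = rest_dur,
    stringsAsFactors = FALSE
  )
}

new_schedule <- function(trials, session, seed, lead_in) {
  structure(trials,
    session = session, seed = as.integer(seed), lead_in = lead_in,
    class = c("session_schedule", "data.frame")
  )
}

#' Build a conditioning-training trial schedule
#'
#' Training presents only the two matched pairings — 10 LF-LS and 10 HF-HS
#' trials — in random order. Each trial is sound (5 s), delay (5 s), shock
#' (5 s) and rest (10 s).
#'
#' @param seed Integer seed; schedules are deterministic per seed.
#' @param lead_in Quiet period in s before the first sound onset (default 15),
#'   long enough for a 5 s pre-cue baseline and filter settling.
#' @return A `session_schedule` data frame (one row per trial) with columns
#'   `trial`, `cue`, `shock`, `condition`, `matched`, `sound_onset`,
#'   `sound_dur`, `delay_dur`, `shock_dur`, `rest_dur`.
#' @export
#' @examples
#' sched <- build_training_schedule(seed = 1)
#' table(sched$condition)
build_training_schedule <- function(seed, lead_in = 15) {
  check_scalar_number(seed, "seed")
  condition <- with_seed(seed, sample(rep(c("LF-LS", "HF-HS"), each = 10)))
  new_schedule(trial_frame(condition, rest_dur = rep(10, 20), lead_in = lead_in),
    session = "training", seed = seed, lead_in = lead_in
  )
}

#' Build an NIRS recording-session trial schedule
#'
#' The recording session has 32 trials: 13 LF-LS and 11 HF-HS matched trials
#' plus 4 LF-HS and 4 HF-LS mismatched trials (25% mismatched), presented
#' pseudo-randomly. Rest durations are drawn uniformly from `rest_range` so
#' that sound onsets are not anticipated.
#'
#' The pseudo-random order is a uniform permutation re-drawn until no condition
#' occurs more than `max_run` times consecutively and (optionally) no
#' mismatched trial falls in the first two positions; the paper does not pin
#' these constraints down, so both are configurable.
#'
#' @inheritParams build_training_schedule
#' @param rest_range Length-2 numeric, inclusive rest-duration range in s
#'   (default `c(20, 30)`).
#' @param max_run Maximum allowed run of one condition (default 3).
#' @param protect_start If `TRUE` (default) the first two trials must be
#'   matched.
#' @return A `session_schedule` data frame; see [build_training_schedule()].
#' @export
#' @examples
#' sched <- build_recording_schedule(seed = 7)
#' table(sched$condition)        # 13, 11, 4, 4
#' range(sched$rest_dur)         # within [20, 30]
build_recording_schedule <- function(seed, rest_range = c(20, 30),
                                     lead_in = 15, max_run = 3,
                                     protect_start = TRUE) {
  check_scalar_number(seed, "seed")
  if (!is.numeric(rest_range) || length(rest_range) != 2L ||
    any(!is.finite(rest_range)) || rest_range[1] < 0 ||
    rest_range[1] >= rest_range[2]) {
    stop_invalid("`rest_range` must be c(low, high) with 0 <= low < high")
  }
  base <- rep(c("LF-LS", "HF-HS", "LF-HS", "HF-LS"), times = c(13, 11, 4, 4))
  trials <- with_seed(seed, {
    for (attempt in 1:1000) {
      condition <- sample(base)
      runs <- rle(condition)
      ok <- max(runs$lengths) <= max_run
      if (protect_start && ok) {
        ok <- all(condition[1:2] %in% c("LF-LS", "HF-HS"))
      }
      if (ok) break
    }
    if (!ok) stop_invalid("could not satisfy schedule order constraints")
    rest <- runif(length(condition), rest_range[1], rest_range[2])
    trial_frame(condition, rest_dur = rest, lead_in = lead_in)
  })
  new_schedule(trials, session = "recording", seed = seed, lead_in = lead_in)
}

#' Session duration implied by a schedule
#'
#' End of the final trial's rest period plus a short tail, i.e. the minimum
#' recording length that contains every epoch window.
#'
#' @param schedule A `session_schedule`.
#' @param tail Extra time in s appended after the last rest (default 5).
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule, tail = 5) {
  last <- nrow(schedule)
  schedule$sound_onset[last] + SOUND_DUR + DELAY_DUR + SHOCK_DUR +
    schedule$rest_dur[last] + tail
}

#' Expand a schedule to a long per-phase events table
#'
#' @param schedule A `session_schedule`.
#' @return A data frame with one row per phase (sound, delay, shock, rest) and
#'   columns `onset_s`, `duration_s`, `phase`, `cue`, `shock`, `condition`,
#'   `matched`.
#' @export
schedule_events <- function(schedule) {
  phases <- c("sound", "delay", "shock", "rest")
  durs <- cbind(
    schedule$sound_dur, schedule$delay_dur,
    schedule$shock_dur, schedule$rest_dur
  )
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    onset <- schedule$sound_onset[i] + cumsum(c(0, durs[i, 1:3]))
    data.frame(
      onset_s = onset,
      duration_s = as.numeric(durs[i, ]),
      phase = phases,
      cue = as.character(schedule$cue[i]),
      shock = as.character(schedule$shock[i]),
      condition = as.character(schedule$condition[i]),
      matched = schedule$matched[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf(
    "<session_schedule> %s session, %d trials (seed %d)\n",
    attr(x, "session"), nrow(x), attr(x, "seed")
  ))
  print(table(condition = x$condition))
  invisible(x)
}

#' Write a schedule as a tab-separated events table
#'
#' @param schedule A `session_schedule`.
#' @param path Output file path.
#' @param long If `TRUE` write the per-phase table from [schedule_events()];
#'   otherwise one row per trial.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, long = FALSE) {
  tab <- if (long) schedule_events(schedule) else as.data.frame(schedule)
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}
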