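#' Cue-locked epoch average
#'
#' Extracts, for every channel, the epochs around each sound onset of the
#' given cue (regardless of the shock delivered; the response window ends at
#' shock onset) on the half-open window `[onset - 5, onset + 10)` s, averages
#' them pointwise, and subtracts each channel's mean over the pre-cue baseline
#' `[-5, 0)` s.
#'
#' @param recording A (cleaned) `nirs_recording` with per-trial events.
#' @param cue `"LF"` or `"HF"`.
#' @param chromophore Series to analyse (default `"HbO"`).
#' @param baseline,response Window bounds in s relative to sound onset,
#'   half-open `[lo, hi)`.
#' @param include_mismatched If `TRUE` (default) mismatched trials sharing the
#'   cue sound are included in the average.
#' @return An object of class `averaged_response`: list with `timebase`
#'   (s relative to onset), `mean_series` (samples x channels matrix, baseline
#'   corrected), `channels`, `cue`, `n_trials`, `baseline`, `response`,
#'   `sampling_rate`.
#' @export
epoch_average <- function(recording, cue, chromophore = "HbO",
                          baseline = c(-5, 0), response = c(0, 10),
                          include_mismatched = TRUE) {
  stopifnot(inherits(recording, "nirs_recording"))
  cue <- match.arg(cue, CUE_LEVELS)
  ev <- recording$events
  if (is.null(ev) || !nrow(ev)) stop_invalid("recording carries no events")
  sel <- as.character(ev$cue) == cue
  if (!include_mismatched) sel <- sel & ev$matched
  onsets <- ev$sound_onset[sel]
  if (!length(onsets)) stop_invalid("no trials with cue %s", cue)
  fs <- recording$sampling_rate
  pre <- round(-baseline[1] * fs)
  post <- round(response[2] * fs)
  n <- nrow(recording$signals)
  cols <- chrom_cols(recording, chromophore)
  start <- round(onsets * fs) + 1L - pre # first sample of each epoch
  ok <- start >= 1L & (start + pre + post - 1L) <= n
  if (any(!ok)) {
    warning(sprintf(
      "%d trial(s) extend past the recording bounds and were dropped", sum(!ok)
    ), call. = FALSE)
    start <- start[ok]
  }
  if (!length(start)) stop_invalid("no usable trials with cue %s", cue)
  len <- pre + post
  acc <- matrix(0, len, length(cols))
  ss_trials <- numeric(length(cols)) # pooled per-trial baseline sum of squares
  timebase <- (seq_len(len) - 1L - pre) / fs
  base_rel <- which(timebase >= baseline[1] & timebase < baseline[2])
  for (s in start) {
    ep <- recording$signals[s:(s + len - 1L), cols, drop = FALSE]
    acc <- acc + ep
    bl <- ep[base_rel, , drop = FALSE]
    ss_trials <- ss_trials +
      colSums(sweep(bl, 2, colMeans(bl))^2)
  }
  avg <- acc / length(start)
  # pooled SD over the individual trials' pre-cue windows (trial-centered)
  sd_trials <- sqrt(ss_trials / (length(start) * (length(base_rel) - 1L)))
  avg <- sweep(avg, 2, colMeans(avg[base_rel, , drop = FALSE]))
  colnames(avg) <- sub(paste0("_", chromophore, "$"), "", cols)
  structure(
    list(
      timebase = timebase, mean_series = avg, channels = colnames(avg),
      cue = cue, n_trials = length(start), baseline = baseline,
      response = response, sampling_rate = fs,
      baseline_sd_trials = setNames(sd_trials, colnames(avg))
    ),
    class = "averaged_response"
  )
}

#' @export
print.averaged_response <- function(x, ...) {
  cat(sprintf(
    "<averaged_response> cue %s, %d trials, %d channels, window [%g, %g) s\n",
    x$cue, x$n_trials, length(x$channels), x$baseline[1], x$response[2]
  ))
  invisible(x)
}

#' Cue-locked effect size per channel
#'
#' The effect size of a cue-locked response is defined as
#' \deqn{d = \frac{\bar{x}_{[0,10)} - \bar{x}_{[-5,0)}}{SD(x_{[-5,0)})}}
#' i.e. the mean signal during the 10 s after sound onset minus the mean
#' baseline during the 5 s before onset, divided by the baseline standard
#' deviation (sample SD, n-1-type denominator). Numerator terms are always
#' taken from the trial-averaged series. The baseline SD can be estimated
#' two ways: `sd_source = "trials"` (default) pools the individual trials'
#' pre-cue windows (each trial centered on its own baseline mean), giving a
#' stable denominator with roughly `n_trials` times the effective degrees of
#' freedom; `sd_source = "average"` takes the SD of the averaged series'
#' baseline segment itself. For band-limited (0.01-0.1 Hz) signals the 5-s
#' averaged baseline is close to a straight line, so the `"average"` variant
#' has very few effective degrees of freedom and yields a much noisier
#' statistic; see the package vignette. Channels whose baseline SD is zero
#' yield `NA` with a warning.
#'
#' @param avg An `averaged_response` from [epoch_average()].
#' @param sd_source `"trials"` (pooled single-trial baseline SD, default) or
#'   `"average"` (SD of the trial-averaged baseline segment).
#' @return Named numeric vector of effect sizes, one per channel.
#' @export
effect_size <- function(avg, sd_source = c("trials", "average")) {
  stopifnot(inherits(avg, "averaged_response"))
  sd_source <- match.arg(sd_source)
  tb <- avg$timebase
  base_idx <- tb >= avg$baseline[1] & tb < avg$baseline[2]
  resp_idx <- tb >= avg$response[1] & tb < avg$response[2]
  base <- avg$mean_series[base_idx, , drop = FALSE]
  resp <- avg$mean_series[resp_idx, , drop = FALSE]
  sd_b <- if (sd_source == "trials" && !is.null(avg$baseline_sd_trials)) {
    avg$baseline_sd_trials
  } else {
    apply(base, 2, sd)
  }
  es <- (colMeans(resp) - colMeans(base)) / sd_b
  bad <- !is.finite(es)
  if (any(bad)) {
    es[bad] <- NA_real_
    warning(sprintf(
      "effect size undefined (zero baseline SD) for channel(s): %s",
      paste(avg$channels[bad], collapse = ", ")
    ), call. = FALSE)
  }
  setNames(es, avg$channels)
}

#' Effect size of a single epoch series
#'
#' Convenience wrapper applying the effect-size formula to one numeric series
#' on a given timebase (s relative to sound onset).
#'
#' @param series Numeric vector.
#' @param timebase Numeric vector of times in s relative to onset.
#' @inheritParams epoch_average
#' @return A single effect size.
#' @export
#' @examples
#' tb <- c(-2, -1.5, -1, -0.5, 0, 1)
#' effect_size_series(c(1, 3, 1, 3, 5, 5), tb,
#'   baseline = c(-2, 0), response = c(0, 2)
#' ) # (5 - 2) / sd(c(1,3,1,3)) = 2.598
effect_size_series <- function(series, timebase, baseline = c(-5, 0),
                               response = c(0, 10)) {
  stopifnot(length(series) == length(timebase))
  b <- series[timebase >= baseline[1] & timebase < baseline[2]]
  r <- series[timebase >= response[1] & timebase < response[2]]
  if (length(b) < 2 || sd(b) == 0) {
    stop_invalid("effect size undefined: baseline SD is zero or baseline too short")
  }
  (mean(r) - mean(b)) / sd(b)
}

#' ROI-mean effect size
#'
#' Unweighted mean of per-channel effect sizes over the composite channels
#' labelled with the given ROI; channels with undefined effect size (`NA`)
#' are excluded with a warning.
#'
#' @param es Named effect-size vector from [effect_size()].
#' @param geometry Channel geometry table with `roi` labels.
#' @param roi `"right_dlPFC"` or `"left_dlPFC"`.
#' @return List with `roi`, `effect_size` (the ROI mean) and `n_channels`.
#' @export
roi_effect_size <- function(es, geometry, roi = c("right_dlPFC", "left_dlPFC")) {
  roi <- match.arg(roi)
  ids <- geometry$channel_id[geometry$roi == roi & geometry$kind == "composite"]
  if (!length(ids)) stop_invalid("no composite channels labelled %s", roi)
  vals <- es[intersect(ids, names(es))]
  if (!length(vals)) stop_invalid("no effect sizes available for ROI %s", roi)
  if (anyNA(vals)) {
    warning(sprintf(
      "excluding %d channel(s) with undefined effect size from ROI %s",
      sum(is.na(vals)), roi
    ), call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) stop_invalid("all ROI %s effect sizes undefined", roi)
  list(roi = roi, effect_size = mean(vals), n_channels = length(vals))
}

#' Full preprocessing + effect-size pipeline for one recording
#'
#' Band-pass filters, removes the systemic component, epochs around each cue
#' and returns the ROI-mean effect sizes — the per-participant unit of the
#' analysis.
#'
#' @param recording A raw `nirs_recording` with events.
#' @param geometry Channel geometry table.
#' @param low_cut,high_cut,order Band-pass settings; see [bandpass()].
#' @param n_components Principal components to remove; see
#'   [remove_systemic()].
#' @param rois ROIs to aggregate (defaults to those present in `geometry`).
#' @param include_mismatched Passed to [epoch_average()].
#' @param sd_source Baseline-SD estimator; see [effect_size()].
#' @return Data frame with one row per ROI x cue: `roi`, `cue`,
#'   `effect_size`, `n_trials`, `n_channels`.
#' @export
participant_effect_sizes <- function(recording, geometry,
                                     low_cut = 0.01, high_cut = 0.1, order = 3,
                                     n_components = 2, rois = NULL,
                                     include_mismatched = TRUE,
                                     sd_source = "trials") {
  rois <- rois %||% intersect(
    c("right_dlPFC", "left_dlPFC"),
    as.character(unique(geometry$roi))
  )
  rec <- bandpass(recording, low_cut, high_cut, order)
  rec <- remove_systemic(rec, geometry, n_components)
  rows <- list()
  for (cue in CUE_LEVELS) {
    avg <- epoch_average(rec, cue, include_mismatched = include_mismatched)
    es <- effect_size(avg, sd_source = sd_source)
    for (roi in rois) {
      r <- roi_effect_size(es, geometry, roi)
      rows[[paste(roi, cue)]] <- data.frame(
        roi = roi, cue = cue, effect_size = r$effect_size,
        n_trials = avg$n_trials, n_channels = r$n_channels,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROI effect sizes for a whole cohort
#'
#' Applies [participant_effect_sizes()] to every recording of a cohort (or to
#' a cohort streamed from a config; see [simulate_cohort()]'s `FUN` argument)
#' and returns the tidy participant x ROI x cue table the statistical battery
#' consumes.
#'
#' @param cohort A `nirs_cohort` with recordings, or a `cohort_config` (the
#'   cohort is then simulated participant-by-participant without keeping
#'   recordings in memory).
#' @param montage,chromophores Used only when `cohort` is a config.
#' @param ... Passed to [participant_effect_sizes()].
#' @return List with `effect_sizes` (data frame: `participant_id`, `group`,
#'   `roi`, `cue`, `effect_size`, `n_trials`, `n_channels`), `vas_table`,
#'   `profiles`, `ground_truth`.
#' @export
cohort_effect_sizes <- function(cohort, montage = "full",
                                chromophores = "HbO", ...) {
  if (inherits(cohort, "cohort_config")) {
    cohort <- simulate_cohort(cohort,
      montage = montage, chromophores = chromophores,
      keep_recordings = FALSE,
      FUN = function(rec, geom) participant_effect_sizes(rec, geom, ...)
    )
    per <- cohort$measures
  } else {
    stopifnot(inherits(cohort, "nirs_cohort"))
    if (!length(cohort$measures)) {
      if (!length(cohort$recordings)) {
        stop_invalid("cohort holds neither recordings nor measures")
      }
      per <- lapply(
        cohort$recordings,
        function(rec) participant_effect_sizes(rec, cohort$geometry, ...)
      )
    } else {
      per <- cohort$measures
    }
  }
  rows <- lapply(names(per), function(id) {
    df <- per[[id]]
    df$participant_id <- id
    df$group <- cohort$profiles$group[cohort$profiles$participant_id == id]
    df[, c(
      "participant_id", "group", "roi", "cue", "effect_size",
      "n_trials", "n_channels"
    )]
  })
  es <- do.call(rbind, rows)
  rownames(es) <- NULL
  list(
    effect_sizes = es, vas_table = cohort$vas_table,
    profiles = cohort$profiles, ground_truth = cohort$ground_truth
  )
}

#' Cue-locked signal-to-noise ratio per channel
#'
#' SNR of the event-locked average, defined as the peak absolute amplitude of
#' the averaged response within the response window divided by the SD of the
#' averaged series over the baseline segment. Used to quantify how much the
#' systemic-component removal improves the cue-locked average.
#'
#' @inheritParams epoch_average
#' @return Named numeric vector of SNR values, one per channel.
#' @export
channel_snr <- function(recording, cue = "LF", chromophore = "HbO") {
  avg <- epoch_average(recording, cue, chromophore = chromophore)
  tb <- avg$timebase
  resp <- tb >= avg$response[1] & tb < avg$response[2]
  base <- tb >= avg$baseline[1] & tb < avg$baseline[2]
  peak <- apply(abs(avg$mean_series[resp, , drop = FALSE]), 2, max)
  noise <- apply(avg$mean_series[base, , drop = FALSE], 2, sd)
  peak / noise
}
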