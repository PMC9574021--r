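# Recording with a known kernel planted at each cue onset and no noise.
planted_recording <- function(sched, amp_lf = 1, amp_hf = 0, fs = 10, nch = 1) {
  n <- floor(schedule_duration(sched) * fs)
  reg <- amp_lf * placebonirs:::cue_regressor(
    n, fs, sched$sound_onset[sched$cue == "LF"]
  ) +
    amp_hf * placebonirs:::cue_regressor(
      n, fs, sched$sound_onset[sched$cue == "HF"]
    )
  sig <- matrix(rep(reg, nch), n, nch)
  colnames(sig) <- sprintf("C%02d_HbO", seq_len(nch))
  make_recording(sig, fs = fs, events = as.data.frame(sched))
}

test_that("epoch averages recover a planted noise-free response", {
  sched <- build_recording_schedule(3)
  rec <- planted_recording(sched)
  avg <- epoch_average(rec, "LF")
  expect_equal(avg$n_trials, 17) # 13 matched + 4 mismatched LF trials
  expect_equal(epoch_average(rec, "HF")$n_trials, 15) # 11 + 4
  expect_equal(
    epoch_average(rec, "LF", include_mismatched = FALSE)$n_trials, 13
  )
  # the averaged response matches the kernel (tails of neighbouring trials
  # are tiny at these inter-trial intervals)
  k <- hrf_kernel(10)
  resp <- avg$mean_series[avg$timebase >= 0, 1]
  expect_lt(max(abs(resp - k[seq_along(resp)])), 5e-3)
})

test_that("a constant signal averages to zero after baseline correction", {
  sched <- build_recording_schedule(4)
  n <- floor(schedule_duration(sched) * 10)
  sig <- matrix(7.3, n, 1, dimnames = list(NULL, "C01_HbO"))
  rec <- make_recording(sig, events = as.data.frame(sched))
  avg <- epoch_average(rec, "LF")
  expect_true(all(avg$mean_series == 0))
})

test_that("epochs outside the recording are dropped with a warning", {
  sched <- build_recording_schedule(5)
  rec <- planted_recording(sched)
  rec$signals <- rec$signals[seq_len(round(sched$sound_onset[32] * 10)), , drop = FALSE]
  rec$time <- rec$time[seq_len(nrow(rec$signals))]
  expect_warning(avg <- epoch_average(rec, as.character(sched$cue[32])), "dropped")
  expect_error(
    suppressWarnings(epoch_average(rec, "LF", baseline = c(-1e5, 0))),
    "usable"
  )
})

test_that("the effect-size formula matches the hand-computed oracle", {
  # baseline {1,3,1,3}: sample SD = sqrt(4/3); response mean 5, baseline mean 2
  tb <- c(-2, -1.5, -1, -0.5, 0, 0.5)
  es <- effect_size_series(c(1, 3, 1, 3, 5, 5), tb,
    baseline = c(-2, 0), response = c(0, 1)
  )
  expect_equal(es, 3 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(es, 2.598, tolerance = 1e-3)
  # response mean equal to baseline mean gives zero
  expect_equal(
    effect_size_series(c(1, 3, 1, 3, 2, 2), tb, c(-2, 0), c(0, 1)), 0
  )
  # constant baseline is undefined
  expect_error(
    effect_size_series(c(2, 2, 2, 2, 5, 5), tb, c(-2, 0), c(0, 1)),
    "undefined"
  )
})

test_that("effect sizes are invariant to scaling and shifting the recording", {
  sched <- build_recording_schedule(6)
  cfg <- quick_config(seed = 9)
  geom <- build_geometry("right_dlpfc")
  p <- participant_profiles(cfg)[1, ]
  rec <- simulate_recording(p, sched, geom, cfg, chromophores = "HbO")
  avg0 <- epoch_average(rec, "LF")
  for (sd_source in c("trials", "average")) {
    es0 <- effect_size(avg0, sd_source)
    rec2 <- rec
    rec2$signals <- rec$signals * 3.7 + 11
    es2 <- effect_size(epoch_average(rec2, "LF"), sd_source)
    expect_equal(es2, es0, tolerance = 1e-9)
  }
  # and for the plain series form, over randomized inputs
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(150)
    tb <- seq(-5, 9.9, by = 0.1)
    c0 <- runif(1, 0.1, 10)
    d0 <- runif(1, -50, 50)
    expect_equal(
      effect_size_series(c0 * x + d0, tb),
      effect_size_series(x, tb),
      tolerance = 1e-9
    )
  }
})

test_that("ROI aggregation averages channels and excludes undefined ones", {
  geom <- make_geometry(n_comp = 3, n_short = 1, n_roi = 3)
  es <- c(C01 = 1.0, C02 = 2.0, C03 = 3.0)
  r <- roi_effect_size(es, geom, "right_dlPFC")
  expect_equal(r$effect_size, 2.0)
  expect_equal(r$n_channels, 3)
  # single-channel ROI
  geom1 <- make_geometry(n_comp = 3, n_short = 1, n_roi = 1)
  expect_equal(roi_effect_size(es, geom1, "right_dlPFC")$effect_size, 1.0)
  # undefined channel dropped with a warning
  es_na <- c(C01 = 1.0, C02 = NA, C03 = 3.0)
  expect_warning(r2 <- roi_effect_size(es_na, geom, "right_dlPFC"), "excluding")
  expect_equal(r2$effect_size, 2.0)
  expect_equal(r2$n_channels, 2)
  expect_error(roi_effect_size(es, geom1, "left_dlPFC"), "no composite channels")
})

test_that("ROI labels follow Brodmann area and hemisphere of MNI x", {
  geom <- data.frame(
    channel_id = c("A", "B", "C", "D"),
    source_id = "S", detector_id = "D",
    distance = 3.0, kind = "composite",
    mni_x = c(22, -30, 15, 40), mni_y = c(57, 40, 60, 42),
    mni_z = c(37, 30, 20, 10), # D sits below the lookup box

    ba = c(NA, 46, 10, NA),
    roi = factor("none", levels = c("right_dlPFC", "left_dlPFC", "none")),
    stringsAsFactors = FALSE
  )
  lookup <- data.frame(
    ba = 9, x_min = 10, x_max = 50, y_min = 40, y_max = 70,
    z_min = 25, z_max = 60
  )
  out <- assign_roi(geom, lookup)
  expect_equal(as.character(out$roi), c("right_dlPFC", "left_dlPFC", "none", "none"))
  # pre-labelled channels pass through unchanged
  geom$roi[3] <- "left_dlPFC"
  out2 <- assign_roi(geom, lookup)
  expect_equal(as.character(out2$roi[3]), "left_dlPFC")
  geom_bad <- geom
  geom_bad$mni_x <- NA
  geom_bad$ba <- NA
  geom_bad$roi[] <- "none"
  expect_error(assign_roi(geom_bad[, setdiff(names(geom_bad), "ba")]), "neither")
})

test_that("ROI effect size grows monotonically with the planted amplitude", {
  sched <- build_recording_schedule(8)
  geom <- make_geometry(n_comp = 2, n_short = 2, n_roi = 2)
  es_at <- vapply(c(0.5, 1, 2, 4, 8), function(a) {
    rec <- planted_recording(sched, amp_lf = a, nch = 1)
    # duplicate the channel to fill the 2-channel ROI, add fixed tiny noise
    sig <- cbind(rec$signals, rec$signals, 0, 0)
    set.seed(42)
    sig <- sig + matrix(rnorm(length(sig), 0, 1e-3), nrow(sig))
    colnames(sig) <- paste0(geom$channel_id, "_HbO")
    r <- make_recording(sig, events = as.data.frame(sched))
    es <- effect_size(epoch_average(r, "LF"))
    roi_effect_size(es, geom, "right_dlPFC")$effect_size
  }, numeric(1))
  expect_true(all(diff(es_at) > 0))
})
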