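#' Default per-group generative parameters
#'
#' One list entry per participant group (elderly/young x male/female), each
#' holding the group means and SDs that drive the synthetic cohort: cerebral
#' response amplitudes per hemisphere x cue, pain-index means, VAS condition
#' means, demographic distributions, and the coupling correlation between the
#' true right dl-PFC response to the safe (LF) cue and the pain-reduction
#' index. Coupling correlations default to `{0.669, 0.582, 0.580, 0.271}` for
#' the elderly-male, elderly-female, young-male and young-female groups; the
#' demographic means/SEMs follow the study's baseline table (SDs recovered as
#' SEM x sqrt(15)). Response amplitudes and VAS means are illustrative
#' defaults chosen to reproduce the qualitative group pattern (highest
#' response and reduction index in elderly females, lowest in young females);
#' no empirical amplitudes are published.
#'
#' @return Named list of per-group parameter lists.
#' @export
default_group_params <- function() {
  grp <- function(amp, reduction, enhancement, vas_hfhs, vas_lfls, rho,
                  age, age_sd, mmse, mmse_sd, ma, ma_sd) {
    list(
      amp = amp, amp_sd = 0.65 * unname(amp["right_LF"]), amp_cor = 0.5,
      reduction_mean = reduction, reduction_sd = 8,
      enhancement_mean = enhancement, enhancement_sd = 6,
      vas_hfhs = vas_hfhs, vas_lfls = vas_lfls, vas_between_sd = 6,
      vas_sd = 2, coupling_rho = rho,
      age_mean = age, age_sd = age_sd,
      mmse_mean = mmse, mmse_sd = mmse_sd,
      max_current_mean = ma, max_current_sd = ma_sd
    )
  }
  amp_names <- c("right_LF", "right_HF", "left_LF", "left_HF")
  list(
    elderly_male = grp(
      setNames(c(1.00, 0.95, 0.80, 0.80), amp_names),
      reduction = 12, enhancement = 14, vas_hfhs = 72, vas_lfls = 45,
      rho = 0.669, age = 66.2, age_sd = 8.1, mmse = 29.0, mmse_sd = 1.12,
      ma = 2.12, ma_sd = 1.24
    ),
    elderly_female = grp(
      setNames(c(1.40, 1.35, 0.85, 0.85), amp_names),
      reduction = 25, enhancement = 16, vas_hfhs = 75, vas_lfls = 47,
      rho = 0.582, age = 66.3, age_sd = 6.6, mmse = 29.5, mmse_sd = 0.81,
      ma = 1.68, ma_sd = 1.16
    ),
    young_male = grp(
      setNames(c(1.00, 0.95, 0.80, 0.80), amp_names),
      reduction = 12, enhancement = 8, vas_hfhs = 70, vas_lfls = 44,
      rho = 0.580, age = 22.3, age_sd = 1.9, mmse = NA, mmse_sd = NA,
      ma = 3.93, ma_sd = 1.59
    ),
    young_female = grp(
      setNames(c(0.55, 0.60, 0.75, 0.75), amp_names),
      reduction = 4, enhancement = 7, vas_hfhs = 70, vas_lfls = 44,
      rho = 0.271, age = 22.5, age_sd = 2.3, mmse = NA, mmse_sd = NA,
      ma = 3.01, ma_sd = 2.13
    )
  )
}

#' Cohort simulation configuration
#'
#' @param n_per_group Participants per group (>= 2; default 15, the study's
#'   group size).
#' @param seed Master integer seed; per-participant seeds are derived from it
#'   with [derive_seed()].
#' @param sampling_rate Sampling rate in Hz (> 0.2; default 10).
#' @param noise List of physiological/instrumental noise amplitudes
#'   (concentration units): `drift_amp`, `mayer = list(amp, freq)`,
#'   `respiratory = list(amp, freq)`, `cardiac = list(amp, freq)`, `white_sd`.
#' @param systemic_rank Number of shared systemic source time courses (>= 2).
#' @param background_amp Cerebral response amplitude planted on composite
#'   channels outside the dl-PFC ROIs (a widespread auditory response), so
#'   every composite channel has a defined cue-locked signal.
#' @param group_params Per-group generative parameters; see
#'   [default_group_params()].
#' @param empirical If `TRUE` (default) the per-group latent scores (response
#'   amplitudes, pain indices) realize the configured means, SDs and coupling
#'   correlations exactly in-sample (`MASS::mvrnorm(empirical = TRUE)`), so
#'   parameter-recovery error measures pipeline distortion rather than cohort
#'   sampling noise. Set `FALSE` for fully stochastic cohorts. Groups smaller
#'   than 7 always fall back to stochastic draws.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 15, seed = 1, sampling_rate = 10,
                          noise = list(
                            drift_amp = 1.0,
                            mayer = list(amp = 4, freq = 0.1),
                            respiratory = list(amp = 0.8, freq = 0.3),
                            cardiac = list(amp = 0.6, freq = 1.2),
                            white_sd = 1.2
                          ),
                          systemic_rank = 2, background_amp = 0.6,
                          group_params = default_group_params(),
                          empirical = TRUE) {
  check_scalar_number(n_per_group, "n_per_group", positive = TRUE)
  if (n_per_group < 2) stop_invalid("`n_per_group` must be >= 2")
  check_scalar_number(seed, "seed")
  check_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (sampling_rate <= 0.2) stop_invalid("`sampling_rate` must exceed 0.2 Hz")
  check_scalar_number(systemic_rank, "systemic_rank", positive = TRUE)
  if (systemic_rank < 2) stop_invalid("`systemic_rank` must be >= 2")
  stopifnot(identical(sort(names(group_params)), sort(GROUP_LEVELS)))
  structure(
    list(
      n_per_group = as.integer(n_per_group), seed = as.integer(seed),
      sampling_rate = sampling_rate, noise = noise,
      systemic_rank = as.integer(systemic_rank),
      background_amp = background_amp,
      group_params = group_params, empirical = isTRUE(empirical)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d participants/group x 4 groups, fs = %g Hz, seed = %d\n",
    x$n_per_group, x$sampling_rate, x$seed
  ))
  rho <- vapply(x$group_params, `[[`, numeric(1), "coupling_rho")
  cat("coupling rho:", paste(sprintf("%s %.3f", names(rho), rho), collapse = ", "), "\n")
  invisible(x)
}

# Correlation model for the latent per-participant scores of one group:
# the four response amplitudes share a common factor (pairwise r = amp_cor);
# the reduction index correlates with the right-LF amplitude at coupling_rho
# (and with the other amplitudes at amp_cor * coupling_rho, consistent with
# the factor structure); the enhancement index is independent.
latent_sigma <- function(gp) {
  r_a <- gp$amp_cor
  rho <- gp$coupling_rho
  C <- diag(6)
  C[1:4, 1:4] <- r_a
  diag(C) <- 1
  C[5, 1:4] <- C[1:4, 5] <- c(rho, r_a * rho, r_a * rho, r_a * rho)
  sds <- c(rep(gp$amp_sd, 4), gp$reduction_sd, gp$enhancement_sd)
  diag(sds) %*% C %*% diag(sds)
}

#' Draw per-participant profiles for the four groups
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with one row per participant: identifiers, group,
#'   demographics (`age`, `mmse`, `max_current`), true response amplitudes
#'   (`amp_right_LF`, `amp_right_HF`, `amp_left_LF`, `amp_left_HF`), true pain
#'   indices (`reduction_true`, `enhancement_true`), per-condition VAS means
#'   (`vas_LF.LS`, `vas_HF.HS`, `vas_LF.HS`, `vas_HF.LS`), `vas_sd`,
#'   `coupling_rho` and the derived per-participant `seed`.
#' @export
participant_profiles <- function(config) {
  n <- config$n_per_group
  rows <- lapply(seq_along(GROUP_LEVELS), function(g) {
    grp <- GROUP_LEVELS[g]
    gp <- config$group_params[[grp]]
    seed_g <- derive_seed(config$seed, 1000 + g)
    with_seed(seed_g, {
      mu <- c(gp$amp, gp$reduction_mean, gp$enhancement_mean)
      Sigma <- latent_sigma(gp)
      emp <- config$empirical && n > ncol(Sigma)
      lat <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma, empirical = emp)
      vas_hfhs <- gp$vas_hfhs + rnorm(n, 0, gp$vas_between_sd)
      vas_lfls <- gp$vas_lfls + rnorm(n, 0, gp$vas_between_sd)
      age <- gp$age_mean + rnorm(n, 0, gp$age_sd)
      mmse <- if (is.na(gp$mmse_mean)) rep(NA_real_, n) else
        pmin(30, round(gp$mmse_mean + rnorm(n, 0, gp$mmse_sd)))
      max_current <- pmax(0.2, gp$max_current_mean + rnorm(n, 0, gp$max_current_sd))
      data.frame(
        participant_id = sprintf("%s_%02d", grp, seq_len(n)),
        group = grp,
        age = age, mmse = mmse, max_current = max_current,
        amp_right_LF = lat[, 1], amp_right_HF = lat[, 2],
        amp_left_LF = lat[, 3], amp_left_HF = lat[, 4],
        reduction_true = lat[, 5], enhancement_true = lat[, 6],
        vas_HF.HS = vas_hfhs,
        vas_LF.HS = vas_hfhs - lat[, 5],
        vas_LF.LS = vas_lfls,
        vas_HF.LS = vas_lfls + lat[, 6],
        vas_sd = gp$vas_sd, coupling_rho = gp$coupling_rho,
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = GROUP_LEVELS)
  out$seed <- derive_seed(config$seed, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Shared systemic source time courses: each of `rank` sources mixes Mayer,
# respiratory and cardiac sinusoids at random phase with an AR(1) slow
# process; source k is scaled by 1/k so the principal-component order of the
# short channels is stable.
systemic_sources <- function(n, fs, noise, rank) {
  t <- (seq_len(n) - 1) / fs
  S <- matrix(0, n, rank)
  for (k in seq_len(rank)) {
    ph <- runif(3, 0, 2 * pi)
    src <- noise$mayer$amp * sin(2 * pi * noise$mayer$freq * t + ph[1]) +
      noise$respiratory$amp * sin(2 * pi * noise$respiratory$freq * t + ph[2]) +
      noise$cardiac$amp * sin(2 * pi * noise$cardiac$freq * t + ph[3])
    # slow scalp blood-flow drift: AR(1) with ~100 s time constant, well
    # below the cue-response band so it does not mimic event-locked signal
    ar <- stats::filter(rnorm(n), 0.999, method = "recursive")
    ar <- as.numeric(ar) / sqrt(1 / (1 - 0.999^2)) * (0.3 * noise$mayer$amp)
    S[, k] <- (src + ar) / k
  }
  S
}

per_channel_amp <- function(geometry, profile, background_amp) {
  amp <- matrix(0, nrow(geometry), 2, dimnames = list(geometry$channel_id, CUE_LEVELS))
  comp <- geometry$kind == "composite"
  amp[comp, "LF"] <- background_amp
  amp[comp, "HF"] <- background_amp
  r <- geometry$roi == "right_dlPFC"
  l <- geometry$roi == "left_dlPFC"
  amp[r, "LF"] <- profile$amp_right_LF
  amp[r, "HF"] <- profile$amp_right_HF
  amp[l, "LF"] <- profile$amp_left_LF
  amp[l, "HF"] <- profile$amp_left_HF
  amp
}

#' Simulate one participant's multi-channel NIRS recording
#'
#' Composite-channel oxygenated hemoglobin (HbO) is built as the sum of a
#' cue-locked cerebral response (unit-peak hemodynamic kernel at each sound
#' onset, scaled by the participant's true amplitude for that channel's ROI
#' and cue), a shared low-rank systemic component mixed into every channel
#' through a random positive loading matrix, slow drift, and white noise.
#' Non-cerebral (short) channels receive the systemic, drift and noise terms
#' but no cerebral term. Deoxygenated hemoglobin (HbR) is modelled as -0.3
#' times the cerebral term plus independent noise, and HbT = HbO + HbR.
#'
#' @param profile One row of [participant_profiles()] (data frame or list).
#' @param schedule A recording-session schedule from
#'   [build_recording_schedule()].
#' @param geometry Channel geometry table; must contain at least one composite
#'   and one non-cerebral channel and dl-PFC ROI labels.
#' @param config A [cohort_config()].
#' @param chromophores Which chromophores to generate (subset of
#'   `c("HbO", "HbR", "HbT")`).
#' @param duration Optional recording duration in s; must not be shorter than
#'   the schedule. Defaults to [schedule_duration()].
#' @return An object of class `nirs_recording`: a list with `sampling_rate`,
#'   `time`, `signals` (numeric matrix, one column per `<channel>_<chromophore>`),
#'   `channels`, `chromophores`, `events` (the per-trial schedule) and
#'   `provenance`.
#' @export
simulate_recording <- function(profile, schedule, geometry, config,
                               chromophores = c("HbO", "HbR", "HbT"),
                               duration = NULL) {
  profile <- as.list(profile)
  validate_geometry(geometry)
  chromophores <- match.arg(chromophores, several.ok = TRUE)
  if ("HbT" %in% chromophores && !all(c("HbO", "HbR") %in% chromophores)) {
    stop_invalid("HbT requires HbO and HbR")
  }
  if (!any(geometry$roi != "none")) {
    stop_invalid("geometry carries no ROI labels; run assign_roi() first")
  }
  if (sum(geometry$kind == "composite") < 1 ||
    sum(geometry$kind == "non_cerebral") < 1) {
    stop_invalid("geometry needs at least one composite and one non-cerebral channel")
  }
  fs <- config$sampling_rate
  need <- schedule_duration(schedule)
  if (is.null(duration)) duration <- need
  if (duration < need) {
    stop_invalid(
      "schedule (%.1f s) is longer than the requested duration (%.1f s)",
      need, duration
    )
  }
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- nrow(geometry)
  noise <- config$noise
  amp <- per_channel_amp(geometry, profile, config$background_amp)

  sig <- with_seed(profile$seed %||% config$seed, {
    reg <- vapply(
      CUE_LEVELS,
      function(cu) cue_regressor(n, fs, schedule$sound_onset[schedule$cue == cu]),
      numeric(n)
    )
    cerebral <- reg %*% t(amp) # n x nch
    S <- systemic_sources(n, fs, noise, config$systemic_rank)
    L <- matrix(runif(nch * config$systemic_rank, 0.5, 1.5),
      nch, config$systemic_rank
    )
    slope <- runif(nch, -1, 1)
    ph <- runif(nch, 0, 2 * pi)
    drift <- outer(t / max(t[n], 1) - 0.5, slope) * noise$drift_amp +
      noise$drift_amp * 0.5 * sin(outer(2 * pi * 0.004 * t, rep(1, nch)) +
        rep(ph, each = n))
    hbo <- cerebral + S %*% t(L) + drift +
      matrix(rnorm(n * nch, 0, noise$white_sd), n, nch)
    out <- list(HbO = hbo)
    if (any(c("HbR", "HbT") %in% chromophores)) {
      hbr <- -0.3 * cerebral +
        matrix(rnorm(n * nch, 0, 0.5 * noise$white_sd), n, nch)
      out$HbR <- hbr
      if ("HbT" %in% chromophores) out$HbT <- hbo + hbr
    }
    out
  })

  mats <- lapply(chromophores, function(cc) {
    m <- sig[[cc]]
    colnames(m) <- paste0(geometry$channel_id, "_", cc)
    m
  })
  signals <- do.call(cbind, mats)
  new_recording(
    sampling_rate = fs, time = t, signals = signals,
    channels = geometry$channel_id, chromophores = chromophores,
    events = as.data.frame(schedule),
    provenance = list(sprintf(
      "simulate_recording: participant=%s seed=%s fs=%g n=%d channels=%d",
      profile$participant_id %||% "?", profile$seed %||% config$seed, fs, n, nch
    ))
  )
}

#' Simulate per-trial VAS pain ratings
#'
#' Each trial's rating is the participant's condition-level VAS mean (which
#' already carries the placebo/nocebo structure and the coupling to the true
#' right dl-PFC response) plus independent trial noise, clipped to `[0, 100]`.
#'
#' @param profile One row of [participant_profiles()].
#' @param schedule A `session_schedule`.
#' @param seed Optional integer seed; defaults to a stream derived from the
#'   profile's seed.
#' @return The schedule data frame with an added `vas` column.
#' @export
simulate_vas <- function(profile, schedule, seed = NULL) {
  profile <- as.list(profile)
  seed <- seed %||% derive_seed(profile$seed %||% 0, 77)
  means <- c(
    "LF-LS" = profile$vas_LF.LS, "HF-HS" = profile$vas_HF.HS,
    "LF-HS" = profile$vas_LF.HS, "HF-LS" = profile$vas_HF.LS
  )
  ev <- as.data.frame(schedule)
  ev$vas <- with_seed(seed, {
    pmin(100, pmax(0, means[as.character(ev$condition)] +
      rnorm(nrow(ev), 0, profile$vas_sd)))
  })
  rownames(ev) <- NULL
  ev
}

#' Simulate a full four-group cohort
#'
#' Draws participant profiles, builds one pseudo-random recording schedule per
#' participant, and simulates the NIRS recording and per-trial VAS ratings.
#' Ground truth (true amplitudes, true indices, realized seeds) is returned
#' losslessly for parameter-recovery studies.
#'
#' @param config A [cohort_config()].
#' @param montage Geometry montage passed to [build_geometry()].
#' @param chromophores Chromophores to simulate; restrict to `"HbO"` for large
#'   recovery studies (the analysis uses HbO only).
#' @param keep_recordings If `FALSE`, recordings are dropped after `FUN` is
#'   applied (saves memory on large cohorts).
#' @param FUN Optional function `(recording, geometry) -> value` applied to
#'   each recording as it is produced; results are returned in `$measures`.
#' @return An object of class `nirs_cohort`: list with `profiles`, `geometry`,
#'   `schedules`, `recordings` (named list, possibly empty), `events` (per-
#'   trial tables with VAS), `vas_table` (participant x condition means),
#'   `ground_truth`, `measures`, `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 2, seed = 1)
#' coh <- simulate_cohort(cfg, montage = "right_dlpfc", chromophores = "HbO")
#' nrow(coh$profiles) # 8 participants
simulate_cohort <- function(config, montage = "full",
                            chromophores = c("HbO", "HbR", "HbT"),
                            keep_recordings = TRUE, FUN = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  geometry <- build_geometry(montage)
  profiles <- participant_profiles(config)
  recordings <- list()
  events <- list()
  schedules <- list()
  measures <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    sched <- build_recording_schedule(seed = derive_seed(p$seed, 5))
    rec <- simulate_recording(p, sched, geometry, config, chromophores)
    ev <- simulate_vas(p, sched)
    rec$events <- ev
    id <- p$participant_id
    schedules[[id]] <- sched
    events[[id]] <- ev
    if (!is.null(FUN)) measures[[id]] <- FUN(rec, geometry)
    if (keep_recordings) recordings[[id]] <- rec
  }
  vas_table <- cohort_vas_table(events, profiles)
  ground_truth <- profiles[, c(
    "participant_id", "group", "amp_right_LF", "amp_right_HF",
    "amp_left_LF", "amp_left_HF", "reduction_true", "enhancement_true",
    "coupling_rho", "seed"
  )]
  structure(
    list(
      profiles = profiles, geometry = geometry, schedules = schedules,
      recordings = recordings, events = events, vas_table = vas_table,
      ground_truth = ground_truth, measures = measures, config = config
    ),
    class = "nirs_cohort"
  )
}

# Participant x condition mean VAS table from per-trial events.
cohort_vas_table <- function(events, profiles) {
  rows <- lapply(names(events), function(id) {
    ev <- events[[id]]
    m <- tapply(ev$vas, ev$condition, mean)
    data.frame(
      participant_id = id,
      group = profiles$group[profiles$participant_id == id],
      condition = factor(names(m), levels = CONDITION_LEVELS),
      mean_vas = as.numeric(m),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.nirs_cohort <- function(x, ...) {
  cat(sprintf(
    "<nirs_cohort> %d participants (%d/group), %d channels, seed %d\n",
    nrow(x$profiles), x$config$n_per_group, nrow(x$geometry), x$config$seed
  ))
  cat(sprintf(
    "  recordings kept: %d; chromophores: %s\n",
    length(x$recordings),
    if (length(x$recordings)) paste(x$recordings[[1]]$chromophores, collapse = "/") else "-"
  ))
  invisible(x)
}
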