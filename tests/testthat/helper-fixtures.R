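# Small fixtures shared across test files; everything is built in code.

# Recording wrapping a raw signal matrix (columns already named
# <channel>_<chromophore>) on a uniform grid.
make_recording <- function(signals, fs = 10, events = NULL) {
  chans <- unique(sub("_(HbO|HbR|HbT)$", "", colnames(signals)))
  chroms <- intersect(
    c("HbO", "HbR", "HbT"),
    unique(sub("^.*_", "", colnames(signals)))
  )
  new_recording(
    sampling_rate = fs, time = (seq_len(nrow(signals)) - 1) / fs,
    signals = signals, channels = chans, chromophores = chroms,
    events = events
  )
}

# Minimal multi-distance geometry: n_comp long channels (first `n_roi` of them
# labelled right dl-PFC) plus n_short short channels.
make_geometry <- function(n_comp = 3, n_short = 2, n_roi = 1) {
  n <- n_comp + n_short
  data.frame(
    channel_id = sprintf("C%02d", seq_len(n)),
    source_id = "S01", detector_id = sprintf("D%02d", seq_len(n)),
    distance = rep(c(3.0, 1.5), c(n_comp, n_short)),
    kind = rep(c("composite", "non_cerebral"), c(n_comp, n_short)),
    mni_x = NA_real_, mni_y = NA_real_, mni_z = NA_real_, ba = NA_real_,
    roi = factor(rep(c("right_dlPFC", "none"), c(n_roi, n - n_roi)),
      levels = c("right_dlPFC", "left_dlPFC", "none")
    ),
    stringsAsFactors = FALSE
  )
}

# A tiny cohort configuration for fast end-to-end tests.
quick_config <- function(n_per_group = 2, seed = 1, ...) {
  cohort_config(n_per_group = n_per_group, seed = seed, ...)
}
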