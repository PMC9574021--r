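#' Canonical hemodynamic response regressor
#'
#' Double-gamma hemodynamic response function (peak 6 s, undershoot 16 s,
#' undershoot ratio 1/6) convolved with a boxcar of length `stim_dur` and
#' normalized to unit peak, sampled at `fs`. This is the event-response shape
#' the synthetic-data generator plants at each sound onset; a planted
#' amplitude of `a` therefore produces a peak concentration change of `a`.
#'
#' @param fs Sampling rate in Hz.
#' @param stim_dur Boxcar (stimulus) duration in s; default 5 s, the cue-sound
#'   duration.
#' @param length_s Kernel length in s (default 35, covering the undershoot).
#' @return Numeric vector of kernel samples (unit peak).
#' @export
#' @examples
#' k <- hrf_kernel(fs = 10)
#' plot(seq_along(k) / 10, k, type = "l", xlab = "s", ylab = "response")
hrf_kernel <- function(fs, stim_dur = 5, length_s = 35) {
  check_scalar_number(fs, "fs", positive = TRUE)
  t <- seq(0, length_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  box <- rep(1, max(1L, round(stim_dur * fs)))
  k <- convolve(h, rev(box), type = "open")[seq_along(t)]
  k / max(k)
}

# Cerebral response time course for one cue: unit-amplitude kernel placed at
# each sound onset of that cue. n = number of samples, onsets in seconds.
cue_regressor <- function(n, fs, onsets) {
  y <- numeric(n)
  k <- hrf_kernel(fs)
  idx <- round(onsets * fs) + 1L
  for (i in idx[idx >= 1L & idx <= n]) {
    j <- min(n, i + length(k) - 1L)
    y[i:j] <- y[i:j] + k[seq_len(j - i + 1L)]
  }
  y
}
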