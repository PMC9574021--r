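#' Zero-phase band-pass filter for hemoglobin time series
#'
#' Filters every channel-chromophore series with a forward-backward
#' (zero-phase) Butterworth band-pass filter, the standard step that removes
#' cardiac and respiratory oscillations and slow baseline drift while
#' preserving event-locked latency. The default 0.01-0.1 Hz pass band is the
#' conventional fNIRS analysis band.
#'
#' @param recording A `nirs_recording`.
#' @param low_cut,high_cut Pass-band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < sampling_rate / 2`.
#' @param order Butterworth order per pass (default 3; the forward-backward
#'   pass squares the magnitude response).
#' @return The filtered `nirs_recording` (each series has mean approximately
#'   zero afterwards), with provenance updated.
#' @seealso [filter_gain()] for the analytic magnitude response.
#' @export
bandpass <- function(recording, low_cut = 0.01, high_cut = 0.1, order = 3) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$sampling_rate
  check_scalar_number(low_cut, "low_cut", positive = TRUE)
  check_scalar_number(high_cut, "high_cut", positive = TRUE)
  if (low_cut >= high_cut) stop_invalid("`low_cut` must be below `high_cut`")
  if (high_cut >= fs / 2) {
    stop_invalid(
      "`high_cut` (%g Hz) must be below the Nyquist frequency (%g Hz)",
      high_cut, fs / 2
    )
  }
  n <- nrow(recording$signals)
  min_n <- ceiling(3 * fs / low_cut)
  if (n <= min_n) {
    stop_invalid(
      "series too short for a %g Hz high-pass: need more than %d samples, got %d",
      low_cut, min_n, n
    )
  }
  bf <- signal::butter(order, c(low_cut, high_cut) / (fs / 2), type = "pass")
  pad <- ceiling(4 * fs / low_cut)
  # demean first: the DC level is outside the pass band anyway, and removing
  # it up front avoids amplifying cancellation error in the recursion
  centered <- scale(recording$signals, center = TRUE, scale = FALSE)
  filtered <- filtfilt_padded(bf$b, bf$a, centered, pad)
  colnames(filtered) <- colnames(recording$signals)
  recording$signals <- filtered
  add_provenance(recording, sprintf(
    "bandpass: butterworth order %d, zero-phase, %g-%g Hz", order, low_cut, high_cut
  ))
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding.
# The padding (several time constants of the slowest pole) absorbs the filter
# transients so the retained segment carries the steady-state forward-backward
# response; both passes run through stats::filter's compiled loops.
filtfilt_padded <- function(b, a, X, pad) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, ncol = 1)
  out <- .filtfilt_mat(b, a, X, as.integer(pad))
  if (vec) out[, 1] else out
}

#' Analytic magnitude response of the zero-phase band-pass filter
#'
#' Gain of [bandpass()] at frequency `freq`, i.e. the squared magnitude of the
#' single-pass Butterworth response (forward-backward filtering applies the
#' filter twice).
#'
#' @param freq Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @inheritParams bandpass
#' @return Numeric gain values in `[0, 1]`.
#' @export
filter_gain <- function(freq, fs, low_cut = 0.01, high_cut = 0.1, order = 3) {
  bf <- signal::butter(order, c(low_cut, high_cut) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freq / fs)
  polyval <- function(p) {
    r <- rep(0 + 0i, length(z))
    for (cf in p) r <- r * z + cf
    r
  }
  Mod(polyval(bf$b) / polyval(bf$a))^2
}

#' Remove systemic hemodynamics estimated from non-cerebral channels
#'
#' Estimates the shared systemic (scalp/skull) hemodynamic component as the
#' leading principal components of the short non-cerebral channels and
#' subtracts each composite channel's least-squares projection onto those
#' component time courses. Performed per chromophore on mean-centered but
#' unstandardized short-channel series (the channels share units), over the
#' full session. Components are ordered by explained variance with signs
#' fixed so each component's largest-magnitude loading is positive.
#'
#' @param recording A `nirs_recording`, normally already band-pass filtered.
#' @param geometry Channel geometry table identifying composite and
#'   non-cerebral channels.
#' @param n_components Number of principal components to remove (default 2,
#'   the conventional choice for a five-channel short-separation set);
#'   `0` returns the input unchanged.
#' @return The cleaned `nirs_recording`; residual composite series are
#'   orthogonal to each removed component.
#' @export
remove_systemic <- function(recording, geometry, n_components = 2) {
  stopifnot(inherits(recording, "nirs_recording"))
  validate_geometry(geometry)
  check_scalar_number(n_components, "n_components")
  if (n_components < 0) stop_invalid("`n_components` must be >= 0")
  if (n_components == 0) {
    return(add_provenance(recording, "remove_systemic: skipped (n_components = 0)"))
  }
  short_id <- geometry$channel_id[geometry$kind == "non_cerebral"]
  comp_id <- geometry$channel_id[geometry$kind == "composite"]
  if (length(short_id) < n_components) {
    stop_invalid(
      "need at least %d non-cerebral channels, geometry has %d",
      n_components, length(short_id)
    )
  }
  warns <- character(0)
  for (cc in recording$chromophores) {
    short_cols <- paste0(short_id, "_", cc)
    comp_cols <- paste0(comp_id, "_", cc)
    short_cols <- intersect(short_cols, colnames(recording$signals))
    comp_cols <- intersect(comp_cols, colnames(recording$signals))
    if (!length(short_cols) || !length(comp_cols)) next
    M <- scale(recording$signals[, short_cols, drop = FALSE],
      center = TRUE, scale = FALSE
    )
    sv <- svd(M, nu = min(n_components, ncol(M)), nv = 0)
    pos <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10
    k <- min(n_components, sum(pos))
    if (k < n_components) {
      warns <- c(warns, sprintf(
        "remove_systemic: %s non-cerebral matrix rank %d < %d requested; using %d",
        cc, sum(pos), n_components, k
      ))
    }
    if (k == 0) next
    Tm <- sv$u[, seq_len(k), drop = FALSE] # orthonormal component scores
    # fix component signs by the largest-|loading| convention
    load <- crossprod(M, Tm) # loadings (short channels x components)
    for (j in seq_len(k)) {
      i_max <- which.max(abs(load[, j]))
      if (load[i_max, j] < 0) Tm[, j] <- -Tm[, j]
    }
    Y <- recording$signals[, comp_cols, drop = FALSE]
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2, mu)
    fit <- Tm %*% crossprod(Tm, Yc) # projection (T orthonormal)
    recording$signals[, comp_cols] <- sweep(Yc - fit, 2, mu, `+`)
  }
  for (w in warns) warning(w, call. = FALSE)
  add_provenance(recording, sprintf(
    "remove_systemic: removed first %d PC(s) of %d non-cerebral channels%s",
    n_components, length(short_id),
    if (length(warns)) paste0(" [", paste(warns, collapse = "; "), "]") else ""
  ))
}
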