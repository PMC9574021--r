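#' Construct a multi-channel NIRS recording object
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param time Time vector in s (strictly increasing, uniform step).
#' @param signals Numeric matrix, one column per `<channel>_<chromophore>`
#'   series.
#' @param channels Character vector of channel ids.
#' @param chromophores Chromophores present (subset of HbO/HbR/HbT).
#' @param events Per-trial events data frame (may be `NULL`).
#' @param provenance List of processing-step strings.
#' @return An object of class `nirs_recording`.
#' @export
new_recording <- function(sampling_rate, time, signals, channels, chromophores,
                          events = NULL, provenance = list()) {
  stopifnot(is.matrix(signals), length(time) == nrow(signals))
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) ||
    max(abs(dt - 1 / sampling_rate)) > 1e-6 / sampling_rate)) {
    bad <- which(abs(dt - 1 / sampling_rate) > 1e-6 / sampling_rate |
      dt <= 0)[1]
    stop_invalid(
      "time vector is not a uniform grid at %g Hz (first offending index: %d)",
      sampling_rate, bad + 1L
    )
  }
  structure(
    list(
      sampling_rate = sampling_rate, time = time, signals = signals,
      channels = channels, chromophores = chromophores,
      events = events, provenance = provenance
    ),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf(
    "<nirs_recording> %d samples @ %g Hz (%.1f s), %d channels x {%s}\n",
    length(x$time), x$sampling_rate, length(x$time) / x$sampling_rate,
    length(x$channels), paste(x$chromophores, collapse = ", ")
  ))
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d trials\n", nrow(x$events)))
  }
  for (p in x$provenance) cat("  *", p, "\n")
  invisible(x)
}

# Column names for one chromophore, in channel order.
chrom_cols <- function(recording, chromophore) {
  cols <- paste0(recording$channels, "_", chromophore)
  missing <- setdiff(cols, colnames(recording$signals))
  if (length(missing)) {
    stop_invalid("recording lacks series: %s", paste(missing, collapse = ", "))
  }
  cols
}

add_provenance <- function(recording, msg) {
  recording$provenance <- c(recording$provenance, msg)
  recording
}
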