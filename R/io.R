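#' Write a recording as a tab-separated time-series table
#'
#' Columns are `time_s` followed by one `<channel>_<HbO|HbR|HbT>` column per
#' series. Sampling rate and provenance are written to a JSON-ish sidecar
#' (`<path>.meta`) as `key=value` lines.
#'
#' @param recording A `nirs_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  tab <- data.frame(time_s = recording$time, recording$signals,
    check.names = FALSE
  )
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  meta <- c(
    sprintf("sampling_rate=%.10g", recording$sampling_rate),
    sprintf("chromophores=%s", paste(recording$chromophores, collapse = ",")),
    sprintf("provenance=%s", vapply(recording$provenance, identity, ""))
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a tab-separated time-series table
#'
#' Inverse of [write_timeseries()]: expects a `time_s` column and
#' `<channel>_<HbO|HbR|HbT>` series columns on a uniform time grid.
#'
#' @param path File path.
#' @param events Optional per-trial events data frame to attach.
#' @return A `nirs_recording`.
#' @export
read_timeseries <- function(path, events = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(tab)) {
    stop_invalid("time-series file lacks a `time_s` column")
  }
  time <- tab$time_s
  sig_cols <- setdiff(names(tab), "time_s")
  parsed <- regmatches(sig_cols, regexec("^(.*)_(HbO|HbR|HbT)$", sig_cols))
  bad <- vapply(parsed, length, 0L) != 3L
  if (any(bad)) {
    stop_invalid(
      "column(s) not named <channel>_<HbO|HbR|HbT>: %s",
      paste(sig_cols[bad], collapse = ", ")
    )
  }
  channels <- unique(vapply(parsed, `[[`, "", 2))
  chromophores <- intersect(
    c("HbO", "HbR", "HbT"),
    unique(vapply(parsed, `[[`, "", 3))
  )
  dt <- diff(time)
  if (!length(dt)) stop_invalid("time-series file has fewer than 2 samples")
  fs <- 1 / median(dt)
  meta_path <- paste0(path, ".meta")
  provenance <- list()
  if (file.exists(meta_path)) {
    meta <- readLines(meta_path)
    fs_line <- grep("^sampling_rate=", meta, value = TRUE)
    if (length(fs_line)) fs <- as.numeric(sub("^sampling_rate=", "", fs_line[1]))
    provenance <- as.list(sub("^provenance=", "",
      grep("^provenance=", meta, value = TRUE)
    ))
  }
  new_recording(
    sampling_rate = fs, time = time,
    signals = as.matrix(tab[, sig_cols, drop = FALSE]),
    channels = channels, chromophores = chromophores,
    events = events, provenance = provenance
  )
}

#' Write / read a channel geometry table
#'
#' @param geometry Geometry data frame (see [build_geometry()]).
#' @param path File path.
#' @return `path` / the geometry data frame.
#' @export
write_geometry <- function(geometry, path) {
  write.table(geometry, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  geom <- read.delim(path, check.names = FALSE)
  geom$roi <- factor(as.character(geom$roi), levels = ROI_LEVELS)
  validate_geometry(geom)
  geom
}

#' Write / read a per-trial events table (with optional VAS column)
#'
#' @param events Events data frame.
#' @param path File path.
#' @return `path` / the events data frame.
#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, check.names = FALSE)
  if ("condition" %in% names(ev)) {
    ev$condition <- factor(ev$condition, levels = CONDITION_LEVELS)
  }
  if ("cue" %in% names(ev)) ev$cue <- factor(ev$cue, levels = CUE_LEVELS)
  ev
}
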