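#' Synthetic channel geometry tables
#'
#' Builds a synthetic probe montage mimicking a bilateral prefrontal
#' multi-distance fNIRS cap: composite (long, 3.0 cm source-detector) channels
#' that mix cerebral and extracerebral hemodynamics, and non-cerebral (short,
#' 1.5 cm) channels dominated by scalp/skull physiology. Five composite
#' channels per hemisphere carry a dorsolateral prefrontal cortex (dl-PFC,
#' Brodmann areas 9/46) region-of-interest label; the remainder are unlabelled
#' cortex. MNI coordinates are synthetic placements consistent with the ROI
#' labels (right hemisphere x > 0).
#'
#' @param montage One of `"full"` (95 composite + 5 non-cerebral channels),
#'   `"dlpfc"` (both ROIs' channels + 5 non-cerebral) or `"right_dlpfc"`
#'   (right-ROI channels + 5 non-cerebral). The reduced montages carry the
#'   identical ROI channels and short channels as the full montage and exist
#'   so that large simulation studies touching only the dl-PFC can run on a
#'   smaller problem.
#' @return A `data.frame` with columns `channel_id`, `source_id`,
#'   `detector_id`, `distance` (cm), `kind` (`composite`/`non_cerebral`),
#'   `mni_x`, `mni_y`, `mni_z` (mm, `NA` for short channels), `ba` (Brodmann
#'   area, `NA` where not assigned) and `roi`
#'   (`right_dlPFC`/`left_dlPFC`/`none`).
#' @export
#' @examples
#' geom <- build_geometry()
#' table(geom$kind)
#' table(geom$roi)
build_geometry <- function(montage = c("full", "dlpfc", "right_dlpfc")) {
  montage <- match.arg(montage)
  n_comp <- 95
  id <- sprintf("CH%03d", seq_len(n_comp + 5))
  kind <- rep(c("composite", "non_cerebral"), c(n_comp, 5))
  distance <- rep(c(3.0, 1.5), c(n_comp, 5))
  source_id <- sprintf("S%02d", ((seq_len(n_comp + 5) - 1) %% 28) + 1)
  detector_id <- sprintf("D%02d", ((seq_len(n_comp + 5) - 1) %% 32) + 1)

  roi <- rep("none", n_comp + 5)
  ba <- rep(NA_real_, n_comp + 5)
  right_idx <- 37:41 # includes CH041, the canonical right dl-PFC channel
  left_idx <- 55:59
  roi[right_idx] <- "right_dlPFC"
  roi[left_idx] <- "left_dlPFC"
  ba[c(right_idx, left_idx)] <- c(9, 9, 46, 46, 46, 9, 9, 46, 46, 46)

  mni <- matrix(NA_real_, n_comp + 5, 3)
  # deterministic grid over the prefrontal patch for unlabelled cortex
  comp <- seq_len(n_comp)
  mni[comp, 1] <- round(-60 + 120 * ((comp - 1) %% 10) / 9)
  mni[comp, 2] <- round(20 + 45 * (((comp - 1) %/% 10) %% 5) / 4)
  mni[comp, 3] <- round(10 + 50 * ((comp - 1) %/% 50))
  mni[right_idx, ] <- matrix(c(
    34, 44, 30,
    40, 36, 38,
    42, 42, 22,
    38, 50, 26,
    22, 57, 37
  ), ncol = 3, byrow = TRUE)
  mni[left_idx, ] <- matrix(c(
    -34, 44, 30,
    -40, 36, 38,
    -42, 42, 22,
    -38, 50, 26,
    -22, 57, 37
  ), ncol = 3, byrow = TRUE)

  geom <- data.frame(
    channel_id = id, source_id = source_id, detector_id = detector_id,
    distance = distance, kind = kind,
    mni_x = mni[, 1], mni_y = mni[, 2], mni_z = mni[, 3],
    ba = ba, roi = factor(roi, levels = ROI_LEVELS),
    stringsAsFactors = FALSE
  )
  keep <- switch(montage,
    full = seq_len(n_comp + 5),
    dlpfc = c(right_idx, left_idx, n_comp + 1:5),
    right_dlpfc = c(right_idx, n_comp + 1:5)
  )
  out <- geom[keep, , drop = FALSE]
  rownames(out) <- NULL
  validate_geometry(out)
  out
}

validate_geometry <- function(geometry) {
  need <- c("channel_id", "distance", "kind", "roi")
  missing <- setdiff(need, names(geometry))
  if (length(missing)) {
    stop_invalid("geometry table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  comp <- geometry$kind == "composite"
  if (any(comp & geometry$distance < 3.0 - 0.05) ||
    any(!comp & geometry$distance > 1.5 + 0.05)) {
    stop_invalid("channel kind inconsistent with source-detector distance")
  }
  if (any(!comp & geometry$roi != "none")) {
    stop_invalid("only composite channels may carry an ROI label")
  }
  invisible(geometry)
}

#' Assign dl-PFC ROI labels from MNI coordinates and Brodmann areas
#'
#' Channels whose Brodmann area is 9 or 46 are assigned to the right or left
#' dl-PFC by the sign of their MNI x coordinate (x > 0 is right). Channels
#' already carrying a non-`none` `roi` label pass through unchanged. The
#' Brodmann area can be supplied either as a `ba` column in `geometry` or via
#' a `lookup` table of axis-aligned MNI boxes.
#'
#' @param geometry Geometry table (see [build_geometry()]).
#' @param lookup Optional lookup `data.frame` with columns `ba`, `x_min`,
#'   `x_max`, `y_min`, `y_max`, `z_min`, `z_max`; a channel falling inside a
#'   box takes that Brodmann area.
#' @return The geometry table with `roi` filled in.
#' @export
assign_roi <- function(geometry, lookup = NULL) {
  roi <- as.character(geometry$roi %||% rep("none", nrow(geometry)))
  has_label <- !is.na(roi) & roi != "none"
  ba <- geometry$ba %||% rep(NA_real_, nrow(geometry))
  has_mni <- all(c("mni_x", "mni_y", "mni_z") %in% names(geometry)) &&
    any(!is.na(geometry$mni_x))
  if (!any(has_label) && all(is.na(ba)) && (is.null(lookup) || !has_mni)) {
    stop_invalid("geometry carries neither roi labels nor MNI coordinates/Brodmann areas")
  }
  if (!is.null(lookup) && has_mni) {
    for (i in which(is.na(ba))) {
      x <- geometry$mni_x[i]; y <- geometry$mni_y[i]; z <- geometry$mni_z[i]
      if (is.na(x)) next
      hit <- lookup$x_min <= x & x <= lookup$x_max &
        lookup$y_min <= y & y <= lookup$y_max &
        lookup$z_min <= z & z <= lookup$z_max
      if (any(hit)) ba[i] <- lookup$ba[which(hit)[1]]
    }
  }
  dl <- !has_label & !is.na(ba) & ba %in% c(9, 46) & geometry$kind == "composite"
  roi[dl] <- ifelse(geometry$mni_x[dl] > 0, "right_dlPFC", "left_dlPFC")
  roi[is.na(roi)] <- "none"
  geometry$roi <- factor(roi, levels = ROI_LEVELS)
  geometry$ba <- ba
  validate_geometry(geometry)
  geometry
}
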