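# Tracking-error analysis: per-frame aperture-to-marker offsets, the
# baseline-referenced tracking error E_T, and per-field / per-patient
# statistics.

#' Offset of the marker COM relative to the aperture center
#'
#' Signed offsets along the pan (column) and tilt (row) axes, converted to mm
#' at the isocenter plane via the de-magnified pixel pitch.
#'
#' @param center_px Aperture center, 0-based `(row, col)`.
#' @param com_px Marker COM, 0-based `(row, col)`.
#' @param geometry A [geometry_config()].
#' @return Named numeric vector `c(pan_mm, tilt_mm)`.
#' @export
frame_offset <- function(center_px, com_px, geometry = geometry_config()) {
  stopifnot(length(center_px) == 2L, length(com_px) == 2L,
            all(is.finite(center_px)), all(is.finite(com_px)))
  s <- geometry$pixel_mm_at_iso
  c(pan_mm = (com_px[[2L]] - center_px[[2L]]) * s,
    tilt_mm = (com_px[[1L]] - center_px[[1L]]) * s)
}

#' Baseline-referenced tracking error for a series
#'
#' The tracking error of frame *i* is the absolute change of the
#' aperture-to-marker offset relative to the series baseline:
#' `et_pan(i) = |pan(i) - pan(b)|`, likewise for tilt, and
#' `et_2d(i) = sqrt(et_pan(i)^2 + et_tilt(i)^2)`. The baseline *b* is the
#' first frame of the series with a usable detection (normally frame #1); its
#' own tracking error is zero by construction and is retained in the
#' statistics. Any offset common to all frames — e.g. a systematic
#' aperture-to-COM calibration shift — cancels in the subtraction. Excluded
#' frames carry `NA` tracking errors.
#'
#' @param offsets Data frame with columns `index`, `time_s`, `n_markers`,
#'   `pan_mm`, `tilt_mm`, `included`, `reason` (one row per collected frame).
#' @param metadata Optional [series_metadata()] attached to the result.
#' @return An object of class `tracking_series`: list with `metadata`,
#'   `offsets` (the input augmented with `et_pan_mm`, `et_tilt_mm`,
#'   `et_2d_mm`) and `baseline_index`.
#' @export
tracking_error_series <- function(offsets, metadata = NULL) {
  stopifnot(is.data.frame(offsets),
            all(c("index", "pan_mm", "tilt_mm", "included") %in% names(offsets)))
  inc <- which(offsets$included)
  if (length(inc) == 0L)
    stop("empty series: no frames with a usable detection")
  b <- inc[1L]
  et_pan <- et_tilt <- et_2d <- rep(NA_real_, nrow(offsets))
  dp <- offsets$pan_mm[inc] - offsets$pan_mm[b]
  dt <- offsets$tilt_mm[inc] - offsets$tilt_mm[b]
  et_pan[inc] <- abs(dp)
  et_tilt[inc] <- abs(dt)
  et_2d[inc] <- sqrt(dp^2 + dt^2)
  offsets$et_pan_mm <- et_pan
  offsets$et_tilt_mm <- et_tilt
  offsets$et_2d_mm <- et_2d
  if (!"time_s" %in% names(offsets)) offsets$time_s <- NA_real_
  if (!"n_markers" %in% names(offsets)) offsets$n_markers <- NA_integer_
  if (!"reason" %in% names(offsets)) offsets$reason <- ""
  structure(
    list(metadata = metadata, offsets = offsets,
         baseline_index = offsets$index[b]),
    class = "tracking_series"
  )
}

#' @export
print.tracking_series <- function(x, ...) {
  inc <- sum(x$offsets$included)
  cat(sprintf(
    "Tracking series: %d frames (%d analyzed), baseline frame #%d\n",
    nrow(x$offsets), inc, x$baseline_index))
  invisible(x)
}

.et_directions <- c(pan = "et_pan_mm", tilt = "et_tilt_mm", `2d` = "et_2d_mm")

.stat_row <- function(et, n_collected) {
  out <- list()
  for (d in names(.et_directions)) {
    x <- et[[.et_directions[[d]]]]
    key <- sub("2d", "2d", d)
    out[[paste0("mean_", key, "_mm")]] <- mean(x)
    out[[paste0("sd_", key, "_mm")]] <- stats::sd(x)
    out[[paste0("p90_", key, "_mm")]] <-
      stats::quantile(x, 0.9, type = 7, names = FALSE)
    out[[paste0("max_", key, "_mm")]] <- max(x)
  }
  out$n_analyzed <- nrow(et)
  out$n_collected <- n_collected
  out$detection_rate <- nrow(et) / n_collected
  as.data.frame(out, check.names = FALSE)
}

#' Per-field tracking-error statistics
#'
#' Mean, SD, 90th percentile (linear interpolation between order statistics)
#' and maximum of the tracking error over all analyzed frames of one field,
#' per direction, plus the detection rate. The baseline frame's zero error is
#' part of the sample.
#'
#' @param series A `tracking_series`.
#' @return One-row data frame of class `field_stats`.
#' @export
field_stats <- function(series) {
  stopifnot(inherits(series, "tracking_series"))
  et <- series$offsets[series$offsets$included, ]
  if (nrow(et) < 2L)
    stop("insufficient data: need at least 2 analyzed frames for field statistics")
  out <- .stat_row(et, nrow(series$offsets))
  if (!is.null(series$metadata)) {
    out <- cbind(data.frame(patient_id = series$metadata$patient_id,
                            fraction_id = series$metadata$fraction_id,
                            field_id = series$metadata$field_id,
                            stringsAsFactors = FALSE), out)
  }
  class(out) <- c("field_stats", class(out))
  out
}

#' Per-patient tracking-error statistics
#'
#' Pools every analyzed frame of all of a patient's fields and fractions
#' (frame-weighted: a field with more usable frames contributes more) and
#' computes the same statistics as [field_stats()]. Equivalent to
#' concatenating all included tracking errors and summarizing once.
#'
#' @param series_list List of `tracking_series` belonging to one patient.
#' @return One-row data frame of class `patient_stats`.
#' @export
patient_stats <- function(series_list) {
  if (inherits(series_list, "tracking_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "tracking_series")))
  pooled <- do.call(rbind, lapply(series_list, function(s)
    s$offsets[s$offsets$included, c("pan_mm", "tilt_mm", "et_pan_mm",
                                    "et_tilt_mm", "et_2d_mm")]))
  n_collected <- sum(vapply(series_list, function(s) nrow(s$offsets), 0L))
  if (nrow(pooled) == 0L)
    stop("insufficient data: no analyzed frames for this patient")
  out <- .stat_row(pooled, n_collected)
  md <- series_list[[1L]]$metadata
  if (!is.null(md)) {
    out <- cbind(data.frame(patient_id = md$patient_id,
                            stringsAsFactors = FALSE), out)
  }
  out$n_fields <- length(series_list)
  class(out) <- c("patient_stats", class(out))
  out
}

#' Analyze one EPID series end to end
#'
#' Runs the full per-frame pipeline — field segmentation, chain-code boundary
#' tracing, marker detection — on every frame, assembles the offset table and
#' computes the baseline-referenced tracking errors. Frames on which any stage
#' fails (no field, incomplete marker set when `require_complete` is on) are
#' flagged excluded with the failure reason and the run continues.
#'
#' @param series An `epid_series` from [read_image_series()] or
#'   [render_series()], or a plain list of [epid_image()] (then `metadata`
#'   must be given).
#' @param config A [run_config()]; controls every stage's parameters.
#' @param metadata Overrides the series' own metadata.
#' @return A `tracking_series` (see [tracking_error_series()]).
#' @export
analyze_series <- function(series, config = run_config(), metadata = NULL) {
  if (inherits(series, "epid_series")) {
    metadata <- metadata %||% series$metadata
    images <- series$images
  } else {
    images <- series
  }
  if (is.null(metadata)) stop("analyze_series: metadata required")
  geom <- metadata$geometry
  lp <- log_params(config$preprocessing$sigma_px,
                   config$preprocessing$kernel_halfwidth_px)
  rules <- marker_filter_rules(
    edge_margin_mm = config$markers$edge_margin_mm,
    min_area_px2 = config$markers$min_area_px2,
    max_area_px2 = config$markers$max_area_px2,
    max_elongation = config$markers$max_elongation,
    require_complete = config$markers$require_complete)
  n <- length(images)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    row <- data.frame(index = img$index, time_s = img$time_s,
                      n_markers = 0L, pan_mm = NA_real_, tilt_mm = NA_real_,
                      included = FALSE, reason = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      fm <- segment_field(img,
                          edge_threshold = config$aperture$edge_threshold,
                          min_field_area_px2 = config$aperture$min_field_area_px2,
                          min_contrast = config$aperture$min_contrast)
      ct <- trace_boundary(fm)
      ms <- detect_markers(img, ct, lp, config$preprocessing$k_sigma, rules,
                           metadata$expected_markers, geom,
                           config$markers$connectivity)
      list(ct = ct, ms = ms)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      row$reason <- res
    } else {
      ms <- res$ms
      row$n_markers <- ms$n_detected
      usable <- if (rules$require_complete) ms$complete else ms$n_detected >= 1L
      if (usable) {
        off <- frame_offset(aperture_center(res$ct), ms$com_px, geom)
        row$pan_mm <- off[["pan_mm"]]
        row$tilt_mm <- off[["tilt_mm"]]
        row$included <- TRUE
      } else {
        row$reason <- sprintf("incomplete marker set (%d of %d)",
                              ms$n_detected, metadata$expected_markers)
      }
    }
    rows[[i]] <- row
  }
  tracking_error_series(do.call(rbind, rows), metadata)
}
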