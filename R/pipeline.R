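# Workflow assembly: full-cohort aggregation and file-based run entry points
# used by the command-line wrapper.

#' Summarize a cohort of analyzed series
#'
#' Takes analyzed series grouped by patient and reproduces the standard
#' cohort layout: one statistics row per patient, an over-all row pooling
#' every analyzed frame, and the population decomposition (systematic error
#' Sigma, random error sigma, Van Herk margin) per direction. With a single
#' patient the population decomposition is omitted with a warning (Sigma
#' needs at least two patients).
#'
#' @param series_by_patient Named list: `patient_id -> list of
#'   tracking_series`.
#' @return List with `per_patient` (data frame, one row per patient),
#'   `overall` (one pooled row) and `population` (a [population_stats()], or
#'   `NULL` for a single patient).
#' @export
cohort_summary <- function(series_by_patient) {
  stopifnot(is.list(series_by_patient), length(series_by_patient) >= 1L)
  per <- do.call(rbind, lapply(series_by_patient, patient_stats))
  rownames(per) <- NULL
  all_series <- unlist(series_by_patient, recursive = FALSE)
  overall <- patient_stats(all_series)
  overall$patient_id <- "overall"
  pop <- if (nrow(per) >= 2L) {
    population_stats(per)
  } else {
    warning("single patient: population systematic error not estimable")
    NULL
  }
  list(per_patient = per, overall = overall, population = pop)
}

#' Analyze a series directory into output files
#'
#' File-level wrapper around [read_image_series()], [analyze_series()],
#' [field_stats()] and the CSV writers: writes `offsets.csv`,
#' `field_stats.csv`, the resolved `config.yaml` and a detection overlay PNG
#' of the first analyzed frame into `output_dir`.
#'
#' @param input Series directory or manifest (see [read_image_series()]).
#' @param metadata A [series_metadata()].
#' @param config A [run_config()].
#' @param output_dir Output directory, created if needed.
#' @return The `tracking_series`, invisibly.
#' @export
run_analyze <- function(input, metadata, config = run_config(),
                        output_dir = ".") {
  dialect <- do.call(raw_dialect, config$io)
  series <- read_image_series(input, metadata, dialect)
  ts <- analyze_series(series, config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_offsets_csv(ts, file.path(output_dir, "offsets.csv"))
  fs <- field_stats(ts)
  utils::write.csv(fs, file.path(output_dir, "field_stats.csv"),
                   row.names = FALSE)
  save_run_config(config, file.path(output_dir, "config.yaml"))
  first_inc <- which(ts$offsets$included)[1L]
  if (!is.na(first_inc)) {
    img <- series$images[[first_inc]]
    fm <- segment_field(img, config$aperture$edge_threshold,
                        config$aperture$min_field_area_px2,
                        config$aperture$min_contrast)
    ct <- trace_boundary(fm)
    ms <- detect_markers(img, ct,
                         log_params(config$preprocessing$sigma_px,
                                    config$preprocessing$kernel_halfwidth_px),
                         config$preprocessing$k_sigma,
                         do.call(marker_filter_rules,
                                 config$markers[c("edge_margin_mm",
                                                  "min_area_px2",
                                                  "max_area_px2",
                                                  "max_elongation",
                                                  "require_complete")]),
                         metadata$expected_markers, metadata$geometry,
                         config$markers$connectivity)
    write_overlay_png(img, ct, ms, file.path(output_dir, "overlay.png"))
  }
  invisible(ts)
}

#' Export the traced contour as a CSV polygon
#'
#' @param contour An `aperture_contour`.
#' @param path CSV path; columns `row_px`, `col_px` (0-based, closed
#'   polygon).
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "aperture_contour"))
  utils::write.csv(data.frame(row_px = contour$boundary_px[, 1L],
                              col_px = contour$boundary_px[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' QA overlay image
#'
#' Writes a review PNG of one frame with the detected field edge (green), the
#' aperture center (blue), detected marker centroids (red) and the marker COM
#' (yellow), in the style of a per-field QA snapshot.
#'
#' @param image An [epid_image()] or numeric matrix.
#' @param contour An `aperture_contour`.
#' @param markers A `marker_set` (optional).
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, contour, markers = NULL, path) {
  px <- .as_pixels(image)
  g <- 1 - px   # display: open field bright
  rgb <- array(g, dim = c(nrow(g), ncol(g), 3L))
  paint <- function(r, c, col) {
    ok <- r >= 1L & r <= nrow(g) & c >= 1L & c <= ncol(g)
    r <- r[ok]; c <- c[ok]
    for (ch in 1:3) rgb[cbind(r, c, ch)] <<- col[ch]
  }
  bp <- contour$boundary_px + 1L
  paint(bp[, 1L], bp[, 2L], c(0, 1, 0))
  cr <- round(contour$center_px) + 1L
  sq <- expand.grid(r = cr[1L] + (-2:2), c = cr[2L] + (-2:2))
  paint(sq$r, sq$c, c(0, 0.4, 1))
  if (!is.null(markers) && markers$n_detected >= 1L) {
    for (b in markers$blobs) {
      mc <- round(b$centroid_px) + 1L
      cross <- rbind(cbind(mc[1L] + (-3:3), mc[2L]),
                     cbind(mc[1L], mc[2L] + (-3:3)))
      paint(cross[, 1L], cross[, 2L], c(1, 0, 0))
    }
    cm <- round(markers$com_px) + 1L
    paint(cm[1L] + (-1:1), rep(cm[2L], 3L), c(1, 1, 0))
    paint(rep(cm[1L], 3L), cm[2L] + (-1:1), c(1, 1, 0))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
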