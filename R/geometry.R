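#' Imaging geometry of the treatment unit
#'
#' Bundles the fixed acquisition geometry of the portal imager: source-detector
#' distance, the detector pixel pitch de-magnified to the isocenter plane
#' (100 cm from the source), the frame rate, and the detector matrix size.
#' Defaults describe a gimbal-mounted DTT linac with an amorphous-silicon EPID
#' at 221.2 cm SDD, 0.18 mm isocenter-plane pixels, 2 Hz cine acquisition and a
#' 1024 x 1024 matrix.
#'
#' All offsets reported by the package are in millimetres at the isocenter
#' plane: pixel displacements are multiplied by `pixel_mm_at_iso`.
#'
#' @param sdd_cm Source-detector distance in cm.
#' @param pixel_mm_at_iso Pixel pitch in mm, de-magnified to isocenter.
#' @param frame_rate_hz Cine acquisition rate in Hz.
#' @param matrix_size Detector dimension in pixels (square matrix).
#' @return An object of class `geometry_config`.
#' @examples
#' geometry_config()
#' geometry_config(matrix_size = 256)
#' @export
geometry_config <- function(sdd_cm = 221.2, pixel_mm_at_iso = 0.18,
                            frame_rate_hz = 2.0, matrix_size = 1024L) {
  stopifnot(
    is.numeric(sdd_cm), length(sdd_cm) == 1L, sdd_cm > 0,
    is.numeric(pixel_mm_at_iso), length(pixel_mm_at_iso) == 1L, pixel_mm_at_iso > 0,
    is.numeric(frame_rate_hz), length(frame_rate_hz) == 1L, frame_rate_hz > 0,
    is.numeric(matrix_size), length(matrix_size) == 1L, matrix_size >= 64
  )
  structure(
    list(sdd_cm = sdd_cm, pixel_mm_at_iso = pixel_mm_at_iso,
         frame_rate_hz = frame_rate_hz, matrix_size = as.integer(matrix_size)),
    class = "geometry_config"
  )
}

#' @export
print.geometry_config <- function(x, ...) {
  cat(sprintf(
    "EPID geometry: SDD %.1f cm | %.2f mm/px at isocenter | %.1f Hz | %d x %d px\n",
    x$sdd_cm, x$pixel_mm_at_iso, x$frame_rate_hz, x$matrix_size, x$matrix_size))
  invisible(x)
}

#' Per-series acquisition metadata
#'
#' Identifies one cine EPID series (one treatment beam of one fraction of one
#' patient) and records how many fiducial markers the detector should find.
#' Clinically three to four gold seeds (3 mm x 1 mm) are implanted near the
#' target.
#'
#' @param patient_id,fraction_id,field_id Labels for the series.
#' @param expected_markers Number of implanted fiducials (>= 1).
#' @param geometry A [geometry_config()].
#' @return An object of class `series_metadata`.
#' @export
series_metadata <- function(patient_id, fraction_id = "1", field_id = "1",
                            expected_markers = 3L, geometry = geometry_config()) {
  stopifnot(expected_markers >= 1, inherits(geometry, "geometry_config"))
  structure(
    list(patient_id = as.character(patient_id),
         fraction_id = as.character(fraction_id),
         field_id = as.character(field_id),
         expected_markers = as.integer(expected_markers),
         geometry = geometry),
    class = "series_metadata"
  )
}
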