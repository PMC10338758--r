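# Run configuration: one nested list, loadable from YAML, with documented
# defaults for every stage.

#' Analysis run configuration
#'
#' Collects every tunable of the per-frame pipeline in one nested list so a
#' run is fully described by a single YAML file. Any element omitted from the
#' YAML falls back to the documented default.
#'
#' @param geometry A [geometry_config()] or a named list of overrides.
#' @param preprocessing List: `sigma_px` (LoG scale, default 2),
#'   `kernel_halfwidth_px` (default `ceiling(3 * sigma_px)`), `k_sigma`
#'   (robust detection threshold, default 5).
#' @param aperture List: `edge_threshold` (default `NULL` = half-maximum
#'   rule), `min_field_area_px2` (default 400), `min_contrast` (default
#'   0.35).
#' @param markers List: `connectivity` (default 8), `min_area_px2` (4),
#'   `max_area_px2` (80), `max_elongation` (6), `edge_margin_mm` (1.24),
#'   `require_complete` (TRUE).
#' @param io List: raw-dialect settings (`bytes_per_pixel`, `header_bytes`,
#'   `endian`, `invert`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = geometry_config(),
                       preprocessing = list(), aperture = list(),
                       markers = list(), io = list()) {
  if (!inherits(geometry, "geometry_config"))
    geometry <- do.call(geometry_config, geometry)
  pp <- utils::modifyList(
    list(sigma_px = 2.0, kernel_halfwidth_px = NULL, k_sigma = 5),
    preprocessing)
  ap <- utils::modifyList(
    list(edge_threshold = NULL, min_field_area_px2 = 400, min_contrast = 0.35),
    aperture)
  mk <- utils::modifyList(
    list(connectivity = 8L, min_area_px2 = 4, max_area_px2 = 120,
         max_elongation = 6, edge_margin_mm = 1.24, require_complete = TRUE),
    markers)
  dio <- utils::modifyList(
    list(bytes_per_pixel = 2L, header_bytes = 0L, endian = "little",
         invert = TRUE),
    io)
  structure(list(geometry = geometry, preprocessing = pp, aperture = ap,
                 markers = mk, io = dio),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; recognized top-level keys are `geometry`,
#'   `preprocessing`, `aperture`, `markers`, `io`.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(geometry = y$geometry %||% geometry_config(),
             preprocessing = y$preprocessing %||% list(),
             aperture = y$aperture %||% list(),
             markers = y$markers %||% list(),
             io = y$io %||% list())
}

#' Save the resolved run configuration as YAML
#'
#' Written alongside every run's outputs so a run can be reproduced
#' bit-for-bit from its own artifacts.
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- list(geometry = unclass(config$geometry),
            preprocessing = config$preprocessing,
            aperture = config$aperture,
            markers = config$markers,
            io = config$io)
  yaml::write_yaml(y, path)
  invisible(path)
}
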