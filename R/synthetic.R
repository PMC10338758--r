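# Synthetic EPID phantom: renders cine series with a translating polygonal
# MLC aperture, dark elliptical marker shadows, a controllable residual
# tracking offset between aperture center and marker COM, Gaussian edge blur
# and additive noise — with exact ground truth for every frame.

#' Respiratory motion trace
#'
#' @param kind `"sinusoid"` (displacement `amplitude_mm * sin(2*pi*t/period_s
#'   + phase_rad)`), `"constant"` (fixed displacement `amplitude_mm`), or
#'   `"custom"` (linear interpolation of `samples`, a data frame with columns
#'   `t_s` and `mm`).
#' @param amplitude_mm Peak displacement in mm (default 20, a typical deep
#'   hepatic excursion; 6 breaths/min at this amplitude is the standard
#'   1D phantom programme).
#' @param period_s Breathing period in s (default 10 s = 6 BPM).
#' @param phase_rad Phase offset.
#' @param samples Data frame for `kind = "custom"`.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(kind = c("sinusoid", "constant", "custom"),
                         amplitude_mm = 20, period_s = 10, phase_rad = 0,
                         samples = NULL) {
  kind <- match.arg(kind)
  stopifnot(amplitude_mm >= 0 || kind == "constant", period_s > 0)
  if (kind == "custom")
    stopifnot(is.data.frame(samples), all(c("t_s", "mm") %in% names(samples)))
  structure(list(kind = kind, amplitude_mm = amplitude_mm,
                 period_s = period_s, phase_rad = phase_rad,
                 samples = samples),
            class = "motion_trace")
}

#' Evaluate a motion trace
#'
#' @param trace A [motion_trace()].
#' @param t_s Numeric vector of times in seconds.
#' @return Displacement in mm at each time.
#' @export
motion_displacement <- function(trace, t_s) {
  switch(trace$kind,
         sinusoid = trace$amplitude_mm *
           sin(2 * pi * t_s / trace$period_s + trace$phase_rad),
         constant = rep(trace$amplitude_mm, length(t_s)),
         custom = stats::approx(trace$samples$t_s, trace$samples$mm,
                                xout = t_s, rule = 2)$y)
}

# Even-odd point-in-polygon test, vectorized over query points.
.in_polygon <- function(px, py, vx, vy) {
  inside <- rep(FALSE, length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from a point to the closest polygon edge.
.dist_to_polygon <- function(p, vx, vy) {
  n <- length(vx)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
    len2 <- ex^2 + ey^2
    tt <- if (len2 == 0) 0 else
      max(0, min(1, ((p[1] - vx[i]) * ex + (p[2] - vy[i]) * ey) / len2))
    d <- min(d, sqrt((p[1] - (vx[i] + tt * ex))^2 +
                       (p[2] - (vy[i] + tt * ey))^2))
  }
  d
}

.polygon_centroid <- function(vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1L)
  cross <- vx * vy[j] - vx[j] * vy
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(vx), mean(vy)))
  c(sum((vx + vx[j]) * cross) / (6 * a),
    sum((vy + vy[j]) * cross) / (6 * a))
}

#' Synthetic scene configuration
#'
#' Describes one cine series in isocenter-plane mm: the MLC aperture polygon,
#' the implanted-marker layout (re-centered so its mean is the target COM),
#' the respiratory motion that both aperture and markers follow, and the
#' per-frame residual tracking offset applied to the markers only — the
#' quantity the analysis pipeline is supposed to recover. The x axis is pan
#' (image columns), y is tilt (image rows).
#'
#' @param aperture_shape Data frame with columns `x_mm`, `y_mm` (polygon
#'   vertices); default a 30 x 30 mm square centered on the target.
#' @param marker_layout Data frame with `x_mm`, `y_mm` and optionally
#'   `angle_deg` (marker long-axis orientation); default three seeds.
#'   Re-centered to zero mean so the ground-truth COM equals the target
#'   position.
#' @param marker_size_mm Length and diameter of the seeds, default
#'   `c(3.0, 1.0)`.
#' @param motion A [motion_trace()]; applied along `motion_axis`.
#' @param motion_axis `"tilt"` (default; superior-inferior projects mainly to
#'   tilt at the reference gantry/ring pose) or `"pan"`.
#' @param tracking_offset `NULL` (perfect tracking), a length-2 constant
#'   `c(pan_mm, tilt_mm)`, an `n_frames x 2` matrix, or a
#'   `function(t_s)` returning `c(pan_mm, tilt_mm)`.
#' @param noise_sd Additive Gaussian noise SD in normalized grayscale units.
#' @param occlusion_margin_mm If 0 (default), any marker approaching the
#'   field edge closer than its own half-length raises a configuration error;
#'   if positive, markers may approach or cross the edge and are rendered
#'   partially blocked (clipped by the aperture).
#' @param blur_px Gaussian edge blur applied to the ideal scene (detector
#'   point-spread stand-in); 0 disables.
#' @param bg_level,field_level,marker_attenuation Detector-signal levels of
#'   the blocked region, open field and marker shadow depth.
#' @param n_frames Number of frames.
#' @param seed RNG seed for the noise (rendering is bit-reproducible given
#'   the seed).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(aperture_shape = NULL, marker_layout = NULL,
                         marker_size_mm = c(3.0, 1.0),
                         motion = motion_trace("sinusoid"),
                         motion_axis = c("tilt", "pan"),
                         tracking_offset = NULL, noise_sd = 0.01,
                         occlusion_margin_mm = 0, blur_px = 1,
                         bg_level = 0.12, field_level = 0.95,
                         marker_attenuation = 0.35,
                         n_frames = 21L, seed = 1L) {
  motion_axis <- match.arg(motion_axis)
  if (is.null(aperture_shape)) {
    aperture_shape <- data.frame(x_mm = c(-15, 15, 15, -15),
                                 y_mm = c(-15, -15, 15, 15))
  }
  if (is.null(marker_layout)) {
    marker_layout <- data.frame(x_mm = c(0, 6, -6), y_mm = c(7, -5, -2),
                                angle_deg = c(0, 40, -30))
  }
  if (is.null(marker_layout$angle_deg)) marker_layout$angle_deg <- 0
  # re-center: marker positions are relative to the target COM
  marker_layout$x_mm <- marker_layout$x_mm - mean(marker_layout$x_mm)
  marker_layout$y_mm <- marker_layout$y_mm - mean(marker_layout$y_mm)
  stopifnot(n_frames >= 1L, noise_sd >= 0, length(marker_size_mm) == 2L,
            nrow(aperture_shape) >= 3L, nrow(marker_layout) >= 1L)
  structure(
    list(aperture_shape = aperture_shape, marker_layout = marker_layout,
         marker_size_mm = marker_size_mm, motion = motion,
         motion_axis = motion_axis, tracking_offset = tracking_offset,
         noise_sd = noise_sd, occlusion_margin_mm = occlusion_margin_mm,
         blur_px = blur_px, bg_level = bg_level, field_level = field_level,
         marker_attenuation = marker_attenuation,
         n_frames = as.integer(n_frames), seed = seed),
    class = "scene_config"
  )
}

.resolve_offsets <- function(off, n, t_s) {
  if (is.null(off)) return(matrix(0, n, 2L))
  if (is.function(off)) {
    m <- t(vapply(t_s, off, numeric(2L)))
  } else if (is.matrix(m0 <- off)) {
    stopifnot(nrow(m0) == n, ncol(m0) == 2L)
    m <- m0
  } else {
    stopifnot(length(off) == 2L)
    m <- matrix(rep(as.numeric(off), each = n), n, 2L)
  }
  colnames(m) <- c("pan_mm", "tilt_mm")
  m
}

#' Render a synthetic EPID series with ground truth
#'
#' Per frame, the aperture polygon is translated by the motion trace and the
#' markers by motion plus the residual tracking offset; markers are rendered
#' as constant-attenuation ellipses clipped to the open field, the scene is
#' blurred, noise is added, and the frame is min-max normalized into the
#' 0 (white) / 1 (black) grayscale convention. Identical seeds give
#' bit-identical stacks.
#'
#' @param scene A [scene_config()].
#' @param geometry A [geometry_config()]; `matrix_size` sets the rendering
#'   resolution.
#' @return List of class `epid_series` with `images`, `metadata = NULL`, and
#'   `truth`: a data frame per frame with the exact aperture center, marker
#'   COM (0-based pixel coordinates) and the injected pan/tilt offsets in mm.
#' @export
render_series <- function(scene, geometry = geometry_config()) {
  stopifnot(inherits(scene, "scene_config"))
  M <- geometry$matrix_size
  pmm <- geometry$pixel_mm_at_iso
  n <- scene$n_frames
  t_s <- (seq_len(n) - 1L) / geometry$frame_rate_hz
  disp <- motion_displacement(scene$motion, t_s)
  mot <- matrix(0, n, 2L, dimnames = list(NULL, c("pan_mm", "tilt_mm")))
  mot[, if (scene$motion_axis == "pan") 1L else 2L] <- disp
  off <- .resolve_offsets(scene$tracking_offset, n, t_s)
  ctr <- (M - 1) / 2
  ax_mm <- ((0:(M - 1)) - ctr) * pmm
  X <- matrix(ax_mm, M, M, byrow = TRUE)   # pan / x
  Y <- matrix(ax_mm, M, M)                 # tilt / y
  a_len <- scene$marker_size_mm[1L] / 2
  b_rad <- scene$marker_size_mm[2L] / 2
  cen0 <- .polygon_centroid(scene$aperture_shape$x_mm, scene$aperture_shape$y_mm)
  if (!is.null(scene$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(scene$seed)
  }
  images <- vector("list", n)
  truth <- vector("list", n)
  for (f in seq_len(n)) {
    vx <- scene$aperture_shape$x_mm + mot[f, 1L]
    vy <- scene$aperture_shape$y_mm + mot[f, 2L]
    infield <- matrix(.in_polygon(as.vector(X), as.vector(Y), vx, vy), M, M)
    counts <- scene$bg_level +
      (scene$field_level - scene$bg_level) * infield
    mk <- scene$marker_layout
    mk_x <- mk$x_mm + mot[f, 1L] + off[f, 1L]
    mk_y <- mk$y_mm + mot[f, 2L] + off[f, 2L]
    for (m in seq_len(nrow(mk))) {
      d_edge <- .dist_to_polygon(c(mk_x[m], mk_y[m]), vx, vy)
      inside_m <- .in_polygon(mk_x[m], mk_y[m], vx, vy)
      if (scene$occlusion_margin_mm <= 0 && (!inside_m || d_edge < a_len))
        stop(sprintf(
          "scene config error: marker %d leaves the aperture at frame %d and occlusion is disabled",
          m, f))
      th <- mk$angle_deg[m] * pi / 180
      win <- 2 * a_len  # mm half-window around the marker
      ci <- which(abs(ax_mm - mk_x[m]) <= win)
      ri <- which(abs(ax_mm - mk_y[m]) <= win)
      if (!length(ri) || !length(ci)) next
      dx <- X[ri, ci, drop = FALSE] - mk_x[m]
      dy <- Y[ri, ci, drop = FALSE] - mk_y[m]
      u <- (dx * cos(th) + dy * sin(th)) / a_len
      v <- (-dx * sin(th) + dy * cos(th)) / b_rad
      ell <- (u^2 + v^2) <= 1
      counts[ri, ci] <- counts[ri, ci] -
        scene$marker_attenuation * ell * infield[ri, ci]
    }
    if (scene$blur_px > 0)
      counts <- .conv2_reflect(counts, .gaussian_kernel(scene$blur_px))
    if (scene$noise_sd > 0)
      counts <- counts + stats::rnorm(length(counts), 0, scene$noise_sd)
    images[[f]] <- epid_image(.normalize_counts(counts, invert = TRUE),
                              index = f,
                              frame_rate_hz = geometry$frame_rate_hz)
    ap_x <- cen0[1L] + mot[f, 1L]
    ap_y <- cen0[2L] + mot[f, 2L]
    com_x <- mot[f, 1L] + off[f, 1L]   # marker layout has zero mean
    com_y <- mot[f, 2L] + off[f, 2L]
    truth[[f]] <- data.frame(
      index = f, time_s = t_s[f],
      aperture_row_px = ap_y / pmm + ctr, aperture_col_px = ap_x / pmm + ctr,
      com_row_px = com_y / pmm + ctr, com_col_px = com_x / pmm + ctr,
      offset_pan_mm = com_x - ap_x, offset_tilt_mm = com_y - ap_y,
      injected_pan_mm = off[f, 1L], injected_tilt_mm = off[f, 2L])
  }
  structure(list(images = images, metadata = NULL,
                 truth = do.call(rbind, truth)),
            class = "epid_series")
}

#' Write ground truth alongside a simulated series
#'
#' @param series A rendered `epid_series` with a `truth` component.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(series, path) {
  stopifnot(!is.null(series$truth))
  utils::write.csv(series$truth, path, row.names = FALSE)
  invisible(path)
}
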