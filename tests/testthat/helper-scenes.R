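# Shared fixture builders. Everything is generated in code at test time.

# Small-matrix geometry for fast rendering (same 0.18 mm/px pitch).
small_geometry <- function(size = 200L) geometry_config(matrix_size = size)

# A compact static scene: 27 mm square aperture, three seeds, no motion.
static_scene <- function(n_frames = 1L, noise_sd = 0, tracking_offset = NULL,
                         seed = 1L, ...) {
  scene_config(
    aperture_shape = data.frame(x_mm = c(-13.5, 13.5, 13.5, -13.5),
                                y_mm = c(-13.5, -13.5, 13.5, 13.5)),
    marker_layout = data.frame(x_mm = c(0, 5, -5), y_mm = c(6, -5, -1),
                               angle_deg = c(0, 40, -30)),
    motion = motion_trace("constant", amplitude_mm = 0),
    tracking_offset = tracking_offset, noise_sd = noise_sd,
    n_frames = n_frames, seed = seed, ...)
}

# Rectangular binary mask in a frame, 1-based row/col ranges.
rect_mask <- function(nr, nc, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

# Random union of two overlapping axis-aligned rectangles (single connected
# region, no holes possible with two rectangles).
random_rectilinear_mask <- function(size = 90L, min_side = 4L) {
  repeat {
    r1 <- sort(sample(5:(size - 5), 2))
    c1 <- sort(sample(5:(size - 5), 2))
    if (diff(r1) < min_side || diff(c1) < min_side) next
    # second rectangle forced to overlap the first
    r0 <- sample(r1[1]:r1[2], 1)
    c0 <- sample(c1[1]:c1[2], 1)
    r2 <- sort(c(r0, max(5L, min(size - 5L, r0 + sample(-25:25, 1)))))
    c2 <- sort(c(c0, max(5L, min(size - 5L, c0 + sample(-25:25, 1)))))
    if (diff(r2) < min_side || diff(c2) < min_side) next
    m <- rect_mask(size, size, r1[1]:r1[2], c1[1]:c1[2])
    m[r2[1]:r2[2], c2[1]:c2[2]] <- TRUE
    return(m)
  }
}

# Offsets table with the minimum columns tracking_error_series() needs.
offsets_table <- function(pan, tilt, included = TRUE) {
  n <- length(pan)
  data.frame(index = seq_len(n), time_s = (seq_len(n) - 1) / 2,
             n_markers = 3L, pan_mm = pan, tilt_mm = tilt,
             included = rep_len(included, n), reason = "",
             stringsAsFactors = FALSE)
}
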