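test_that("rendering is deterministic given the seed", {
  g <- small_geometry(128L)
  a <- render_series(static_scene(n_frames = 2L, noise_sd = 0.02, seed = 12), g)
  b <- render_series(static_scene(n_frames = 2L, noise_sd = 0.02, seed = 12), g)
  expect_identical(a$images[[1]]$pixels, b$images[[1]]$pixels)
  expect_identical(a$images[[2]]$pixels, b$images[[2]]$pixels)
  c2 <- render_series(static_scene(n_frames = 2L, noise_sd = 0.02, seed = 13), g)
  expect_false(identical(a$images[[1]]$pixels, c2$images[[1]]$pixels))
})

test_that("a 21-frame series at 2 Hz spans one-and-a-half 6 BPM cycles", {
  g <- small_geometry(256L)
  sc <- scene_config(motion = motion_trace("sinusoid", amplitude_mm = 2,
                                           period_s = 10),
                     noise_sd = 0, n_frames = 21L)
  rs <- render_series(sc, g)
  expect_equal(rs$truth$time_s, seq(0, 10, by = 0.5))
  disp <- motion_displacement(sc$motion, rs$truth$time_s)
  # one full period after 10 s
  expect_equal(disp[21], disp[1], tolerance = 1e-12)
  # and the trace actually moves the aperture in the truth record
  expect_equal(diff(range(rs$truth$aperture_row_px)) * g$pixel_mm_at_iso,
               2 * sc$motion$amplitude_mm, tolerance = 0.01)
})

test_that("ground-truth COM is the analytic mean of the marker positions", {
  g <- small_geometry(160L)
  off <- rbind(c(0.2, -0.1), c(0.5, 0.3))
  sc <- static_scene(n_frames = 2L, tracking_offset = off)
  rs <- render_series(sc, g)
  ctr <- (g$matrix_size - 1) / 2
  # layout is zero-mean, so COM = motion (zero here) + injected offset
  expect_equal(rs$truth$com_col_px, off[, 1] / g$pixel_mm_at_iso + ctr)
  expect_equal(rs$truth$com_row_px, off[, 2] / g$pixel_mm_at_iso + ctr)
  expect_equal(rs$truth$injected_pan_mm, off[, 1])
})

test_that("markers leaving the aperture are a config error unless occlusion is on", {
  g <- small_geometry(160L)
  sc <- static_scene(tracking_offset = c(9, 0))  # pushes a marker past the edge
  expect_error(render_series(sc, g), "occlusion is disabled")
  sc_ok <- static_scene(tracking_offset = c(9, 0),
                        occlusion_margin_mm = 2)
  expect_silent(rs <- render_series(sc_ok, g))
  expect_length(rs$images, 1L)
})

test_that("occlusion near the field edge lowers detection with explained exclusions", {
  g <- small_geometry(200L)
  # drift one marker toward the edge over the series
  drift <- cbind(seq(0, 8.5, length.out = 12L), 0)
  sc <- static_scene(n_frames = 12L, noise_sd = 0.01,
                     tracking_offset = drift, occlusion_margin_mm = 3)
  rs <- render_series(sc, g)
  rs$metadata <- series_metadata("P1", geometry = g)
  ts <- analyze_series(rs)
  expect_lt(mean(ts$offsets$included), 1)
  bad <- ts$offsets[!ts$offsets$included, ]
  expect_true(all(nzchar(bad$reason)))
  expect_true(any(grepl("incomplete marker set", bad$reason)))
})

test_that("perfect tracking yields near-zero E_T through the full pipeline", {
  g <- small_geometry(256L)
  sc <- scene_config(
    aperture_shape = data.frame(x_mm = c(-12, 12, 12, -12),
                                y_mm = c(-12, -12, 12, 12)),
    marker_layout = data.frame(x_mm = c(0, 4, -4), y_mm = c(5, -4, -1)),
    motion = motion_trace("sinusoid", amplitude_mm = 4, period_s = 10),
    tracking_offset = NULL, noise_sd = 0, n_frames = 11L)
  rs <- render_series(sc, g)
  rs$metadata <- series_metadata("P1", geometry = g)
  ts <- analyze_series(rs)
  expect_true(all(ts$offsets$included))
  expect_true(all(ts$offsets$et_2d_mm < 0.5 * g$pixel_mm_at_iso + 1e-9))
})

test_that("make_population returns the nested layout and seeds reproducibly", {
  models <- data.frame(patient_id = c("A", "B"), bias_mm = c(0.8, 1.1),
                       sd_mm = 0.3)
  pop <- make_population(models, n_fields = 2L, n_frames = 3L, seed = 5,
                         geometry = small_geometry(160L))
  expect_named(pop$series, c("A", "B"))
  expect_length(pop$series$A, 2L)
  expect_equal(dim(pop$series$A[[1]]$offsets_true), c(3L, 2L))
  expect_equal(pop$series$A[[1]]$offsets_true[1, ], c(0, 0))
  pop2 <- make_population(models, n_fields = 2L, n_frames = 3L, seed = 5,
                          geometry = small_geometry(160L))
  expect_identical(pop$series$B[[2]]$images[[3]]$pixels,
                   pop2$series$B[[2]]$images[[3]]$pixels)

  # single-frame fields cannot support field statistics downstream
  pop1 <- make_population(models, n_fields = 1L, n_frames = 1L, seed = 5,
                          geometry = small_geometry(160L))
  ts <- analyze_series(pop1$series$A[[1]])
  expect_error(field_stats(ts), "insufficient data")
})
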