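test_that("raw frames round-trip through the writer and reader", {
  g <- small_geometry(128L)
  rs <- render_series(static_scene(noise_sd = 0.02, seed = 4), g)
  img <- rs$images[[1]]
  path <- withr::local_tempfile(fileext = ".raw")
  write_raw_frame(img, path, raw_dialect())
  back <- read_raw_frame(path, raw_dialect(), g)
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 65535 + 1e-9)

  # 8-bit dialect quantizes more coarsely but still round-trips
  d8 <- raw_dialect(bytes_per_pixel = 1L)
  write_raw_frame(img, path, d8)
  expect_lt(max(abs(read_raw_frame(path, d8, g)$pixels - img$pixels)),
            1 / 255 + 1e-9)
})

test_that("count normalization is affine-invariant and maps the midpoint to 0.5", {
  counts <- matrix(c(100, 600, 1100, 350), 2, 2)
  norm <- epidtrack:::.normalize_counts(counts, invert = FALSE)
  expect_equal(norm[2, 1], 0.5)  # 600 is midway between 100 and 1100
  expect_equal(epidtrack:::.normalize_counts(counts * 7.3, invert = FALSE), norm)
  expect_equal(epidtrack:::.normalize_counts(counts, invert = TRUE), 1 - norm)
})

test_that("degenerate and malformed raw frames are rejected with specifics", {
  g <- small_geometry(64L)
  path <- withr::local_tempfile(fileext = ".raw")
  writeBin(rep(1000L, 64L * 64L), path, size = 2L, endian = "little")
  expect_error(read_raw_frame(path, raw_dialect(), g), "no contrast")
  writeBin(1:100, path, size = 2L, endian = "little")
  expect_error(read_raw_frame(path, raw_dialect(), g), "expected 8192 bytes")
})

test_that("series acquisition order and timestamps follow the frame rate", {
  g <- small_geometry(128L)
  rs <- render_series(static_scene(n_frames = 21L, noise_sd = 0.01), g)
  dir <- withr::local_tempdir()
  write_image_series(rs$images, dir)
  md <- series_metadata("P1", geometry = g)
  series <- read_image_series(dir, md)
  expect_length(series$images, 21L)
  times <- vapply(series$images, `[[`, 0, "time_s")
  expect_equal(times, seq(0, 10, by = 0.5))
  expect_equal(unique(round(diff(times), 12)), 1 / g$frame_rate_hz)

  one <- read_image_series(dir, md)
  expect_equal(one$images[[1]]$time_s, 0)
})

test_that("a manifest overrides filename order", {
  g <- small_geometry(128L)
  rs <- render_series(static_scene(n_frames = 3L,
                                   tracking_offset = rbind(c(0, 0), c(1, 0),
                                                           c(2, 0)),
                                   noise_sd = 0), g)
  dir <- withr::local_tempdir()
  paths <- write_image_series(rs$images, dir)
  manifest <- file.path(dir, "order.txt")
  writeLines(basename(paths[c(3, 1, 2)]), manifest)
  series <- read_image_series(manifest, series_metadata("P1", geometry = g))
  # first series frame is rendered frame 3 (within 16-bit quantization) ...
  expect_lt(max(abs(series$images[[1]]$pixels - rs$images[[3]]$pixels)),
            1 / 65535 + 1e-9)
  # ... and clearly not rendered frame 1 (offsets differ by 2 mm)
  expect_gt(max(abs(series$images[[1]]$pixels - rs$images[[1]]$pixels)), 0.1)
  expect_equal(series$images[[1]]$index, 1L)  # indices follow manifest order

  empty <- withr::local_tempdir()
  expect_error(read_image_series(empty, series_metadata("P1", geometry = g)),
               "no frames")
})

test_that("offsets CSV round-trips, with excluded frames carrying empty E_T cells", {
  pan <- c(0, 0.31234, 0.5, -0.2)
  tilt <- c(0, -0.4, 0.25, 0.1)
  inc <- c(TRUE, TRUE, FALSE, TRUE)
  ts <- tracking_error_series(offsets_table(pan, tilt, included = inc))
  path <- withr::local_tempfile(fileext = ".csv")
  write_offsets_csv(ts, path)
  raw <- readLines(path)
  expect_length(raw, 5L)  # header + one row per collected frame
  back <- read_offsets_csv(path)
  expect_equal(back$et_pan_mm[!inc], NA_real_)
  expect_equal(round(back$et_pan_mm[inc], 3),
               round(ts$offsets$et_pan_mm[inc], 3))
  expect_equal(round(back$pan_mm, 3), round(pan, 3))
})
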