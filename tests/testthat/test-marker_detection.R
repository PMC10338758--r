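test_that("labeling respects the configured neighbor connectivity", {
  m <- matrix(FALSE, 10L, 10L)
  m[4, 4] <- m[5, 5] <- TRUE   # diagonal touch
  resp <- matrix(1, 10L, 10L)
  expect_length(label_candidates(m, resp, connectivity = 8L), 1L)
  expect_length(label_candidates(m, resp, connectivity = 4L), 2L)
  expect_length(label_candidates(matrix(FALSE, 10L, 10L), resp), 0L)
})

test_that("blob moments give sane centroid, area and elongation", {
  m <- matrix(FALSE, 30L, 30L)
  m[10:12, 5:14] <- TRUE       # 3 x 10 horizontal bar
  resp <- matrix(1, 30L, 30L)
  b <- label_candidates(m, resp)[[1]]
  expect_equal(b$centroid_px, c(10, 8.5))  # 0-based
  expect_equal(b$area_px2, 30L)
  expect_gt(b$elongation, 2.5)
  # a single pixel has elongation exactly 1
  m1 <- matrix(FALSE, 10L, 10L); m1[3, 7] <- TRUE
  expect_equal(label_candidates(m1, resp[1:10, 1:10])[[1]]$elongation, 1)
})

test_that("rendered markers are found with sub-pixel accuracy", {
  g <- small_geometry(200L)
  sc <- static_scene(noise_sd = 0, tracking_offset = c(0.53, -0.37))
  rs <- render_series(sc, g)
  ct <- trace_boundary(segment_field(rs$images[[1]]))
  ms <- detect_markers(rs$images[[1]], ct, geometry = g)
  expect_true(ms$complete)
  ctr <- (g$matrix_size - 1) / 2
  true_px <- cbind(
    (sc$marker_layout$y_mm - 0.37) / g$pixel_mm_at_iso + ctr,
    (sc$marker_layout$x_mm + 0.53) / g$pixel_mm_at_iso + ctr)
  found <- do.call(rbind, lapply(ms$blobs, `[[`, "centroid_px"))
  for (k in seq_len(nrow(true_px))) {
    d <- sqrt((found[, 1] - true_px[k, 1])^2 + (found[, 2] - true_px[k, 2])^2)
    expect_lt(min(d), 0.3)
  }
  # ground-truth COM equals the analytic marker mean
  expect_equal(unname(colMeans(found)),
               unname(colMeans(true_px)), tolerance = 0.2)
})

test_that("filter rules exclude specks, edge-adjacent and elongated blobs", {
  contour <- trace_boundary(rect_mask(100L, 100L, 21:80, 21:80))
  cand <- matrix(FALSE, 100L, 100L)
  cand[48:51, 48:51] <- TRUE             # genuine marker-like blob
  cand[60, 60] <- TRUE                   # one-pixel speck
  cand[23:26, 48:51] <- TRUE             # ~0.5 mm from the field edge
  cand[70:71, 30:69] <- TRUE             # elongated edge-like ridge
  resp <- matrix(1, 100L, 100L)
  ms <- filter_markers(label_candidates(cand, resp), contour,
                       expected_markers = 3L)
  expect_equal(ms$n_detected, 1L)
  expect_false(ms$complete)
  expect_equal(ms$blobs[[1]]$centroid_px, c(48.5, 48.5))
  expect_setequal(
    ms$excluded$reason,
    c("below minimum area", "within 1.24 mm of field edge", "too elongated"))
})

test_that("an empty candidate set yields an undefined COM", {
  contour <- trace_boundary(rect_mask(50L, 50L, 11:40, 11:40))
  ms <- filter_markers(list(), contour)
  expect_equal(ms$n_detected, 0L)
  expect_false(ms$complete)
  expect_error(markers_com(ms), "undefined COM")
})

test_that("the COM is the unweighted centroid mean, order- and shift-stable", {
  mk <- function(centers, nr = 60L) {
    m <- matrix(FALSE, nr, nr)
    for (ctr in centers) m[ctr[1] + (0:2), ctr[2] + (0:2)] <- TRUE
    label_candidates(m, matrix(1, nr, nr))
  }
  contour <- trace_boundary(rect_mask(60L, 60L, 2:59, 2:59))
  rules <- marker_filter_rules(edge_margin_mm = 0, min_area_px2 = 1)
  b <- mk(list(c(10, 10), c(20, 30)))
  ms <- filter_markers(b, contour, rules, expected_markers = 2L)
  expect_equal(ms$com_px, c(15, 20))  # mean of (10,10) and (20,30), 0-based
  ms_rev <- filter_markers(rev(b), contour, rules, expected_markers = 2L)
  expect_equal(ms_rev$com_px, ms$com_px)
  b2 <- mk(list(c(15, 14), c(25, 34)))  # both shifted by (+5, +4)
  ms2 <- filter_markers(b2, contour, rules, expected_markers = 2L)
  expect_equal(ms2$com_px, ms$com_px + c(5, 4))
})

test_that("all frames of a clean moving series are detected completely", {
  g <- small_geometry(256L)
  sc <- scene_config(
    aperture_shape = data.frame(x_mm = c(-12, 12, 12, -12),
                                y_mm = c(-12, -12, 12, 12)),
    marker_layout = data.frame(x_mm = c(0, 4, -4), y_mm = c(5, -4, -1)),
    motion = motion_trace("sinusoid", amplitude_mm = 4, period_s = 10),
    tracking_offset = c(0.4, 0.6), noise_sd = 0.01, n_frames = 11L, seed = 6)
  rs <- render_series(sc, g)
  rs$metadata <- series_metadata("P1", geometry = g)
  ts <- analyze_series(rs)
  expect_true(all(ts$offsets$included))
  expect_equal(unique(ts$offsets$n_markers), 3L)
})

test_that("centroid accuracy degrades gracefully with noise", {
  g <- small_geometry(200L)
  rms_at <- function(noise) {
    sc <- static_scene(n_frames = 3L, noise_sd = noise,
                       tracking_offset = c(0.3, 0.2), seed = 8)
    rs <- render_series(sc, g)
    errs <- vapply(seq_len(3L), function(f) {
      ct <- trace_boundary(segment_field(rs$images[[f]]))
      ms <- detect_markers(rs$images[[f]], ct, geometry = g)
      tr <- rs$truth[f, ]
      sqrt(sum((ms$com_px - c(tr$com_row_px, tr$com_col_px))^2))
    }, 0)
    sqrt(mean(errs^2))
  }
  clean <- rms_at(0)
  noisy <- rms_at(0.05)
  expect_lt(clean, 0.3)     # sub-pixel on noise-free scenes
  expect_gt(noisy, clean * 0.5)  # no spurious precision gain under noise
  expect_lt(noisy, 2)       # still within ~2 px even at heavy noise
})
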