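test_that("pixel displacements convert to mm at isocenter", {
  g <- geometry_config()
  expect_equal(frame_offset(c(100, 100), c(100, 110), g),
               c(pan_mm = 1.8, tilt_mm = 0))
  expect_equal(frame_offset(c(100, 100), c(100, 100), g),
               c(pan_mm = 0, tilt_mm = 0))
  expect_equal(frame_offset(c(100, 100), c(95, 105), g),
               c(pan_mm = 0.9, tilt_mm = -0.9))
})

test_that("tracking error is baseline-referenced with the 3-4-5 closed form", {
  ts <- tracking_error_series(offsets_table(c(0, 0.3), c(0, -0.4)))
  expect_equal(ts$baseline_index, 1L)
  expect_equal(ts$offsets$et_pan_mm, c(0, 0.3))
  expect_equal(ts$offsets$et_tilt_mm, c(0, 0.4))
  expect_equal(ts$offsets$et_2d_mm, c(0, 0.5))

  # constant offsets track perfectly
  flat <- tracking_error_series(offsets_table(rep(1.2, 5), rep(-0.8, 5)))
  expect_equal(flat$offsets$et_2d_mm, rep(0, 5))
})

test_that("E_T is invariant to a constant shift of all offsets", {
  set.seed(4)
  pan <- rnorm(12); tilt <- rnorm(12)
  a <- tracking_error_series(offsets_table(pan, tilt))
  b <- tracking_error_series(offsets_table(pan + 3.7, tilt - 1.1))
  expect_equal(a$offsets$et_pan_mm, b$offsets$et_pan_mm)
  expect_equal(a$offsets$et_2d_mm, b$offsets$et_2d_mm)
})

test_that("an excluded first frame promotes the next usable frame to baseline", {
  inc <- c(FALSE, TRUE, TRUE, TRUE)
  ts <- tracking_error_series(offsets_table(c(9, 1, 1.5, 1), c(9, 2, 2, 2.5),
                                            included = inc))
  expect_equal(ts$baseline_index, 2L)
  expect_true(is.na(ts$offsets$et_pan_mm[1]))
  expect_equal(ts$offsets$et_pan_mm[2], 0)
  expect_equal(ts$offsets$et_pan_mm[3], 0.5)
  expect_error(tracking_error_series(offsets_table(1, 1, included = FALSE)),
               "empty series")
})

test_that("per-frame triangle bounds hold on random analyzed series", {
  set.seed(77)
  for (i in 1:20) {
    ts <- tracking_error_series(offsets_table(rnorm(30), rnorm(30)))
    et <- ts$offsets
    expect_true(all(et$et_2d_mm >= pmax(et$et_pan_mm, et$et_tilt_mm) - 1e-12))
    expect_true(all(et$et_2d_mm <= et$et_pan_mm + et$et_tilt_mm + 1e-12))
  }
})

test_that("field statistics match closed forms and validate their input", {
  # E_T values {0, 1, 2, 3, 4} along pan via offsets 0..4 from baseline 0
  ts <- tracking_error_series(offsets_table(c(0, 1, 2, 3, 4), rep(0, 5)))
  fs <- field_stats(ts)
  expect_equal(fs$mean_pan_mm, 2)
  expect_equal(fs$max_pan_mm, 4)
  expect_equal(fs$p90_pan_mm, quantile(0:4, 0.9, names = FALSE))
  expect_equal(fs$detection_rate, 1)

  # {0, c, c, c} has mean 3c/4
  ts2 <- tracking_error_series(offsets_table(c(0, 0.8, 0.8, 0.8), rep(0, 4)))
  expect_equal(field_stats(ts2)$mean_pan_mm, 0.6)

  one <- tracking_error_series(offsets_table(0, 0))
  expect_error(field_stats(one), "insufficient data")
})

test_that("long-run field statistics agree with the analytic model", {
  set.seed(123)
  n <- 1000L
  bias <- 0.9; s <- 0.25
  pan <- c(0, rnorm(n - 1, bias, s))
  ts <- tracking_error_series(offsets_table(pan, rep(0, n)))
  fs <- field_stats(ts)
  ex <- expected_patient_et(bias, s, n_fields = 1L, n_frames = n)
  se_mean <- s / sqrt(n)
  expect_lt(abs(fs$mean_pan_mm - ex$mean_mm), 3 * se_mean)
  se_sd <- ex$sd_mm / sqrt(2 * (n - 1))
  expect_lt(abs(fs$sd_pan_mm - ex$sd_mm), 3 * se_sd)
})

test_that("patient pooling equals the concatenation oracle", {
  set.seed(9)
  mk <- function(n) tracking_error_series(offsets_table(rnorm(n), rnorm(n)),
                                          series_metadata("P1"))
  fields <- list(mk(15L), mk(25L), mk(10L))
  ps <- patient_stats(fields)
  pooled <- unlist(lapply(fields, function(s)
    s$offsets$et_2d_mm[s$offsets$included]))
  expect_equal(ps$mean_2d_mm, mean(pooled))
  expect_equal(ps$sd_2d_mm, sd(pooled))
  expect_equal(ps$p90_2d_mm, quantile(pooled, 0.9, type = 7, names = FALSE))
  expect_equal(ps$n_analyzed, 50L)

  # a single field reduces to its own field statistics
  single <- patient_stats(fields[1])
  fs <- field_stats(fields[[1]])
  expect_equal(single$mean_pan_mm, fs$mean_pan_mm)
  expect_equal(single$sd_tilt_mm, fs$sd_tilt_mm)
})
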