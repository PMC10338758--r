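# Synthetic multi-patient datasets for systematic/random error recovery
# studies.

#' Generate a synthetic patient population
#'
#' Builds a nested synthetic dataset for Sigma/sigma parameter-recovery
#' studies: each patient has a patient-specific systematic offset
#' (`bias_mm`) and within-patient frame-to-frame SD (`sd_mm`); for every
#' field, the baseline frame's tracking offset is exactly zero (the reference
#' geometry captured at beam-on) and each subsequent frame draws independent
#' pan and tilt offsets from `N(bias_mm, sd_mm)`. Because the tracking error
#' is baseline-referenced, this anchored-baseline model is what makes a
#' per-patient systematic component observable at all: a bias shared by the
#' baseline would cancel identically in the subtraction.
#'
#' Scenes are rendered at a reduced matrix (default 160 px at the standard
#' 0.18 mm/px pitch) with a static 24 mm aperture: the offsets under study,
#' not the respiratory excursion, are the signal, and both aperture and
#' markers ride the same motion anyway.
#'
#' @param models Data frame with columns `patient_id`, `bias_mm`, `sd_mm`
#'   (>= 2 patients).
#' @param n_fields Fields per patient.
#' @param n_frames Frames per field (>= 2 for downstream statistics).
#' @param seed RNG seed governing both the offset draws and the rendering
#'   noise.
#' @param noise_sd Grayscale noise SD passed to the renderer.
#' @param geometry Rendering geometry.
#' @return List with `series` (a list per patient of rendered series, each a
#'   list with `images`, `metadata`, `truth`, `offsets_true`) and the
#'   generating `models`.
#' @export
make_population <- function(models, n_fields = 7L, n_frames = 50L, seed = 1L,
                            noise_sd = 0.01,
                            geometry = geometry_config(matrix_size = 160L)) {
  stopifnot(is.data.frame(models), nrow(models) >= 2L,
            all(c("patient_id", "bias_mm", "sd_mm") %in% names(models)),
            n_frames >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  base_shape <- data.frame(x_mm = c(-12, 12, 12, -12),
                           y_mm = c(-12, -12, 12, 12))
  layout <- data.frame(x_mm = c(0, 4, -4), y_mm = c(5, -4, -1),
                       angle_deg = c(0, 35, -25))
  out <- vector("list", nrow(models))
  names(out) <- as.character(models$patient_id)
  for (p in seq_len(nrow(models))) {
    fields <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      offs <- rbind(c(0, 0),
                    cbind(stats::rnorm(n_frames - 1L, models$bias_mm[p],
                                       models$sd_mm[p]),
                          stats::rnorm(n_frames - 1L, models$bias_mm[p],
                                       models$sd_mm[p])))[seq_len(n_frames), ,
                                                          drop = FALSE]
      sc <- scene_config(aperture_shape = base_shape, marker_layout = layout,
                         motion = motion_trace("constant", amplitude_mm = 0),
                         tracking_offset = offs, noise_sd = noise_sd,
                         n_frames = n_frames,
                         seed = sample.int(.Machine$integer.max - 1L, 1L))
      rs <- render_series(sc, geometry)
      rs$metadata <- series_metadata(models$patient_id[p], "1", f,
                                     expected_markers = nrow(layout),
                                     geometry = geometry)
      rs$offsets_true <- offs
      fields[[f]] <- rs
    }
    out[[p]] <- fields
  }
  list(series = out, models = models, n_fields = n_fields, n_frames = n_frames)
}

#' Expected per-patient E_T statistics under the population model
#'
#' Closed-form expectations of the pipeline's per-patient pooled mean and
#' sample variance under the [make_population()] generative model: per field,
#' one structural zero (the baseline) plus `n_frames - 1` draws of
#' `|N(bias, sd)|` (folded normal). Used as the analytic reference in
#' Monte-Carlo recovery checks.
#'
#' @param bias_mm,sd_mm Patient model parameters.
#' @param n_fields,n_frames Population layout.
#' @return List with `mean_mm` (expected pooled mean E_T per direction) and
#'   `sd_mm` (square root of the expected pooled sample variance).
#' @export
expected_patient_et <- function(bias_mm, sd_mm, n_fields = 7L, n_frames = 50L) {
  # folded-normal moments
  mu_f <- sd_mm * sqrt(2 / pi) * exp(-bias_mm^2 / (2 * sd_mm^2)) +
    bias_mm * (1 - 2 * stats::pnorm(-bias_mm / sd_mm))
  var_f <- bias_mm^2 + sd_mm^2 - mu_f^2
  N <- n_fields * n_frames          # pooled frames per patient
  k <- n_fields                     # structural zeros (one baseline per field)
  m <- N - k                        # folded-normal draws
  e_mean <- m * mu_f / N
  # E[sample variance] of {k zeros, m iid folded-normal draws}
  e_var <- (m * (N - 1) * var_f / N + m * k * mu_f^2 / N) / (N - 1)
  list(mean_mm = e_mean, sd_mm = sqrt(e_var))
}
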