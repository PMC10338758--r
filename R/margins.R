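# Population error decomposition and the Van Herk planning-target-margin
# contribution. Conventions pinned here: the systematic error Sigma is the
# sample SD (divisor n-1) of the per-patient mean errors; the random error
# sigma is the plain RMS (divisor n) of the per-patient error SDs.

#' Population random error (sigma)
#'
#' Root mean square of the per-patient tracking-error SDs, divisor `n`:
#' `sqrt(mean(sds^2))`.
#'
#' @param per_patient_sds Numeric vector of per-patient SDs in mm (all >= 0).
#' @return sigma in mm.
#' @export
random_error <- function(per_patient_sds) {
  stopifnot(length(per_patient_sds) >= 1L, all(is.finite(per_patient_sds)),
            all(per_patient_sds >= 0))
  sqrt(mean(per_patient_sds^2))
}

#' Population systematic error (Sigma)
#'
#' Sample standard deviation (divisor `n - 1`) of the per-patient mean
#' tracking errors.
#'
#' @param per_patient_means Numeric vector of per-patient means in mm
#'   (at least 2).
#' @return Sigma in mm.
#' @export
systematic_error <- function(per_patient_means) {
  if (length(per_patient_means) < 2L)
    stop("systematic error needs at least 2 patients")
  stopifnot(all(is.finite(per_patient_means)))
  stats::sd(per_patient_means)
}

#' Van Herk planning-target-margin contribution
#'
#' The coverage-probability margin recipe `2.5 * Sigma + 0.7 * sigma`, under
#' which 90% of patients receive at least 95% of the prescribed dose to the
#' CTV. Reported rounded to 0.1 mm; full precision is retained in the result.
#'
#' @param Sigma Systematic error in mm (>= 0).
#' @param sigma Random error in mm (>= 0).
#' @return An object of class `margin_result` with `margin_mm`,
#'   `margin_rounded_mm`, the inputs and a `formula_id`.
#' @examples
#' van_herk_margin(0.20, 0.79)  # rounds to 1.1 mm
#' @export
van_herk_margin <- function(Sigma, sigma) {
  stopifnot(is.finite(Sigma), is.finite(sigma))
  if (Sigma < 0 || sigma < 0)
    stop("van_herk_margin: Sigma and sigma must be non-negative")
  m <- 2.5 * Sigma + 0.7 * sigma
  structure(
    list(margin_mm = m, margin_rounded_mm = round(m, 1),
         Sigma_mm = Sigma, sigma_mm = sigma,
         formula_id = "van-herk-90-95 (2.5*Sigma + 0.7*sigma)"),
    class = "margin_result"
  )
}

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("PTV margin contribution: %.1f mm  [%s; Sigma = %.2f, sigma = %.2f]\n",
              x$margin_rounded_mm, x$formula_id, x$Sigma_mm, x$sigma_mm))
  invisible(x)
}

#' Population statistics from a per-patient summary table
#'
#' Decomposes a per-patient mean/SD table (one row per patient, columns
#' `mean_pan_mm` ... `sd_2d_mm` as produced by [patient_stats()]) into the
#' population systematic error Sigma, random error sigma and the Van Herk
#' margin contribution, per direction. The 2D margin is the quantity of
#' clinical interest; the per-direction margins are a labeled extension.
#'
#' @param per_patient Data frame with one row per patient.
#' @return An object of class `population_stats`: list with `n_patients`,
#'   `per_patient`, and per direction (`pan`, `tilt`, `2d`) the elements
#'   `Sigma_mm`, `sigma_mm` and `margin` (a `margin_result`).
#' @examples
#' pop <- population_stats(liver_cohort_stats())
#' pop$`2d`$margin
#' @export
population_stats <- function(per_patient) {
  stopifnot(is.data.frame(per_patient), nrow(per_patient) >= 2L)
  dirs <- c("pan", "tilt", "2d")
  out <- list(n_patients = nrow(per_patient), per_patient = per_patient)
  for (d in dirs) {
    mcol <- paste0("mean_", d, "_mm")
    scol <- paste0("sd_", d, "_mm")
    stopifnot(mcol %in% names(per_patient), scol %in% names(per_patient))
    Sig <- systematic_error(per_patient[[mcol]])
    sig <- random_error(per_patient[[scol]])
    out[[d]] <- list(Sigma_mm = Sig, sigma_mm = sig,
                     margin = van_herk_margin(Sig, sig))
  }
  structure(out, class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("Population statistics over %d patients:\n", x$n_patients))
  for (d in c("pan", "tilt", "2d")) {
    cat(sprintf("  %-4s Sigma = %.2f mm, sigma = %.2f mm, margin = %.1f mm\n",
                d, x[[d]]$Sigma_mm, x[[d]]$sigma_mm,
                x[[d]]$margin$margin_rounded_mm))
  }
  invisible(x)
}

#' Bundled eight-patient liver SBRT cohort summary
#'
#' Per-patient tracking-error summary statistics (mean, SD and 90th
#' percentile of E_T in the pan, tilt and 2D directions, mm at isocenter) for
#' an eight-patient liver SBRT cohort treated with gimbal-based dynamic
#' tumour tracking. Shipped as the package's worked example for the
#' population-statistics and margin machinery.
#'
#' @return Data frame with one row per patient.
#' @examples
#' population_stats(liver_cohort_stats())
#' @export
liver_cohort_stats <- function() {
  utils::read.csv(system.file("extdata", "liver_cohort_stats.csv",
                              package = "epidtrack"),
                  stringsAsFactors = FALSE)
}

#' Export a population report as JSON
#'
#' @param pop A `population_stats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_json <- function(pop, path) {
  stopifnot(inherits(pop, "population_stats"))
  rep <- list(n_patients = pop$n_patients)
  for (d in c("pan", "tilt", "2d")) {
    rep[[d]] <- list(Sigma_mm = pop[[d]]$Sigma_mm,
                     sigma_mm = pop[[d]]$sigma_mm,
                     margin_mm = pop[[d]]$margin$margin_rounded_mm,
                     formula_id = pop[[d]]$margin$formula_id)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
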