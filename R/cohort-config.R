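#' Cohort configuration for the synthetic study generator
#'
#' Captures the design of the three-arm longitudinal study the generator
#' emulates: a maximum-tolerated-dose arm (MTD, n = 27), a metronomic arm
#' (MET, n = 20) and a saline control arm (CG, n = 14), each followed over
#' six weekly visits.
#'
#' @param n_per_group Named integer vector of tumors per arm.
#' @param weeks Strictly increasing integer visit indices.
#' @param groups Group labels; must name `n_per_group`.
#' @param seed Integer seed for all randomness in the generator.
#' @param missing_rate Probability that a visit's observation is missing.
#' @param artifact_rate Probability that a raw spectrum is corrupted.
#' @param noise_sd_reflectance Relative (multiplicative) SD of spectral noise.
#' @param subject_sd Between-tumor SD of trajectory offsets, fold-change scale.
#' @param noise_sd_value Within-tumor residual SD of derived values
#'   (fold changes, relative expression), fold-change scale.
#' @param spectra_per_visit Raw spectra acquired per tumor per visit.
#' @param ct_noise_sd SD of qPCR triplicate noise, cycles.
#' @param qpcr_weeks Named list of biopsy weeks per group (the study biopsied
#'   MET and CG at weeks 1, 4 and 6 only, MTD weekly).
#'
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 42)
#' cfg$n_per_group
cohort_config <- function(n_per_group = c(CG = 14L, MET = 20L, MTD = 27L),
                          weeks = 1:6,
                          groups = names(n_per_group),
                          seed = 1L,
                          missing_rate = 0.05,
                          artifact_rate = 0.05,
                          noise_sd_reflectance = 0.01,
                          subject_sd = 0.04,
                          noise_sd_value = 0.06,
                          spectra_per_visit = 3L,
                          ct_noise_sd = 0.1,
                          qpcr_weeks = list(CG = c(1, 4, 6),
                                            MET = c(1, 4, 6),
                                            MTD = 1:6)) {
  assert_that(length(n_per_group) >= 1 && all(n_per_group >= 1),
              "n_per_group must contain counts >= 1")
  assert_that(!is.null(names(n_per_group)) && !anyNA(names(n_per_group)),
              "n_per_group must be named by group")
  assert_that(all(diff(weeks) > 0), "weeks must be strictly increasing")
  rates <- c(missing_rate, artifact_rate)
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  assert_that(noise_sd_reflectance >= 0 && subject_sd >= 0 &&
                noise_sd_value >= 0, "noise SDs must be >= 0")
  assert_that(setequal(groups, names(n_per_group)),
              "groups must match names(n_per_group)")
  structure(list(
    n_per_group = n_per_group[groups],
    weeks = as.numeric(weeks),
    groups = groups,
    seed = as.integer(seed),
    missing_rate = missing_rate,
    artifact_rate = artifact_rate,
    noise_sd_reflectance = noise_sd_reflectance,
    subject_sd = subject_sd,
    noise_sd_value = noise_sd_value,
    spectra_per_visit = as.integer(spectra_per_visit),
    ct_noise_sd = ct_noise_sd,
    qpcr_weeks = qpcr_weeks
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  arms:   ", paste(sprintf("%s=%d", names(x$n_per_group),
                                  x$n_per_group), collapse = ", "), "\n")
  cat("  weeks:  ", paste(x$weeks, collapse = ", "), "\n")
  cat("  seed:   ", x$seed, "\n")
  cat(sprintf("  noise:   subject_sd=%.3g value_sd=%.3g reflectance_sd=%.3g\n",
              x$subject_sd, x$noise_sd_value, x$noise_sd_reflectance))
  cat(sprintf("  rates:   missing=%.3g artifact=%.3g\n",
              x$missing_rate, x$artifact_rate))
  invisible(x)
}
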