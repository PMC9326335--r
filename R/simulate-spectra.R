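#' Simulate raw endoscopic reflectance spectra for a cohort
#'
#' For every tumor-visit in the true trajectories, generates
#' `spectra_per_visit` raw spectra by pushing the true optical parameters
#' through the forward model and re-embedding them in instrument units:
#' `raw = reference_shape * R_true / ref_reflectivity + dark`, with
#' multiplicative Gaussian noise at `config$noise_sd_reflectance`. With
#' probability `config$artifact_rate` a spectrum is corrupted by one of
#' three archetypes — detector saturation, near-dark signal, or a baseline
#' shift — and the corruption is recorded in the ground truth so rejection
#' logic can be scored against it.
#'
#' @param trajectories Output of [simulate_trajectories()].
#' @param config A [cohort_config()].
#' @param ext An `extinction_table`.
#' @param model Forward model (surrogate function or LUT).
#' @param wavelengths Detector wavelength grid, nm.
#' @param scattering Per-cohort scattering parameters `c(a, b)` held fixed
#'   across tumors.
#' @param ref_reflectivity Reflectivity of the calibration standard.
#' @param saturation_level Full-scale detector count.
#' @return List: `spectra` (list of raw `drs_spectrum`), `dark` and
#'   `reference` spectra, and `truth` data frame (tumor_id, group, week,
#'   replicate, sto2_true, thb_true, a, b, corrupted, corruption).
#' @export
simulate_spectra <- function(trajectories, config,
                             ext = load_extinction(),
                             model = reflectance_surrogate(),
                             wavelengths = seq(450, 650, by = 2),
                             scattering = c(a = 12, b = 1.3),
                             ref_reflectivity = 0.05,
                             saturation_level = 65535) {
  per <- trajectories$perfusion
  bad_wk <- setdiff(unique(per$week), config$weeks)
  if (length(bad_wk)) {
    stop("trajectory week(s) outside config weeks: ",
         paste(bad_wk, collapse = ", "))
  }
  # lamp shape scaled so that even unity reflectance (20x the 5% standard)
  # stays below detector full scale; only injected artifacts saturate
  dark_level <- 400
  ref_shape <- 2600 * exp(-((wavelengths - 620) / 180)^2) + 300
  dark <- drs_spectrum(wavelengths, rep(dark_level, length(wavelengths)),
                   list(role = "dark"))
  reference <- drs_spectrum(wavelengths, ref_shape + dark_level,
                        list(role = "reference"))

  with_seed(derive_seed(config$seed, "spectra"), {
    spectra <- vector("list", nrow(per) * config$spectra_per_visit)
    truth <- vector("list", length(spectra))
    k <- 0L
    for (i in seq_len(nrow(per))) {
      p <- optical_params(per$thb_true[i], per$sto2_true[i],
                          scattering[["a"]], scattering[["b"]])
      r_true <- forward_reflectance(p, wavelengths, ext, model)
      for (rep_j in seq_len(config$spectra_per_visit)) {
        noise <- if (config$noise_sd_reflectance > 0) {
          stats::rnorm(length(wavelengths), 1, config$noise_sd_reflectance)
        } else 1
        raw <- ref_shape * (r_true / ref_reflectivity) * noise + dark_level
        corruption <- ""
        if (stats::runif(1) < config$artifact_rate) {
          corruption <- sample(c("saturation", "low signal",
                                 "baseline shift"), 1)
          raw <- switch(corruption,
            "saturation" = {
              idx <- seq_len(length(raw) %/% 3)
              raw[idx] <- saturation_level
              raw
            },
            "low signal" = dark_level +
              stats::runif(length(raw), 0, 2),
            "baseline shift" = raw + 0.4 * max(raw))
        }
        raw <- pmin(raw, saturation_level)
        k <- k + 1L
        spectra[[k]] <- drs_spectrum(
          wavelengths, raw,
          list(tumor_id = per$tumor_id[i], group = per$group[i],
               week = per$week[i], replicate = rep_j, role = "sample"))
        truth[[k]] <- data.frame(
          tumor_id = per$tumor_id[i], group = per$group[i],
          week = per$week[i], replicate = rep_j,
          sto2_true = per$sto2_true[i], thb_true = per$thb_true[i],
          a = scattering[["a"]], b = scattering[["b"]],
          corrupted = corruption != "", corruption = corruption)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(spectra = spectra, dark = dark, reference = reference,
         truth = truth)
  })
}
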