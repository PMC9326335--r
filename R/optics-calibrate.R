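#' Construct a spectrum object
#'
#' @param wavelengths Strictly increasing wavelengths, nm.
#' @param intensities Non-negative detector counts (or calibrated
#'   reflectance after [calibrate_spectrum()]).
#' @param meta Named list of metadata (tumor_id, group, week, replicate,
#'   role = sample|dark|reference).
#' @return Object of class `drs_spectrum`.
#' @export
drs_spectrum <- function(wavelengths, intensities, meta = list()) {
  assert_that(length(wavelengths) == length(intensities),
              "wavelengths and intensities must have equal length")
  assert_that(all(diff(wavelengths) > 0),
              "wavelengths must be strictly increasing")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 meta = meta),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  cat(sprintf("<drs_spectrum: %d points, %.0f-%.0f nm%s>\n",
              length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths),
              if (!is.null(x$meta$role)) paste0(", ", x$meta$role) else ""))
  invisible(x)
}

#' Calibrate a raw spectrum against dark and reference measurements
#'
#' Dark-corrects the raw signal and scales it by a reference measurement of
#' a diffuse standard of known reflectivity (5% by default):
#' `R(lambda) = ref_reflectivity * (I_sample - I_dark) / (I_ref - I_dark)`.
#' Reference and dark spectra are linearly interpolated onto the sample
#' grid, and the result is clipped to the configured fit range.
#'
#' @param sample,dark,reference `drs_spectrum` objects.
#' @param ref_reflectivity Reflectivity of the calibration standard.
#' @param fit_range Wavelength window retained for fitting, nm.
#' @return Calibrated `drs_spectrum` (intensities are reflectance) carrying
#'   the sample's metadata plus `role = "calibrated"` and the peak raw
#'   count in `meta$raw_max`.
#' @export
calibrate_spectrum <- function(sample, dark, reference,
                               ref_reflectivity = 0.05,
                               fit_range = c(450, 650)) {
  wl <- sample$wavelengths
  keep <- wl >= fit_range[1] & wl <= fit_range[2]
  assert_that(sum(keep) >= 2, "no wavelengths inside the fit range")
  wl <- wl[keep]
  i_s <- sample$intensities[keep]
  i_d <- stats::approx(dark$wavelengths, dark$intensities, wl, rule = 2)$y
  i_r <- stats::approx(reference$wavelengths, reference$intensities, wl,
                       rule = 2)$y
  denom <- i_r - i_d
  if (any(denom <= 0)) {
    stop(sprintf(
      "calibration error: reference - dark <= 0 at %.1f nm",
      wl[which(denom <= 0)[1]]))
  }
  meta <- sample$meta
  meta$role <- "calibrated"
  meta$raw_max <- max(sample$intensities)
  drs_spectrum(wl, ref_reflectivity * (i_s - i_d) / denom, meta)
}

#' Flag and remove artifact spectra
#'
#' Implements the screening applied before inversion: a spectrum is rejected
#' if (i) any raw count reached detector saturation (probe pressure /
#' specular events), (ii) its median calibrated reflectance falls below a
#' low-signal floor (probe lift-off, blood pooling), or — after inversion —
#' (iii) the model fit residual exceeds an RMSE cap (motion-distorted
#' lineshapes; applied in [invert_spectrum()]).
#'
#' @param spectra List of calibrated `drs_spectrum` objects (each carrying
#'   `meta$raw_max` from calibration).
#' @param saturation_level Raw count treated as saturation.
#' @param low_signal_floor Minimum median calibrated reflectance.
#' @return List with `retained` (list of spectra) and `rejected` (data frame
#'   index/reason).
#' @export
reject_artifacts <- function(spectra,
                             saturation_level = 65535,
                             low_signal_floor = 0.005) {
  reasons <- vapply(spectra, function(s) {
    raw_max <- s$meta$raw_max %||% max(s$intensities)
    if (raw_max >= saturation_level) return("saturation")
    if (stats::median(s$intensities) < low_signal_floor) {
      return("low signal")
    }
    ""
  }, character(1))
  bad <- which(reasons != "")
  list(
    retained = spectra[setdiff(seq_along(spectra), bad)],
    rejected = data.frame(index = bad,
                          reason = reasons[bad],
                          stringsAsFactors = FALSE)
  )
}

#' Per-tumor fold change relative to a baseline week
#'
#' Normalizes each tumor's weekly series of a perfusion metric by its own
#' value at the baseline week. Tumors whose baseline is missing or
#' non-positive are excluded and reported.
#'
#' @param data Data frame with columns tumor_id, week and the metric column.
#' @param metric Column to normalize.
#' @param baseline_week Week used as the within-tumor reference.
#' @return List with `fold` (data frame tumor_id, group?, week, value) and
#'   `excluded` (data frame tumor_id, reason).
#' @export
fold_change <- function(data, metric, baseline_week = 1) {
  stopifnot(all(c("tumor_id", "week", metric) %in% names(data)))
  excl <- list(); out <- list()
  for (id in unique(data$tumor_id)) {
    d <- data[data$tumor_id == id, ]
    base <- d[[metric]][d$week == baseline_week]
    if (length(base) == 0 || is.na(base[1])) {
      excl[[id]] <- "baseline missing"
    } else if (base[1] <= 0) {
      excl[[id]] <- "baseline non-positive"
    } else {
      d$value <- d[[metric]] / base[1]
      out[[id]] <- d[, c(intersect(c("tumor_id", "group", "week"),
                                   names(d)), "value")]
    }
  }
  fold <- if (length(out)) do.call(rbind, out) else
    data.frame(tumor_id = character(), week = numeric(), value = numeric())
  rownames(fold) <- NULL
  list(fold = fold,
       excluded = data.frame(tumor_id = names(excl),
                             reason = unlist(excl, use.names = FALSE)))
}
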