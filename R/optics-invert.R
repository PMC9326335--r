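#' Invert a calibrated reflectance spectrum
#'
#' Bounded least squares over theta = (tHb, StO2, a, b) minimizing the sum
#' of squared differences between measured and modeled reflectance on the
#' fit range, restarted from a small fixed grid of initial values to avoid
#' local minima. The model is the same forward map used in
#' [forward_reflectance()] — an analytic surrogate or an interpolated LUT.
#'
#' @param calibrated A calibrated `drs_spectrum`.
#' @param ext An `extinction_table`.
#' @param model Surrogate function or `reflectance_lut`.
#' @param lower,upper Parameter bounds, order (tHb, StO2, a, b).
#' @param inits Matrix of starting points (rows), same order; defaults to a
#'   coarse 2x3x2 factorial over the interior of the bounds.
#' @param rmse_max Post-fit residual cap: fits with RMSE above it are
#'   flagged rejected with reason "poor fit".
#' @return Object of class `perfusion_estimate`: params, derived perfusion,
#'   rmse, n_points, converged, rejected, reason.
#' @export
invert_spectrum <- function(calibrated, ext,
                            model = reflectance_surrogate(),
                            lower = c(tHb = 0.01, StO2 = 0, a = 1, b = 0),
                            upper = c(tHb = 100, StO2 = 1, a = 50, b = 4),
                            inits = NULL,
                            rmse_max = 0.01) {
  wl <- calibrated$wavelengths
  r_meas <- calibrated$intensities
  if (is.null(inits)) {
    inits <- as.matrix(expand.grid(tHb = c(2, 10),
                                   StO2 = c(0.2, 0.5, 0.9),
                                   a = c(5, 20),
                                   b = 1.2))
  }
  # hoist the wavelength-dependent pieces out of the optimizer loop
  rng <- range(ext$wavelength_nm)
  if (any(wl < rng[1] | wl > rng[2])) {
    stop(sprintf("wavelength outside extinction-table support [%g, %g] nm",
                 rng[1], rng[2]))
  }
  e_o <- stats::approx(ext$wavelength_nm, ext$eps_HbO2, wl)$y
  e_d <- stats::approx(ext$wavelength_nm, ext$eps_Hb, wl)$y
  fac <- log(10) / 64500
  log_wl <- log(wl / 630)
  is_lut <- inherits(model, "reflectance_lut")
  obj <- function(theta) {
    mu_a <- fac * theta[1] * (theta[2] * e_o + (1 - theta[2]) * e_d)
    mu_s <- theta[3] * exp(-theta[4] * log_wl)
    r_mod <- if (is_lut) lut_lookup(model, mu_a, mu_s) else
      model(mu_a, mu_s)
    if (anyNA(r_mod)) return(1e10)
    sum((r_meas - r_mod)^2)
  }
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(inits))) {
    fit <- tryCatch(
      stats::optim(as.numeric(inits[i, ]), obj, method = "L-BFGS-B",
                   lower = as.numeric(lower), upper = as.numeric(upper),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, perfusion = NULL, rmse = NA_real_,
                          n_points = length(wl), converged = FALSE,
                          rejected = TRUE, reason = "optimizer failure",
                          meta = calibrated$meta),
                     class = "perfusion_estimate"))
  }
  theta <- best$par
  params <- optical_params(theta[1], theta[2], theta[3], theta[4])
  rmse <- sqrt(best$value / length(wl))
  rejected <- rmse > rmse_max
  structure(list(params = if (rejected) NULL else params,
                 perfusion = if (rejected) NULL else
                   derive_perfusion(params),
                 rmse = rmse,
                 n_points = length(wl),
                 converged = converged,
                 rejected = rejected,
                 reason = if (rejected) "poor fit" else "",
                 meta = calibrated$meta),
            class = "perfusion_estimate")
}

#' @export
print.perfusion_estimate <- function(x, ...) {
  if (x$rejected) {
    cat(sprintf("<perfusion_estimate: rejected (%s), rmse=%.4g>\n",
                x$reason, x$rmse))
  } else {
    cat(sprintf(
      "<perfusion_estimate: StO2=%.3f tHb=%.2f g/L a=%.1f b=%.2f rmse=%.2e>\n",
      x$params$StO2, x$params$tHb, x$params$a, x$params$b, x$rmse))
  }
  invisible(x)
}

#' Average calibrated replicate spectra
#'
#' Multiple spectra acquired at one tumor-visit are averaged pointwise
#' (after artifact rejection) before inversion, reducing noise without
#' biasing the lineshape.
#'
#' @param spectra List of calibrated `drs_spectrum` on a common grid.
#' @return Single `drs_spectrum`.
#' @export
average_spectra <- function(spectra) {
  assert_that(length(spectra) >= 1, "no spectra to average")
  wl <- spectra[[1]]$wavelengths
  mat <- vapply(spectra, function(s) {
    assert_that(isTRUE(all.equal(s$wavelengths, wl)),
                "spectra must share a wavelength grid")
    s$intensities
  }, numeric(length(wl)))
  m <- spectra[[1]]$meta
  m$n_averaged <- length(spectra)
  drs_spectrum(wl, rowMeans(as.matrix(mat)), m)
}
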