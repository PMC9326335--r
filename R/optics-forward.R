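#' Load the hemoglobin extinction table
#'
#' Reads a molar extinction table (wavelength_nm, eps_HbO2, eps_Hb in
#' L mol^-1 cm^-1). The packaged default is a synthetic smooth emulation of
#' oxy-/deoxyhemoglobin spectra (see `data-raw/hb_extinction.R`): it carries
#' the Q-band doublet, the single deoxy band and their isosbestic crossings,
#' which is what makes StO2 spectrally identifiable, but its magnitudes are
#' not measured values.
#'
#' @param path CSV path; default is the packaged synthetic table.
#' @return Data frame with class `extinction_table`.
#' @export
load_extinction <- function(path = system.file("extdata",
                                               "hb_extinction_synthetic.csv",
                                               package = "drstrend")) {
  ext <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "eps_HbO2", "eps_Hb") %in% names(ext)))
  assert_that(all(ext$eps_HbO2 > 0) && all(ext$eps_Hb > 0),
              "extinction coefficients must be positive")
  assert_that(all(diff(ext$wavelength_nm) > 0),
              "extinction wavelengths must be strictly increasing")
  class(ext) <- c("extinction_table", "data.frame")
  ext
}

#' Optical model parameters
#'
#' @param tHb Total hemoglobin, g/L (>= 0).
#' @param StO2 Oxygen saturation fraction in `[0, 1]`.
#' @param a Reduced scattering at the reference wavelength, cm^-1 (> 0).
#' @param b Scattering power (>= 0).
#' @return Named list of class `optical_params`.
#' @export
optical_params <- function(tHb, StO2, a, b) {
  assert_that(tHb >= 0, "tHb must be >= 0")
  assert_that(StO2 >= 0 && StO2 <= 1, "StO2 must lie in [0, 1]")
  assert_that(a > 0, "scattering amplitude a must be > 0")
  assert_that(b >= 0, "scattering power b must be >= 0")
  structure(list(tHb = tHb, StO2 = StO2, a = a, b = b),
            class = "optical_params")
}

#' Absorption coefficient of a hemoglobin mixture
#'
#' `mu_a(lambda) = ln(10) * (tHb / 64500) * [StO2 * eps_HbO2 + (1 - StO2)
#' * eps_Hb]` in cm^-1, with tHb in g/L and a hemoglobin molar mass of
#' 64,500 g/mol.
#'
#' @param params An [optical_params()].
#' @param wavelengths Wavelengths (nm) within the extinction table support.
#' @param ext An `extinction_table`.
#' @return mu_a values, cm^-1.
#' @export
mu_absorption <- function(params, wavelengths, ext) {
  rng <- range(ext$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    stop(sprintf("wavelength outside extinction-table support [%g, %g] nm",
                 rng[1], rng[2]))
  }
  e_o <- stats::approx(ext$wavelength_nm, ext$eps_HbO2, wavelengths)$y
  e_d <- stats::approx(ext$wavelength_nm, ext$eps_Hb, wavelengths)$y
  log(10) * (params$tHb / 64500) *
    (params$StO2 * e_o + (1 - params$StO2) * e_d)
}

#' Reduced scattering power law
#'
#' `mu_s'(lambda) = a * (lambda / lambda0)^(-b)` with lambda0 = 630 nm.
#'
#' @param params An [optical_params()].
#' @param wavelengths Wavelengths, nm.
#' @param lambda0 Reference wavelength, nm.
#' @return mu_s' values, cm^-1.
#' @export
mu_scattering <- function(params, wavelengths, lambda0 = 630) {
  params$a * (wavelengths / lambda0)^(-params$b)
}

#' Closed-form reflectance surrogate
#'
#' Analytic stand-in for a probe-specific reflectance lookup table:
#' `R(mu_a, mu_s') = (mu_s' / (mu_s' + k1 * mu_a)) * exp(-k2 * mu_a * d)`.
#' The albedo-like first factor captures the competition between
#' scattering-driven return and absorption, and the Beer-Lambert factor an
#' absorption attenuation over a fixed effective photon path `k2 * d`
#' (short source-detector separations constrain the path). The surface is
#' strictly decreasing in mu_a at fixed mu_s' and strictly increasing in
#' mu_s' at fixed mu_a — the behavior any physical diffuse-reflectance
#' forward model must have — and the absolute attenuation term makes the
#' overall (mu_a, mu_s') scale identifiable, not just their ratio. The
#' constants are fixed in configuration and the surrogate is pluggable
#' wherever a forward model is accepted.
#'
#' @param k1 Dimensionless absorption weight in the albedo term.
#' @param k2 Path-length multiplier.
#' @param d Effective path scale, cm (order of the source-detector
#'   separation).
#' @return A function `f(mu_a, mu_s')` vectorized over both arguments.
#' @export
reflectance_surrogate <- function(k1 = 1, k2 = 2, d = 0.029) {
  force(k1); force(k2); force(d)
  function(mu_a, mu_s) {
    (mu_s / (mu_s + k1 * mu_a)) * exp(-k2 * mu_a * d)
  }
}

#' Forward reflectance of a tissue parameter set
#'
#' Maps physiological/optical parameters to calibrated reflectance on a
#' wavelength grid: chromophore absorption from the extinction table, a
#' scattering power law, then the surrogate (or LUT) reflectance model.
#'
#' @param params An [optical_params()].
#' @param wavelengths Wavelengths, nm.
#' @param ext An `extinction_table`.
#' @param model Either a function `f(mu_a, mu_s)` such as
#'   [reflectance_surrogate()], or a LUT built by [build_lut()].
#' @return Reflectance values (dimensionless, calibrated scale).
#' @export
forward_reflectance <- function(params, wavelengths, ext,
                                model = reflectance_surrogate()) {
  mu_a <- mu_absorption(params, wavelengths, ext)
  mu_s <- mu_scattering(params, wavelengths)
  if (inherits(model, "reflectance_lut")) {
    lut_lookup(model, mu_a, mu_s)
  } else {
    model(mu_a, mu_s)
  }
}

#' Derived perfusion quantities
#'
#' HbO2 = StO2 * tHb and HbO = (1 - StO2) * tHb, so HbO2 + HbO = tHb by
#' construction.
#'
#' @param params An [optical_params()] (or any list with StO2 and tHb).
#' @return Named list StO2, tHb, HbO2, HbO.
#' @export
derive_perfusion <- function(params) {
  list(StO2 = params$StO2,
       tHb = params$tHb,
       HbO2 = params$StO2 * params$tHb,
       HbO = (1 - params$StO2) * params$tHb)
}
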