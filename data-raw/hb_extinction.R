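# Builds inst/extdata/hb_extinction_synthetic.csv.
#
# Synthetic smooth emulation of oxy-/deoxyhemoglobin molar extinction
# spectra over the visible fit range. Real tabulated extinction data are
# not redistributed here; these Gaussian-mixture curves reproduce the
# qualitative structure that drives spectral inversion: the red tail of the
# Soret band below ~470 nm, the HbO2 Q-band doublet near 542/577 nm, the
# single broad Hb band near 555 nm, isosbestic crossings between them, and
# the steep HbO2/Hb contrast above 600 nm. Units: L mol^-1 cm^-1.

wl <- seq(440, 660, by = 2)

gauss <- function(x, mu, sd, amp) amp * exp(-((x - mu) / sd)^2)

eps_hbo2 <- gauss(wl, 415, 32, 5e5) +
  gauss(wl, 542, 13, 38000) +
  gauss(wl, 577, 10, 36000) +
  gauss(wl, 650, 200, 350) + 50

eps_hb <- gauss(wl, 430, 34, 4.5e5) +
  gauss(wl, 555, 24, 42000) +
  gauss(wl, 650, 220, 3200) + 100

stopifnot(all(eps_hbo2 > 0), all(eps_hb > 0))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(
  data.frame(wavelength_nm = wl,
             eps_HbO2 = round(eps_hbo2, 1),
             eps_Hb = round(eps_hb, 1)),
  "inst/extdata/hb_extinction_synthetic.csv",
  row.names = FALSE
)
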