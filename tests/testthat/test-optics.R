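test_that("calibration has the 5% fixed point, zero point and linearity", {
  wl <- seq(450, 650, by = 5)
  dark <- drs_spectrum(wl, rep(100, length(wl)))
  ref <- drs_spectrum(wl, 5000 + 10 * (wl - 450))
  same <- calibrate_spectrum(ref, dark, ref)
  expect_equal(same$intensities, rep(0.05, length(wl)))

  dark_as_sample <- calibrate_spectrum(
    drs_spectrum(wl, rep(100, length(wl))), dark, ref)
  expect_equal(dark_as_sample$intensities, rep(0, length(wl)))

  s1 <- drs_spectrum(wl, 100 + 1000 * exp(-((wl - 550) / 40)^2))
  s2 <- drs_spectrum(wl, 100 + 2000 * exp(-((wl - 550) / 40)^2))
  c1 <- calibrate_spectrum(s1, dark, ref)
  c2 <- calibrate_spectrum(s2, dark, ref)
  expect_equal(c2$intensities, 2 * c1$intensities, tolerance = 1e-12)
})

test_that("calibration errors on nonpositive reference-dark denominator", {
  wl <- seq(450, 650, by = 5)
  dark <- drs_spectrum(wl, rep(100, length(wl)))
  bad_ref <- drs_spectrum(wl, ifelse(wl > 600, 50, 5000))
  expect_error(
    calibrate_spectrum(drs_spectrum(wl, rep(500, length(wl))), dark,
                       bad_ref),
    "calibration error.*nm")
})

test_that("absorption follows the chromophore mixture rules", {
  wl <- c(500, 550, 600)
  # pure oxyhemoglobin depends only on eps_HbO2
  p1 <- optical_params(5, 1, 10, 1)
  mu1 <- mu_absorption(p1, wl, ext_tab)
  e_o <- approx(ext_tab$wavelength_nm, ext_tab$eps_HbO2, wl)$y
  expect_equal(mu1, log(10) * (5 / 64500) * e_o, tolerance = 1e-12)

  # at an isosbestic wavelength mu_a is independent of StO2
  iso <- data.frame(wavelength_nm = c(400, 500, 700),
                    eps_HbO2 = c(100, 200, 300),
                    eps_Hb = c(100, 200, 300))
  class(iso) <- c("extinction_table", "data.frame")
  mus <- vapply(c(0, 0.3, 0.7, 1), function(s) {
    mu_absorption(optical_params(5, s, 10, 1), 500, iso)
  }, numeric(1))
  expect_equal(diff(range(mus)), 0, tolerance = 1e-15)

  # bloodless tissue absorbs nothing; reflectance is scattering-only
  p0 <- optical_params(0, 0.5, 10, 1)
  expect_equal(mu_absorption(p0, wl, ext_tab), rep(0, 3))
  r0 <- forward_reflectance(p0, wl, ext_tab, surrogate)
  expect_equal(r0, surrogate(0, mu_scattering(p0, wl)))

  expect_error(mu_absorption(p1, 2000, ext_tab), "support")
})

test_that("LUT reproduces nodes, bounds midpoints and tracks the surrogate", {
  lut <- build_lut(surrogate, n_mu_a = 40L, n_mu_s = 30L)
  # exact at nodes
  i <- 17L; j <- 12L
  expect_equal(lut_lookup(lut, exp(lut$log_mu_a[i]), lut$mu_s[j]),
               lut$R[i, j], tolerance = 1e-12)
  # midway lookups bounded by node values
  mid_a <- exp((lut$log_mu_a[i] + lut$log_mu_a[i + 1]) / 2)
  v <- lut_lookup(lut, mid_a, lut$mu_s[j])
  expect_true(v >= min(lut$R[i:(i + 1), j]) &&
                v <= max(lut$R[i:(i + 1), j]))
  # dense off-grid probe error below tolerance for the default grid
  lut_fine <- build_lut(surrogate)
  set.seed(42)
  qa <- exp(runif(500, log(0.02), log(40)))
  qs <- runif(500, 2, 45)
  err <- abs(lut_lookup(lut_fine, qa, qs) - surrogate(qa, qs))
  expect_lt(max(err), 5e-3)
  # monotone surrogate required
  expect_error(build_lut(function(a, s) a * 0 + s * 0 + 1),
               "decreasing|increasing")
})

test_that("LUT reflectance is monotone in mu_a and mu_s' on all nodes", {
  lut <- build_lut(surrogate)
  expect_true(all(apply(lut$R, 2, diff) < 0))
  expect_true(all(apply(lut$R, 1, diff) > 0))
})

test_that("artifact screening flags saturation and low signal", {
  sat <- clean_calibrated(5, 0.6)
  sat$meta$raw_max <- 65535
  dark_like <- drs_spectrum(wl_grid, rep(1e-4, length(wl_grid)),
                            list(raw_max = 500))
  clean <- clean_calibrated(5, 0.6)
  res <- reject_artifacts(list(sat, dark_like, clean))
  expect_equal(res$rejected$reason, c("saturation", "low signal"))
  expect_length(res$retained, 1L)

  # clean noise-free spectra are fully retained at default thresholds
  many <- lapply(seq(0.1, 0.9, by = 0.2), function(s)
    clean_calibrated(5, s))
  expect_length(reject_artifacts(many)$retained, length(many))
})

test_that("noise-free inversion recovers the generating parameters", {
  grid <- expand.grid(tHb = c(2, 8), StO2 = c(0.15, 0.55, 0.95),
                      a = c(8, 20), b = c(0.8, 1.6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    est <- invert_spectrum(clean_calibrated(g$tHb, g$StO2, g$a, g$b),
                           ext_tab, surrogate)
    expect_false(est$rejected)
    expect_lt(abs(est$params$StO2 - g$StO2), 0.01)
    expect_lt(abs(est$params$tHb - g$tHb) / g$tHb, 0.02)
  }
})

test_that("inversion handles the fully oxygenated boundary", {
  est <- invert_spectrum(clean_calibrated(5, 1), ext_tab, surrogate)
  expect_gt(est$params$StO2, 0.99)
})

test_that("inversion under 1% noise keeps median StO2 error within 0.05", {
  set.seed(101)
  errs <- replicate(50, {
    s <- clean_calibrated(5, 0.6)
    s$intensities <- s$intensities * rnorm(length(s$intensities), 1, 0.01)
    est <- invert_spectrum(s, ext_tab, surrogate)
    abs(est$params$StO2 - 0.6)
  })
  expect_lt(median(errs), 0.05)
})

test_that("derived perfusion conserves hemoglobin mass", {
  d <- derive_perfusion(optical_params(10, 0.6, 10, 1))
  expect_equal(d$HbO2, 6)
  expect_equal(d$HbO, 4)
  expect_equal(derive_perfusion(optical_params(7, 1, 10, 1))$HbO, 0)
  set.seed(8)
  for (k in 1:20) {
    p <- optical_params(runif(1, 0.1, 50), runif(1), runif(1, 1, 40),
                        runif(1, 0, 3))
    d <- derive_perfusion(p)
    expect_equal(d$HbO2 + d$HbO, d$tHb, tolerance = 1e-12)
  }
})

test_that("fold change normalizes per tumor and applies exclusion rules", {
  d <- data.frame(tumor_id = rep(c("t1", "t2", "t3"), each = 3),
                  week = rep(1:3, 3),
                  StO2 = c(10, 11, 12, 5, 5, 5, NA, 4, 4))
  d <- d[!is.na(d$StO2), ]
  fc <- fold_change(d, "StO2")
  expect_equal(fc$fold$value[fc$fold$tumor_id == "t1"], c(1.0, 1.1, 1.2))
  expect_equal(fc$fold$value[fc$fold$tumor_id == "t2"], c(1, 1, 1))
  expect_equal(fc$excluded$tumor_id, "t3")
  expect_equal(fc$excluded$reason, "baseline missing")
  expect_false("t3" %in% fc$fold$tumor_id)

  d2 <- data.frame(tumor_id = "t4", week = 1:2, StO2 = c(-1, 3))
  expect_equal(fold_change(d2, "StO2")$excluded$reason,
               "baseline non-positive")
})
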