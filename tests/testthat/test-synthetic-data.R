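test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n_per_group = c(A = 0)), "counts")
  expect_error(cohort_config(weeks = c(1, 1, 2)), "increasing")
  expect_error(cohort_config(missing_rate = 1.2), "rates")
})

test_that("null effects and zero subject spread give constant trajectories", {
  cfg <- cohort_config(seed = 5, subject_sd = 0)
  eff <- trend_templates()
  for (m in names(eff)) for (g in names(eff[[m]])) {
    eff[[m]][[g]] <- cbind(week = c(1, 6), level = c(1, 1))
  }
  tr <- simulate_trajectories(cfg, eff)
  expect_true(all(abs(tr$perfusion$sto2_fold - 1) < 1e-12))
  expect_true(all(abs(tr$perfusion$thb_fold - 1) < 1e-12))
  expect_true(all(abs(tr$expression$level - 1) < 1e-12))
})

test_that("group templates are reproduced exactly at their anchors", {
  cfg <- cohort_config(seed = 5, subject_sd = 0)
  tr <- simulate_trajectories(cfg)
  met4 <- tr$perfusion[tr$perfusion$group == "MET" &
                         tr$perfusion$week == 4, "sto2_fold"]
  expect_equal(mean(met4), 1.08, tolerance = 1e-12)
  mtd3 <- tr$perfusion[tr$perfusion$group == "MTD" &
                         tr$perfusion$week == 3, "sto2_fold"]
  expect_equal(mean(mtd3), 1.05, tolerance = 1e-12)
  vegf1 <- tr$expression[tr$expression$group == "MTD" &
                           tr$expression$week == 1 &
                           tr$expression$gene == "Vegf", "level"]
  expect_equal(mean(vegf1), 0.5, tolerance = 1e-12)
})

test_that("same config and seed reproduce identical outputs", {
  cfg <- cohort_config(seed = 11)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
  expect_identical(simulate_fold_changes(cfg), simulate_fold_changes(cfg))
  tr <- simulate_trajectories(cfg)
  s1 <- simulate_spectra(tr, cfg)
  s2 <- simulate_spectra(tr, cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$spectra[[5]]$intensities,
                   s2$spectra[[5]]$intensities)
})

test_that("unknown group labels are rejected", {
  cfg <- cohort_config(n_per_group = c(XX = 3))
  expect_error(simulate_trajectories(cfg), "unknown group")
  expect_error(simulate_fold_changes(cfg, trend_templates()$StO2),
               "unknown group")
})

test_that("artifact_rate = 1 corrupts every spectrum in ground truth", {
  cfg <- cohort_config(n_per_group = c(CG = 2, MET = 2, MTD = 2),
                       seed = 3, artifact_rate = 1, spectra_per_visit = 2)
  sim <- simulate_spectra(simulate_trajectories(cfg), cfg)
  expect_true(all(sim$truth$corrupted))
  expect_true(all(sim$truth$corruption %in%
                    c("saturation", "low signal", "baseline shift")))
})

test_that("artifact_rate = 0 leaves spectra clean and invertible shape", {
  cfg <- cohort_config(n_per_group = c(CG = 2), seed = 3,
                       artifact_rate = 0, noise_sd_reflectance = 0,
                       spectra_per_visit = 1)
  sim <- simulate_spectra(simulate_trajectories(cfg), cfg)
  expect_false(any(sim$truth$corrupted))
  # raw = ref_shape * R/0.05 + dark, so calibration must return R exactly
  cal <- calibrate_spectrum(sim$spectra[[1]], sim$dark, sim$reference)
  truth1 <- sim$truth[1, ]
  p <- optical_params(truth1$thb_true, truth1$sto2_true, truth1$a,
                      truth1$b)
  r_true <- forward_reflectance(p, cal$wavelengths, ext_tab, surrogate)
  expect_equal(cal$intensities, r_true, tolerance = 1e-10)
})

test_that("trajectory weeks outside the config are rejected", {
  cfg <- cohort_config(n_per_group = c(CG = 2), seed = 3)
  tr <- simulate_trajectories(cfg)
  tr$perfusion$week[1] <- 9
  expect_error(simulate_spectra(tr, cfg), "outside config weeks")
})

test_that("qPCR generator encodes expression in Ct and standard curves", {
  cfg <- cohort_config(n_per_group = c(CG = 3, MET = 3, MTD = 3),
                       seed = 9, ct_noise_sd = 0, subject_sd = 0)
  tr <- simulate_trajectories(cfg)
  sim <- simulate_qpcr(tr, cfg)

  # noise-free standard curve for E = 2 has slope -1/log10(2)
  gapdh <- sim$standard_curves[sim$standard_curves$gene == "Gapdh", ]
  slope <- unname(coef(lm(ct ~ log10(dilution), gapdh))[2])
  expect_equal(slope, -1 / log10(2), tolerance = 1e-9)

  # expression level 2 with E = 2 shifts Ct down by exactly 1 cycle
  tr2 <- tr
  tr2$expression$level <- ifelse(tr2$expression$gene == "Gapdh", 1, 2)
  sim2 <- simulate_qpcr(tr2, cfg, efficiencies = c(Vegf = 2, Hif1a = 2,
                                                   Gapdh = 2))
  v <- sim2$ct[sim2$ct$gene == "Vegf", ]
  g <- sim2$ct[sim2$ct$gene == "Gapdh", ]
  expect_equal(unique(round(g$ct1 - v$ct1, 9)), 1)

  # housekeeping Ct independent of group
  expect_equal(length(unique(round(g$ct1, 9))), 1L)

  # missing reference gene rejected
  tr3 <- tr
  tr3$expression <- tr3$expression[tr3$expression$gene != "Gapdh", ]
  expect_error(simulate_qpcr(tr3, cfg), "reference gene")
})

test_that("score and mask generators honor rates and fractions", {
  cfg <- cohort_config(n_per_group = c(CG = 4, MET = 4, MTD = 4),
                       seed = 2, missing_rate = 0)
  tr <- simulate_trajectories(cfg)
  sc <- simulate_scores(tr, cfg)
  expect_true(all(!is.na(sc$score)))
  expect_true(all(table(sc$tumor_id) == length(cfg$weeks)))
  expect_true(all(sc$score %in% seq(1, 5, by = 0.5)))

  masks <- simulate_masks(tr, cfg, size = 80L)
  expect_length(masks, 12L)
  mvd <- vapply(masks, compute_mvd, numeric(1))
  grp <- sub("_.*", "", names(mvd))
  # MTD masks are generated with a much lower positive fraction
  expect_lt(mean(mvd[grp == "MTD"]), mean(mvd[grp == "CG"]))
  expect_true(all(abs(mvd / 100 -
                        vapply(masks, attr, numeric(1),
                               "positive_fraction")) < 0.08))
})
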