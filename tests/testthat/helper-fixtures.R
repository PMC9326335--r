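# Shared fixtures, all generated in code.

ext_tab <- load_extinction()
surrogate <- reflectance_surrogate()
wl_grid <- seq(450, 650, by = 2)

# Noise-free forward spectrum already on the calibrated reflectance scale.
clean_calibrated <- function(tHb, StO2, a = 12, b = 1.3) {
  p <- optical_params(tHb, StO2, a, b)
  drs_spectrum(wl_grid, forward_reflectance(p, wl_grid, ext_tab, surrogate),
               list(role = "calibrated", raw_max = 30000))
}

# Two-arm cohort with identical flat truth (null scenario).
null_config <- function(seed = 1, n = 20, ...) {
  cohort_config(n_per_group = c(A = n, B = n), seed = seed,
                missing_rate = 0, ...)
}

flat_templates <- list(A = cbind(week = c(1, 6), level = c(1, 1)),
                       B = cbind(week = c(1, 6), level = c(1, 1)))

# Minimal Ct table: one calibrator stratum plus test samples.
make_ct_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r$sample_id, tumor_id = r$sample_id,
               group = r$group, week = r$week, gene = r$gene,
               ct1 = r$ct, ct2 = r$ct, ct3 = r$ct,
               ratio_260_280 = 1.9)
  }))
}
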