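#' Simulate qPCR Ct tables and standard curves for a cohort
#'
#' Converts true expression levels into triplicate Ct values under the
#' amplification model `Ct = Ct_cal - log_E(level) + noise`, where `E` is
#' the per-gene amplification efficiency and `Ct_cal` the calibrator-level
#' cycle threshold. The housekeeping gene's level is 1 for every sample, so
#' its Ct is independent of group by construction. Standard-curve dilution
#' series are emitted per gene with slope `-1/log10(E)` on the Ct vs
#' log10(dilution) scale. Biopsy visits follow `config$qpcr_weeks` (the
#' emulated study biopsied MET/CG at weeks 1, 4, 6 and MTD weekly).
#'
#' @param trajectories Output of [simulate_trajectories()] (uses
#'   `$expression`).
#' @param config A [cohort_config()].
#' @param efficiencies Named per-gene amplification efficiencies in
#'   `[1.6, 2.1]`; must include `reference_gene`.
#' @param reference_gene Housekeeping gene.
#' @param ct_cal Named per-gene calibrator Ct (cycles); single value
#'   recycled.
#' @param dilutions Standard-curve dilution series (fractions of neat).
#' @return List: `ct` data frame (sample_id, tumor_id, group, week, gene,
#'   ct1..ct3, ratio_260_280) and `standard_curves` data frame (gene,
#'   dilution, ct).
#' @export
simulate_qpcr <- function(trajectories, config,
                          efficiencies = c(Vegf = 1.95, Hif1a = 1.9,
                                           Gapdh = 2.0),
                          reference_gene = "Gapdh",
                          ct_cal = 22,
                          dilutions = 10^(0:-4)) {
  expr <- trajectories$expression
  genes <- unique(expr$gene)
  assert_that(reference_gene %in% genes,
              "reference gene missing from simulated expression")
  assert_that(all(genes %in% names(efficiencies)),
              "every simulated gene needs an efficiency")
  assert_that(all(efficiencies >= 1.6 & efficiencies <= 2.1),
              "efficiencies must lie in [1.6, 2.1]")
  if (length(ct_cal) == 1) {
    ct_cal <- stats::setNames(rep(ct_cal, length(genes)), genes)
  }

  with_seed(derive_seed(config$seed, "qpcr"), {
    keep <- mapply(function(g, w) w %in% (config$qpcr_weeks[[g]] %||%
                                            config$weeks),
                   expr$group, expr$week)
    expr <- expr[keep, , drop = FALSE]
    n <- nrow(expr)
    e_vec <- efficiencies[expr$gene]
    ct_true <- ct_cal[expr$gene] - log(expr$level) / log(e_vec)
    reps <- matrix(stats::rnorm(3 * n, 0, config$ct_noise_sd), ncol = 3)
    ct <- data.frame(
      sample_id = sprintf("%s_w%d", expr$tumor_id, as.integer(expr$week)),
      tumor_id = expr$tumor_id, group = expr$group, week = expr$week,
      gene = expr$gene,
      ct1 = ct_true + reps[, 1],
      ct2 = ct_true + reps[, 2],
      ct3 = ct_true + reps[, 3])
    # one RNA-quality draw per biopsy, shared across its genes
    samples <- unique(ct$sample_id)
    ratios <- stats::setNames(
      pmin(2.05, pmax(1.72, stats::rnorm(length(samples), 1.9, 0.05))),
      samples)
    ct$ratio_260_280 <- ratios[ct$sample_id]
    rownames(ct) <- NULL

    curves <- do.call(rbind, lapply(genes, function(g) {
      slope <- -1 / log10(efficiencies[[g]])
      data.frame(gene = g, dilution = dilutions,
                 ct = ct_cal[[g]] + slope * log10(dilutions) +
                   stats::rnorm(length(dilutions), 0,
                                config$ct_noise_sd / 4))
    }))
    rownames(curves) <- NULL
    list(ct = ct, standard_curves = curves)
  })
}
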