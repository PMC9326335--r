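#' RNA-quality filter on 260/280 absorbance ratios
#'
#' Retains samples whose 260/280 absorbance ratio lies in `[lo, hi]`
#' (inclusive at both ends), the conventional window for clean RNA.
#'
#' @param records Data frame with a `ratio_260_280` column.
#' @param lo,hi Inclusive bounds.
#' @return List: `retained` (data frame) and `excluded` (data frame with
#'   sample ids and their ratios).
#' @export
qc_filter <- function(records, lo = 1.8, hi = 2.0) {
  stopifnot("ratio_260_280" %in% names(records))
  ok <- records$ratio_260_280 >= lo & records$ratio_260_280 <= hi
  ok[is.na(ok)] <- FALSE
  list(retained = records[ok, , drop = FALSE],
       excluded = records[!ok, c(intersect("sample_id", names(records)),
                                 "ratio_260_280"), drop = FALSE])
}

#' Aggregate triplicate Ct values
#'
#' Technical triplicates are averaged; when the replicate range exceeds
#' `max_range` cycles, the single value farthest from the median is dropped
#' first and the record flagged.
#'
#' @param cts Numeric vector of 1-3 Ct values (NAs allowed).
#' @param max_range Maximum tolerated replicate range, cycles.
#' @return List: `ct` (mean), `flagged` (logical), `n_used`.
#' @export
aggregate_triplicates <- function(cts, max_range = 0.5) {
  cts <- cts[!is.na(cts)]
  if (length(cts) == 0) {
    return(list(ct = NA_real_, flagged = FALSE, n_used = 0L))
  }
  flagged <- FALSE
  if (length(cts) > 1 && diff(range(cts)) > max_range) {
    drop <- which.max(abs(cts - stats::median(cts)))
    cts <- cts[-drop]
    flagged <- TRUE
  }
  list(ct = mean(cts), flagged = flagged, n_used = length(cts))
}

#' Amplification efficiency from a standard curve
#'
#' Least-squares fit of Ct against log10(dilution); the efficiency is
#' `E = 10^(-1/slope)` (E = 2 for the ideal slope of -3.3219).
#'
#' @param log10_dilutions log10 of the dilution series (>= 3 points).
#' @param cts Measured Ct at each dilution.
#' @return List of class `qpcr_efficiency`: E, slope, intercept, r2.
#' @export
efficiency_from_standard_curve <- function(log10_dilutions, cts) {
  assert_that(length(log10_dilutions) >= 3,
              "standard curve needs at least 3 dilution points")
  assert_that(length(log10_dilutions) == length(cts),
              "dilutions and Cts must have equal length")
  fit <- stats::lm(cts ~ log10_dilutions)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("non-amplifying standard curve: slope >= 0")
  }
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((cts - mean(cts))^2)
  structure(list(E = 10^(-1 / slope), slope = slope,
                 intercept = unname(stats::coef(fit)[1]), r2 = r2),
            class = "qpcr_efficiency")
}

#' Efficiency-corrected relative expression ratio
#'
#' The Pfaffl ratio `E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = Ct_calibrator - Ct_sample` for each gene.
#'
#' @param e_target,e_ref Amplification efficiencies (> 1).
#' @param dct_target,dct_ref Calibrator-minus-sample Ct differences.
#' @return Relative expression ratio (> 0).
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  assert_that(all(e_target > 1) && all(e_ref > 1),
              "efficiencies must exceed 1")
  e_target^dct_target / e_ref^dct_ref
}

#' Relative expression for a cohort, normalized to control week 1
#'
#' Full relative-quantification pass: triplicates are aggregated per
#' sample-gene, the calibrator Ct for each gene is the mean aggregated Ct
#' of the control-group week-1 samples, and each sample's ratio is the
#' Pfaffl ratio of its target gene against the reference gene. The
#' calibrator group-week therefore maps to a mean relative expression of 1
#' for every gene by construction.
#'
#' @param records Ct data frame (sample_id, tumor_id, group, week, gene,
#'   ct1..ct3).
#' @param efficiencies Named per-gene efficiencies (> 1).
#' @param reference_gene Housekeeping gene.
#' @param calibrator_group,calibrator_week Calibrator stratum.
#' @param calibrator_stat Summary used for the calibrator Ct
#'   (mean by default).
#' @return Data frame (sample_id, tumor_id, group, week, gene,
#'   relative_expression, dct_target, dct_ref, flagged).
#' @export
normalize_expression <- function(records, efficiencies,
                                 reference_gene = "Gapdh",
                                 calibrator_group = "CG",
                                 calibrator_week = 1,
                                 calibrator_stat = mean) {
  need <- c("sample_id", "group", "week", "gene", "ct1")
  stopifnot(all(need %in% names(records)))
  genes <- unique(records$gene)
  assert_that(reference_gene %in% genes, "reference gene absent from data")
  assert_that(all(genes %in% names(efficiencies)),
              paste("missing efficiency for:",
                    paste(setdiff(genes, names(efficiencies)),
                          collapse = ", ")))

  ct_cols <- intersect(c("ct1", "ct2", "ct3"), names(records))
  agg <- records
  tri <- lapply(seq_len(nrow(agg)), function(i) {
    aggregate_triplicates(as.numeric(agg[i, ct_cols]))
  })
  agg$ct <- vapply(tri, `[[`, numeric(1), "ct")
  agg$flagged <- vapply(tri, `[[`, logical(1), "flagged")
  agg <- agg[!is.na(agg$ct), , drop = FALSE]

  cal <- agg[agg$group == calibrator_group & agg$week == calibrator_week, ]
  cal_ct <- tapply(cal$ct, cal$gene, calibrator_stat)
  missing_cal <- setdiff(genes, names(cal_ct))
  if (length(missing_cal)) {
    stop("no calibrator samples for gene(s): ",
         paste(missing_cal, collapse = ", "))
  }

  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- agg[, c("sample_id", setdiff(names(agg), "sample_id"))]
  tgt <- merge(tgt, ref, by = "sample_id")
  tgt$dct_target <- as.numeric(cal_ct[tgt$gene]) - tgt$ct
  tgt$dct_ref <- cal_ct[[reference_gene]] - tgt$ct_ref
  tgt$relative_expression <- as.numeric(pfaffl_ratio(
    unname(efficiencies[tgt$gene]), tgt$dct_target,
    efficiencies[[reference_gene]], tgt$dct_ref))

  keep <- intersect(c("sample_id", "tumor_id", "group", "week", "gene",
                      "relative_expression", "dct_target", "dct_ref",
                      "flagged"), names(tgt))
  out <- tgt[order(tgt$gene, tgt$sample_id), keep]
  rownames(out) <- NULL
  out
}
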