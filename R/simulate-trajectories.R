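#' Default group trend templates
#'
#' Piecewise-cubic (natural spline) interpolants through (week, level) anchor
#' points encode the group-level trends the generator emulates on the
#' fold-change scale: the control arm stays flat at baseline; the metronomic
#' arm's StO2 fold change peaks at 1.08 in week 4; the MTD arm's peaks at
#' 1.05 in week 3; MTD Vegf expression starts ~50% suppressed in week 1 and
#' recovers toward baseline.
#'
#' @param weeks Week domain over which templates are defined.
#' @return Nested list `templates[[metric]][[group]]`, each element a
#'   two-column matrix of (week, level) anchors.
#' @export
trend_templates <- function(weeks = 1:6) {
  lo <- min(weeks); hi <- max(weeks)
  flat <- cbind(week = c(lo, hi), level = c(1, 1))
  list(
    StO2 = list(
      CG  = flat,
      MET = cbind(week = c(1, 4, 6), level = c(1.00, 1.08, 1.02)),
      MTD = cbind(week = c(1, 3, 6), level = c(1.00, 1.05, 1.00))
    ),
    HbO2 = list(
      CG  = flat,
      MET = cbind(week = c(1, 4, 6), level = c(1.00, 1.15, 1.05)),
      MTD = cbind(week = c(1, 3, 6), level = c(1.00, 1.10, 1.00))
    ),
    tHb = list(
      CG  = flat,
      MET = cbind(week = c(1, 6), level = c(1.00, 1.13)),
      MTD = cbind(week = c(1, 6), level = c(1.00, 1.11))
    ),
    Vegf = list(
      CG  = flat,
      MET = cbind(week = c(1, 6), level = c(1.00, 0.90)),
      MTD = cbind(week = c(1, 4, 6), level = c(0.50, 0.80, 0.95))
    ),
    Hif1a = list(
      CG  = cbind(week = c(1, 4, 6), level = c(1.00, 0.85, 1.00)),
      MET = cbind(week = c(1, 4, 6), level = c(1.00, 1.15, 1.00)),
      MTD = cbind(week = c(1, 6), level = c(0.50, 1.00))
    ),
    Gapdh = list(CG = flat, MET = flat, MTD = flat)
  )
}

#' Evaluate a trend template at arbitrary weeks
#'
#' @param anchors Two-column (week, level) anchor matrix.
#' @param week Numeric weeks at which to evaluate.
#' @return Numeric template levels; exact at anchor weeks.
#' @export
template_value <- function(anchors, week) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2) return(rep(anchors[1, 2], length(week)))
  if (nrow(anchors) == 2) {
    return(stats::approx(anchors[, 1], anchors[, 2], xout = week,
                         rule = 2)$y)
  }
  stats::spline(anchors[, 1], anchors[, 2], xout = week,
                method = "natural")$y
}

#' Simulate per-tumor true trajectories
#'
#' Each tumor's true trajectory is its group's template evaluated at the
#' visit weeks plus a tumor-specific Gaussian offset (additive on the
#' fold-change scale). Fold-change trajectories are mapped to absolute
#' perfusion values via baseline StO2 and tHb, and expression templates give
#' per-gene true fold levels.
#'
#' @param config A [cohort_config()].
#' @param effects Trend templates as from [trend_templates()].
#' @param baseline_sto2 Baseline tissue oxygen saturation (fraction).
#' @param baseline_thb Baseline total hemoglobin (g/L).
#' @param genes Genes to simulate (must exist in `effects`).
#' @return List with data frames `perfusion` (tumor_id, group, week,
#'   sto2_fold, thb_fold, sto2_true, thb_true) and `expression`
#'   (tumor_id, group, week, gene, level).
#' @export
simulate_trajectories <- function(config,
                                  effects = trend_templates(config$weeks),
                                  baseline_sto2 = 0.55,
                                  baseline_thb = 5,
                                  genes = c("Vegf", "Hif1a", "Gapdh")) {
  stopifnot(inherits(config, "cohort_config"))
  bad <- setdiff(config$groups, names(effects$StO2))
  if (length(bad)) {
    stop("unknown group label(s) in config: ", paste(bad, collapse = ", "))
  }
  bad_g <- setdiff(genes, names(effects))
  if (length(bad_g)) {
    stop("no template for gene(s): ", paste(bad_g, collapse = ", "))
  }

  with_seed(derive_seed(config$seed, "trajectories"), {
    ids <- unlist(lapply(config$groups, function(g) {
      sprintf("%s_%02d", g, seq_len(config$n_per_group[[g]]))
    }))
    grp <- rep(config$groups, times = config$n_per_group[config$groups])
    offs <- stats::rnorm(length(ids), 0, config$subject_sd)

    wk <- config$weeks
    per <- do.call(rbind, lapply(seq_along(ids), function(i) {
      g <- grp[i]
      sto2_fold <- template_value(effects$StO2[[g]], wk) + offs[i]
      thb_fold <- template_value(effects$tHb[[g]], wk) + offs[i]
      data.frame(tumor_id = ids[i], group = g, week = wk,
                 sto2_fold = sto2_fold, thb_fold = thb_fold,
                 sto2_true = pmin(1, pmax(0, sto2_fold * baseline_sto2)),
                 thb_true = pmax(1e-6, thb_fold * baseline_thb))
    }))

    expr <- do.call(rbind, lapply(seq_along(ids), function(i) {
      g <- grp[i]
      do.call(rbind, lapply(genes, function(gene) {
        lvl <- template_value(effects[[gene]][[g]], wk) + offs[i]
        data.frame(tumor_id = ids[i], group = g, week = wk, gene = gene,
                   level = pmax(1e-6, lvl))
      }))
    }))
    rownames(per) <- rownames(expr) <- NULL
    list(perfusion = per, expression = expr)
  })
}

#' Simulate observed fold-change values directly
#'
#' Draws the tidy longitudinal table the trend models consume: per tumor,
#' group and week, observed value = group template + tumor offset +
#' Gaussian residual, with visits dropped completely at random at the
#' configured missing rate. This is the generator used for calibration
#' studies of the smoothing and band machinery, bypassing the spectral
#' forward/inverse path.
#'
#' @param config A [cohort_config()].
#' @param templates Named list (one anchor matrix per group) for a single
#'   metric, e.g. `trend_templates()$StO2`.
#' @param metric Name recorded in the output's `metric` column.
#' @return Data frame (tumor_id, group, week, value, metric).
#' @export
simulate_fold_changes <- function(config,
                                  templates = trend_templates(config$weeks)$StO2,
                                  metric = "StO2") {
  stopifnot(inherits(config, "cohort_config"))
  bad <- setdiff(config$groups, names(templates))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  with_seed(derive_seed(config$seed, paste0("fold_", metric)), {
    out <- do.call(rbind, lapply(config$groups, function(g) {
      n <- config$n_per_group[[g]]
      offs <- stats::rnorm(n, 0, config$subject_sd)
      truth <- template_value(templates[[g]], config$weeks)
      do.call(rbind, lapply(seq_len(n), function(i) {
        y <- truth + offs[i] +
          stats::rnorm(length(config$weeks), 0, config$noise_sd_value)
        keep <- stats::runif(length(config$weeks)) >= config$missing_rate
        data.frame(tumor_id = sprintf("%s_%02d", g, i), group = g,
                   week = config$weeks, value = y,
                   metric = metric)[keep, , drop = FALSE]
      }))
    }))
    rownames(out) <- NULL
    out
  })
}
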