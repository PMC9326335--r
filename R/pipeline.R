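#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates simulate -> calibrate/invert -> quantify -> fit -> compare
#' -> tally as a seeded, logged run. Every stage reads its inputs from and
#' writes its outputs to `out_dir` as plain CSV/JSON, so stages can be
#' toggled and re-run in isolation: disabling `optics` while a perfusion
#' table is already present leaves downstream results identical. A manifest
#' records per-stage seeds, outcomes and output file hashes.
#'
#' @param config A [cohort_config()]; its `seed` deterministically derives
#'   one seed per stage.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to execute, in order.
#' @param genes Gene panel for the qPCR arm.
#' @param metrics Perfusion metrics to model.
#' @param n_draws Posterior draws per difference band.
#' @param grid_size Week-grid size for curves and bands.
#' @param spec A [basis_spec()] for the trend models.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(),
                         out_dir = "results/pipeline",
                         stages = c("simulate", "optics", "qpcr", "fit",
                                    "compare", "cohort"),
                         genes = c("Vegf", "Hif1a", "Gapdh"),
                         metrics = c("StO2", "tHb", "HbO2", "HbO"),
                         n_draws = 10000L,
                         grid_size = 200L,
                         spec = basis_spec(domain = range(config$weeks)),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  t_all <- Sys.time()

  run_stage <- function(name, fun) {
    if (!name %in% stages) {
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    say(sprintf("[%s] starting", name))
    t0 <- Sys.time()
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     manifest$stages[[name]] <<- paste("failed:",
                                                       conditionMessage(e))
                     stop("stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    manifest$stages[[name]] <<- "ok"
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  path <- function(f) file.path(out_dir, f)
  ext <- load_extinction()
  model <- reflectance_surrogate()

  run_stage("simulate", function() {
    traj <- simulate_trajectories(config, genes = genes)
    sim_sp <- simulate_spectra(traj, config, ext, model)
    sim_q <- simulate_qpcr(traj, config,
                           efficiencies = stats::setNames(
                             rep(c(1.95, 1.9, 2.0),
                                 length.out = length(genes)), genes))
    scores <- simulate_scores(traj, config)
    masks <- simulate_masks(traj, config)

    utils::write.csv(traj$perfusion, path("truth_perfusion.csv"),
                     row.names = FALSE)
    utils::write.csv(traj$expression, path("truth_expression.csv"),
                     row.names = FALSE)
    utils::write.csv(sim_sp$truth, path("truth_spectra.csv"),
                     row.names = FALSE)
    saveRDS_text <- function(obj, f) {
      # spectra are bulky; store the long table as CSV
      utils::write.csv(obj, f, row.names = FALSE)
    }
    long <- do.call(rbind, lapply(sim_sp$spectra, function(s) {
      data.frame(tumor_id = s$meta$tumor_id, group = s$meta$group,
                 week = s$meta$week, replicate = s$meta$replicate,
                 wavelength_nm = s$wavelengths, intensity = s$intensities)
    }))
    saveRDS_text(long, path("spectra_raw.csv"))
    utils::write.csv(data.frame(wavelength_nm = sim_sp$dark$wavelengths,
                                intensity = sim_sp$dark$intensities),
                     path("dark.csv"), row.names = FALSE)
    utils::write.csv(data.frame(
      wavelength_nm = sim_sp$reference$wavelengths,
      intensity = sim_sp$reference$intensities),
      path("reference.csv"), row.names = FALSE)
    utils::write.csv(sim_q$ct, path("qpcr_ct.csv"), row.names = FALSE)
    utils::write.csv(sim_q$standard_curves, path("qpcr_standard_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, path("scores.csv"), row.names = FALSE)
    mvd_truth <- data.frame(
      tumor_id = names(masks),
      mvd = vapply(masks, compute_mvd, numeric(1)))
    dir.create(path("masks"), showWarnings = FALSE)
    for (id in names(masks)) {
      write_mask_png(masks[[id]], path(file.path("masks",
                                                 paste0(id, ".png"))))
    }
    utils::write.csv(mvd_truth, path("truth_mvd.csv"), row.names = FALSE)
  })

  run_stage("optics", function() {
    long <- utils::read.csv(path("spectra_raw.csv"))
    dark_df <- utils::read.csv(path("dark.csv"))
    ref_df <- utils::read.csv(path("reference.csv"))
    dark <- drs_spectrum(dark_df$wavelength_nm, dark_df$intensity,
                     list(role = "dark"))
    refs <- drs_spectrum(ref_df$wavelength_nm, ref_df$intensity,
                     list(role = "reference"))
    keys <- unique(long[, c("tumor_id", "group", "week")])
    rows <- vector("list", nrow(keys))
    for (i in seq_len(nrow(keys))) {
      sel <- long$tumor_id == keys$tumor_id[i] & long$week == keys$week[i]
      d <- long[sel, ]
      cal <- lapply(split(d, d$replicate), function(dd) {
        calibrate_spectrum(
          drs_spectrum(dd$wavelength_nm, dd$intensity,
                   list(tumor_id = keys$tumor_id[i],
                        group = keys$group[i], week = keys$week[i],
                        role = "sample")),
          dark, refs)
      })
      scr <- reject_artifacts(cal)
      if (!length(scr$retained)) {
        rows[[i]] <- data.frame(tumor_id = keys$tumor_id[i],
                                group = keys$group[i],
                                week = keys$week[i],
                                StO2 = NA, tHb = NA, HbO2 = NA, HbO = NA,
                                rmse = NA, rejected = TRUE,
                                reason = "all replicates rejected")
        next
      }
      est <- invert_spectrum(average_spectra(scr$retained), ext, model)
      rows[[i]] <- data.frame(
        tumor_id = keys$tumor_id[i], group = keys$group[i],
        week = keys$week[i],
        StO2 = if (est$rejected) NA else est$perfusion$StO2,
        tHb = if (est$rejected) NA else est$perfusion$tHb,
        HbO2 = if (est$rejected) NA else est$perfusion$HbO2,
        HbO = if (est$rejected) NA else est$perfusion$HbO,
        rmse = est$rmse, rejected = est$rejected, reason = est$reason)
    }
    perf <- do.call(rbind, rows)
    utils::write.csv(perf, path("perfusion.csv"), row.names = FALSE)

    fold_all <- do.call(rbind, lapply(metrics, function(m) {
      fc <- fold_change(perf[!perf$rejected & !is.na(perf[[m]]), ], m)
      if (nrow(fc$fold) == 0) return(NULL)
      fc$fold$metric <- m
      fc$fold
    }))
    utils::write.csv(fold_all, path("perfusion_fold.csv"),
                     row.names = FALSE)
  })

  run_stage("qpcr", function() {
    ct <- utils::read.csv(path("qpcr_ct.csv"))
    curves <- utils::read.csv(path("qpcr_standard_curves.csv"))
    qc <- qc_filter(ct)
    effs <- vapply(split(curves, curves$gene), function(d) {
      efficiency_from_standard_curve(log10(d$dilution), d$ct)$E
    }, numeric(1))
    expr <- normalize_expression(qc$retained, effs)
    utils::write.csv(expr, path("expression.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(effs), path("efficiencies.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  run_stage("fit", function() {
    fold <- utils::read.csv(path("perfusion_fold.csv"))
    expr <- utils::read.csv(path("expression.csv"))
    expr_t <- expr[expr$gene != "Gapdh", ]
    expr_t$value <- expr_t$relative_expression
    expr_t$metric <- expr_t$gene
    tidy <- rbind(fold[, c("tumor_id", "group", "week", "value", "metric")],
                  expr_t[, c("tumor_id", "group", "week", "value",
                             "metric")])
    curves <- list(); summaries <- list()
    for (m in unique(tidy$metric)) {
      d <- tidy[tidy$metric == m, ]
      fit <- fit_gam(build_design(d, spec))
      for (g in fit$design$groups) {
        cu <- predict_curve(fit, g, seq(spec$domain[1], spec$domain[2],
                                        length.out = grid_size))
        cu$group <- g; cu$metric <- m
        curves[[paste(m, g)]] <- cu
      }
      summaries[[m]] <- list(lambda = as.list(fit$lambda),
                             edf = as.list(fit$edf),
                             sigma2 = fit$sigma2, gcv = fit$gcv)
    }
    utils::write.csv(do.call(rbind, curves), path("curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summaries, path("fit_summaries.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  run_stage("compare", function() {
    fold <- utils::read.csv(path("perfusion_fold.csv"))
    expr <- utils::read.csv(path("expression.csv"))
    expr_t <- expr[expr$gene != "Gapdh", ]
    expr_t$value <- expr_t$relative_expression
    expr_t$metric <- expr_t$gene
    tidy <- rbind(fold[, c("tumor_id", "group", "week", "value", "metric")],
                  expr_t[, c("tumor_id", "group", "week", "value",
                             "metric")])
    bands <- list(); windows <- list()
    for (m in unique(tidy$metric)) {
      d <- tidy[tidy$metric == m, ]
      fit <- fit_gam(build_design(d, spec))
      gs <- fit$design$groups
      pairs <- utils::combn(gs, 2, simplify = FALSE)
      for (pr in pairs) {
        dd <- smooth_difference(fit, pr[1], pr[2],
                                seq(spec$domain[1], spec$domain[2],
                                    length.out = grid_size))
        band <- simultaneous_band(
          dd, fit, n_draws = n_draws,
          seed = derive_seed(config$seed,
                             paste("band", m, pr[1], pr[2])))
        win <- significant_windows(band)
        key <- paste(m, pr[1], pr[2], sep = "_")
        bands[[key]] <- data.frame(
          metric = m, pair = paste(pr, collapse = "-"),
          week = band$grid, diff = band$diff, se = band$se,
          lo = band$lo, hi = band$hi,
          significant = band$lo > 0 | band$hi < 0)
        windows[[key]] <- if (nrow(win)) cbind(metric = m,
                                               pair = paste(pr,
                                                            collapse = "-"),
                                               win) else NULL
      }
    }
    utils::write.csv(do.call(rbind, bands), path("difference_bands.csv"),
                     row.names = FALSE)
    win_all <- do.call(rbind, Filter(Negate(is.null), windows))
    jsonlite::write_json(win_all %||% list(), path("windows.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  run_stage("cohort", function() {
    scores <- utils::read.csv(path("scores.csv"))
    props <- score_proportions(scores)
    traj <- score_trajectories(scores)
    utils::write.csv(props, path("score_proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(traj, path("score_trajectories.csv"),
                     row.names = FALSE)
    mask_files <- list.files(path("masks"), full.names = TRUE,
                             pattern = "\\.png$")
    mvd <- data.frame(
      sample_id = sub("\\.png$", "", basename(mask_files)),
      mvd = vapply(mask_files, function(f) compute_mvd(read_mask_png(f)),
                   numeric(1)))
    mvd$group <- sub("_.*$", "", mvd$sample_id)
    cmp <- compare_mvd(mvd)
    utils::write.csv(mvd, path("mvd.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
           significant = cmp$significant, medians = as.list(cmp$medians)),
      path("mvd_test.json"), auto_unbox = TRUE, digits = NA)
  })

  files <- list.files(out_dir, pattern = "\\.(csv|json)$",
                      full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_all,
                                            units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render summary figures from a pipeline results directory
#'
#' Draws, for whatever outputs are present: per-metric trend panels with
#' pointwise ribbons, pairwise difference-band panels with significant
#' windows shaded, weekly score-proportion bars, and an MVD violin plot.
#' Missing inputs skip the corresponding figure with a message.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @param fig_dir Where to write figures (PDF).
#' @return Invisibly, the paths written.
#' @export
make_report <- function(out_dir, fig_dir = file.path(out_dir, "figures")) {
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  grab <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }

  curves <- grab("curves.csv")
  if (!is.null(curves)) {
    p <- ggplot2::ggplot(curves, ggplot2::aes(week, estimate,
                                              color = group,
                                              fill = group)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                           alpha = 0.2, color = NA) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = "week", y = "fitted trend") +
      ggplot2::theme_minimal()
    f <- file.path(fig_dir, "trends.pdf")
    ggplot2::ggsave(f, p, width = 9, height = 6)
    written <- c(written, f)
  } else message("curves.csv missing; skipping trend panels")

  bands <- grab("difference_bands.csv")
  if (!is.null(bands)) {
    p <- ggplot2::ggplot(bands, ggplot2::aes(week, diff)) +
      ggplot2::geom_rect(
        data = bands[bands$significant, , drop = FALSE],
        ggplot2::aes(xmin = week, xmax = week, ymin = -Inf, ymax = Inf),
        color = "purple", alpha = 0.1, linewidth = 0.3) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                           alpha = 0.3, fill = "goldenrod") +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                          color = "red") +
      ggplot2::facet_grid(metric ~ pair, scales = "free_y") +
      ggplot2::labs(x = "week", y = "difference of trends") +
      ggplot2::theme_minimal()
    f <- file.path(fig_dir, "difference_bands.pdf")
    ggplot2::ggsave(f, p, width = 9, height = 10)
    written <- c(written, f)
  } else message("difference_bands.csv missing; skipping band panels")

  props <- grab("score_proportions.csv")
  if (!is.null(props)) {
    props <- props[!is.na(props$proportion) & props$proportion > 0, ]
    p <- ggplot2::ggplot(props, ggplot2::aes(factor(week), proportion,
                                             fill = factor(score))) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(x = "week", y = "proportion of tumors",
                    fill = "score") +
      ggplot2::theme_minimal()
    f <- file.path(fig_dir, "score_proportions.pdf")
    ggplot2::ggsave(f, p, width = 9, height = 4)
    written <- c(written, f)
  } else message("score_proportions.csv missing; skipping score barplots")

  mvd <- grab("mvd.csv")
  if (!is.null(mvd)) {
    p <- ggplot2::ggplot(mvd, ggplot2::aes(group, mvd, fill = group)) +
      ggplot2::geom_violin(alpha = 0.6) +
      ggplot2::geom_jitter(width = 0.1, size = 0.6) +
      ggplot2::labs(x = NULL, y = "microvessel density (%)") +
      ggplot2::theme_minimal()
    f <- file.path(fig_dir, "mvd.pdf")
    ggplot2::ggsave(f, p, width = 5, height = 4)
    written <- c(written, f)
  } else message("mvd.csv missing; skipping MVD violin")

  invisible(written)
}
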