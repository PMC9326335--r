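#' Difference between two fitted group trends
#'
#' Evaluates `d(x) = f_A(x) - f_B(x)` on a week grid from a joint fit,
#' with the pointwise standard error from the Bayesian covariance. Group
#' intercepts are part of the difference by default, so the comparison is
#' between the full group trends rather than the centered smooths alone.
#'
#' @param fit A [fit_gam()] result containing both groups.
#' @param group_a,group_b Groups to contrast (A minus B).
#' @param grid Evaluation weeks (default 200 points across the domain).
#' @param include_parametric Include the group intercepts in the contrast.
#' @return List: grid, diff, se, L (contrast matrix), groups.
#' @export
smooth_difference <- function(fit, group_a, group_b, grid = NULL,
                              include_parametric = TRUE) {
  design <- fit$design
  if (is.null(grid)) {
    grid <- seq(design$spec$domain[1], design$spec$domain[2],
                length.out = 200)
  }
  L <- prediction_design(design, group_a, grid, include_parametric) -
    prediction_design(design, group_b, grid, include_parametric)
  d <- as.numeric(L %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((L %*% fit$V) * L)))
  list(grid = grid, diff = d, se = se, L = L,
       groups = c(group_a, group_b))
}

#' Simultaneous confidence band for a difference of smooths
#'
#' Builds a band that contains the entire true difference function at the
#' nominal level by posterior simulation of the model coefficients: draws
#' `beta* ~ N(beta_hat, V)`, computes the maximum over the grid of the
#' standardized deviation `|L (beta* - beta_hat)| / SE`, and takes the
#' empirical level-quantile of that maximum as the critical multiplier
#' `m*`. The band is `d_hat +/- m* SE`; because the maximum is taken over
#' the whole grid, `m*` is never below the pointwise normal quantile.
#'
#' @param diff A [smooth_difference()] result.
#' @param fit The [fit_gam()] result the difference came from.
#' @param level Simultaneous coverage level.
#' @param n_draws Number of posterior draws.
#' @param seed Integer seed for the draws.
#' @param se_floor Grid points with SE below this are masked out of the
#'   maximization (degenerate, e.g. a self-difference).
#' @return Object of class `difference_band`: grid, diff, se, lo, hi,
#'   crit (m*), level, n_draws, seed, groups.
#' @export
simultaneous_band <- function(diff, fit, level = 0.95, n_draws = 10000L,
                              seed = 1L, se_floor = 1e-12) {
  V <- fit$V
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("coefficient covariance is not positive semidefinite")
  }
  active <- diff$se > se_floor
  if (!any(active)) stop("all grid points have degenerate (zero) SE")

  crit <- with_seed(seed, {
    R <- chol(V + diag(1e-12 * max(diag(V)), nrow(V)))
    draws <- matrix(stats::rnorm(n_draws * nrow(V)), n_draws) %*% R
    # integrate out sigma^2: scale each draw by the posterior of the
    # residual variance (chi-square mixing -> multivariate t), so the
    # multiplier reflects scale uncertainty as well
    df <- fit$df_residual %||% Inf
    if (is.finite(df) && df > 0) {
      draws <- draws * sqrt(df / stats::rchisq(n_draws, df))
    }
    dev <- abs(draws %*% t(diff$L[active, , drop = FALSE]))
    dev <- sweep(dev, 2, diff$se[active], "/")
    maxdev <- apply(dev, 1, max)
    unname(stats::quantile(maxdev, level, type = 8))
  })

  structure(list(grid = diff$grid, diff = diff$diff, se = diff$se,
                 lo = diff$diff - crit * diff$se,
                 hi = diff$diff + crit * diff$se,
                 crit = crit, level = level, n_draws = n_draws,
                 seed = seed, groups = diff$groups, active = active),
            class = "difference_band")
}

#' @export
print.difference_band <- function(x, ...) {
  cat(sprintf(
    "<difference_band %s - %s: m*=%.3f, level=%.2f, %d grid points>\n",
    x$groups[1], x$groups[2], x$crit, x$level, length(x$grid)))
  invisible(x)
}

#' Time intervals where a difference band excludes zero
#'
#' Scans the band for contiguous runs where the lower band is above zero
#' (positive difference) or the upper band below zero (negative), and
#' converts run edges to week values by linear interpolation of the
#' band-zero crossing. Single-grid-cell excursions are flagged short.
#'
#' @param band A [simultaneous_band()] result.
#' @return Data frame (start, end, direction, short); zero rows when the
#'   band covers zero everywhere.
#' @export
significant_windows <- function(band) {
  g <- band$grid
  sig_pos <- band$lo > 0
  sig_neg <- band$hi < 0

  runs_of <- function(sig, bound, direction) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (i in which(r$values)) {
      s <- starts[i]; e <- ends[i]
      # interpolate the zero crossing of the bounding curve at each edge
      start_w <- if (s == 1L) g[1] else {
        x0 <- g[s - 1L]; x1 <- g[s]
        y0 <- bound[s - 1L]; y1 <- bound[s]
        x0 + (0 - y0) / (y1 - y0) * (x1 - x0)
      }
      end_w <- if (e == length(g)) g[length(g)] else {
        x0 <- g[e]; x1 <- g[e + 1L]
        y0 <- bound[e]; y1 <- bound[e + 1L]
        x0 + (0 - y0) / (y1 - y0) * (x1 - x0)
      }
      out[[length(out) + 1L]] <- data.frame(
        start = start_w, end = end_w, direction = direction,
        short = e - s < 1L)
    }
    out
  }

  res <- c(runs_of(sig_pos, band$lo, "positive"),
           runs_of(sig_neg, band$hi, "negative"))
  if (!length(res)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0), short = logical(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average across-the-function pointwise coverage of the trend interval
#'
#' Simulates single-group cohorts from a known smooth trajectory, fits the
#' penalized-spline model, and records the fraction of grid points at
#' which the level-`level` pointwise interval contains the true function,
#' averaged over replicates. This is the empirical counterpart of the
#' across-the-function coverage property of Bayesian smoothing intervals.
#'
#' @param config A [cohort_config()] with a single group.
#' @param template Anchor matrix for the group's true trajectory.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param grid_size Evaluation grid size.
#' @param level Interval level.
#' @param spec A [basis_spec()].
#' @return List: coverage (mean fraction of grid covered), se (SD of the
#'   per-replicate fractions / sqrt(n_reps)), n_reps.
#' @export
pointwise_coverage_simulation <- function(config, template,
                                          n_reps = 100L, seed = 1L,
                                          grid_size = 200L, level = 0.95,
                                          spec = basis_spec(
                                            domain = range(config$weeks))) {
  assert_that(length(config$groups) == 1,
              "pointwise coverage simulation uses a single group")
  g <- config$groups[1]
  grid <- seq(spec$domain[1], spec$domain[2], length.out = grid_size)
  truth <- template_value(template, grid)
  fracs <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("pw", r))
    dat <- simulate_fold_changes(cfg, stats::setNames(list(template), g))
    fit <- fit_gam(build_design(dat, spec))
    cu <- predict_curve(fit, g, grid, level = level)
    mean(cu$lo <= truth & truth <= cu$hi)
  }, numeric(1))
  list(coverage = mean(fracs),
       se = stats::sd(fracs) / sqrt(n_reps),
       n_reps = n_reps)
}

#' Coverage / detection simulation for the band machinery
#'
#' Repeats simulate -> fit -> band under a declared truth and scores the
#' band against it: under a null scenario (both groups share a template)
#' the statistic is whole-function coverage of the zero difference; under
#' an effect scenario it is the fraction of replicates whose significant
#' windows overlap a target week.
#'
#' @param config A [cohort_config()] describing one replicate's cohort
#'   (its `groups` must name exactly two groups for the difference).
#' @param templates Per-group anchor matrices (one metric), as in
#'   [trend_templates()].
#' @param n_reps Number of replicates.
#' @param seed Integer seed; replicate r uses a seed derived from it.
#' @param n_draws Posterior draws per band.
#' @param grid_size Evaluation grid size.
#' @param target_week For detection scenarios: a window counts as a
#'   detection when it overlaps `target_week +/- target_halfwidth`.
#' @param target_halfwidth Half-width of the detection target, weeks.
#' @param level Band level.
#' @param spec A [basis_spec()].
#' @return List: coverage (fraction of replicates whose band covers the
#'   true difference everywhere), detection (fraction with a window
#'   overlapping the target), binomial SEs, n_reps.
#' @export
coverage_simulation <- function(config, templates, n_reps = 100L,
                                seed = 1L, n_draws = 2000L,
                                grid_size = 200L,
                                target_week = 4, target_halfwidth = 0.5,
                                level = 0.95,
                                spec = basis_spec(
                                  domain = range(config$weeks))) {
  gpair <- config$groups
  assert_that(length(gpair) == 2, "coverage simulation needs two groups")
  grid <- seq(spec$domain[1], spec$domain[2], length.out = grid_size)
  true_d <- template_value(templates[[gpair[1]]], grid) -
    template_value(templates[[gpair[2]]], grid)

  covered <- logical(n_reps)
  detected <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("rep", r))
    dat <- simulate_fold_changes(cfg, templates)
    fit <- fit_gam(build_design(dat, spec))
    d <- smooth_difference(fit, gpair[1], gpair[2], grid)
    band <- simultaneous_band(d, fit, level = level, n_draws = n_draws,
                              seed = derive_seed(cfg$seed, "band"))
    covered[r] <- all(band$lo <= true_d & true_d <= band$hi)
    win <- significant_windows(band)
    detected[r] <- nrow(win) > 0 &&
      any(win$start <= target_week + target_halfwidth &
            win$end >= target_week - target_halfwidth)
  }
  cov <- mean(covered); det <- mean(detected)
  list(coverage = cov, detection = det,
       coverage_se = sqrt(cov * (1 - cov) / n_reps),
       detection_se = sqrt(det * (1 - det) / n_reps),
       n_reps = n_reps)
}
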