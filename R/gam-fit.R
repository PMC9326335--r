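#' Fit the penalized-spline model
#'
#' Minimizes `||y - X beta||^2 + sum_g lambda_g beta' S_g beta` with one
#' smoothing parameter per group smooth. Smoothing parameters are selected
#' by restricted maximum likelihood (REML) by default — the selector with
#' the most stable smoothing-parameter estimates and interval calibration —
#' or by generalized cross-validation,
#' `GCV = n * RSS / (n - tr(A))^2` with `A` the influence matrix. Either
#' criterion is minimized by coordinate descent over a log-spaced grid
#' with golden-section refinement of each coordinate.
#' The returned covariance is the Bayesian posterior covariance of the
#' penalized fit, `V = sigma^2 (X'X + sum lambda_g S_g)^{-1}`, whose
#' intervals have the usual across-the-function coverage interpretation.
#'
#' @param design A [build_design()] object.
#' @param y Response vector; defaults to the one captured in the design.
#' @param method `"REML"` (default) or `"GCV"` to select smoothing
#'   parameters, `"fixed"` to use `lambda` as given.
#' @param lambda Optional fixed smoothing parameters (named by group or
#'   recycled).
#' @param lambda_range Search range for the selector, log-spaced.
#' @param n_grid Grid size per coordinate sweep.
#' @param tol Convergence tolerance on the criterion between sweeps.
#' @return Object of class `smooth_fit`: beta, V, lambda, edf (per group),
#'   sigma2, gcv, fitted, residuals, design.
#' @export
fit_gam <- function(design, y = design$y,
                    method = c("REML", "GCV", "fixed"),
                    lambda = NULL,
                    lambda_range = c(1e-4, 1e6),
                    n_grid = 40L, tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(design, "gam_design"), length(y) == design$n)
  assert_that(all(is.finite(y)), "responses must be finite")
  X <- design$X
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  n <- design$n
  G <- length(design$groups)
  # penalty ranks and pseudo-determinants for the REML criterion
  pen_rank <- vapply(design$penalty_sqrts, function(C) qr(C)$rank,
                     integer(1))
  pen_logdet <- vapply(seq_len(G), function(j) {
    ev <- eigen(design$penalties[[j]], symmetric = TRUE,
                only.values = TRUE)$values
    sum(log(ev[seq_len(pen_rank[j])]))
  }, numeric(1))
  null_dim <- design$p - sum(pen_rank)

  solve_lambda <- function(lam) {
    # QR of the penalty-augmented matrix: A = X'X + sum lambda_g S_g = R'R
    aug <- do.call(rbind, c(list(X), lapply(seq_len(G), function(j) {
      sqrt(lam[j]) * design$penalty_sqrts[[j]]
    })))
    R <- qr.R(qr(aug))
    if (any(abs(diag(R)) < 1e-12 * max(abs(diag(R))))) return(NULL)
    Ainv <- chol2inv(R)
    beta <- Ainv %*% Xty
    fitted <- as.numeric(X %*% beta)
    rss <- sum((y - fitted)^2)
    hat_diag <- rowSums(Ainv * XtX)   # diag(Ainv %*% XtX)
    tr_a <- sum(hat_diag)
    gcv <- n * rss / (n - tr_a)^2
    pen <- sum(vapply(seq_len(G), function(j) {
      lam[j] * sum((design$penalty_sqrts[[j]] %*% beta)^2)
    }, numeric(1)))
    # -2 * restricted log-likelihood, profiled over sigma^2, up to consts
    sig2_r <- (rss + pen) / (n - null_dim)
    reml <- (n - null_dim) * log(sig2_r) + 2 * sum(log(abs(diag(R)))) -
      sum(pen_rank * log(lam)) - sum(pen_logdet)
    list(beta = as.numeric(beta), Ainv = Ainv, fitted = fitted,
         rss = rss, tr_a = tr_a, gcv = gcv, reml = reml,
         hat_diag = hat_diag)
  }

  if (method == "fixed") {
    assert_that(!is.null(lambda), "method 'fixed' requires lambda")
    lam <- rep_len(as.numeric(lambda), G)
  } else {
    crit_name <- if (method == "REML") "reml" else "gcv"
    grid <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                    length.out = n_grid))
    lam <- rep(1, G)
    gcv_at <- function(lv) {
      s <- solve_lambda(lv)
      if (is.null(s)) Inf else s[[crit_name]]
    }
    prev <- Inf
    for (sweep in seq_len(10L)) {
      for (j in seq_len(G)) {
        vals <- vapply(grid, function(l) {
          lv <- lam; lv[j] <- l; gcv_at(lv)
        }, numeric(1))
        i_best <- which.min(vals)
        # golden-section refinement between the neighbors of the grid optimum
        lo <- log(grid[max(1L, i_best - 1L)])
        hi <- log(grid[min(n_grid, i_best + 1L)])
        gr <- (sqrt(5) - 1) / 2
        x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
        f1 <- gcv_at(`[<-`(lam, j, exp(x1)))
        f2 <- gcv_at(`[<-`(lam, j, exp(x2)))
        for (it in seq_len(40L)) {
          if (hi - lo < 1e-4) break
          if (f1 < f2) {
            hi <- x2; x2 <- x1; f2 <- f1
            x1 <- hi - gr * (hi - lo)
            f1 <- gcv_at(`[<-`(lam, j, exp(x1)))
          } else {
            lo <- x1; x1 <- x2; f1 <- f2
            x2 <- lo + gr * (hi - lo)
            f2 <- gcv_at(`[<-`(lam, j, exp(x2)))
          }
        }
        lam[j] <- exp(if (f1 < f2) x1 else x2)
      }
      cur <- gcv_at(lam)
      if (abs(prev - cur) < tol) break
      prev <- cur
    }
    if (sweep == 10L && abs(prev - cur) >= tol) {
      warning("GCV coordinate descent did not converge; using last iterate")
    }
  }

  sol <- solve_lambda(lam)
  if (is.null(sol)) stop("singular penalized system")
  df_resid <- n - sol$tr_a
  sigma2 <- if (df_resid > 0) sol$rss / df_resid else NA_real_
  V <- sigma2 * sol$Ainv

  if (method != "fixed") {
    # propagate smoothing-parameter uncertainty into the coefficient
    # covariance: V += J Omega J', with J = d beta / d log(lambda) and
    # Omega the inverse curvature of the selection criterion at its
    # optimum (coefficients conditioned on a data-selected lambda are
    # otherwise treated as if lambda were known)
    h <- 0.5
    rho <- log(lam)
    crit_of <- function(r) {
      s <- solve_lambda(exp(r))
      if (is.null(s)) Inf else s[[crit_name]]
    }
    beta_of <- function(r) {
      s <- solve_lambda(exp(r))
      if (is.null(s)) sol$beta else s$beta
    }
    J <- matrix(0, design$p, G)
    H <- matrix(0, G, G)
    f0 <- sol[[crit_name]]
    for (g in seq_len(G)) {
      rp <- rho; rp[g] <- rho[g] + h
      rm <- rho; rm[g] <- rho[g] - h
      J[, g] <- (beta_of(rp) - beta_of(rm)) / (2 * h)
      H[g, g] <- (crit_of(rp) + crit_of(rm) - 2 * f0) / h^2
    }
    if (G > 1) {
      for (g in seq_len(G - 1)) for (j in (g + 1):G) {
        rpp <- rho; rpp[c(g, j)] <- rpp[c(g, j)] + h
        rpm <- rho; rpm[g] <- rpm[g] + h; rpm[j] <- rpm[j] - h
        rmp <- rho; rmp[g] <- rmp[g] - h; rmp[j] <- rmp[j] + h
        rmm <- rho; rmm[c(g, j)] <- rmm[c(g, j)] - h
        H[g, j] <- H[j, g] <-
          (crit_of(rpp) - crit_of(rpm) - crit_of(rmp) + crit_of(rmm)) /
          (4 * h^2)
      }
    }
    eh <- eigen(H / 2, symmetric = TRUE)  # criterion is -2 log-lik scale
    pos <- eh$values > 1e-8
    if (any(pos)) {
      omega <- eh$vectors[, pos, drop = FALSE] %*%
        (t(eh$vectors[, pos, drop = FALSE]) / eh$values[pos])
      V <- V + J %*% omega %*% t(J)
    }
  }
  edf <- vapply(design$groups, function(g) {
    sum(sol$hat_diag[design$col_map[[g]]$smooth])
  }, numeric(1))

  structure(list(beta = sol$beta, V = V,
                 lambda = stats::setNames(lam, design$groups),
                 edf = edf, sigma2 = sigma2, gcv = sol$gcv,
                 fitted = sol$fitted, residuals = y - sol$fitted,
                 tr_a = sol$tr_a, df_residual = df_resid,
                 design = design),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("Penalized-spline group-trend fit\n")
  cat("  groups:", paste(x$design$groups, collapse = ", "), "\n")
  cat("  lambda:", paste(sprintf("%s=%.3g", names(x$lambda), x$lambda),
                         collapse = ", "), "\n")
  cat("  smooth EDF:", paste(sprintf("%.2f", x$edf), collapse = ", "),
      " sigma^2:", sprintf("%.4g", x$sigma2), "\n")
  invisible(x)
}

#' Fitted trend curve with pointwise interval for one group
#'
#' Evaluates the group's intercept-plus-smooth on a week grid with
#' pointwise standard errors from the Bayesian covariance and a normal
#' pointwise confidence interval.
#'
#' @param fit A [fit_gam()] result.
#' @param group Group label.
#' @param grid Evaluation weeks (default 200 points across the domain).
#' @param level Interval level.
#' @return Data frame (week, estimate, se, lo, hi) of class
#'   `curve_estimate`.
#' @export
predict_curve <- function(fit, group, grid = NULL, level = 0.95) {
  design <- fit$design
  if (is.null(grid)) {
    grid <- seq(design$spec$domain[1], design$spec$domain[2],
                length.out = 200)
  }
  L <- prediction_design(design, group, grid)
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((L %*% fit$V) * L)))
  z <- stats::qnorm((1 + level) / 2)
  out <- data.frame(week = grid, estimate = est, se = se,
                    lo = est - z * se, hi = est + z * se)
  class(out) <- c("curve_estimate", "data.frame")
  attr(out, "group") <- group
  attr(out, "level") <- level
  out
}
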