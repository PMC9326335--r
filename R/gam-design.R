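#' Basis specification for per-group penalized smooths
#'
#' @param k Basis dimension per smooth (cubic B-splines).
#' @param penalty_order Order of the difference penalty on spline
#'   coefficients (2 penalizes curvature, leaving straight lines
#'   unpenalized).
#' @param domain Week domain covered by the basis.
#' @return Object of class `basis_spec`.
#' @export
basis_spec <- function(k = 6L, penalty_order = 2L, domain = c(1, 6)) {
  assert_that(k >= 3, "basis dimension k must be >= 3")
  assert_that(penalty_order >= 1 && penalty_order < k,
              "penalty order must be in [1, k)")
  structure(list(k = as.integer(k), penalty_order = as.integer(penalty_order),
                 domain = as.numeric(domain)),
            class = "basis_spec")
}

# Equally spaced (P-spline) knot sequence for k B-splines of order
# min(4, k) covering the domain. Uniform spacing — extending beyond the
# boundaries rather than stacking boundary knots — is what makes the
# second-order coefficient-difference penalty annihilate exactly the
# straight lines in week.
spline_knots <- function(spec) {
  ord <- min(4L, spec$k)
  h <- diff(spec$domain) / (spec$k - ord + 1L)
  list(knots = seq(spec$domain[1] - (ord - 1L) * h,
                   spec$domain[2] + (ord - 1L) * h, by = h),
       ord = ord)
}

# Raw (uncentered) basis matrix at x.
raw_basis <- function(spec, x) {
  kn <- spline_knots(spec)
  if (any(x < spec$domain[1] | x > spec$domain[2])) {
    stop("prediction outside the week domain [",
         spec$domain[1], ", ", spec$domain[2], "]")
  }
  splines::splineDesign(kn$knots, x, ord = kn$ord, outer.ok = TRUE)
}

#' Build the treatment-by-time interaction design
#'
#' Constructs the model matrix for one smooth trend per group plus one
#' intercept per group: columns are group indicators followed, per group,
#' by a centered B-spline basis (the sum-to-zero constraint over that
#' group's observed weeks is absorbed by reparameterization, so each
#' group's smooth is identifiable next to its intercept). Each smooth
#' carries a block second-order difference penalty with its own smoothing
#' parameter; straight-line trends lie in the penalty null space and are
#' never shrunk.
#'
#' @param data Data frame with columns week, group, and the response name
#'   given in `response`.
#' @param spec A [basis_spec()].
#' @param response Response column name.
#' @return Object of class `gam_design`: X, y, per-group penalty matrices
#'   (embedded at their blocks), column maps, constraint transforms, spec.
#' @export
build_design <- function(data, spec = basis_spec(), response = "value") {
  stopifnot(all(c("week", "group", response) %in% names(data)))
  groups <- unique(as.character(data$group))
  n_weeks <- length(unique(data$week))
  if (spec$k > n_weeks + 2L) {
    stop(sprintf(
      "basis dimension k=%d exceeds the identifiable dimension for %d distinct weeks; reduce k to at most %d",
      spec$k, n_weeks, n_weeks + 2L))
  }
  for (g in groups) {
    if (length(unique(data$week[data$group == g])) < 2) {
      stop("group ", g, " has fewer than 2 distinct weeks")
    }
  }

  n <- nrow(data)
  k <- spec$k
  p <- length(groups) * (1L + (k - 1L))
  X <- matrix(0, n, p)
  col_map <- list()
  Z_list <- list()
  penalties <- list()
  penalty_sqrts <- list()

  D <- diff(diag(k), differences = spec$penalty_order)
  S_raw <- crossprod(D)

  col <- 0L
  for (g in groups) {
    rows <- which(as.character(data$group) == g)
    B <- raw_basis(spec, data$week[rows])
    cons <- colSums(B)
    Z <- qr.Q(qr(matrix(cons, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
    BZ <- B %*% Z

    icol <- col + 1L
    scol <- (col + 2L):(col + 1L + ncol(Z))
    X[rows, icol] <- 1
    X[rows, scol] <- BZ

    S <- matrix(0, p, p)
    S[scol, scol] <- t(Z) %*% S_raw %*% Z
    penalties[[g]] <- S
    # penalty square root (S = C'C) for numerically stable augmented fits
    Csr <- matrix(0, nrow(D), p)
    Csr[, scol] <- D %*% Z
    penalty_sqrts[[g]] <- Csr
    Z_list[[g]] <- Z
    col_map[[g]] <- list(intercept = icol, smooth = scol)
    col <- col + 1L + ncol(Z)
  }

  structure(list(X = X, y = data[[response]], groups = groups,
                 col_map = col_map, Z = Z_list, penalties = penalties,
                 penalty_sqrts = penalty_sqrts,
                 spec = spec, n = n, p = p),
            class = "gam_design")
}

# Prediction rows for one group on a week grid (same layout as X).
prediction_design <- function(design, group, grid,
                              include_parametric = TRUE) {
  if (!group %in% design$groups) {
    stop("unknown group: ", group)
  }
  B <- raw_basis(design$spec, grid)
  L <- matrix(0, length(grid), design$p)
  cm <- design$col_map[[group]]
  if (include_parametric) L[, cm$intercept] <- 1
  L[, cm$smooth] <- B %*% design$Z[[group]]
  L
}
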