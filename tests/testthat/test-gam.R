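make_two_group_data <- function(n = 12, seed = 1, f_a = function(w) 0 * w,
                                f_b = function(w) 0 * w, sd = 0.1) {
  set.seed(seed)
  do.call(rbind, lapply(c("A", "B"), function(g) {
    f <- if (g == "A") f_a else f_b
    do.call(rbind, lapply(seq_len(n), function(i) {
      w <- 1:6
      data.frame(tumor_id = paste0(g, i), group = g, week = w,
                 value = f(w) + rnorm(6, 0, sd))
    }))
  }))
}

test_that("design has correct shape, centered bases and linear null space", {
  d <- make_two_group_data(n = 5)
  des <- build_design(d, basis_spec(k = 6, domain = c(1, 6)))
  expect_equal(nrow(des$X), nrow(d))
  expect_equal(des$p, 2 * 6)

  # each group's smooth columns sum to zero over that group's rows
  for (g in des$groups) {
    rows <- which(d$group == g)
    cs <- colSums(des$X[rows, des$col_map[[g]]$smooth, drop = FALSE])
    expect_equal(max(abs(cs)), 0, tolerance = 1e-9)
  }

  # rank agrees with an independent dense construction via base splines
  B <- splines::bs(d$week, df = 6, degree = 3, intercept = TRUE)
  dense <- cbind(model.matrix(~ 0 + group, d),
                 model.matrix(~ 0 + group, d)[, 1] * B[, -1],
                 model.matrix(~ 0 + group, d)[, 2] * B[, -1])
  expect_equal(qr(des$X)$rank, qr(dense)$rank)

  # second-difference penalty annihilates straight lines:
  # a linear-in-week fit must have zero penalty through the smooth blocks
  fit <- fit_gam(des, y = 2 + 0.5 * d$week, method = "fixed", lambda = 1)
  for (g in des$groups) {
    S <- des$penalties[[g]]
    expect_equal(as.numeric(t(fit$beta) %*% S %*% fit$beta), 0,
                 tolerance = 1e-9)
  }
})

test_that("k above the identifiable dimension errors with a suggestion", {
  d <- make_two_group_data(n = 4)
  expect_error(build_design(d, basis_spec(k = 9, domain = c(1, 6))),
               "reduce k")
  d2 <- d[d$week == 1, ]
  expect_error(build_design(d2, basis_spec(k = 3, domain = c(1, 6))),
               "fewer than 2 distinct weeks")
})

test_that("exactly linear data are reproduced with ~0 residuals", {
  d <- make_two_group_data(n = 6, sd = 0)
  d$value <- ifelse(d$group == "A", 1 + 0.2 * d$week, 2 - 0.1 * d$week)
  for (lam in c(1e-3, 1, 1e5)) {
    fit <- fit_gam(build_design(d, basis_spec(domain = c(1, 6))),
                   method = "fixed", lambda = lam)
    expect_lt(max(abs(fit$residuals)), 1e-7)
  }
})

test_that("the large-lambda limit equals per-group OLS lines", {
  d <- make_two_group_data(n = 8, seed = 42,
                           f_a = function(w) 1 + 0.1 * w + 0.05 * w^2,
                           f_b = function(w) 2 - 0.2 * w, sd = 0.15)
  des <- build_design(d, basis_spec(domain = c(1, 6)))
  fit <- fit_gam(des, method = "fixed", lambda = 1e12)
  for (g in c("A", "B")) {
    sel <- d$group == g
    ols <- lm(value ~ week, d[sel, ])
    expect_equal(unname(fit$fitted[sel]),
                 unname(fitted(ols)), tolerance = 1e-6)
  }
})

test_that("GCV shrinks pure-noise smooths toward the linear null space", {
  edfs <- vapply(1:20, function(r) {
    d <- make_two_group_data(n = 10, seed = 1000 + r, sd = 0.1)
    fit <- fit_gam(build_design(d, basis_spec(domain = c(1, 6))))
    max(fit$edf)
  }, numeric(1))
  expect_lt(median(edfs), 2)
})

test_that("EDF bounds and covariance positive semidefiniteness hold", {
  d <- make_two_group_data(n = 10, seed = 7,
                           f_a = function(w) sin(w), sd = 0.1)
  fit <- fit_gam(build_design(d, basis_spec(k = 6, domain = c(1, 6))))
  expect_true(all(fit$edf >= 1 - 1e-8))
  expect_true(all(fit$edf <= 6))
  ev <- eigen(fit$V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  # fitted-residual orthogonality up to the penalty term
  expect_lt(abs(sum(fit$residuals * fit$fitted)) /
              sqrt(sum(fit$fitted^2) * sum(fit$residuals^2)), 0.05)
})

test_that("prediction reproduces fitted values and interval geometry", {
  d <- make_two_group_data(n = 10, seed = 3,
                           f_a = function(w) 1 + 0.3 * sin(w), sd = 0.05)
  fit <- fit_gam(build_design(d, basis_spec(domain = c(1, 6))))
  cu <- predict_curve(fit, "A", grid = 1:6)
  sel <- d$group == "A"
  fitted_by_week <- tapply(fit$fitted[sel], d$week[sel], mean)
  expect_equal(cu$estimate, as.numeric(fitted_by_week), tolerance = 1e-9)

  cu2 <- predict_curve(fit, "A", grid = seq(1, 6, 0.5), level = 0.95)
  expect_equal((cu2$hi - cu2$estimate) / cu2$se,
               rep(qnorm(0.975), nrow(cu2)), tolerance = 1e-9)
  expect_error(predict_curve(fit, "A", grid = c(0.5, 3)), "domain")
  expect_error(predict_curve(fit, "Z", grid = 1:6), "unknown group")
})

test_that("pointwise SE vanishes as noise vanishes", {
  ses <- vapply(c(0.2, 0.02, 0.002), function(s) {
    d <- make_two_group_data(n = 10, seed = 5, sd = s)
    fit <- fit_gam(build_design(d, basis_spec(domain = c(1, 6))),
                   method = "fixed", lambda = 1)
    mean(predict_curve(fit, "A")$se)
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[3], 1e-3)
})

test_that("fits agree with an independent penalized-spline implementation", {
  skip_if_not_installed("mgcv")
  d <- make_two_group_data(n = 20, seed = 9,
                           f_a = function(w) 1 + 0.08 * sin((w - 1) / 5 * pi),
                           f_b = function(w) rep(1, length(w)), sd = 0.06)
  fit <- fit_gam(build_design(d, basis_spec(domain = c(1, 6))))
  d$group <- factor(d$group)
  mg <- mgcv::gam(value ~ group + s(week, by = group, k = 6, bs = "cr"),
                  data = d, method = "REML")
  grid <- data.frame(week = seq(1, 6, length.out = 50))
  ours <- predict_curve(fit, "A", grid$week)$estimate
  theirs <- as.numeric(predict(mg, data.frame(week = grid$week,
                                              group = factor("A",
                                                             levels = c("A", "B")))))
  expect_lt(sqrt(mean((ours - theirs)^2)), 0.02)
})
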