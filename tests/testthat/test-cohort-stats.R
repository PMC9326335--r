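test_that("score proportions exclude missing visits from denominators", {
  rec <- data.frame(tumor_id = paste0("t", 1:4), group = "CG", week = 2,
                    score = c(3.5, 3.5, 4, NA))
  pr <- score_proportions(rec)
  expect_equal(unique(pr$denominator), 3)
  expect_equal(pr$proportion[pr$score == 3.5], 2 / 3)
  expect_equal(pr$proportion[pr$score == 4], 1 / 3)
  expect_equal(sum(pr$proportion), 1)

  # degenerate distribution
  rec2 <- data.frame(tumor_id = paste0("t", 1:5), group = "MET", week = 1,
                     score = 3.5)
  pr2 <- score_proportions(rec2)
  expect_equal(pr2$proportion[pr2$score == 3.5], 1)

  # empty cell emitted with zero denominator and NA proportions
  rec3 <- data.frame(tumor_id = "t1", group = "MTD", week = 6,
                     score = NA_real_)
  pr3 <- score_proportions(rec3)
  expect_equal(unique(pr3$denominator), 0)
  expect_true(all(is.na(pr3$proportion)))

  expect_error(score_proportions(
    data.frame(tumor_id = "t", group = "CG", week = 1, score = 3.2)),
    "invalid score")
})

test_that("proportions sum to one in every non-empty group-week cell", {
  cfg <- cohort_config(seed = 14, missing_rate = 0.2)
  sc <- simulate_scores(simulate_trajectories(cfg), cfg)
  pr <- score_proportions(sc)
  sums <- tapply(pr$proportion, paste(pr$group, pr$week), sum)
  denoms <- tapply(pr$denominator, paste(pr$group, pr$week), max)
  expect_true(all(abs(sums[denoms > 0] - 1) < 1e-12))
})

test_that("scored-tumor subset sizes are honored in the tallies", {
  # the scoring arm follows its own tumor subset, distinct from the
  # spectroscopy arm sizes
  cfg <- cohort_config(n_per_group = c(MET = 29, CG = 16, MTD = 33),
                       seed = 77, missing_rate = 0)
  sc <- simulate_scores(simulate_trajectories(cfg), cfg)
  pr <- score_proportions(sc)
  denom <- tapply(pr$denominator, list(pr$group, pr$week), max)
  expect_true(all(denom["MET", ] == 29))
  expect_true(all(denom["CG", ] == 16))
  expect_true(all(denom["MTD", ] == 33))
})

test_that("score trajectories are ordered and reject duplicates", {
  rec <- data.frame(tumor_id = c("t1", "t1", "t2"), group = "CG",
                    week = c(2, 1, 1), score = c(3, 2, NA))
  tr <- score_trajectories(rec)
  expect_equal(tr$week[tr$tumor_id == "t1"], c(1, 2))
  expect_equal(tr$missing, c(FALSE, FALSE, TRUE))

  dup <- rbind(rec, data.frame(tumor_id = "t1", group = "CG", week = 2,
                               score = 4))
  expect_error(score_trajectories(dup), "t1 2")
  expect_equal(nrow(score_trajectories(rec[0, ])), 0L)
})

test_that("MVD is positive area over tissue area, background excluded", {
  m <- matrix(0L, 40, 40)
  m[1:10, 1:10] <- 2L   # 100 positive
  m[11:30, 1:15] <- 1L  # 300 tissue
  expect_equal(compute_mvd(m), 100 * 100 / 400)

  m_zero <- m; m_zero[m_zero == 2L] <- 1L
  expect_equal(compute_mvd(m_zero), 0)
  m_all <- m; m_all[m_all == 1L] <- 2L
  expect_equal(compute_mvd(m_all), 100)

  # invariant under background padding
  pad <- matrix(0L, 60, 60); pad[11:50, 11:50] <- m
  expect_equal(compute_mvd(pad), compute_mvd(m))

  expect_error(compute_mvd(matrix(0L, 5, 5)), "no tissue")
  expect_error(compute_mvd(matrix(3L, 2, 2)), "labels")
})

test_that("a 25% positive fraction mask yields 25% MVD", {
  m <- matrix(1L, 20, 20)
  m[1:100] <- 2L
  expect_equal(compute_mvd(m), 25)
})

test_that("mask PNG round trip preserves labels", {
  cfg <- cohort_config(n_per_group = c(CG = 1), seed = 4)
  masks <- simulate_masks(simulate_trajectories(cfg), cfg, size = 32L)
  f <- tempfile(fileext = ".png")
  write_mask_png(masks[[1]], f)
  expect_identical(read_mask_png(f), matrix(as.integer(masks[[1]]),
                                            nrow(masks[[1]])))
  unlink(f)
})

test_that("group comparison matches the closed-form rank statistic", {
  # two identical groups: H = 0, p = 1
  same <- data.frame(group = rep(c("A", "B"), each = 4),
                     mvd = rep(c(1, 2, 3, 4), 2))
  cmp <- compare_mvd(same)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)
  expect_false(cmp$significant)

  # completely separated groups, n = 5 each: hand rank computation
  sep <- data.frame(group = rep(c("A", "B", "C"), each = 5),
                    mvd = c(1:5, 11:15, 21:25))
  n <- 15
  rbar <- tapply(rank(sep$mvd), sep$group, mean)
  h_hand <- 12 / (n * (n + 1)) * sum(5 * (rbar - (n + 1) / 2)^2)
  expect_equal(compare_mvd(sep)$statistic, h_hand, tolerance = 1e-12)

  # invariance under monotone transformation
  sep2 <- sep; sep2$mvd <- log(sep2$mvd + 1)
  expect_equal(compare_mvd(sep2)$statistic, compare_mvd(sep)$statistic)
})

test_that("synthetic masks separate the low-vascularity group", {
  cfg <- cohort_config(n_per_group = c(CG = 8, MET = 8, MTD = 8),
                       seed = 31)
  masks <- simulate_masks(simulate_trajectories(cfg), cfg)
  mvd <- data.frame(sample_id = names(masks),
                    group = sub("_.*", "", names(masks)),
                    mvd = vapply(masks, compute_mvd, numeric(1)))
  cmp <- compare_mvd(mvd)
  expect_true(cmp$significant)
  expect_lt(cmp$medians[["MTD"]], min(cmp$medians[["CG"]],
                                      cmp$medians[["MET"]]))
})

test_that("ROI aggregation by sample mean is available", {
  d <- data.frame(sample_id = c("s1", "s1", "s2", "s3", "s4"),
                  group = c("A", "A", "A", "B", "B"),
                  mvd = c(10, 20, 30, 5, 15))
  cmp <- compare_mvd(d, aggregate_by_sample = TRUE)
  expect_equal(sum(cmp$n), 4)
})
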