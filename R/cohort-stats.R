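#' Weekly proportions of tumor scores per group
#'
#' Tallies, for each group-week cell, the proportion of tumors at each
#' score among the non-missing observations; missing visits are excluded
#' from the denominator. A cell with no non-missing observations is
#' emitted with denominator 0 and NA proportions.
#'
#' @param records Score data frame (tumor_id, group, week, score; NA =
#'   missing visit).
#' @param score_levels Admissible scores.
#' @return Data frame (group, week, score, proportion, denominator).
#' @export
score_proportions <- function(records,
                              score_levels = seq(1, 5, by = 0.5)) {
  stopifnot(all(c("group", "week", "score") %in% names(records)))
  present <- records$score[!is.na(records$score)]
  bad <- setdiff(unique(present), score_levels)
  if (length(bad)) {
    stop("invalid score value(s): ", paste(bad, collapse = ", "))
  }
  cells <- unique(records[, c("group", "week")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$group == cells$group[i] & records$week == cells$week[i]
    sc <- records$score[sel]
    sc <- sc[!is.na(sc)]
    denom <- length(sc)
    data.frame(group = cells$group[i], week = cells$week[i],
               score = score_levels,
               proportion = if (denom == 0) NA_real_ else
                 vapply(score_levels, function(s) mean(sc == s),
                        numeric(1)),
               denominator = denom)
  }))
  rownames(out) <- NULL
  out
}

#' Per-tumor ordered score series
#'
#' @param records Score data frame (tumor_id, group, week, score).
#' @return Data frame ordered by tumor and week, with a logical `missing`
#'   column; duplicate (tumor, week) rows are an error.
#' @export
score_trajectories <- function(records) {
  stopifnot(all(c("tumor_id", "week", "score") %in% names(records)))
  if (nrow(records) == 0) return(records)
  key <- paste(records$tumor_id, records$week)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicate (tumor, week) observation(s): ",
         paste(unique(dup), collapse = "; "))
  }
  out <- records[order(records$tumor_id, records$week), , drop = FALSE]
  out$missing <- is.na(out$score)
  rownames(out) <- NULL
  out
}

#' Microvessel density of a three-class label mask
#'
#' MVD is the percentage of marker-positive area relative to total tissue
#' area: `100 * n_positive / (n_positive + n_tissue)`. Background pixels
#' never enter the denominator, so padding a mask with background leaves
#' the value unchanged.
#'
#' @param mask Integer matrix with labels 0 (background), 1 (tissue),
#'   2 (positive).
#' @return MVD percent in `[0, 100]`.
#' @export
compute_mvd <- function(mask) {
  bad <- setdiff(unique(as.integer(mask)), c(0L, 1L, 2L))
  if (length(bad)) {
    stop("mask labels must be 0/1/2; found: ", paste(bad, collapse = ", "))
  }
  n_pos <- sum(mask == 2L)
  n_tis <- sum(mask == 1L)
  if (n_pos + n_tis == 0) stop("mask contains no tissue pixels")
  100 * n_pos / (n_pos + n_tis)
}

#' Compare microvessel density across groups
#'
#' Rank-based (Kruskal-Wallis) comparison of MVD values between treatment
#' groups, with a significance flag at the conventional 0.05 level. ROI-
#' level values are treated as independent observations by default; set
#' `aggregate_by_sample` to compare per-sample means instead.
#'
#' @param mvd Data frame with columns group, mvd, and (optionally)
#'   sample_id.
#' @param alpha Significance level.
#' @param aggregate_by_sample Average ROIs within sample first.
#' @return List: statistic (H), df, p_value, significant, medians per
#'   group, n per group.
#' @export
compare_mvd <- function(mvd, alpha = 0.05, aggregate_by_sample = FALSE) {
  stopifnot(all(c("group", "mvd") %in% names(mvd)))
  if (aggregate_by_sample) {
    stopifnot("sample_id" %in% names(mvd))
    agg <- stats::aggregate(mvd ~ group + sample_id, mvd, mean)
    mvd <- agg
  }
  groups <- unique(mvd$group)
  assert_that(length(groups) >= 2, "need at least two groups")
  kt <- stats::kruskal.test(mvd$mvd, factor(mvd$group))
  list(statistic = unname(kt$statistic),
       df = unname(kt$parameter),
       p_value = kt$p.value,
       significant = !is.na(kt$p.value) && kt$p.value < alpha,
       medians = tapply(mvd$mvd, mvd$group, stats::median),
       n = table(mvd$group))
}
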