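#' Simulate weekly endoscopic tumor scores
#'
#' Scores live on the nine-category scale {1, 1.5, ..., 5}. Each tumor's
#' weekly score is drawn by jittering a group-by-week mean trend and
#' rounding to the nearest half-step; visits go missing completely at
#' random at `config$missing_rate`. Default trends mirror the emulated
#' study: control and metronomic tumors drift upward (continued growth),
#' MTD tumors stay low with cyclic shrinkage.
#'
#' @param trajectories Output of [simulate_trajectories()] (tumor roster).
#' @param config A [cohort_config()].
#' @param mean_trend Function `(group, week) -> mean score`.
#' @param score_sd SD of the jitter before rounding.
#' @return Data frame (tumor_id, group, week, score) with NA for missing
#'   visits.
#' @export
simulate_scores <- function(trajectories, config,
                            mean_trend = default_score_trend,
                            score_sd = 0.5) {
  roster <- unique(trajectories$perfusion[, c("tumor_id", "group")])
  with_seed(derive_seed(config$seed, "scores"), {
    out <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
      mu <- vapply(config$weeks,
                   function(w) mean_trend(roster$group[i], w), numeric(1))
      raw <- stats::rnorm(length(config$weeks), mu, score_sd)
      sc <- pmin(5, pmax(1, round(raw * 2) / 2))
      sc[stats::runif(length(sc)) < config$missing_rate] <- NA
      data.frame(tumor_id = roster$tumor_id[i], group = roster$group[i],
                 week = config$weeks, score = sc)
    }))
    rownames(out) <- NULL
    out
  })
}

#' @rdname simulate_scores
#' @param group,week Group label and visit week.
#' @export
default_score_trend <- function(group, week) {
  switch(group,
         CG  = 2 + 0.35 * (week - 1),
         MET = 2 + 0.30 * (week - 1),
         MTD = 2 + 0.10 * (week - 1) - 0.3 * (week %% 2 == 0),
         stop("unknown group label: ", group))
}

#' Simulate vessel-label masks
#'
#' Produces one three-class label image per tumor: 0 = background,
#' 1 = tissue, 2 = marker-positive (vessel) pixels. A central disc is
#' tissue; within it, pixels are positive independently with the group's
#' positive fraction (defaults near CG 25%, MET 24%, MTD 8%, matching the
#' emulated microvessel-density contrast).
#'
#' @param trajectories Output of [simulate_trajectories()] (tumor roster).
#' @param config A [cohort_config()].
#' @param positive_fraction Named per-group fraction of tissue that is
#'   marker-positive.
#' @param size Mask side length, pixels.
#' @return Named list of integer matrices (one per tumor) with a
#'   `positive_fraction` attribute recording the generating fraction.
#' @export
simulate_masks <- function(trajectories, config,
                           positive_fraction = c(CG = 0.25, MET = 0.24,
                                                 MTD = 0.08),
                           size = 64L) {
  roster <- unique(trajectories$perfusion[, c("tumor_id", "group")])
  assert_that(all(roster$group %in% names(positive_fraction)),
              "positive_fraction must cover every group")
  with_seed(derive_seed(config$seed, "masks"), {
    cx <- (size + 1) / 2
    rr <- outer(seq_len(size), seq_len(size),
                function(i, j) sqrt((i - cx)^2 + (j - cx)^2))
    tissue <- rr <= 0.42 * size
    masks <- lapply(seq_len(nrow(roster)), function(i) {
      p <- positive_fraction[[roster$group[i]]]
      m <- matrix(0L, size, size)
      m[tissue] <- 1L
      pos <- tissue & matrix(stats::runif(size * size) < p, size, size)
      m[pos] <- 2L
      attr(m, "positive_fraction") <- p
      m
    })
    names(masks) <- roster$tumor_id
    masks
  })
}

#' Write and read three-class label masks as PNG
#'
#' Labels {0 = background, 1 = tissue, 2 = positive} are stored in a
#' grayscale PNG as intensities {0, 128, 255}.
#'
#' @param mask Integer label matrix.
#' @param path Output PNG path.
#' @return `read_mask_png` returns the integer label matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(c(0, 128, 255)[mask + 1L] / 255,
                       nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- matrix(0L, nrow(img), ncol(img))
  m[img > 0.25 & img <= 0.75] <- 1L
  m[img > 0.75] <- 2L
  m
}
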