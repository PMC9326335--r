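#' Build a reflectance lookup table
#'
#' Tabulates a forward reflectance model on a (mu_a, mu_s') grid, mu_a
#' log-spaced, and validates the monotonicity a physical reflectance surface
#' must satisfy: strictly decreasing in mu_a at fixed mu_s', strictly
#' increasing in mu_s' at fixed mu_a. Lookups interpolate bilinearly in
#' (log mu_a, mu_s').
#'
#' @param surrogate Function `f(mu_a, mu_s)` to tabulate.
#' @param mu_a_range Range of mu_a, cm^-1 (log-spaced grid).
#' @param mu_s_range Range of mu_s', cm^-1 (linear grid).
#' @param n_mu_a,n_mu_s Grid sizes.
#' @return Object of class `reflectance_lut`.
#' @export
build_lut <- function(surrogate = reflectance_surrogate(),
                      mu_a_range = c(0.01, 50),
                      mu_s_range = c(1, 50),
                      n_mu_a = 80L, n_mu_s = 60L) {
  stopifnot(mu_a_range[1] > 0, mu_s_range[1] > 0,
            n_mu_a >= 2, n_mu_s >= 2)
  mu_a <- exp(seq(log(mu_a_range[1]), log(mu_a_range[2]),
                  length.out = n_mu_a))
  mu_s <- seq(mu_s_range[1], mu_s_range[2], length.out = n_mu_s)
  R <- outer(mu_a, mu_s, surrogate)
  assert_that(all(R > 0), "LUT reflectance must be positive")
  assert_that(all(apply(R, 2, diff) < 0),
              "surrogate not strictly decreasing in mu_a on the grid")
  assert_that(all(apply(R, 1, diff) > 0),
              "surrogate not strictly increasing in mu_s' on the grid")
  structure(list(log_mu_a = log(mu_a), mu_s = mu_s, R = R,
                 mu_a_range = mu_a_range, mu_s_range = mu_s_range),
            class = "reflectance_lut")
}

#' Interpolate a reflectance LUT
#'
#' Bilinear interpolation in (log mu_a, mu_s'); queries are clamped to the
#' grid boundary.
#'
#' @param lut A `reflectance_lut`.
#' @param mu_a,mu_s Query points (vectors of equal length or scalars).
#' @return Interpolated reflectance values.
#' @export
lut_lookup <- function(lut, mu_a, mu_s) {
  n <- max(length(mu_a), length(mu_s))
  mu_a <- rep_len(mu_a, n); mu_s <- rep_len(mu_s, n)
  la <- pmin(pmax(log(mu_a), lut$log_mu_a[1]),
             lut$log_mu_a[length(lut$log_mu_a)])
  ms <- pmin(pmax(mu_s, lut$mu_s[1]), lut$mu_s[length(lut$mu_s)])
  ia <- pmin(findInterval(la, lut$log_mu_a), length(lut$log_mu_a) - 1L)
  is <- pmin(findInterval(ms, lut$mu_s), length(lut$mu_s) - 1L)
  ta <- (la - lut$log_mu_a[ia]) /
    (lut$log_mu_a[ia + 1L] - lut$log_mu_a[ia])
  ts <- (ms - lut$mu_s[is]) / (lut$mu_s[is + 1L] - lut$mu_s[is])
  r00 <- lut$R[cbind(ia, is)]
  r10 <- lut$R[cbind(ia + 1L, is)]
  r01 <- lut$R[cbind(ia, is + 1L)]
  r11 <- lut$R[cbind(ia + 1L, is + 1L)]
  (1 - ta) * (1 - ts) * r00 + ta * (1 - ts) * r10 +
    (1 - ta) * ts * r01 + ta * ts * r11
}
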