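#' Estimate change-point model hyperparameters from one profile
#'
#' The model needs a baseline mean `mu0`, a probe measurement variance
#' `sigma2` and a segment-level variance `sigma0_2`.  These are estimated
#' robustly from the profile itself: `mu0` is the median log2 ratio; sliding
#' windows of `window` probes (stride 1) give `V`, the median of the window
#' sample variances, and `M`, the maximum absolute difference between a window
#' mean and `mu0`.  The measurement variance is set to `sigma2_rule * V`
#' (default `2V`, deliberately inflated so local trends are not chased) and
#' the segment variance to `M`, `M^2` or `M^3` per `sigma0_rule` (default
#' `M^2`).
#'
#' When the estimated noise dominates the signal range (`sigma >= 3 * sigma0`)
#' breakpoint detection is hopeless and the profile is flagged so the sampler
#' reports zero breakpoints instead of noise-driven ones.
#'
#' @param profile A [cn_profile()].
#' @param window Sliding-window length in probes (default 10).
#' @param sigma2_rule One of `"V"`, `"2V"`, `"3V"`: multiplier on the median
#'   window variance.
#' @param sigma0_rule One of `"M"`, `"M2"`, `"M3"`: power of the maximal
#'   window-mean deviation.
#' @param p_single Prior probability that the profile is a single segment;
#'   remaining mass is uniform over 2..k_max segments.
#' @param k_max Maximum number of segments (clipped to the number of unmasked
#'   probes).
#' @param eps Variance floor applied when the profile is (near) constant.
#' @return A `cn_hyper` list with fields `mu0`, `sigma2`, `sigma0_2`, `V`,
#'   `M`, `p_single`, `k_max`, and logical `zero_breakpoints`.
#' @examples
#' p <- cn_profile("s", "c", 1:100, rnorm(100, sd = 0.2))
#' h <- estimate_hyperparameters(p)
#' h$sigma2
#' @export
estimate_hyperparameters <- function(profile, window = 10,
                                     sigma2_rule = c("2V", "V", "3V"),
                                     sigma0_rule = c("M2", "M", "M3"),
                                     p_single = 0.5, k_max = 50,
                                     eps = 1e-8) {
  assert_profile(profile)
  sigma2_rule <- match.arg(sigma2_rule)
  sigma0_rule <- match.arg(sigma0_rule)
  x <- unmasked_values(profile)
  n <- length(x)
  if (n < window)
    stop("need at least ", window, " unmasked probes to estimate variances")
  if (p_single <= 0 || p_single >= 1) stop("p_single must be in (0,1)")

  mu0 <- median(x)
  nw <- n - window + 1L
  cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
  wsum <- cs[(window + 1):(n + 1)] - cs[1:nw]
  wss <- css[(window + 1):(n + 1)] - css[1:nw]
  wmean <- wsum / window
  wvar <- (wss - window * wmean^2) / (window - 1)
  wvar[wvar < 0] <- 0
  V <- median(wvar)
  M <- max(abs(wmean - mu0))

  mult <- c(V = 1, `2V` = 2, `3V` = 3)[[sigma2_rule]]
  sigma2 <- mult * V
  if (sigma2 <= eps) {
    warning("profile variance ~0; flooring sigma2 at eps")
    sigma2 <- eps
  }
  pw <- c(M = 1, M2 = 2, M3 = 3)[[sigma0_rule]]
  sigma0_2 <- M^pw

  k_max <- as.integer(min(k_max, n))
  if (k_max < 1) k_max <- 1L

  structure(
    list(mu0 = mu0, sigma2 = sigma2, sigma0_2 = sigma0_2, V = V, M = M,
         p_single = p_single, k_max = k_max,
         zero_breakpoints = sqrt(sigma2) >= 3 * sqrt(sigma0_2)),
    class = "cn_hyper")
}

#' Prior distribution over the number of segments
#'
#' Mass `p_single` on K = 1 and the remainder uniform on 2..k_max.
#'
#' @param hyper A `cn_hyper` object (or any list with `p_single`, `k_max`).
#' @return Numeric vector of length `k_max` summing to 1.
#' @export
segment_count_prior <- function(hyper) {
  k_max <- hyper$k_max
  if (k_max == 1) return(1)
  c(hyper$p_single, rep((1 - hyper$p_single) / (k_max - 1), k_max - 1))
}
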