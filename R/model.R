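#' Log marginal likelihood of a probe segment
#'
#' Integrates the segment level analytically out of the Gaussian likelihood
#' under its conjugate Normal prior: with segment length `l`, mean `xbar` and
#' within-segment sum of squares `SS`,
#' \deqn{\log m = -\tfrac{l}{2}\log(2\pi\sigma^2)
#'   + \tfrac12\log\frac{\sigma^2}{\sigma^2 + l\sigma_0^2}
#'   - \frac{SS}{2\sigma^2}
#'   - \frac{l(\bar x - \mu_0)^2}{2(\sigma^2 + l\sigma_0^2)}.}
#' Indices refer to the unmasked probe sequence; the call is vectorised over
#' `i`, `j`.
#'
#' @param profile A [cn_profile()].
#' @param i,j 1-based first/last unmasked probe index of the segment.
#' @param hyper A `cn_hyper` from [estimate_hyperparameters()] (or a list with
#'   `mu0`, `sigma2`, `sigma0_2`).
#' @return Numeric vector of log marginal likelihoods.
#' @export
segment_marginal_loglik <- function(profile, i, j, hyper) {
  assert_profile(profile)
  marginal_loglik_cpp(unmasked_values(profile), as.integer(i), as.integer(j),
                      hyper$mu0, hyper$sigma2, hyper$sigma0_2)
}

#' Dynamic program over all segmentations of a profile
#'
#' Fills the table \eqn{S_k(j)}, the sum over all placements of `k - 1`
#' breakpoints in probes 1..j of the product of per-segment marginal
#' likelihoods.  With a uniform prior over breakpoint sequences given K,
#' \eqn{P(X | K = k) = S_k(n) / \binom{n-1}{k-1}}, and the evidence mixes
#' these over the segment-count prior.  All arithmetic is in log space.
#'
#' @param profile A [cn_profile()].
#' @param hyper A `cn_hyper`; `k_max` larger than the probe count is clipped
#'   with a warning.
#' @return A `cn_dp` list: `log_S` (k_max x n matrix), `log_px_given_k`,
#'   `log_px`, `post_k` (posterior over K, sums to 1), plus the inputs.
#' @examples
#' p <- cn_profile("s", "c", 1:60, c(rnorm(30), rnorm(30, 1)))
#' h <- estimate_hyperparameters(p)
#' dp <- compute_dp(p, h)
#' which.max(dp$post_k)
#' @export
compute_dp <- function(profile, hyper) {
  assert_profile(profile)
  x <- unmasked_values(profile)
  n <- length(x)
  k_max <- hyper$k_max
  if (k_max > n) {
    warning("k_max > number of unmasked probes; clipping to n")
    k_max <- n
  }
  hyper$k_max <- as.integer(k_max)
  log_S <- dp_table_cpp(x, hyper$mu0, hyper$sigma2, hyper$sigma0_2, k_max,
                        rep(FALSE, n - 1L))
  k <- seq_len(k_max)
  log_px_given_k <- log_S[, n] - lchoose(n - 1, k - 1)
  prior_k <- segment_count_prior(hyper)
  log_joint <- log_px_given_k + log(prior_k)
  log_px <- logsumexp(log_joint)
  post_k <- exp(log_joint - log_px)
  post_k <- post_k / sum(post_k)
  structure(
    list(log_S = log_S, log_px_given_k = log_px_given_k, log_px = log_px,
         post_k = post_k, prior_k = prior_k, hyper = hyper, n = n,
         profile = profile),
    class = "cn_dp")
}

#' Draw exact, independent breakpoint sequences from the posterior
#'
#' Each draw first picks the number of segments K from its posterior, then
#' walks the dynamic-programming table backwards, drawing each earlier
#' boundary from its exact conditional.  Per segment the posterior-mean level
#' \eqn{\hat\theta = (\sigma_0^2 l \bar x + \sigma^2 \mu_0) /
#' (\sigma^2 + l \sigma_0^2)} is recorded; these drive copy-change directions
#' and the mean-segmentation export.
#'
#' Profiles flagged `zero_breakpoints` by [estimate_hyperparameters()] skip
#' the model entirely: every draw is the single whole-chromosome segment.
#'
#' @param dp A `cn_dp` from [compute_dp()], or (if the guard fired) the
#'   profile's hyperparameters are consulted via `dp$hyper`.
#' @param n_samples Number of posterior draws (>= 1).
#' @param seed Integer seed; draws are reproducible given (inputs, seed).
#' @return A `bp_samples` list: `gaps` (list of sorted integer gap indices per
#'   draw), `levels` (list of per-segment posterior means), `n_samples`, `n`,
#'   `seed`.
#' @export
sample_breakpoint_sequences <- function(dp, n_samples = 1000, seed) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (missing(seed)) stop("seed is required for reproducibility")
  n <- dp$n
  if (isTRUE(dp$hyper$zero_breakpoints)) {
    x <- unmasked_values(dp$profile)
    th <- single_segment_postmean(x, dp$hyper)
    out <- list(gaps = rep(list(integer(0)), n_samples),
                levels = rep(list(th), n_samples))
  } else {
    out <- with_seed(seed, sample_sequences_cpp(
      unmasked_values(dp$profile), dp$log_S, dp$post_k,
      dp$hyper$mu0, dp$hyper$sigma2, dp$hyper$sigma0_2, as.integer(n_samples)))
  }
  structure(
    list(gaps = out$gaps, levels = out$levels,
         n_samples = as.integer(n_samples), n = n, seed = seed),
    class = "bp_samples")
}

#' Exact posterior probability that a gap set is breakpoint-free
#'
#' Sums the posterior over all segmentations placing no breakpoint at any of
#' the given gaps, via a restricted dynamic program that forbids those gaps
#' as segment boundaries: `P(no breakpoint in W | X) =
#' P_restricted(X) / P(X)`.  This gives analytic (sampling-free)
#' counterparts of the sampled gap, interval and joint probabilities:
#' the marginal probability of gap `g` is `1 - free({g})`; an interval's hit
#' probability is `1 - free(W)`; a same-chromosome joint hit probability
#' follows by inclusion-exclusion, `1 - free(W1) - free(W2) + free(W1 U W2)`.
#' Each call costs a full DP, so this is intended for small problems and
#' verification; cohort-scale scans use posterior sampling.
#'
#' @param dp A `cn_dp` from [compute_dp()].
#' @param gaps Integer gap indices (between 1 and n-1); empty set gives 1.
#' @return Posterior probability that none of the gaps carries a breakpoint.
#' @export
exact_breakpoint_free_posterior <- function(dp, gaps) {
  n <- dp$n
  gaps <- as.integer(gaps)
  if (length(gaps) == 0) return(1)
  if (any(gaps < 1 | gaps > n - 1)) stop("gap indices out of range")
  forb <- rep(FALSE, n - 1L)
  forb[gaps] <- TRUE
  hy <- dp$hyper
  log_Sr <- dp_table_cpp(unmasked_values(dp$profile), hy$mu0, hy$sigma2,
                         hy$sigma0_2, hy$k_max, forb)
  k <- seq_len(hy$k_max)
  log_pxk_r <- log_Sr[, n] - lchoose(n - 1, k - 1)
  log_px_r <- logsumexp(log_pxk_r + log(dp$prior_k))
  exp(log_px_r - dp$log_px)
}

single_segment_postmean <- function(x, hyper) {
  l <- length(x)
  (hyper$sigma0_2 * l * mean(x) + hyper$sigma2 * hyper$mu0) /
    (hyper$sigma2 + l * hyper$sigma0_2)
}

#' Convenience wrapper: hyperparameters + DP + posterior sampling
#'
#' @inheritParams compute_dp
#' @inheritParams sample_breakpoint_sequences
#' @param ... Passed to [estimate_hyperparameters()].
#' @return List with `hyper`, `dp` (NULL when the zero-breakpoint guard
#'   fired), and `samples`.
#' @export
segment_profile <- function(profile, n_samples = 1000, seed, ...) {
  hyper <- estimate_hyperparameters(profile, ...)
  if (hyper$zero_breakpoints) {
    dp <- structure(list(log_S = NULL, post_k = 1, prior_k = segment_count_prior(hyper),
                         hyper = hyper, n = n_unmasked(profile),
                         profile = profile), class = "cn_dp")
    samples <- sample_breakpoint_sequences(dp, n_samples, seed)
    return(list(hyper = hyper, dp = NULL, samples = samples))
  }
  dp <- compute_dp(profile, hyper)
  samples <- sample_breakpoint_sequences(dp, n_samples, seed)
  list(hyper = hyper, dp = dp, samples = samples)
}

# long-format breakpoint token table: one row per (draw, gap) with the sign
# of the copy-number change across the gap (+1 if right segment level >= left)
token_table <- function(samples) {
  gaps <- samples$gaps
  nper <- lengths(gaps)
  draw <- rep.int(seq_along(gaps), nper)
  gap <- unlist(gaps, use.names = FALSE)
  if (is.null(gap)) gap <- integer(0)
  sign <- integer(length(gap))
  idx <- 1L
  for (s in seq_along(gaps)) {
    k <- nper[s]
    if (k > 0) {
      lv <- samples$levels[[s]]
      d <- lv[-1] - lv[-length(lv)]
      sign[idx:(idx + k - 1L)] <- ifelse(d >= 0, 1L, -1L)
      idx <- idx + k
    }
  }
  data.frame(draw = draw, gap = gap, sign = sign)
}

#' Per-gap breakpoint probabilities from posterior samples
#'
#' For each gap (boundary between adjacent unmasked probes) the fraction of
#' sampled segmentations containing a breakpoint there, split by direction of
#' copy-number change (positive: the segment right of the gap has the higher
#' posterior-mean level; ties count as positive).
#'
#' @param samples A `bp_samples` from [sample_breakpoint_sequences()].
#' @return Data frame with columns `gap`, `p_any`, `p_pos`, `p_neg` (one row
#'   per gap 1..n-1); `p_pos + p_neg == p_any`.
#' @export
gap_breakpoint_probabilities <- function(samples) {
  ngap <- samples$n - 1L
  tok <- token_table(samples)
  pos <- tabulate(tok$gap[tok$sign > 0], nbins = ngap)
  neg <- tabulate(tok$gap[tok$sign < 0], nbins = ngap)
  data.frame(gap = seq_len(ngap),
             p_any = (pos + neg) / samples$n_samples,
             p_pos = pos / samples$n_samples,
             p_neg = neg / samples$n_samples)
}

#' Probability that an interval contains at least one breakpoint
#'
#' The fraction of sampled segmentations with one or more breakpoints among
#' `gaps_in_w` (the gaps whose two flanking probes both lie inside the
#' interval).  The individual's direction call for the interval follows a 90%
#' rule over all its sampled in-interval breakpoints: `"+"` if at least 90%
#' are positive, `"-"` if at least 90% negative, otherwise `NA`.
#'
#' @param samples A `bp_samples`.
#' @param gaps_in_w Integer vector of gap indices inside the interval (may be
#'   empty, in which case the interval is non-scorable).
#' @return List: `p` (probability), `direction` (`"+"`, `"-"` or `NA`),
#'   `scorable` (FALSE iff `gaps_in_w` is empty).
#' @export
interval_breakpoint_probability <- function(samples, gaps_in_w) {
  if (length(gaps_in_w) == 0)
    return(list(p = 0, direction = NA_character_, scorable = FALSE))
  tok <- token_table(samples)
  inw <- tok$gap %in% gaps_in_w
  p <- length(unique(tok$draw[inw])) / samples$n_samples
  dir <- NA_character_
  npos <- sum(tok$sign[inw] > 0); ntot <- sum(inw)
  if (ntot > 0) {
    if (npos >= 0.9 * ntot) dir <- "+"
    else if (ntot - npos >= 0.9 * ntot) dir <- "-"
  }
  list(p = p, direction = dir, scorable = TRUE)
}

#' Joint probability of breakpoints in two intervals
#'
#' Same chromosome: the fraction of sampled segmentations containing at least
#' one breakpoint in each interval (the events are dependent through the
#' shared segmentation).  Different chromosomes: chromosomes are segmented
#' independently, so the joint probability is the product of the two marginal
#' interval probabilities.
#'
#' @param samples1 `bp_samples` for the first interval's chromosome.
#' @param gaps_w1,gaps_w2 Gap index sets of the two intervals.  When both
#'   intervals are on one chromosome they must not share gaps.
#' @param samples2 `bp_samples` for the second chromosome, or `NULL` (default)
#'   when both intervals lie on the chromosome of `samples1`.
#' @return Joint probability in `[0, 1]`.
#' @export
joint_interval_probability <- function(samples1, gaps_w1, gaps_w2,
                                       samples2 = NULL) {
  if (is.null(samples2)) {
    if (length(intersect(gaps_w1, gaps_w2)) > 0)
      stop("intervals overlap (shared gaps)")
    tok <- token_table(samples1)
    d1 <- unique(tok$draw[tok$gap %in% gaps_w1])
    d2 <- unique(tok$draw[tok$gap %in% gaps_w2])
    length(intersect(d1, d2)) / samples1$n_samples
  } else {
    p1 <- interval_breakpoint_probability(samples1, gaps_w1)$p
    p2 <- interval_breakpoint_probability(samples2, gaps_w2)$p
    p1 * p2
  }
}
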