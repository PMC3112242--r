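#' Normalised rank of scores within one individual
#'
#' Converts one individual's per-unit scores (gap breakpoint probabilities,
#' interval log-odds, ...) into normalised ranks
#' \eqn{\rho(u) = (\#\{u': s(u') > s(u)\} + \#\{\mathrm{ties\ incl.}\ u\}) / (N + 1)},
#' i.e. `(r + 1) / (N + 1)` for distinct scores, with tied units all taking
#' the worst rank of their tie group.  Counting ties against the unit keeps
#' \eqn{\rho \in (0, 1]} and makes ranks stochastically conservative under the
#' heavy ties at zero that arise when most units carry no breakpoint evidence,
#' so the uniform-null argument behind the binomial order statistic still
#' yields valid (conservative) p-values.
#'
#' @param scores Finite numeric vector of per-unit scores (larger = stronger
#'   breakpoint evidence).
#' @return Numeric vector of ranks in `(0, 1]`; invariant under strictly
#'   monotone transforms of `scores`.
#' @examples
#' normalized_rank(c(0.9, 0.1, 0.1, 0.1))
#' @export
normalized_rank <- function(scores) {
  N <- length(scores)
  if (N == 0) stop("no units to rank")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (N > 1 && all(scores == scores[1]))
    warning("all scores tied; ranks are degenerate")
  (N - rank(scores, ties.method = "min") + 1) / (N + 1)
}

#' Binomial order statistic combining ranks across individuals
#'
#' Under the null each individual's normalised rank is (at most) uniform on
#' (0, 1], so with ranks sorted ascending the chance that `h` or more of `m`
#' individuals fall at or below the `h`-th smallest rank is a binomial tail.
#' The p-value minimises this tail over `h` from `h_min` to `m`; the
#' minimising `h` identifies the supporting individuals.
#'
#' @param rhos Numeric vector of normalised ranks, one per individual, each in
#'   (0, 1].
#' @param h_min Smallest number of shared individuals worth calling.
#' @return List: `p` (the minimised tail), `h_star` (optimising h), `support`
#'   (indices into `rhos` of the `h_star` smallest ranks).
#' @examples
#' binomial_order_pvalue(c(0.5, 0.9), h_min = 1)  # p = 0.75 at h = 1
#' @export
binomial_order_pvalue <- function(rhos, h_min = 4) {
  m <- length(rhos)
  if (h_min < 1 || h_min > m) stop("need m >= h_min >= 1")
  if (any(rhos <= 0 | rhos > 1)) stop("ranks must lie in (0, 1]")
  o <- order(rhos)
  sorted <- rhos[o]
  hs <- h_min:m
  tails <- pbinom(hs - 1, m, sorted[hs], lower.tail = FALSE)
  best <- which.min(tails)
  list(p = tails[best], h_star = hs[best], support = o[seq_len(hs[best])])
}

#' Benjamini-Hochberg q-values and rejection set
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Target false discovery rate.
#' @return List: `q` (step-up adjusted values, monotone) and `reject`
#'   (logical, `q <= alpha`).
#' @export
bh_fdr <- function(p_values, alpha = 0.01) {
  q <- p.adjust(p_values, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Prior probability that an interval is breakpoint-free
#'
#' Under the flat prior over breakpoint placements given K and the segment
#' count prior P(K), the chance that none of `w` designated gaps (out of
#' `n - 1`) carries a breakpoint is
#' \deqn{\sum_k P(K=k) \binom{n-1-w}{k-1} / \binom{n-1}{k-1},}
#' the fraction of placements of `k - 1` breakpoints avoiding all `w` gaps.
#' For pairs of intervals pass `w = w1 + w2` to exclude both jointly.
#'
#' @param n Number of (unmasked) probes on the chromosome.
#' @param w Number of excluded gaps, `0 <= w <= n - 1`.
#' @param prior_k Prior over the segment count (e.g.
#'   [segment_count_prior()]); length defines k_max.
#' @return Probability in `[0, 1]`; exactly 1 when `w = 0`.
#' @export
prior_breakpoint_free_probability <- function(n, w, prior_k) {
  if (w < 0 || w > n - 1) stop("w must be in [0, n-1]")
  k <- seq_along(prior_k)
  ratio <- exp(lchoose(n - 1 - w, k - 1) - lchoose(n - 1, k - 1))
  ratio[k - 1 > n - 1 - w] <- 0
  sum(prior_k * ratio)
}

#' Log-odds that an individual has a breakpoint in an interval
#'
#' Compares the posterior odds of at least one breakpoint in the interval
#' against the prior odds implied by interval size:
#' \eqn{\ell = \mathrm{logit}(P(b \in W | S_j)) - \mathrm{logit}(1 - P_{free})}.
#' The posterior probability is a sample fraction over `n_samples` draws and
#' is clipped to `[1/(n_samples+1), 1 - 1/(n_samples+1)]` to keep the score
#' finite.
#'
#' @param posterior_p Sampled probability of a breakpoint in the interval.
#' @param prior_free Prior breakpoint-free probability from
#'   [prior_breakpoint_free_probability()]; must be in (0, 1).
#' @param n_samples Number of posterior draws behind `posterior_p`.
#' @return The log-odds score (0 when posterior equals prior hit rate).
#' @export
interval_log_odds <- function(posterior_p, prior_free, n_samples) {
  if (any(prior_free <= 0 | prior_free >= 1))
    stop("prior_free must be in (0,1); intervals with no gaps are non-scorable")
  eps <- 1 / (n_samples + 1)
  p <- pmin(pmax(posterior_p, eps), 1 - eps)
  qlogis(p) - qlogis(1 - prior_free)
}

#' Log-odds for a pair of intervals
#'
#' Joint analogue of [interval_log_odds()]: `log(q/(1-q)) - log(pi/(1-pi))`
#' with `q` the joint posterior probability of a breakpoint in each interval
#' and `pi` the joint prior hit probability.  On different chromosomes the
#' prior is the product of the marginal hit probabilities; on the same
#' chromosome it follows by inclusion-exclusion over the combinatorial
#' placement counts: `pi = 1 - free(w1) - free(w2) + free(w1 + w2)`.
#'
#' @param joint_posterior Sampled joint probability (see
#'   [joint_interval_probability()]).
#' @param joint_prior Joint prior hit probability (see
#'   [pair_prior_probability()]).
#' @param n_samples Posterior draws behind `joint_posterior`.
#' @return The pair log-odds score.
#' @export
pair_log_odds <- function(joint_posterior, joint_prior, n_samples) {
  if (any(joint_prior <= 0 | joint_prior >= 1))
    stop("joint prior must be in (0,1)")
  eps <- 1 / (n_samples + 1)
  q <- pmin(pmax(joint_posterior, eps), 1 - eps)
  qlogis(q) - qlogis(joint_prior)
}

#' Joint prior hit probability for two intervals
#'
#' @param n1 Probe count on the first interval's chromosome.
#' @param w1,w2 Gap counts of the two intervals.
#' @param prior_k1 Segment-count prior for the first chromosome.
#' @param n2,prior_k2 As above for the second chromosome, or `NULL` (default)
#'   when both intervals share the first chromosome.
#' @return Probability that both intervals contain a breakpoint a priori.
#' @export
pair_prior_probability <- function(n1, w1, w2, prior_k1,
                                   n2 = NULL, prior_k2 = NULL) {
  if (is.null(n2)) {
    f1 <- prior_breakpoint_free_probability(n1, w1, prior_k1)
    f2 <- prior_breakpoint_free_probability(n1, w2, prior_k1)
    f12 <- prior_breakpoint_free_probability(n1, w1 + w2, prior_k1)
    1 - f1 - f2 + f12
  } else {
    (1 - prior_breakpoint_free_probability(n1, w1, prior_k1)) *
      (1 - prior_breakpoint_free_probability(n2, w2, prior_k2))
  }
}
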