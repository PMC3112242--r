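# Independent oracles: brute-force enumeration over all segmentations and a
# fresh implementation of the conjugate segment marginal.  Nothing here calls
# the package's DP or sampler.

oracle_marginal <- function(x, i, j, mu0, sigma2, sigma0_2) {
  xs <- x[i:j]
  l <- length(xs)
  xb <- mean(xs)
  ss <- sum((xs - xb)^2)
  -l / 2 * log(2 * pi * sigma2) +
    0.5 * log(sigma2 / (sigma2 + l * sigma0_2)) -
    ss / (2 * sigma2) -
    l * (xb - mu0)^2 / (2 * (sigma2 + l * sigma0_2))
}

oracle_lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# enumerate every segmentation (gap subset) of x up to k_max segments,
# returning per-segmentation log weights and derived exact posteriors
oracle_enumerate <- function(x, mu0, sigma2, sigma0_2, p_single, k_max) {
  n <- length(x)
  prior_k <- if (k_max == 1) 1 else
    c(p_single, rep((1 - p_single) / (k_max - 1), k_max - 1))
  segs <- list()
  for (k in seq_len(k_max)) {
    sets <- if (k == 1) list(integer(0)) else
      combn(seq_len(n - 1), k - 1, simplify = FALSE)
    for (g in sets) {
      b <- c(0L, g, n)
      lp <- sum(vapply(seq_len(k), function(s)
        oracle_marginal(x, b[s] + 1, b[s + 1], mu0, sigma2, sigma0_2),
        numeric(1)))
      # posterior segment-mean levels (deterministic given the segmentation)
      th <- vapply(seq_len(k), function(s) {
        xs <- x[(b[s] + 1):b[s + 1]]
        l <- length(xs)
        (sigma0_2 * l * mean(xs) + sigma2 * mu0) / (sigma2 + l * sigma0_2)
      }, numeric(1))
      segs[[length(segs) + 1]] <- list(
        k = k, gaps = g, levels = th,
        log_w = lp + log(prior_k[k]) - lchoose(n - 1, k - 1))
    }
  }
  lw <- vapply(segs, `[[`, numeric(1), "log_w")
  log_px <- oracle_lse(lw)
  w <- exp(lw - log_px)
  ks <- vapply(segs, `[[`, numeric(1), "k")
  post_k <- vapply(seq_len(k_max), function(k) sum(w[ks == k]), numeric(1))
  log_pxk <- vapply(seq_len(k_max), function(k)
    oracle_lse(lw[ks == k]) - log(prior_k[k]), numeric(1))

  gap_any <- gap_pos <- gap_neg <- numeric(n - 1)
  for (s in seq_along(segs)) {
    g <- segs[[s]]$gaps
    if (length(g) == 0) next
    th <- segs[[s]]$levels
    d <- diff(th)
    gap_any[g] <- gap_any[g] + w[s]
    gap_pos[g[d >= 0]] <- gap_pos[g[d >= 0]] + w[s]
    gap_neg[g[d < 0]] <- gap_neg[g[d < 0]] + w[s]
  }
  interval_p <- function(gaps_w) {
    if (length(gaps_w) == 0) return(0)
    sum(w[vapply(segs, function(s) any(s$gaps %in% gaps_w), logical(1))])
  }
  joint_p <- function(w1, w2) {
    sum(w[vapply(segs, function(s)
      any(s$gaps %in% w1) && any(s$gaps %in% w2), logical(1))])
  }
  list(log_px = log_px, log_px_given_k = log_pxk, post_k = post_k,
       gap_any = gap_any, gap_pos = gap_pos, gap_neg = gap_neg,
       interval_p = interval_p, joint_p = joint_p, segs = segs, w = w)
}

# prior probability that no breakpoint hits `gaps_w`, by enumerating gap
# subsets under the placement prior (no data involved)
oracle_prior_free <- function(n, gaps_w, prior_k) {
  tot <- 0
  for (k in seq_along(prior_k)) {
    sets <- if (k == 1) list(integer(0)) else
      combn(seq_len(n - 1), k - 1, simplify = FALSE)
    pw <- prior_k[k] / choose(n - 1, k - 1)
    for (g in sets) if (!any(g %in% gaps_w)) tot <- tot + pw
  }
  tot
}

make_hyper <- function(mu0 = 0, sigma2 = 0.5, sigma0_2 = 0.8,
                       p_single = 0.5, k_max = 3) {
  structure(list(mu0 = mu0, sigma2 = sigma2, sigma0_2 = sigma0_2,
                 V = NA, M = NA, p_single = p_single,
                 k_max = as.integer(k_max), zero_breakpoints = FALSE),
            class = "cn_hyper")
}
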