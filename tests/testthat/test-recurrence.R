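test_that("normalized ranks follow the strict-fraction convention with ties counted worst", {
  r <- normalized_rank(c(0.9, 0.1, 0.1, 0.1))
  expect_equal(r[1], 1 / 5) # nothing higher: (0 + 1) / (N + 1)
  expect_equal(r[2:4], rep(4 / 5, 3)) # tied group takes its worst rank
  expect_true(all(r > 0 & r <= 1))

  expect_warning(rt <- normalized_rank(rep(2, 6)), "tied")
  expect_equal(rt, rep(6 / 7, 6))

  # distinct scores: (r + 1) / (N + 1) exactly
  s <- c(5, 3, 4, 1, 2)
  expect_equal(normalized_rank(s), (rank(-s)) / 6)
  expect_error(normalized_rank(numeric(0)))
  expect_error(normalized_rank(c(1, NA)))
})

test_that("ranks are invariant under strictly monotone score transforms", {
  set.seed(21)
  for (rep in 1:5) {
    s <- runif(50)
    expect_equal(normalized_rank(s), normalized_rank(2 * s + 3))
    expect_equal(normalized_rank(s), normalized_rank(exp(s)))
    expect_equal(normalized_rank(s), normalized_rank(qlogis(s)))
  }
})

test_that("ranks of continuous scores are uniform on the rank grid", {
  set.seed(22)
  N <- 200
  counts <- table(factor(round(normalized_rank(runif(N)) * (N + 1)),
                         levels = 1:N))
  expect_true(all(counts == 1)) # a permutation of 1..N over N+1
})

test_that("binomial order statistic reproduces hand-computed tails", {
  r <- binomial_order_pvalue(c(0.5, 0.9), h_min = 1)
  expect_equal(r$p, 0.75) # h=1: 1 - (1-0.5)^2 ; h=2: 0.81
  expect_equal(r$h_star, 1)
  expect_equal(r$support, 1)

  expect_equal(binomial_order_pvalue(rep(1, 5), h_min = 2)$p, 1)

  # manual minimisation over h for a 4-rank case
  rho <- c(0.05, 0.1, 0.6, 0.8)
  tails <- sapply(2:4, function(h)
    pbinom(h - 1, 4, sort(rho)[h], lower.tail = FALSE))
  got <- binomial_order_pvalue(rho, h_min = 2)
  expect_equal(got$p, min(tails))
  expect_equal(got$h_star, (2:4)[which.min(tails)])

  expect_error(binomial_order_pvalue(c(0.5, 1.2), 1), "ranks")
  expect_error(binomial_order_pvalue(c(0, 0.5), 1), "ranks")
  expect_error(binomial_order_pvalue(c(0.5, 0.6), 3), "h_min")
})

test_that("more strongly supported configurations get smaller p-values", {
  base <- c(0.02, 0.03, 0.5, 0.6, 0.7, 0.8)
  better <- c(0.02, 0.03, 0.04, 0.6, 0.7, 0.8)
  expect_lt(binomial_order_pvalue(better, 2)$p,
            binomial_order_pvalue(base, 2)$p)
})

test_that("the combined p-value is only mildly anti-conservative under the null", {
  # brute-force null: iid uniform ranks.  Each fixed-h binomial tail is an
  # exact p-value, so the min over h obeys the union bound
  # P(p <= a) <= (m - h_min + 1) * a; assert it with Monte-Carlo slack
  set.seed(23)
  m <- 10
  p <- replicate(4000, binomial_order_pvalue(runif(m), h_min = 1)$p)
  expect_lt(mean(p <= 0.01), 10 * 0.01 + 3 * sqrt(0.1 * 0.9 / 4000))
  expect_lt(mean(p <= 0.05), 10 * 0.05 + 3 * sqrt(0.5 * 0.5 / 4000))
  # and with a realistic h_min the selection is much tighter
  p4 <- replicate(4000, binomial_order_pvalue(runif(m), h_min = 4)$p)
  expect_lt(mean(p4 <= 0.01), 7 * 0.01 + 3 * sqrt(0.07 * 0.93 / 4000))
})

test_that("combinatorial priors match subset enumeration", {
  # pinned example: n = 4 (3 gaps), w = 1, all prior mass on K = 2
  expect_equal(prior_breakpoint_free_probability(4, 1, c(0, 1)), 2 / 3)
  expect_equal(prior_breakpoint_free_probability(9, 0, c(0.5, 0.3, 0.2)), 1)

  prior_k <- c(0.4, 0.3, 0.2, 0.1)
  n <- 12
  for (w in c(1, 2, 4, 8, 11)) {
    expect_equal(prior_breakpoint_free_probability(n, w, prior_k),
                 oracle_prior_free(n, seq_len(w), prior_k),
                 tolerance = 1e-12)
  }
  # depends only on the count of excluded gaps, not which ones
  expect_equal(prior_breakpoint_free_probability(n, 3, prior_k),
               oracle_prior_free(n, c(2, 7, 11), prior_k), tolerance = 1e-12)
})

test_that("interval log-odds is zero at the prior and increases with evidence", {
  pf <- 0.8 # prior free => prior hit 0.2
  expect_equal(interval_log_odds(0.2, pf, 1e6), 0, tolerance = 1e-4)
  l1 <- interval_log_odds(0.5, pf, 1000)
  l2 <- interval_log_odds(0.99, pf, 1000)
  expect_gt(l1, 0)
  expect_gt(l2, l1)
  # clipping keeps scores finite at the sample extremes
  expect_true(is.finite(interval_log_odds(1, pf, 1000)))
  expect_true(is.finite(interval_log_odds(0, pf, 1000)))
  expect_error(interval_log_odds(0.5, 1, 1000), "prior_free")
})

test_that("pair priors and log-odds agree with enumeration", {
  prior_k <- c(0.5, 0.25, 0.15, 0.1)
  n <- 10
  # same chromosome, single-gap intervals: enumeration over gap subsets
  for (gpair in list(c(2, 7), c(1, 9), c(4, 5))) {
    f1 <- oracle_prior_free(n, gpair[1], prior_k)
    f2 <- oracle_prior_free(n, gpair[2], prior_k)
    f12 <- oracle_prior_free(n, gpair, prior_k)
    exact <- 1 - f1 - f2 + f12
    expect_equal(pair_prior_probability(n, 1, 1, prior_k), exact,
                 tolerance = 1e-12)
  }
  # independence across chromosomes: product of hit probabilities
  pri <- pair_prior_probability(10, 1, 2, prior_k, n2 = 8, prior_k2 = prior_k)
  expect_equal(pri,
               (1 - prior_breakpoint_free_probability(10, 1, prior_k)) *
                 (1 - prior_breakpoint_free_probability(8, 2, prior_k)))
  # both odds ratios at 1 give zero score
  expect_equal(pair_log_odds(pri, pri, 1e6), 0, tolerance = 1e-3)
  expect_gt(pair_log_odds(0.9, pri, 1000), 0)
})

test_that("BH q-values follow the step-up arithmetic", {
  r <- bh_fdr(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(r$q, c(0.03, 0.03, 0.04))
  expect_true(all(r$reject))
  expect_false(any(bh_fdr(rep(1, 10), 0.1)$reject))
})

test_that("BH controls the realized FDR on uniform nulls", {
  set.seed(24)
  fdp <- replicate(60, {
    p <- runif(2000)
    rej <- bh_fdr(p, alpha = 0.05)$reject
    if (sum(rej) == 0) 0 else 1 # any rejection under a pure null is false
  })
  expect_lte(mean(fdp), 0.07) # at alpha = 0.05 plus Monte-Carlo slack
})
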