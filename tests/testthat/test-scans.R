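# small planted cohorts keep these deep end-to-end checks fast; the
# acceptance suite runs the full-size versions

test_that("probe scan recovers exactly conserved breakpoints with directions", {
  sim <- simulate_cohort(
    m = 12, n_probes = 120, noise_sd = 0.15,
    events = list(list(chrom = "chr1", start_probe = 41, length = 30,
                       log2 = 1, carriers = 1:8)),
    seed = 41)
  fit <- segment_cohort(sim$profiles, n_samples = 300, seed = 42)
  calls <- scan_recurrent_probe_breakpoints(fit, h_min = 4, fdr_alpha = 0.01)
  expect_gte(nrow(calls), 2)
  # both flank gaps: gap 40 (step up, +) and gap 70 (step down, -)
  up <- calls[calls$left_pos == 40 * 10000, ]
  dn <- calls[calls$left_pos == 70 * 10000, ]
  expect_equal(up$direction, "+")
  expect_equal(dn$direction, "-")
  expect_gte(up$h_support, 6)
  # no stray calls away from the planted flanks
  expect_true(all(calls$left_pos %in% (c(40, 70) * 10000)))
  # supporting individuals are carriers
  sup <- strsplit(up$support_ids, ",")[[1]]
  expect_true(all(sup %in% sprintf("ind%03d", 1:8)))
})

test_that("probe scan on a null cohort makes no calls", {
  sim <- simulate_cohort(m = 10, n_probes = 150, noise_sd = 0.25, seed = 43)
  fit <- segment_cohort(sim$profiles, n_samples = 300, seed = 44)
  calls <- scan_recurrent_probe_breakpoints(fit, h_min = 4, fdr_alpha = 0.01)
  expect_equal(nrow(calls), 0)
  expect_equal(attr(calls, "n_hypotheses"), 149 * 2)
})

test_that("mismatched probe grids are rejected", {
  p1 <- cn_profile("a", "c1", 1:20 * 10, rnorm(20))
  p2 <- cn_profile("b", "c1", 1:20 * 10 + 5, rnorm(20))
  fit <- segment_cohort(list(p1, p2), n_samples = 50, seed = 1)
  expect_error(scan_recurrent_probe_breakpoints(fit), "grids differ")
})

test_that("interval scan catches jittered in-gene breakpoints that the probe scan misses", {
  # truncation: event start jittered +/- ~3 probes inside a 14-probe gene in
  # 7/14 individuals; probe-exact recurrence is diluted below h_min.  Rank
  # resolution comes from a background of tiling genes (the real scan ranks
  # against genome-wide gene sets)
  ev <- list(list(chrom = "chr1", start_probe = 60, length = 80, log2 = -1,
                  carriers = 1:7, jitter = 2))
  sim <- simulate_cohort(m = 14, n_probes = 200, noise_sd = 0.2,
                         events = ev, seed = 45)
  bg_starts <- seq(2, 186, by = 7)
  bg_starts <- bg_starts[!(bg_starts >= 45 & bg_starts <= 72) &
                           !(bg_starts >= 125 & bg_starts <= 155)]
  genes <- cohort_gene_map(sim$grid, data.frame(
    name = c("TRUNC", sprintf("BG%02d", seq_along(bg_starts))),
    chrom = "chr1",
    start_probe = c(52, bg_starts), end_probe = c(66, bg_starts + 5),
    strand = rep(c("-", "+"), c(1, length(bg_starts)))))
  fit <- segment_cohort(sim$profiles, n_samples = 300, seed = 46)

  gene_calls <- scan_recurrent_interval_breakpoints(fit, genes, h_min = 4,
                                                    fdr_alpha = 0.01)
  expect_true("TRUNC" %in% gene_calls$gene)
  expect_false(any(grepl("^BG", gene_calls$gene)))
  tc <- gene_calls[gene_calls$gene == "TRUNC", ]
  expect_true("-" %in% tc$direction) # deletion starts: step down into event
  expect_gte(max(tc$h_support), 6)

  probe_calls <- scan_recurrent_probe_breakpoints(fit, h_min = 4,
                                                  fdr_alpha = 0.01)
  # the jittered left flanks must not be probe-exactly recurrent
  left_region <- (55:65) * 10000
  expect_false(any(probe_calls$left_pos %in% left_region))
})

test_that("genes spanning too few probes are reported non-scorable", {
  sim <- simulate_cohort(m = 4, n_probes = 60, noise_sd = 0.2, seed = 47)
  genes <- data.frame(name = c("TINY", "OK"), chrom = "chr1",
                      start = c(15000, 100000), end = c(16000, 200000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  fit <- segment_cohort(sim$profiles, n_samples = 100, seed = 48)
  calls <- scan_recurrent_interval_breakpoints(fit, genes, h_min = 2)
  expect_equal(attr(calls, "non_scorable"), "TINY")
  expect_equal(attr(calls, "n_hypotheses"), 2) # one scorable gene x 2 dirs
})

test_that("pair scan finds fusion-configured deletions and stays quiet on nulls", {
  # deletion whose flank gaps land inside two genes => pair with dirs (-, +)
  ev <- list(list(chrom = "chr1", start_probe = 41, length = 60, log2 = -1,
                  carriers = 1:6))
  sim <- simulate_cohort(m = 12, n_probes = 200, noise_sd = 0.2,
                         events = ev, seed = 49)
  bg_starts <- seq(112, 190, by = 6)
  genes <- cohort_gene_map(sim$grid, data.frame(
    name = c("GA", "GB", sprintf("BG%02d", seq_along(bg_starts))),
    chrom = "chr1",
    start_probe = c(36, 96, bg_starts), end_probe = c(45, 105, bg_starts + 4),
    strand = c("-", "-", rep("+", length(bg_starts)))))
  fit <- segment_cohort(sim$profiles, n_samples = 300, seed = 50)
  calls <- suppressWarnings(scan_recurrent_pairs(
    fit, genes, type = "gene", h_min = 4, fdr_alpha = 0.01,
    background_pairs = 500, seed = 51))
  expect_gte(nrow(calls), 1)
  top <- calls[1, ]
  expect_setequal(c(top$name1, top$name2), c("GA", "GB"))
  expect_equal(c(top$direction1, top$direction2)[order(c(top$name1,
                                                         top$name2))],
               c("-", "+")) # down into the deletion at GA, up out of it at GB

  # same machinery on a null cohort: nothing survives
  sim0 <- simulate_cohort(m = 12, n_probes = 200, noise_sd = 0.2, seed = 52)
  fit0 <- segment_cohort(sim0$profiles, n_samples = 300, seed = 53)
  calls0 <- suppressWarnings(scan_recurrent_pairs(
    fit0, genes, type = "gene", h_min = 4, fdr_alpha = 0.01,
    background_pairs = 500, seed = 54))
  expect_equal(nrow(calls0), 0)
})

test_that("probe-pair scan links the two flanks of an exactly recurrent event", {
  ev <- list(list(chrom = "chr1", start_probe = 31, length = 40, log2 = 1,
                  carriers = 1:6))
  sim <- simulate_cohort(m = 10, n_probes = 120, noise_sd = 0.15,
                         events = ev, seed = 55)
  fit <- segment_cohort(sim$profiles, n_samples = 300, seed = 56)
  calls <- suppressWarnings(scan_recurrent_pairs(
    fit, type = "probe", h_min = 4, fdr_alpha = 0.01,
    background_pairs = 500, seed = 57))
  expect_gte(nrow(calls), 1)
  # top pair joins gap 30 (left flank, +) with gap 70 (right flank, -)
  top <- calls[1, ]
  expect_setequal(c(top$start1, top$start2), c(30, 70) * 10000)
  expect_equal(top$direction1, "+")
  expect_equal(top$direction2, "-")
})
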