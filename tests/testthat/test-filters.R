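test_that("single-probe aberrations are masked by the jump rule", {
  p <- cn_profile("s", "c", 1:5, c(0, 0, 3, 0, 0))
  m1 <- mask_single_probe_aberrations(p, tau = 1, delta = 0.5)
  expect_equal(which(m1$mask), 3)
  # idempotent
  m2 <- mask_single_probe_aberrations(m1, tau = 1, delta = 0.5)
  expect_identical(m2$mask, m1$mask)

  # two consecutive elevated probes are a real segment, not an artifact
  p2 <- cn_profile("s", "c", 1:6, c(0, 0, 3, 3, 0, 0))
  expect_equal(sum(mask_single_probe_aberrations(p2, tau = 1,
                                                 delta = 0.5)$mask), 0)
  # flanks must agree: a step is not masked
  p3 <- cn_profile("s", "c", 1:5, c(0, 0, 3, 6, 6))
  expect_equal(sum(mask_single_probe_aberrations(p3, tau = 1,
                                                 delta = 0.5)$mask), 0)
  expect_error(mask_single_probe_aberrations(p, tau = 1, delta = 2), "tau")
})

test_that("data-driven thresholds leave genuine 40-probe events usable", {
  # an extreme noise probe inside the event can occasionally satisfy the
  # single-probe rule (it is then indistinguishable from an artifact); what
  # matters for breakpoint detection is that the event flanks survive and
  # interior masking stays rare
  sim <- simulate_single_aberration(noise_sd = 0.2, n_replicates = 25,
                                    seed = 61)
  n_event_masked <- 0
  for (p in sim$profiles) {
    masked <- which(mask_single_probe_aberrations(p)$mask)
    n_event_masked <- n_event_masked + length(intersect(masked, 31:70))
    expect_length(intersect(masked, c(30, 31, 70, 71)), 0)
  }
  expect_lte(n_event_masked, 2)
})

test_that("masking is idempotent and catches isolated spikes", {
  set.seed(62)
  for (r in 1:5) {
    x <- rnorm(200, sd = 0.2)
    spikes <- seq(20, 180, by = 40) + sample(-5:5, 5)
    x[spikes] <- x[spikes] + sample(c(-4, 4), 5, replace = TRUE)
    x[spikes + 1] <- x[spikes - 1] # flanks agree across the spike
    p <- cn_profile("s", "c", 1:200, x)
    m1 <- mask_single_probe_aberrations(p)
    m2 <- mask_single_probe_aberrations(m1)
    expect_identical(m1$mask, m2$mask)
    expect_true(all(spikes %in% which(m1$mask)))
  }
})

test_that("known-variant proximity flags single-locus calls", {
  cat <- data.frame(chrom = "c1", start = 1000000, end = 1200000,
                    variant_id = "v1", stringsAsFactors = FALSE)
  calls <- data.frame(type = "probe", chrom = "c1",
                      left_pos = c(1005000, 1500000),
                      right_pos = c(1006000, 1501000),
                      direction = "+", h_support = 4, support_ids = "a",
                      p = 0.001, q = 0.001, status = "pass",
                      stringsAsFactors = FALSE)
  out <- filter_known_variants(calls, cat)
  expect_equal(out$status, c("filtered_dgv", "pass")) # 5 kb near, 300 kb far
  # records are flagged, never dropped
  expect_equal(nrow(out), 2)
  # empty catalogue: no-op
  expect_equal(filter_known_variants(calls, cat[0, ])$status,
               c("pass", "pass"))
})

test_that("pair calls need both endpoint proximity and mutual overlap", {
  # prediction interval [100k, 200k] vs variant [150k, 260k]:
  # overlap 50k; mutual overlap = min(50/100, 50/110) ~ 0.45 < 0.5 -> kept
  cat <- data.frame(chrom = "c1", start = 150000, end = 260000,
                    variant_id = "v1", stringsAsFactors = FALSE)
  pair <- data.frame(type = "probe_pair", name1 = "a", chrom1 = "c1",
                     start1 = 100000, end1 = 100001, name2 = "b",
                     chrom2 = "c1", start2 = 200000, end2 = 200001,
                     direction1 = "+", direction2 = "-", h_support = 4,
                     support_ids = "a", p = 1e-5, q = 1e-4, status = "pass",
                     stringsAsFactors = FALSE)
  expect_equal(filter_known_variants(pair, cat)$status, "pass")
  # enlarge the variant overlap so mutual overlap exceeds 50%
  cat2 <- data.frame(chrom = "c1", start = 120000, end = 210000,
                     variant_id = "v2", stringsAsFactors = FALSE)
  expect_equal(filter_known_variants(pair, cat2)$status, "filtered_dgv")
  # interchromosomal pairs are never DGV-filtered
  pair_x <- pair; pair_x$chrom2 <- "c2"
  expect_equal(filter_known_variants(pair_x, cat2)$status, "pass")
})

test_that("matched-normal subtraction flags shared loci only", {
  tum <- data.frame(type = "probe", chrom = "c1",
                    left_pos = c(100, 500), right_pos = c(200, 600),
                    direction = c("+", "-"), h_support = 4,
                    support_ids = "a", p = 0.001, q = 0.001,
                    status = "pass", stringsAsFactors = FALSE)
  nrm <- tum[1, ]
  out <- subtract_matched_normals(tum, nrm)
  expect_equal(out$status, c("filtered_blood", "pass"))
  expect_warning(out2 <- subtract_matched_normals(tum, NULL), "no-op")
  expect_equal(out2$status, c("pass", "pass"))
})

test_that("germline events are vetoed by normals while somatic ones survive", {
  evs <- list(
    list(chrom = "chr1", start_probe = 31, length = 30, log2 = 1,
         carriers = 1:6, germline = TRUE),
    list(chrom = "chr1", start_probe = 121, length = 30, log2 = -1,
         carriers = 1:6))
  sim <- simulate_cohort(m = 10, n_probes = 200, noise_sd = 0.15,
                         events = evs, n_normals = 10, seed = 63)
  fit <- segment_cohort(sim$profiles, n_samples = 300, seed = 64)
  nfit <- segment_cohort(sim$normal_profiles, n_samples = 300, seed = 65)
  tum <- scan_recurrent_probe_breakpoints(fit, h_min = 4, fdr_alpha = 0.01)
  nrm <- scan_recurrent_probe_breakpoints(nfit, h_min = 4, fdr_alpha = 0.1)
  out <- subtract_matched_normals(tum, nrm)
  germ <- out[out$left_pos %in% (c(30, 60) * 10000), ]
  soma <- out[out$left_pos %in% (c(120, 150) * 10000), ]
  expect_true(all(germ$status == "filtered_blood"))
  expect_true(all(soma$status == "pass"))
  expect_gte(nrow(soma), 2)
})

test_that("RMS scores concordant flanks near zero and penalises discordant ones", {
  # two individuals, constructed profiles: a deletion joining the outsides
  # of GA and GB leaves both flanks at baseline 0 -> rms ~ 0
  mk <- function(sid, disc = 0) {
    x <- rep(0, 60)
    x[21:40] <- -1          # deleted interior
    x[41:60] <- x[41:60] + disc # discordant right flank if disc != 0
    cn_profile(sid, "c1", 1:60 * 100, x)
  }
  fit <- suppressWarnings( # noiseless fixture trips the variance floor
    segment_cohort(list(mk("a"), mk("b")), n_samples = 50, seed = 66))
  pair <- data.frame(name1 = "GA", chrom1 = "c1", start1 = 1500,
                     end1 = 2250, name2 = "GB", chrom2 = "c1",
                     start2 = 3850, end2 = 4450,
                     direction1 = "-", direction2 = "+",
                     support_ids = "a,b", stringsAsFactors = FALSE)
  r <- rms_rank(pair, fit)
  expect_lt(r$rms, 1e-9) # flanks exactly 0 on both sides
  expect_false(r$short_flank)

  # swapping the two partners leaves the score unchanged
  pair_sw <- pair
  pair_sw[, c("name1", "chrom1", "start1", "end1", "direction1")] <-
    pair[, c("name2", "chrom2", "start2", "end2", "direction2")]
  pair_sw[, c("name2", "chrom2", "start2", "end2", "direction2")] <-
    pair[, c("name1", "chrom1", "start1", "end1", "direction1")]
  expect_equal(rms_rank(pair_sw, fit)$rms, r$rms)

  # discordant flank levels score the quadratic mean of the differences
  fit2 <- suppressWarnings(segment_cohort(list(mk("a", 0.3), mk("b", 0.4)),
                                          n_samples = 50, seed = 67))
  r2 <- rms_rank(pair, fit2)
  expect_equal(r2$rms, sqrt((0.3^2 + 0.4^2) / 2), tolerance = 1e-9)

  # fewer than 3 flanking probes available -> flagged
  pair_edge <- pair
  pair_edge$start1 <- 100; pair_edge$end1 <- 250 # gene at chromosome start
  expect_true(rms_rank(pair_edge, fit)$short_flank)
})
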