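#' Simulate artificial chromosomes with one planted aberration
#'
#' Generates replicate single-chromosome profiles: a baseline of 0 with a
#' contiguous block of `event_length` probes at `event_log2`, plus i.i.d.
#' Gaussian probe noise.  The defaults reproduce the calibration setting of a
#' 100-probe chromosome carrying a centred 40-probe single-copy gain
#' (log2 ratio 1), whose true breakpoints fall at gaps 30 and 70.
#'
#' @param n_probes Probes per chromosome.
#' @param event_start 1-based first probe of the aberration.
#' @param event_length Aberration length in probes.
#' @param event_log2 Log2 ratio of the aberration.
#' @param noise_sd Probe noise standard deviation.
#' @param n_replicates Number of chromosomes to generate.
#' @param seed Integer seed.
#' @param spacing_bp Distance between probe midpoints (bp).
#' @return List: `profiles` (list of [cn_profile()]), `truth_gaps` (integer
#'   vector, the two flanking gaps), `spec` (the arguments).
#' @examples
#' sim <- simulate_single_aberration(n_replicates = 2, seed = 1)
#' sim$truth_gaps  # 30 70
#' @export
simulate_single_aberration <- function(n_probes = 100, event_start = 31,
                                       event_length = 40, event_log2 = 1,
                                       noise_sd = 0.2, n_replicates = 1,
                                       seed, spacing_bp = 10000) {
  if (missing(seed)) stop("seed is required")
  if (event_start < 1 || event_start + event_length - 1 > n_probes)
    stop("event must fit within the chromosome")
  mu <- rep(0, n_probes)
  ev <- event_start:(event_start + event_length - 1)
  mu[ev] <- event_log2
  pos <- seq_len(n_probes) * spacing_bp
  profiles <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    cn_profile(sprintf("rep%03d", r), "chrS",
               pos, mu + rnorm(n_probes, 0, noise_sd))
  }))
  truth <- c(event_start - 1L, event_start + event_length - 1L)
  truth <- truth[truth >= 1 & truth <= n_probes - 1]
  list(profiles = profiles, truth_gaps = as.integer(truth),
       spec = list(n_probes = n_probes, event_start = event_start,
                   event_length = event_length, event_log2 = event_log2,
                   noise_sd = noise_sd, n_replicates = n_replicates,
                   seed = seed))
}

#' Simulate a multi-individual cohort with planted recurrent events
#'
#' Emulates the structure of tumor aCGH cohorts: every individual shares one
#' probe grid; carrier individuals receive planted copy-number events whose
#' breakpoints are either probe-exact (`jitter = 0`) or jittered per carrier
#' by a discrete number of probes; non-carriers are pure noise.  Deletion
#' events whose flanks fall inside two genes create the fusion-gene geometry;
#' events marked `germline` are copied into the optional matched-normal
#' cohort.
#'
#' @param m Number of individuals.
#' @param chroms Character vector of chromosome names.
#' @param n_probes Probes per chromosome (recycled over `chroms`).
#' @param noise_sd Probe noise sd.
#' @param events List of planted events; each a list with fields `chrom`,
#'   `start_probe` (1-based first affected probe), `length` (probes),
#'   `log2` (signed magnitude; negative = deletion), `carriers` (integer ids
#'   or a fraction of `m`), optional `jitter` (sd in probes, default 0) and
#'   `germline` (default FALSE).
#' @param n_normals Matched normals to generate (0 = none); normals carry
#'   only `germline` events (same carriers by index, recycled).
#' @param spacing_bp Probe spacing (bp).
#' @param seed Integer seed.
#' @return List: `profiles`, `normal_profiles`, `truth` (per individual, data
#'   frame of planted gap indices and directions), `genes` implied by events
#'   is NOT generated here (see [cohort_gene_map()]), `grid` (positions per
#'   chromosome).
#' @export
simulate_cohort <- function(m = 20, chroms = "chr1", n_probes = 500,
                            noise_sd = 0.25, events = list(),
                            n_normals = 0, spacing_bp = 10000, seed) {
  if (missing(seed)) stop("seed is required")
  n_probes <- rep_len(n_probes, length(chroms))
  names(n_probes) <- chroms
  grid <- lapply(chroms, function(ch)
    seq_len(n_probes[[ch]]) * spacing_bp)
  names(grid) <- chroms

  resolve_carriers <- function(ev, mm) {
    cr <- ev$carriers
    if (is.null(cr)) stop("event needs carriers")
    if (length(cr) == 1 && cr < 1) cr <- seq_len(round(cr * mm))
    as.integer(cr)
  }

  build <- function(ids, prefix, germline_only, sub_seed) {
    with_seed(sub_seed, {
      truth <- list()
      profiles <- list()
      for (j in ids) {
        mu <- lapply(chroms, function(ch) rep(0, n_probes[[ch]]))
        names(mu) <- chroms
        tr <- list()
        for (ev in events) {
          if (germline_only && !isTRUE(ev$germline)) next
          carriers <- resolve_carriers(ev, length(ids))
          if (!(j %in% carriers)) next
          jit <- if (is.null(ev$jitter)) 0 else ev$jitter
          off <- if (jit > 0) as.integer(round(rnorm(1, 0, jit))) else 0L
          s <- ev$start_probe + off
          e <- s + ev$length - 1L
          np <- n_probes[[ev$chrom]]
          s <- max(2L, min(s, np - 1L))
          e <- max(s, min(e, np)) # event may run to the chromosome end
          if (any(vapply(tr, function(t)
            t$chrom == ev$chrom && s <= t$end_probe && e >= t$start_probe,
            logical(1))))
            stop("overlapping planted events on one individual")
          mu[[ev$chrom]][s:e] <- mu[[ev$chrom]][s:e] + ev$log2
          tr[[length(tr) + 1]] <- list(
            chrom = ev$chrom, start_probe = s, end_probe = e,
            gaps = c(s - 1L, if (e < np) e), log2 = ev$log2,
            # left gap: level steps onto the event; right gap: steps off it
            dir_left = if (ev$log2 > 0) "+" else "-",
            dir_right = if (ev$log2 > 0) "-" else "+",
            germline = isTRUE(ev$germline))
        }
        sid <- sprintf("%s%03d", prefix, j)
        for (ch in chroms) {
          profiles[[paste(sid, ch)]] <- cn_profile(
            sid, ch, grid[[ch]],
            mu[[ch]] + rnorm(n_probes[[ch]], 0, noise_sd))
        }
        truth[[sid]] <- tr
      }
      list(profiles = unname(profiles), truth = truth)
    })
  }

  tum <- build(seq_len(m), "ind", FALSE, derive_seed(seed, 1))
  nor <- if (n_normals > 0)
    build(seq_len(n_normals), "nrm", TRUE, derive_seed(seed, 2))
  else list(profiles = NULL, truth = NULL)

  list(profiles = tum$profiles, truth = tum$truth,
       normal_profiles = nor$profiles, normal_truth = nor$truth,
       grid = grid, seed = seed)
}

#' Gene map bracketing planted events
#'
#' Builds a BED6-style gene table whose regions cover the flanks of planted
#' events (for fusion/truncation simulations) plus background genes, so
#' end-to-end tests exercise the interval machinery over a realistic gene
#' set.
#'
#' @param grid Probe-position list from [simulate_cohort()].
#' @param gene_spec Data frame with `name`, `chrom`, `start_probe`,
#'   `end_probe` (1-based, inclusive) and `strand`.
#' @return Gene data frame (`name`, `chrom`, `start`, `end`, `strand`) in bp,
#'   0-based half-open, compatible with the interval scans.
#' @export
cohort_gene_map <- function(grid, gene_spec) {
  data.frame(
    name = gene_spec$name, chrom = gene_spec$chrom,
    start = vapply(seq_len(nrow(gene_spec)), function(r)
      grid[[gene_spec$chrom[r]]][gene_spec$start_probe[r]] - 1, numeric(1)),
    end = vapply(seq_len(nrow(gene_spec)), function(r)
      grid[[gene_spec$chrom[r]]][gene_spec$end_probe[r]] + 1, numeric(1)),
    strand = gene_spec$strand, stringsAsFactors = FALSE)
}

#' Evaluate predicted breakpoints against planted truth
#'
#' Matches predicted gaps to true gaps greedily by increasing distance, one
#' prediction per truth gap, counting a match when the gap indices differ by
#' at most `tolerance` probes.
#'
#' @param predicted Integer vector of predicted gap indices (e.g. gaps with
#'   posterior breakpoint probability at or above a threshold).
#' @param truth Integer vector of true gap indices.
#' @param tolerance Maximum probe distance for a match (default 2).
#' @return List: `tp` (truth gaps matched) and `fp` (predictions matching no
#'   truth gap).
#' @examples
#' evaluate_breakpoint_calls(c(31, 69), c(30, 70))  # tp = 2, fp = 0
#' @export
evaluate_breakpoint_calls <- function(predicted, truth, tolerance = 2) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) == 0) return(list(tp = 0L, fp = 0L))
  if (length(truth) == 0) return(list(tp = 0L, fp = length(predicted)))
  d <- abs(outer(predicted, truth, "-"))
  used_p <- rep(FALSE, length(predicted))
  used_t <- rep(FALSE, length(truth))
  tp <- 0L
  repeat {
    d2 <- d
    d2[used_p, ] <- NA; d2[, used_t] <- NA
    if (all(is.na(d2)) || min(d2, na.rm = TRUE) > tolerance) break
    idx <- which(d2 == min(d2, na.rm = TRUE), arr.ind = TRUE)[1, ]
    used_p[idx[1]] <- TRUE; used_t[idx[2]] <- TRUE
    tp <- tp + 1L
  }
  # unmatched predictions within tolerance of an already-matched truth gap
  # are redundant hits, not false positives
  fp <- sum(!used_p & apply(d > tolerance, 1, all))
  list(tp = tp, fp = fp)
}
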