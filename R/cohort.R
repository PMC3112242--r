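#' Segment every profile of a cohort and cache posterior summaries
#'
#' Runs hyperparameter estimation, the segmentation dynamic program and
#' posterior sampling for each (individual, chromosome) profile.  Per-profile
#' seeds are derived deterministically from `seed`, so a cohort fit is a pure
#' function of (profiles, configuration, seed).
#'
#' @param profiles List of [cn_profile()] objects (one per individual and
#'   chromosome; individuals may span several chromosomes).
#' @param n_samples Posterior draws per profile.
#' @param seed Master integer seed.
#' @param mask_singletons Mask single-probe aberrations (see
#'   [mask_single_probe_aberrations()]) before estimation.
#' @param ... Further arguments to [estimate_hyperparameters()].
#' @return A `bp_cohort_fit`: list with `fits` (nested
#'   `[[sample_id]][[chrom]]`, each holding `profile`, `hyper`, `samples`,
#'   `gap_probs`, `tok`, `n`, `prior_k`), `samples_ids`, `chroms`,
#'   `n_samples`, `seed`.
#' @examples
#' prof <- simulate_cohort(m = 3, n_probes = 60, noise_sd = 0.2, seed = 1)
#' fit <- segment_cohort(prof$profiles, n_samples = 100, seed = 1)
#' @export
segment_cohort <- function(profiles, n_samples = 1000, seed,
                           mask_singletons = TRUE, ...) {
  if (missing(seed)) stop("seed is required")
  fits <- list()
  idx <- 0L
  for (p in profiles) {
    idx <- idx + 1L
    if (mask_singletons) p <- mask_single_probe_aberrations(p)
    sp <- segment_profile(p, n_samples = n_samples,
                          seed = derive_seed(seed, idx), ...)
    tok <- token_table(sp$samples)
    entry <- list(profile = p, hyper = sp$hyper, samples = sp$samples,
                  gap_probs = gap_breakpoint_probabilities(sp$samples),
                  tok = tok, n = n_unmasked(p),
                  prior_k = segment_count_prior(sp$hyper))
    fits[[p$sample_id]][[p$chrom]] <- entry
  }
  structure(list(fits = fits, sample_ids = names(fits),
                 chroms = unique(unlist(lapply(fits, names))),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "bp_cohort_fit")
}

#' @export
print.bp_cohort_fit <- function(x, ...) {
  cat(sprintf("<bp_cohort_fit> %d individuals, chromosomes: %s, %d draws\n",
              length(x$sample_ids), paste(x$chroms, collapse = ","),
              x$n_samples))
  invisible(x)
}

# gap descriptor table for one fitted profile: gap index, flanking unmasked
# probe positions, and whether the two probes are adjacent on the original
# (pre-mask) grid -- only such gaps are comparable probe-exactly across
# individuals
gap_keys <- function(entry) {
  prof <- entry$profile
  up <- unmasked_pos(prof)
  ngap <- length(up) - 1L
  if (ngap < 1)
    return(data.frame(gap = integer(0), lpos = numeric(0), rpos = numeric(0),
                      adjacent = logical(0)))
  full_idx <- which(!prof$mask)
  data.frame(gap = seq_len(ngap), lpos = up[-length(up)], rpos = up[-1],
             adjacent = diff(full_idx) == 1L)
}

# interval probability from a cached token table
interval_prob_tok <- function(tok, n_samples, gaps) {
  if (length(gaps) == 0)
    return(list(p = 0, direction = NA_character_, scorable = FALSE))
  inw <- tok$gap %in% gaps
  p <- length(unique(tok$draw[inw])) / n_samples
  dir <- NA_character_
  ntot <- sum(inw)
  if (ntot > 0) {
    npos <- sum(tok$sign[inw] > 0)
    if (npos >= 0.9 * ntot) dir <- "+"
    else if (ntot - npos >= 0.9 * ntot) dir <- "-"
  }
  list(p = p, direction = dir, scorable = TRUE)
}

# draws (integer ids) containing >= 1 breakpoint in the gap set
hit_draws_tok <- function(tok, gaps) unique(tok$draw[tok$gap %in% gaps])

# gaps whose two flanking unmasked probes both lie in [start, end)
gaps_in_interval <- function(entry, start, end) {
  up <- unmasked_pos(entry$profile)
  inw <- up >= start & up < end
  ngap <- length(up) - 1L
  if (ngap < 1) return(integer(0))
  which(inw[-length(inw)] & inw[-1])
}
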