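#' Mask single-probe aberrations
#'
#' Segments consisting of a single probe are indistinguishable from
#' hybridisation artifacts, so they are masked before any model fitting.  A
#' probe is a single-probe aberration when both adjacent jumps are large
#' (`> tau`) with opposite signs and the values flanking it are similar
#' (`< delta` apart).  Applied to the unmasked probe sequence; already-masked
#' probes are ignored.
#'
#' Default thresholds scale with the profile's noise level estimated on the
#' raw profile: `tau = 3 * sigma_hat`, `delta = sigma_hat`, where
#' `sigma_hat = sqrt(2V)` and `V` is the median sliding-window variance.
#'
#' @param profile A [cn_profile()].
#' @param tau Jump threshold (log2 units); `NULL` for the data-driven default.
#' @param delta Flank-similarity threshold; `NULL` for the default.
#' @param window Window length for the noise estimate behind the defaults.
#' @return The profile with offending probes added to its mask.
#' @examples
#' p <- cn_profile("s", "c", 1:5, c(0, 0, 3, 0, 0))
#' mask_single_probe_aberrations(p, tau = 1, delta = 0.5)$mask
#' @export
mask_single_probe_aberrations <- function(profile, tau = NULL, delta = NULL,
                                          window = 10) {
  x <- unmasked_values(profile)
  n <- length(x)
  if (n < 3) return(profile)
  if (is.null(tau) || is.null(delta)) {
    if (n < window) return(profile)
    nw <- n - window + 1L
    cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
    wmean <- (cs[(window + 1):(n + 1)] - cs[1:nw]) / window
    wvar <- (css[(window + 1):(n + 1)] - css[1:nw] - window * wmean^2) /
      (window - 1)
    sig <- sqrt(2 * max(median(pmax(wvar, 0)), 0))
    if (sig == 0) return(profile)
    if (is.null(tau)) tau <- 3 * sig
    if (is.null(delta)) delta <- sig
  }
  if (tau <= delta) stop("tau must exceed delta")
  i <- 2:(n - 1)
  d_in <- x[i] - x[i - 1]
  d_out <- x[i + 1] - x[i]
  hit <- abs(d_in) > tau & abs(d_out) > tau & sign(d_in) != sign(d_out) &
    abs(x[i + 1] - x[i - 1]) < delta
  if (!any(hit)) return(profile)
  unmasked_idx <- which(!profile$mask)
  profile$mask[unmasked_idx[i[hit]]] <- TRUE
  profile
}

#' Mark predictions matching known germline variants
#'
#' Predictions coinciding with catalogued copy-number polymorphisms are
#' flagged (never deleted).  A probe-level or gene-level call is flagged when
#' it lies within `proximity_bp` of either endpoint of any catalogued
#' variant.  An intrachromosomal pair call is flagged only when additionally
#' the interval it spans and the variant interval mutually overlap by more
#' than `mutual_overlap_min` (fraction of the shorter-relative measure:
#' `min(|I∩V|/|I|, |I∩V|/|V|)`).
#'
#' @param calls Data frame of calls from the scans / [assemble_predictions()].
#' @param catalogue Data frame from [read_known_variants()] (`chrom`, `start`,
#'   `end`, `variant_id`); an empty catalogue leaves calls untouched.
#' @param proximity_bp Endpoint proximity (default 10 kb).
#' @param mutual_overlap_min Mutual-overlap threshold for pair calls
#'   (default 0.5).
#' @return `calls` with `status` set to `"filtered_dgv"` where matched.
#' @export
filter_known_variants <- function(calls, catalogue, proximity_bp = 10000,
                                  mutual_overlap_min = 0.5) {
  if (is.null(calls) || nrow(calls) == 0 || is.null(catalogue) ||
      nrow(catalogue) == 0)
    return(calls)

  near_endpoint <- function(chrom, lo, hi) {
    # interval [lo, hi] within proximity of a variant endpoint
    v <- catalogue[catalogue$chrom == chrom, , drop = FALSE]
    if (nrow(v) == 0) return(FALSE)
    ends <- c(v$start, v$end)
    any(ends >= lo - proximity_bp & ends <= hi + proximity_bp)
  }

  for (r in seq_len(nrow(calls))) {
    if (calls$status[r] != "pass") next
    if (!is.null(calls$chrom2) && !is.na(calls$chrom2[r])) {
      # pair call
      if (calls$chrom1[r] != calls$chrom2[r]) next # interchromosomal: kept
      bp1 <- c(calls$start1[r], calls$end1[r])
      bp2 <- c(calls$start2[r], calls$end2[r])
      near <- near_endpoint(calls$chrom1[r], bp1[1], bp1[2]) ||
        near_endpoint(calls$chrom2[r], bp2[1], bp2[2])
      if (!near) next
      I <- c(min(bp1, bp2), max(bp1, bp2))
      v <- catalogue[catalogue$chrom == calls$chrom1[r], , drop = FALSE]
      if (nrow(v) == 0) next
      isect <- pmax(0, pmin(I[2], v$end) - pmax(I[1], v$start))
      mo <- pmin(isect / (I[2] - I[1]), isect / (v$end - v$start))
      if (any(mo > mutual_overlap_min)) calls$status[r] <- "filtered_dgv"
    } else {
      # single locus: probe gap or gene interval
      if (!is.null(calls$left_pos)) {
        lo <- calls$left_pos[r]; hi <- calls$right_pos[r]
        ch <- calls$chrom[r]
      } else {
        lo <- calls$start[r]; hi <- calls$end[r]
        ch <- calls$chrom[r]
      }
      if (near_endpoint(ch, lo, hi)) calls$status[r] <- "filtered_dgv"
    }
  }
  calls
}

#' Remove tumor calls that recur in matched normals
#'
#' Recurrent breakpoints also present in a matched-normal (e.g. blood) cohort
#' are germline and flagged `filtered_blood`.  The normal cohort should be
#' scanned at a lenient FDR (default 0.1 in [run_pipeline()]) so that weak
#' germline signals still veto tumor calls.  Loci are matched by type and
#' coordinates, ignoring direction.
#'
#' @param tumor_calls Calls from the tumor cohort scans.
#' @param normal_calls Calls from the same scan run on the normal cohort, or
#'   `NULL`/empty for a no-op (with a warning).
#' @return `tumor_calls` with `status` updated.
#' @export
subtract_matched_normals <- function(tumor_calls, normal_calls) {
  if (is.null(tumor_calls) || nrow(tumor_calls) == 0) return(tumor_calls)
  if (is.null(normal_calls) || nrow(normal_calls) == 0) {
    warning("no normal calls supplied; matched-normal subtraction is a no-op")
    return(tumor_calls)
  }
  key <- function(df) {
    if (!is.null(df$name1))
      paste(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2)
    else if (!is.null(df$left_pos))
      paste(df$chrom, df$left_pos, df$right_pos)
    else paste(df$chrom, df$start, df$end)
  }
  hit <- key(tumor_calls) %in% key(normal_calls)
  tumor_calls$status[hit & tumor_calls$status == "pass"] <- "filtered_blood"
  tumor_calls
}

#' Copy-level discordance (RMS) of a paired prediction
#'
#' Both breakpoints of a physically joined pair lie on the same derivative
#' chromosome, so the copy levels just outside the two partner regions on
#' their fused (higher-copy) sides should agree.  For each supporting
#' individual the fused-side level of each partner is the mean of the
#' `flank` probes immediately outside the region on that side (genomic right
#' when the breakpoint direction is `"+"`, left when `"-"`); the score is the
#' root-mean-square of the per-individual differences.  Concordant pairs
#' score near 0 and rank first.
#'
#' @param pair_call One row of a pair-call data frame (needs `chrom1/2`,
#'   `start1/2`, `end1/2`, `direction1/2`, `support_ids`).
#' @param fit The [segment_cohort()] fit providing the profiles.
#' @param flank Number of flanking probes to average (default 3; fewer are
#'   used, with a flag, when the region abuts the chromosome end).
#' @return List: `rms` (log2 units) and `short_flank` (TRUE if any side had
#'   fewer than `flank` probes).
#' @export
rms_rank <- function(pair_call, fit, flank = 3) {
  ids <- strsplit(pair_call$support_ids, ",")[[1]]
  short <- FALSE
  flank_level <- function(sid, chrom, start, end, dir) {
    e <- fit$fits[[sid]][[chrom]]
    up <- unmasked_pos(e$profile)
    uv <- unmasked_values(e$profile)
    if (dir == "+") idx <- which(up >= end) else idx <- rev(which(up < start))
    if (length(idx) < flank) short <<- TRUE
    idx <- idx[seq_len(min(flank, length(idx)))]
    if (length(idx) == 0) return(NA_real_)
    mean(uv[idx])
  }
  d <- vapply(ids, function(sid) {
    cl <- flank_level(sid, pair_call$chrom1, pair_call$start1,
                      pair_call$end1, pair_call$direction1)
    cr <- flank_level(sid, pair_call$chrom2, pair_call$start2,
                      pair_call$end2, pair_call$direction2)
    cl - cr
  }, numeric(1))
  d <- d[is.finite(d)]
  list(rms = if (length(d) == 0) NA_real_ else sqrt(mean(d^2)),
       short_flank = short)
}

#' Append RMS scores to pair calls and sort by them
#'
#' @param pair_calls Pair-call data frame ([scan_recurrent_pairs()] output or
#'   fusion predictions).
#' @param fit The cohort fit.
#' @param flank Flanking probes per side (see [rms_rank()]).
#' @return `pair_calls` with an `rms` column, sorted ascending by it.
#' @export
add_rms_scores <- function(pair_calls, fit, flank = 3) {
  if (is.null(pair_calls) || nrow(pair_calls) == 0) return(pair_calls)
  pair_calls$rms <- vapply(seq_len(nrow(pair_calls)), function(r)
    rms_rank(pair_calls[r, ], fit, flank)$rms, numeric(1))
  pair_calls[order(pair_calls$rms), , drop = FALSE]
}
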