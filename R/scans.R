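#' Scan a cohort for recurrent probe-level breakpoints
#'
#' For each gap between adjacent probes and each direction of copy-number
#' change, the direction-specific breakpoint probabilities are rank-normalised
#' within each individual (over all that individual's gaps, genome-wide) and
#' combined across individuals with the binomial order statistic.  Testing
#' both directions doubles the number of hypotheses; Benjamini-Hochberg FDR
#' control is applied over all (gap, direction) hypotheses.
#'
#' All individuals must share the probe grid.  Gaps whose flanking probes are
#' not adjacent on the original grid in some individual (because a probe was
#' masked there) take the worst rank for that individual.
#'
#' @param fit A [segment_cohort()] fit.
#' @param h_min Minimum number of supporting individuals.
#' @param fdr_alpha FDR level for the call set.
#' @return Data frame of calls (rows with `q <= fdr_alpha`): `type`, `chrom`,
#'   `left_pos`, `right_pos`, `direction`, `h_support`, `support_ids`, `p`,
#'   `q`, `status`.  Attribute `n_hypotheses` records the tested count.
#' @export
scan_recurrent_probe_breakpoints <- function(fit, h_min = 4,
                                             fdr_alpha = 0.01) {
  ids <- fit$sample_ids
  m <- length(ids)
  check_shared_grid(fit)

  # per individual: genome-wide gap table with direction-specific ranks
  per_ind <- lapply(ids, function(sid) {
    chroms <- names(fit$fits[[sid]])
    tabs <- lapply(chroms, function(ch) {
      e <- fit$fits[[sid]][[ch]]
      gk <- gap_keys(e)
      cbind(chrom = ch, gk, p_pos = e$gap_probs$p_pos,
            p_neg = e$gap_probs$p_neg)
    })
    tab <- do.call(rbind, tabs)
    tab$rho_pos <- suppressWarnings(normalized_rank(tab$p_pos))
    tab$rho_neg <- suppressWarnings(normalized_rank(tab$p_neg))
    tab$key <- paste(tab$chrom, tab$lpos, tab$rpos, sep = ":")
    tab
  })
  names(per_ind) <- ids

  # hypothesis space: original-grid-adjacent gap keys seen in any individual
  keys <- unique(unlist(lapply(per_ind, function(t) t$key[t$adjacent])))
  hyp <- expand.grid(key = keys, direction = c("+", "-"),
                     stringsAsFactors = FALSE)

  rho_mat <- function(col) {
    mat <- matrix(1, nrow = length(keys), ncol = m,
                  dimnames = list(keys, ids))
    for (sid in ids) {
      t <- per_ind[[sid]]
      ok <- t$adjacent & t$key %in% keys
      mat[t$key[ok], sid] <- t[[col]][ok]
    }
    mat
  }
  rp <- rho_mat("rho_pos"); rn <- rho_mat("rho_neg")

  res <- lapply(seq_len(nrow(hyp)), function(r) {
    rho <- if (hyp$direction[r] == "+") rp[hyp$key[r], ] else rn[hyp$key[r], ]
    binomial_order_pvalue(rho, h_min)
  })
  hyp$p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- bh_fdr(hyp$p, fdr_alpha)
  hyp$q <- fdr$q

  calls <- hyp[fdr$reject, , drop = FALSE]
  out <- data.frame(
    type = rep("probe", nrow(calls)),
    chrom = sub(":.*", "", calls$key),
    left_pos = as.numeric(vapply(strsplit(calls$key, ":"), `[`, "", 2)),
    right_pos = as.numeric(vapply(strsplit(calls$key, ":"), `[`, "", 3)),
    direction = calls$direction,
    h_support = vapply(res[fdr$reject], `[[`, numeric(1), "h_star"),
    support_ids = vapply(res[fdr$reject], function(z)
      paste(ids[z$support], collapse = ","), ""),
    p = calls$p, q = calls$q, status = rep("pass", nrow(calls)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$chrom, out$left_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_hypotheses") <- nrow(hyp)
  out
}

check_shared_grid <- function(fit) {
  for (ch in fit$chroms) {
    ref <- NULL
    for (sid in fit$sample_ids) {
      e <- fit$fits[[sid]][[ch]]
      if (is.null(e)) next
      if (is.null(ref)) ref <- e$profile$pos
      else if (!identical(ref, e$profile$pos))
        stop("probe grids differ across individuals on ", ch)
    }
  }
  invisible(TRUE)
}

# per-individual per-gene interval statistics shared by the interval and pair
# scans: posterior hit probability, direction (90% rule), gap count, log-odds
gene_interval_stats <- function(fit, genes) {
  ids <- fit$sample_ids
  m <- length(ids)
  G <- nrow(genes)
  S <- fit$n_samples
  p <- matrix(0, G, m, dimnames = list(genes$name, ids))
  dir <- matrix(NA_character_, G, m, dimnames = list(genes$name, ids))
  w <- matrix(0L, G, m)
  ell <- matrix(NA_real_, G, m, dimnames = list(genes$name, ids))
  gapsets <- vector("list", G * m)
  dim(gapsets) <- c(G, m)
  for (jm in seq_len(m)) {
    sid <- ids[jm]
    for (g in seq_len(G)) {
      e <- fit$fits[[sid]][[genes$chrom[g]]]
      if (is.null(e)) next
      gw <- gaps_in_interval(e, genes$start[g], genes$end[g])
      w[g, jm] <- length(gw)
      gapsets[[g, jm]] <- gw
      if (length(gw) == 0) next
      ip <- interval_prob_tok(e$tok, S, gw)
      p[g, jm] <- ip$p
      dir[g, jm] <- ip$direction
      pf <- prior_breakpoint_free_probability(e$n, length(gw), e$prior_k)
      ell[g, jm] <- interval_log_odds(ip$p, pf, S)
    }
  }
  list(p = p, dir = dir, w = w, ell = ell, gapsets = gapsets, ids = ids,
       genes = genes)
}

#' Scan a cohort for recurrent interval (gene) breakpoints
#'
#' Detects breakpoints that recur within the same genomic interval even when
#' their probe-level positions differ between individuals.  Per individual and
#' gene a log-odds score compares the posterior probability of a breakpoint
#' inside the gene against the size-dependent prior; scores are
#' rank-normalised within each individual over all scorable genes and
#' combined with the binomial order statistic, separately per direction of
#' copy change (an individual supports direction `d` only if its in-gene
#' breakpoints satisfy the 90% direction rule for `d`; undetermined
#' individuals take the worst rank for both directions).
#'
#' @param fit A [segment_cohort()] fit.
#' @param genes Data frame with `name`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (see [read_gene_regions()]).
#' @param h_min Minimum supporting individuals.
#' @param fdr_alpha FDR level.
#' @return Data frame of calls: `type = "interval"`, `gene`, `chrom`, `start`,
#'   `end`, `direction`, `h_support`, `support_ids`, `p`, `q`, `status`.
#'   Attributes: `n_hypotheses`, `non_scorable` (genes spanning < 1 gap in
#'   every individual).
#' @export
scan_recurrent_interval_breakpoints <- function(fit, genes, h_min = 4,
                                                fdr_alpha = 0.01) {
  st <- gene_interval_stats(fit, genes)
  scorable_any <- rowSums(st$w >= 1) > 0
  non_scorable <- genes$name[!scorable_any]
  gsc <- which(scorable_any)
  m <- length(st$ids)

  # within-individual ranks over that individual's scorable genes
  rho <- matrix(1, nrow(genes), m, dimnames = dimnames(st$ell))
  for (jm in seq_len(m)) {
    sc <- which(st$w[, jm] >= 1)
    if (length(sc) > 0)
      rho[sc, jm] <- suppressWarnings(normalized_rank(st$ell[sc, jm]))
  }

  hyp <- expand.grid(g = gsc, direction = c("+", "-"),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(hyp)), function(r) {
    g <- hyp$g[r]
    rr <- ifelse(!is.na(st$dir[g, ]) & st$dir[g, ] == hyp$direction[r],
                 rho[g, ], 1)
    binomial_order_pvalue(rr, h_min)
  })
  hyp$p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- bh_fdr(hyp$p, fdr_alpha)

  sel <- which(fdr$reject)
  out <- data.frame(
    type = rep("interval", length(sel)),
    gene = genes$name[hyp$g[sel]],
    chrom = genes$chrom[hyp$g[sel]],
    start = genes$start[hyp$g[sel]],
    end = genes$end[hyp$g[sel]],
    direction = hyp$direction[sel],
    h_support = vapply(res[sel], `[[`, numeric(1), "h_star"),
    support_ids = vapply(res[sel], function(z)
      paste(st$ids[z$support], collapse = ","), ""),
    p = hyp$p[sel], q = fdr$q[sel],
    status = rep("pass", length(sel)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_hypotheses") <- nrow(hyp)
  attr(out, "non_scorable") <- non_scorable
  out
}

#' Scan a cohort for recurrent pairs of breakpoints
#'
#' Tests pairs of non-overlapping units -- gene regions (`type = "gene"`,
#' genome-wide pairs, the fusion-gene substrate) or single probe gaps
#' (`type = "probe"`, pairs within one chromosome arm, the structural-variant
#' substrate) -- for breakpoints co-occurring in the same individuals.  Per
#' individual a joint log-odds score compares the joint posterior hit
#' probability of the pair against its combinatorial prior; scores are
#' rank-normalised against the empirical distribution over a seeded random
#' background of non-overlapping pairs plus all candidates, and combined with
#' the binomial order statistic for each of the four direction combinations.
#'
#' Exhaustively scoring all pairs is prohibitive, so candidates are
#' pre-filtered to pairs where at least `h_min` individuals have posterior
#' interval probability `>= min_prob` in both members.
#'
#' @param fit A [segment_cohort()] fit.
#' @param genes Gene regions (required for `type = "gene"`).
#' @param type `"gene"` or `"probe"`.
#' @param h_min Minimum supporting individuals.
#' @param fdr_alpha FDR level.
#' @param background_pairs Number of random background pairs for rank
#'   normalisation; capped (with a warning) at the number available.
#' @param seed Seed for background-pair sampling.
#' @param cytobands Optional data frame (`chrom`, `start`, `end`, `arm`)
#'   restricting probe pairs to one arm; with `NULL` each chromosome is one
#'   arm (warning).
#' @param min_prob Candidate pre-filter threshold on the per-individual
#'   interval probability.
#' @return Data frame of calls: `type = "gene_pair"`/`"probe_pair"`, member
#'   loci, `direction1`, `direction2`, `h_support`, `support_ids`, `p`, `q`,
#'   `status`; attribute `n_hypotheses`.
#' @export
scan_recurrent_pairs <- function(fit, genes = NULL,
                                 type = c("gene", "probe"),
                                 h_min = 4, fdr_alpha = 0.01,
                                 background_pairs = 1e5, seed,
                                 cytobands = NULL, min_prob = 0.1) {
  type <- match.arg(type)
  if (missing(seed)) stop("seed is required")
  if (type == "gene") {
    if (is.null(genes)) stop("genes required for gene-pair scan")
    units <- genes[, c("name", "chrom", "start", "end")]
  } else {
    units <- probe_units(fit, cytobands)
  }
  st <- gene_interval_stats(fit, units)
  ids <- st$ids
  m <- length(ids)
  U <- nrow(units)
  if (U < 2) return(empty_pair_calls(type))

  ok_pair <- function(a, b) {
    if (units$chrom[a] != units$chrom[b]) {
      if (type == "probe") return(FALSE)
      return(TRUE)
    }
    if (type == "probe" && !is.null(units$arm) &&
        units$arm[a] != units$arm[b]) return(FALSE)
    units$end[a] <= units$start[b] || units$end[b] <= units$start[a]
  }

  # candidate pre-filter
  strong <- st$p >= min_prob  # U x m
  n_strong_both <- function(a, b) sum(strong[a, ] & strong[b, ])
  cand <- list()
  hot <- which(rowSums(strong) >= h_min)
  if (length(hot) >= 2) {
    cmb <- combn(hot, 2)
    for (q in seq_len(ncol(cmb))) {
      a <- cmb[1, q]; b <- cmb[2, q]
      if (ok_pair(a, b) && n_strong_both(a, b) >= h_min)
        cand[[length(cand) + 1]] <- c(a, b)
    }
  }
  if (length(cand) == 0) return(empty_pair_calls(type))
  cand <- do.call(rbind, cand)

  # background pairs: exhaustive when the pair space is small, else a seeded
  # random draw
  if (choose(U, 2) <= background_pairs) {
    bg <- t(combn(U, 2))
  } else {
    bg <- with_seed(seed, {
      ntry <- as.integer(min(background_pairs * 4, 2^28))
      a <- sample.int(U, ntry, replace = TRUE)
      b <- sample.int(U, ntry, replace = TRUE)
      keep <- a != b
      lo <- pmin(a, b)[keep]
      hi <- pmax(a, b)[keep]
      unique(cbind(lo, hi))
    })
  }
  valid <- vapply(seq_len(nrow(bg)), function(r) ok_pair(bg[r, 1], bg[r, 2]),
                  logical(1))
  bg <- bg[valid, , drop = FALSE]
  if (nrow(bg) > background_pairs) bg <- bg[seq_len(background_pairs), ,
                                            drop = FALSE]
  if (nrow(bg) < background_pairs)
    warning("fewer background pairs available than requested; using ",
            nrow(bg))

  allp <- unique(rbind(bg, cand))
  P <- nrow(allp)
  is_cand <- apply(allp, 1, function(r)
    any(cand[, 1] == r[1] & cand[, 2] == r[2]))

  # joint log-odds per pair per individual
  S <- fit$n_samples
  ell <- matrix(NA_real_, P, m)
  for (jm in seq_len(m)) {
    sid <- ids[jm]
    for (r in seq_len(P)) {
      a <- allp[r, 1]; b <- allp[r, 2]
      wa <- st$w[a, jm]; wb <- st$w[b, jm]
      if (wa < 1 || wb < 1) { ell[r, jm] <- NA; next }
      cha <- units$chrom[a]; chb <- units$chrom[b]
      ea <- fit$fits[[sid]][[cha]]
      if (cha == chb) {
        da <- hit_draws_tok(ea$tok, st$gapsets[[a, jm]])
        db <- hit_draws_tok(ea$tok, st$gapsets[[b, jm]])
        qq <- length(intersect(da, db)) / S
        pri <- pair_prior_probability(ea$n, wa, wb, ea$prior_k)
      } else {
        eb <- fit$fits[[sid]][[chb]]
        qq <- st$p[a, jm] * st$p[b, jm]
        pri <- pair_prior_probability(ea$n, wa, wb, ea$prior_k,
                                      eb$n, eb$prior_k)
      }
      ell[r, jm] <- pair_log_odds(qq, pri, S)
    }
  }

  # within-individual ranks over scorable pairs (background + candidates)
  rho <- matrix(1, P, m)
  for (jm in seq_len(m)) {
    sc <- which(!is.na(ell[, jm]))
    if (length(sc) > 0)
      rho[sc, jm] <- suppressWarnings(normalized_rank(ell[sc, jm]))
  }

  combos <- cbind(c("+", "+", "-", "-"), c("+", "-", "+", "-"))
  ci <- which(is_cand)
  hyp <- expand.grid(r = ci, cb = 1:4)
  res <- lapply(seq_len(nrow(hyp)), function(i) {
    r <- hyp$r[i]; cb <- hyp$cb[i]
    a <- allp[r, 1]; b <- allp[r, 2]
    match_d <- !is.na(st$dir[a, ]) & st$dir[a, ] == combos[cb, 1] &
      !is.na(st$dir[b, ]) & st$dir[b, ] == combos[cb, 2]
    rr <- ifelse(match_d, rho[r, ], 1)
    binomial_order_pvalue(rr, h_min)
  })
  hyp$p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- bh_fdr(hyp$p, fdr_alpha)
  sel <- which(fdr$reject)

  out <- data.frame(
    type = rep(if (type == "gene") "gene_pair" else "probe_pair",
               length(sel)),
    name1 = units$name[allp[hyp$r[sel], 1]],
    chrom1 = units$chrom[allp[hyp$r[sel], 1]],
    start1 = units$start[allp[hyp$r[sel], 1]],
    end1 = units$end[allp[hyp$r[sel], 1]],
    name2 = units$name[allp[hyp$r[sel], 2]],
    chrom2 = units$chrom[allp[hyp$r[sel], 2]],
    start2 = units$start[allp[hyp$r[sel], 2]],
    end2 = units$end[allp[hyp$r[sel], 2]],
    direction1 = combos[hyp$cb[sel], 1],
    direction2 = combos[hyp$cb[sel], 2],
    h_support = vapply(res[sel], `[[`, numeric(1), "h_star"),
    support_ids = vapply(res[sel], function(z)
      paste(ids[z$support], collapse = ","), ""),
    p = hyp$p[sel], q = fdr$q[sel],
    status = rep("pass", length(sel)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$name1, out$name2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_hypotheses") <- nrow(hyp)
  out
}

empty_pair_calls <- function(type) {
  out <- data.frame(type = character(0), name1 = character(0),
                    chrom1 = character(0), start1 = numeric(0),
                    end1 = numeric(0), name2 = character(0),
                    chrom2 = character(0), start2 = numeric(0),
                    end2 = numeric(0), direction1 = character(0),
                    direction2 = character(0), h_support = numeric(0),
                    support_ids = character(0), p = numeric(0),
                    q = numeric(0), status = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_hypotheses") <- 0L
  out
}

# single-gap pseudo-units for the probe-pair (structural variant) scan;
# each unit is the open interval covering one original-grid gap
probe_units <- function(fit, cytobands = NULL) {
  check_shared_grid(fit)
  if (is.null(cytobands))
    warning("no cytobands supplied; treating each chromosome as one arm")
  tabs <- list()
  sid1 <- fit$sample_ids[1]
  for (ch in fit$chroms) {
    e <- fit$fits[[sid1]][[ch]]
    if (is.null(e)) next
    gk <- gap_keys(e)
    gk <- gk[gk$adjacent, , drop = FALSE]
    if (nrow(gk) == 0) next
    tab <- data.frame(name = paste0(ch, ":", gk$lpos, "-", gk$rpos),
                      chrom = ch, start = gk$lpos, end = gk$rpos + 1,
                      stringsAsFactors = FALSE)
    if (!is.null(cytobands)) {
      cb <- cytobands[cytobands$chrom == ch, , drop = FALSE]
      mid <- (tab$start + tab$end) / 2
      tab$arm <- vapply(mid, function(x) {
        i <- which(cb$start <= x & x < cb$end)
        if (length(i) == 0) NA_character_ else cb$arm[i[1]]
      }, "")
    }
    tabs[[ch]] <- tab
  }
  do.call(rbind, tabs)
}
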