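#' Read a multi-sample probe ratio table
#'
#' Expects a tab-delimited file with header `chrom  position  <sample1> ...`;
#' one row per probe, one numeric column per sample.  Returns one profile per
#' (sample, chromosome).  Non-numeric or missing cells are masked, not
#' imputed.  Unsorted rows are sorted with a warning; duplicate positions
#' within a chromosome are an error.
#'
#' @param path File path.
#' @param sample_columns Optional character vector restricting which sample
#'   columns to read.
#' @param coords `"zero"` (default) or `"one"`: coordinate convention of the
#'   file; 1-based positions are shifted to the internal 0-based convention.
#' @return List of [cn_profile()] objects.
#' @export
read_probe_table <- function(path, sample_columns = NULL,
                             coords = c("zero", "one")) {
  coords <- match.arg(coords)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !all(c("chrom", "position") %in% names(df)[1:2]))
    stop("probe table must start with columns 'chrom', 'position'")
  samples <- setdiff(names(df), c("chrom", "position"))
  if (!is.null(sample_columns)) {
    missing_cols <- setdiff(sample_columns, samples)
    if (length(missing_cols) > 0)
      stop("sample columns not in file: ", paste(missing_cols, collapse = ","))
    samples <- sample_columns
  }
  if (coords == "one") df$position <- df$position - 1
  profiles <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (anyDuplicated(sub$position))
      stop("duplicate positions on ", ch)
    for (s in samples) {
      v <- suppressWarnings(as.numeric(sub[[s]]))
      profiles[[length(profiles) + 1]] <-
        cn_profile(s, ch, sub$position, v)
    }
  }
  profiles
}

#' Write a probe ratio table
#'
#' Inverse of [read_probe_table()] for profiles sharing one probe grid.
#'
#' @param profiles List of [cn_profile()] (one per sample and chromosome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(profiles, path) {
  ids <- unique(vapply(profiles, `[[`, "", "sample_id"))
  chroms <- unique(vapply(profiles, `[[`, "", "chrom"))
  rows <- list()
  for (ch in chroms) {
    ps <- Filter(function(p) p$chrom == ch, profiles)
    pos <- ps[[1]]$pos
    df <- data.frame(chrom = ch, position = pos)
    for (p in ps) {
      stopifnot(identical(p$pos, pos))
      v <- p$value
      v[p$mask & !is.finite(p$value)] <- NA
      df[[p$sample_id]] <- v
    }
    rows[[ch]] <- df
  }
  out <- do.call(rbind, rows)
  out$position <- format(out$position, scientific = FALSE, trim = TRUE)
  for (s in ids) out[[s]] <- ifelse(is.na(out[[s]]), "NA",
                                    formatC(out[[s]], digits = 10,
                                            format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read gene regions from a BED6 file
#'
#' Columns: chrom, start, end, name, score, strand.  Strand is mandatory --
#' the fusion configuration rule needs it.  Intervals are 0-based half-open;
#' pass `coords = "one"` for 1-based inclusive dumps.
#'
#' @param path File path.
#' @param coords `"zero"` (default) or `"one"`.
#' @return Data frame: `name`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_regions <- function(path, coords = c("zero", "one")) {
  coords <- match.arg(coords)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6) stop("gene regions require BED6 (strand is needed)")
  out <- data.frame(name = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    strand = as.character(df[[6]]),
                    stringsAsFactors = FALSE)
  if (coords == "one") out$start <- out$start - 1
  if (any(!out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  if (any(!is.finite(out$start) | !is.finite(out$end) |
          out$start >= out$end))
    stop("gene regions must satisfy start < end")
  out
}

#' Write gene regions as BED6
#' @param genes Data frame from [read_gene_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_regions <- function(genes, path) {
  out <- data.frame(genes$chrom,
                    format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE),
                    genes$name, 0, genes$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a known-variant catalogue (BED3+ / DGV-style TSV)
#'
#' Accepts plain BED3 (no header) or a tab-delimited export with a header
#' containing `chrom`, `start`, `end` and optionally `variant_id`.
#'
#' @param path File path.
#' @param coords `"zero"` (default) or `"one"`.
#' @return Data frame: `chrom`, `start`, `end`, `variant_id`.  Overlapping
#'   records are preserved; an empty file yields an empty catalogue.
#' @export
read_known_variants <- function(path, coords = c("zero", "one")) {
  coords <- match.arg(coords)
  first <- readLines(path, n = 1)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), variant_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(first) == 0) return(empty)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- read.delim(path, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  if (has_header) {
    names(df) <- tolower(names(df))
    out <- data.frame(chrom = as.character(df$chrom),
                      start = as.numeric(df$start),
                      end = as.numeric(df$end),
                      variant_id = if ("variant_id" %in% names(df))
                        as.character(df$variant_id)
                      else paste0("v", seq_len(nrow(df))),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = as.character(df[[1]]),
                      start = as.numeric(df[[2]]),
                      end = as.numeric(df[[3]]),
                      variant_id = if (ncol(df) >= 4)
                        as.character(df[[4]])
                      else paste0("v", seq_len(nrow(df))),
                      stringsAsFactors = FALSE)
  }
  if (coords == "one") out$start <- out$start - 1
  if (any(!is.finite(out$start) | !is.finite(out$end) |
          out$start >= out$end))
    stop("malformed variant coordinates (need start < end)")
  out
}

#' Write prediction tables
#'
#' Serialises any of the call/prediction data frames produced by the scans,
#' [assemble_predictions()] and [add_rms_scores()] to a tab-delimited file
#' with a fixed, documented column set.  Output is byte-identical across
#' reruns with identical inputs and seed.  Fusion rows carry the 5' and 3'
#' partner genes.
#'
#' @param calls A call/prediction data frame (possibly empty or `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(calls, path) {
  cols <- c("type", "chrom", "left_pos", "right_pos", "gene", "start", "end",
            "name1", "chrom1", "start1", "end1", "name2", "chrom2", "start2",
            "end2", "direction", "direction1", "direction2", "gene_5p",
            "gene_3p", "h_support", "support_ids", "p", "q", "rms", "status")
  if (is.null(calls)) calls <- data.frame()
  for (cl in setdiff(cols, names(calls))) calls[[cl]] <- rep(NA, nrow(calls))
  write_tsv_stable(calls[, cols, drop = FALSE], path)
}

#' Export the posterior mean segmentation
#'
#' Averages, probe by probe, the posterior segment level over all sampled
#' segmentations (levels are posterior means, so single-draw exports show the
#' usual shrinkage toward `mu0`), then merges runs of equal adjacent values
#' into SEG-style rows `sample  chrom  start  end  n_probes  mean_log2`.
#'
#' @param profile A [cn_profile()].
#' @param samples Matching `bp_samples`.
#' @param path Output path.
#' @return The per-probe mean level vector, invisibly.
#' @export
write_mean_segmentation <- function(profile, samples, path) {
  up <- unmasked_pos(profile)
  n <- samples$n
  acc <- numeric(n)
  for (s in seq_len(samples$n_samples)) {
    gaps <- samples$gaps[[s]]
    lv <- samples$levels[[s]]
    bounds <- c(0L, gaps, n)
    for (seg in seq_along(lv))
      acc[(bounds[seg] + 1):bounds[seg + 1]] <-
        acc[(bounds[seg] + 1):bounds[seg + 1]] + lv[seg]
  }
  mean_lv <- acc / samples$n_samples
  r <- rle(mean_lv)
  endi <- cumsum(r$lengths)
  starti <- c(1, head(endi, -1) + 1)
  df <- data.frame(sample = profile$sample_id, chrom = profile$chrom,
                   start = format(up[starti], scientific = FALSE, trim = TRUE),
                   end = format(up[endi], scientific = FALSE, trim = TRUE),
                   n_probes = r$lengths, mean_log2 = fmt_num(r$values, 10))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(mean_lv)
}
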