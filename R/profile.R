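#' Copy-number profile for one individual on one chromosome
#'
#' Holds ordered probe midpoints (0-based bp) and log2 test:reference ratios,
#' plus a per-probe exclusion mask.  All downstream analysis operates on the
#' unmasked probe subsequence; gap index `g` always refers to the boundary
#' between unmasked probes `g` and `g + 1`.
#'
#' @param sample_id Sample identifier.
#' @param chrom Chromosome name.
#' @param pos Integer-ish vector of probe positions (bp), strictly increasing.
#' @param value Numeric log2 ratios, one per probe.  Non-finite values are
#'   masked automatically.
#' @param mask Logical vector; `TRUE` marks a probe excluded from analysis.
#' @return An object of class `cn_profile`.
#' @examples
#' p <- cn_profile("s1", "chr1", c(100, 200, 300), c(0.1, 0.0, 1.2))
#' n_unmasked(p)
#' @export
cn_profile <- function(sample_id, chrom, pos, value, mask = NULL) {
  pos <- as.numeric(pos)
  value <- as.numeric(value)
  if (length(pos) != length(value))
    stop("pos and value must have equal length")
  if (is.null(mask)) mask <- rep(FALSE, length(pos))
  mask <- as.logical(mask) | !is.finite(value)
  if (is.unsorted(pos, strictly = FALSE)) {
    o <- order(pos)
    pos <- pos[o]; value <- value[o]; mask <- mask[o]
    warning("probe positions were unsorted; sorting")
  }
  if (anyDuplicated(pos))
    stop("duplicate probe positions within chromosome ", chrom)
  structure(
    list(sample_id = as.character(sample_id), chrom = as.character(chrom),
         pos = pos, value = value, mask = mask),
    class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s %s: %d probes (%d masked)\n",
              x$sample_id, x$chrom, length(x$pos), sum(x$mask)))
  invisible(x)
}

#' Number of unmasked probes in a profile
#' @param profile A [cn_profile()].
#' @return Integer count.
#' @export
n_unmasked <- function(profile) sum(!profile$mask)

# unmasked view: values and positions entering the model
unmasked_values <- function(profile) profile$value[!profile$mask]
unmasked_pos <- function(profile) profile$pos[!profile$mask]

assert_profile <- function(profile) {
  if (!inherits(profile, "cn_profile")) stop("not a cn_profile")
  if (n_unmasked(profile) < 2)
    stop("need >= 2 unmasked probes for segmentation")
  invisible(profile)
}
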