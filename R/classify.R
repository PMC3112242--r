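#' Check the fusion-gene configuration of a recurrent gene pair
#'
#' A fusion joins the 5' end of one gene to the 3' end of the other.  From
#' copy-number data, the side of a gene retained in the fusion is the
#' higher-copy side of its breakpoint: the genomic-right side when the copy
#' change across the in-gene breakpoint is positive (`dir = "+"`), the
#' genomic-left side otherwise.  That retained side is the gene's own 3' end
#' exactly when `orient(G) * dir(G) = +` (plus-strand gene keeping its right
#' side, or minus-strand gene keeping its left side).  A valid fusion needs
#' exactly one 5' and one 3' contribution, i.e.
#' `orient(G1) * dir(G1) * orient(G2) * dir(G2) = -1`; the 5' partner is the
#' gene with `orient * dir = -`.
#'
#' @param orient1,orient2 Gene strands, `"+"` or `"-"`.
#' @param dir1,dir2 Copy-change directions of the recurrent breakpoints in
#'   the two genes, `"+"` or `"-"`.
#' @return List: `valid` (logical) and `five_prime_gene` (1 or 2; `NA` when
#'   invalid).  Vectorised over all four arguments.
#' @examples
#' # deletion between two minus-strand genes, right flank rising:
#' fusion_configuration_valid("-", "+", "-", "-")
#' @export
fusion_configuration_valid <- function(orient1, dir1, orient2, dir2) {
  sgn <- function(z) ifelse(z == "+", 1L, ifelse(z == "-", -1L, NA_integer_))
  s1 <- sgn(orient1) * sgn(dir1)
  s2 <- sgn(orient2) * sgn(dir2)
  if (any(is.na(s1) | is.na(s2))) stop("orientations/directions must be + or -")
  valid <- s1 * s2 == -1L
  list(valid = valid,
       five_prime_gene = ifelse(valid, ifelse(s1 == -1L, 1L, 2L), NA_integer_))
}

#' Assemble typed predictions from recurrent calls
#'
#' Routes the three recurrence scans into prediction classes: intra-arm probe
#' pairs become structural variants; single-gene interval calls become gene
#' truncations; gene-pair calls are screened with
#' [fusion_configuration_valid()] -- pairs passing it become fusion
#' predictions with 5'/3' partner assignment, the rest are retained as
#' generic gene pairs.
#'
#' @param probe_pair_calls Calls from [scan_recurrent_pairs()] with
#'   `type = "probe"`, or `NULL`.
#' @param gene_calls Calls from [scan_recurrent_interval_breakpoints()], or
#'   `NULL`.
#' @param gene_pair_calls Calls from [scan_recurrent_pairs()] with
#'   `type = "gene"`, or `NULL`.
#' @param genes Gene regions (needed for strands of fusion partners).
#' @return List of data frames: `structural_variants`, `truncations`,
#'   `fusions` (with `gene_5p`, `gene_3p`, `dir_5p`, `dir_3p`,
#'   `interchromosomal`), `other_pairs` (gene pairs failing the configuration
#'   rule).
#' @export
assemble_predictions <- function(probe_pair_calls = NULL, gene_calls = NULL,
                                 gene_pair_calls = NULL, genes = NULL) {
  sv <- probe_pair_calls
  if (!is.null(sv) && nrow(sv) > 0) sv$type <- "structural_variant"

  tr <- gene_calls
  if (!is.null(tr) && nrow(tr) > 0) tr$type <- "truncation"

  fusions <- NULL
  others <- NULL
  gp <- gene_pair_calls
  if (!is.null(gp) && nrow(gp) > 0) {
    if (is.null(genes)) stop("genes required to classify gene pairs")
    strand <- setNames(genes$strand, genes$name)
    cfg <- fusion_configuration_valid(strand[gp$name1], gp$direction1,
                                      strand[gp$name2], gp$direction2)
    gp$interchromosomal <- gp$chrom1 != gp$chrom2
    fus <- gp[cfg$valid, , drop = FALSE]
    fp <- cfg$five_prime_gene[cfg$valid]
    if (nrow(fus) > 0) {
      fus$gene_5p <- ifelse(fp == 1L, fus$name1, fus$name2)
      fus$gene_3p <- ifelse(fp == 1L, fus$name2, fus$name1)
      fus$dir_5p <- ifelse(fp == 1L, fus$direction1, fus$direction2)
      fus$dir_3p <- ifelse(fp == 1L, fus$direction2, fus$direction1)
      fus$type <- "fusion"
    }
    fusions <- fus
    others <- gp[!cfg$valid, , drop = FALSE]
  }
  list(structural_variants = sv, truncations = tr, fusions = fusions,
       other_pairs = others)
}
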