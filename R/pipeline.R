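#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults.
#' Any subset can be overridden via `...` or by a YAML config file passed to
#' [run_pipeline()].
#'
#' @param ... Name-value overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window = 10, sigma2_rule = "2V", sigma0_rule = "M2",
    p_single = 0.5, k_max = 50, n_samples = 1000,
    h_min = 4, fdr_alpha = 0.01, normal_fdr = 0.1,
    background_pairs = 1e5, min_prob = 0.1,
    proximity_bp = 10000, mutual_overlap_min = 0.5,
    tau = NULL, delta = NULL, flank = 3,
    mask_singletons = TRUE, run_probe_pairs = TRUE)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ","))
  cfg[names(over)] <- over
  cfg
}

#' Run the full recurrent-breakpoint pipeline
#'
#' Orchestrates all stages: single-probe-aberration masking, per-profile
#' hyperparameter estimation, segmentation DP and posterior sampling, the
#' probe / interval / pair recurrence scans, classification into structural
#' variants, truncations and fusions, known-variant and matched-normal
#' filtering, and RMS ranking; writes one TSV per prediction class plus a
#' mean-segmentation export and a run log.  The run is a pure function of
#' (inputs, config, seed): reruns are byte-identical.
#'
#' @param profiles List of [cn_profile()] for the (tumor) cohort, or a probe
#'   table path.
#' @param genes Gene regions data frame or BED6 path (`NULL` skips the
#'   interval and gene-pair scans).
#' @param known_variants Catalogue data frame or path (`NULL` skips the
#'   filter).
#' @param normal_profiles Matched-normal profiles or probe table path
#'   (`NULL` skips subtraction).
#' @param config List from [pipeline_config()] or a YAML file path.
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param cytobands Optional cytoband data frame for arm-restricted probe
#'   pairs.
#' @return List with `fit`, `calls` (per scan), `predictions` (typed lists),
#'   `log` (character vector), and `files` (paths written).
#' @export
run_pipeline <- function(profiles, genes = NULL, known_variants = NULL,
                         normal_profiles = NULL, config = pipeline_config(),
                         seed, out_dir = NULL, cytobands = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  if (is.character(profiles)) profiles <- read_probe_table(profiles)
  if (is.character(genes)) genes <- read_gene_regions(genes)
  if (is.character(known_variants))
    known_variants <- read_known_variants(known_variants)
  if (is.character(normal_profiles))
    normal_profiles <- read_probe_table(normal_profiles)

  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  say("pipeline seed=%d individuals=%d", seed,
      length(unique(vapply(profiles, `[[`, "", "sample_id"))))

  fit <- stage("segment", segment_cohort(
    profiles, n_samples = config$n_samples, seed = seed,
    mask_singletons = config$mask_singletons, window = config$window,
    sigma2_rule = config$sigma2_rule, sigma0_rule = config$sigma0_rule,
    p_single = config$p_single, k_max = config$k_max))
  for (sid in fit$sample_ids) for (ch in names(fit$fits[[sid]])) {
    h <- fit$fits[[sid]][[ch]]$hyper
    say("hyper %s %s: mu0=%.4g sigma2=%.4g sigma0_2=%.4g zero_bp=%s",
        sid, ch, h$mu0, h$sigma2, h$sigma0_2, h$zero_breakpoints)
  }

  probe_calls <- stage("recur-probes", scan_recurrent_probe_breakpoints(
    fit, h_min = config$h_min, fdr_alpha = config$fdr_alpha))
  say("probe scan: %d hypotheses, %d calls",
      attr(probe_calls, "n_hypotheses"), nrow(probe_calls))

  gene_calls <- NULL; gene_pair_calls <- NULL
  if (!is.null(genes)) {
    gene_calls <- stage("recur-genes", scan_recurrent_interval_breakpoints(
      fit, genes, h_min = config$h_min, fdr_alpha = config$fdr_alpha))
    say("interval scan: %d hypotheses, %d calls",
        attr(gene_calls, "n_hypotheses"), nrow(gene_calls))
    gene_pair_calls <- stage("recur-pairs", suppressWarnings(
      scan_recurrent_pairs(
        fit, genes, type = "gene", h_min = config$h_min,
        fdr_alpha = config$fdr_alpha,
        background_pairs = config$background_pairs,
        seed = derive_seed(seed, 9001), min_prob = config$min_prob)))
    say("gene-pair scan: %d hypotheses, %d calls",
        attr(gene_pair_calls, "n_hypotheses"), nrow(gene_pair_calls))
  }

  probe_pair_calls <- NULL
  if (isTRUE(config$run_probe_pairs)) {
    probe_pair_calls <- stage("recur-probe-pairs", suppressWarnings(
      scan_recurrent_pairs(
        fit, type = "probe", h_min = config$h_min,
        fdr_alpha = config$fdr_alpha,
        background_pairs = config$background_pairs,
        seed = derive_seed(seed, 9002), cytobands = cytobands,
        min_prob = config$min_prob)))
    say("probe-pair scan: %d hypotheses, %d calls",
        attr(probe_pair_calls, "n_hypotheses"), nrow(probe_pair_calls))
  }

  # matched normals: lenient-FDR scans on the normal cohort
  if (!is.null(normal_profiles)) {
    nfit <- stage("segment-normals", segment_cohort(
      normal_profiles, n_samples = config$n_samples,
      seed = derive_seed(seed, 9003),
      mask_singletons = config$mask_singletons, window = config$window,
      sigma2_rule = config$sigma2_rule, sigma0_rule = config$sigma0_rule,
      p_single = config$p_single, k_max = config$k_max))
    n_probe <- scan_recurrent_probe_breakpoints(nfit, config$h_min,
                                                config$normal_fdr)
    probe_calls <- subtract_matched_normals(probe_calls, n_probe)
    if (!is.null(genes)) {
      n_gene <- scan_recurrent_interval_breakpoints(nfit, genes, config$h_min,
                                                    config$normal_fdr)
      gene_calls <- subtract_matched_normals(gene_calls, n_gene)
      n_gp <- suppressWarnings(scan_recurrent_pairs(
        nfit, genes, type = "gene", h_min = config$h_min,
        fdr_alpha = config$normal_fdr,
        background_pairs = config$background_pairs,
        seed = derive_seed(seed, 9004), min_prob = config$min_prob))
      gene_pair_calls <- subtract_matched_normals(gene_pair_calls, n_gp)
    }
    say("matched-normal subtraction applied (fdr=%.3g)", config$normal_fdr)
  }

  # known-variant filter
  if (!is.null(known_variants)) {
    probe_calls <- filter_known_variants(probe_calls, known_variants,
                                         config$proximity_bp,
                                         config$mutual_overlap_min)
    gene_calls <- filter_known_variants(gene_calls, known_variants,
                                        config$proximity_bp,
                                        config$mutual_overlap_min)
    gene_pair_calls <- filter_known_variants(gene_pair_calls, known_variants,
                                             config$proximity_bp,
                                             config$mutual_overlap_min)
    probe_pair_calls <- filter_known_variants(probe_pair_calls,
                                              known_variants,
                                              config$proximity_bp,
                                              config$mutual_overlap_min)
    say("known-variant filter applied (%d records)", nrow(known_variants))
  }

  preds <- stage("classify", assemble_predictions(
    probe_pair_calls, gene_calls, gene_pair_calls, genes))
  preds$fusions <- add_rms_scores(preds$fusions, fit, config$flank)
  preds$structural_variants <- add_rms_scores(preds$structural_variants, fit,
                                              config$flank)
  say("predictions: %d SV, %d truncation, %d fusion",
      if (is.null(preds$structural_variants)) 0
      else nrow(preds$structural_variants),
      if (is.null(preds$truncations)) 0 else nrow(preds$truncations),
      if (is.null(preds$fusions)) 0 else nrow(preds$fusions))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wp <- function(df, nm) {
      f <- file.path(out_dir, nm)
      write_predictions(df, f)
      files <<- c(files, f)
    }
    wp(probe_calls, "probe_breakpoints.tsv")
    if (!is.null(genes)) {
      wp(gene_calls, "gene_breakpoints.tsv")
      wp(preds$fusions, "fusions.tsv")
      wp(preds$other_pairs, "gene_pairs_other.tsv")
      wp(preds$truncations, "truncations.tsv")
    }
    wp(preds$structural_variants, "structural_variants.tsv")
    segf <- file.path(out_dir, "mean_segmentation.tsv")
    seg_lines <- character(0)
    for (sid in fit$sample_ids) for (ch in names(fit$fits[[sid]])) {
      e <- fit$fits[[sid]][[ch]]
      tmp <- tempfile()
      write_mean_segmentation(e$profile, e$samples, tmp)
      l <- readLines(tmp)
      unlink(tmp)
      if (length(seg_lines) > 0) l <- l[-1]
      seg_lines <- c(seg_lines, l)
    }
    writeLines(seg_lines, segf)
    files <- c(files, segf)
    writeLines(logline, file.path(out_dir, "run_log.txt"))
    files <- c(files, file.path(out_dir, "run_log.txt"))
  }

  list(fit = fit,
       calls = list(probe = probe_calls, gene = gene_calls,
                    gene_pair = gene_pair_calls,
                    probe_pair = probe_pair_calls),
       predictions = preds, log = logline, files = files)
}
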