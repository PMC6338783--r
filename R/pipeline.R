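#' Assemble a pipeline configuration
#'
#' Collects the generator settings and every stage threshold in one list
#' that round-trips losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param generator Named list of [effect_config()] overrides.
#' @param alpha_dmr Bonferroni-adjusted DMR cutoff (default 0.1).
#' @param min_delta,min_cpgs,min_coverage DME thresholds (defaults 0.1,
#'   10, 5).
#' @param r_min eRNA-mRNA pairing threshold (default 0.3).
#' @param alpha_screen Inverse-screen cutoff (default 0.05).
#' @param loss_below,gain_above Signal-change cutoffs (defaults 0.5, 2).
#' @param stitch_bp Super-enhancer stitch distance (default 12500).
#' @param tss_window Promoter window in bp (default 2000).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), alpha_dmr = 0.1,
                            min_delta = 0.1, min_cpgs = 10L,
                            min_coverage = 5L, r_min = 0.3,
                            alpha_screen = 0.05, loss_below = 0.5,
                            gain_above = 2, stitch_bp = 12500L,
                            tss_window = 2000L, seed = 1L,
                            out_dir = tempfile("enhmeth_run_")) {
  stopifnot(alpha_dmr > 0, alpha_dmr <= 1, min_delta > 0, min_cpgs >= 1,
            r_min >= -1, r_min <= 1, alpha_screen > 0, alpha_screen <= 1,
            loss_below > 0, gain_above > loss_below, stitch_bp >= 0,
            tss_window >= 0)
  cfg <- list(generator = generator, alpha_dmr = alpha_dmr,
              min_delta = min_delta, min_cpgs = min_cpgs,
              min_coverage = min_coverage, r_min = r_min,
              alpha_screen = alpha_screen, loss_below = loss_below,
              gain_above = gain_above, stitch_bp = stitch_bp,
              tss_window = tss_window, seed = seed, out_dir = out_dir)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the end-to-end analysis on a generated cohort
#'
#' Executes the stages in dependency order - cohort generation,
#' coverage-based DMR calling, element enrichment, WGBS-style DME calling,
#' enhancer-target pairing and inverse-methylation screening, chromatin
#' classification with super-enhancer calling and the codepletion report,
#' and survival stratification - writing one plain-text output per stage
#' plus a JSON manifest (seed, thresholds, row counts, md5 checksums).
#' Outputs are pure functions of (config, seed): re-running with an
#' identical configuration reproduces them byte for byte. Any stage error
#' aborts the run with the stage name and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  on.exit({
    if (stage != "done") unlink(written)
  })
  emit <- function(df, file) {
    path <- file.path(out, file)
    .write_tsv(df, path)
    written <<- c(written, path)
    path
  }
  counts <- list()
  tryCatch({
    stage <- "generate"
    gen_args <- config$generator
    gen_args$seed <- config$seed
    cfg <- do.call(effect_config, gen_args)
    cohort <- simulate_cohort(cfg)
    anno_path <- file.path(out, "annotation.bed")
    write_bed(cohort$annotation, anno_path)
    written <- c(written, anno_path)
    emit(cohort$truth, "truth.tsv")

    stage <- "call-dmrs"
    norm <- normalize_coverage(cohort$region_signal$counts)
    dmrs <- call_dmrs(norm, cohort$region_signal$pairs,
                      alpha = config$alpha_dmr)
    emit(dmrs, "dmrs.tsv")
    counts$n_dmrs <- nrow(dmrs)
    counts$n_dmr_hypo <- sum(dmrs$direction == "hypo")

    stage <- "enrichment"
    enh <- cohort$annotation[cohort$annotation$element_class == "enhancer"]
    planted <- cohort$truth$region[cohort$truth$planted]
    dme_gr <- enh[enh$name %in% planted]
    enr <- enrichment(dme_gr, cohort$annotation)
    emit(enr, "enrichment.tsv")

    stage <- "call-dmes"
    meth <- cohort$methylomes
    dmes <- call_dmes(meth$tumor[seq_len(cfg$n_wgbs_tumor)], meth$normal,
                      enh, min_delta = config$min_delta,
                      min_cpgs = config$min_cpgs,
                      min_coverage = config$min_coverage)
    emit(dmes[, setdiff(names(dmes), "per_cpg_deltas")], "dmes.tsv")
    counts$n_dmes <- nrow(dmes)
    n_dir <- dme_direction_summary(dmes)
    counts$dme_hypo_fraction <- if (nrow(dmes)) {
      unname(n_dir["n_hypo"] / sum(n_dir))
    } else NA_real_

    stage <- "screen-targets"
    targets <- stats::setNames(cohort$truth$target_gene,
                               cohort$truth$region)
    cand <- data.frame(enhancer = names(targets), gene = unname(targets),
                       stringsAsFactors = FALSE)
    prs <- pair_enhancers_to_genes(cohort$expression$erna,
                                   cohort$expression$mrna, cand,
                                   r_min = config$r_min)
    hits <- screen_inverse_dmes(dmes, cohort$enh_meth,
                                cohort$expression$mrna, prs,
                                alpha = config$alpha_screen)
    emit(hits, "inverse_dme_hits.tsv")
    emit(rank_targets(hits), "ranked_targets.tsv")
    counts$n_inverse_hits <- nrow(hits)

    stage <- "chromatin"
    chip <- cohort$chip
    mc <- S4Vectors::mcols(chip$regions)
    rs <- data.frame(H3K27ac = mc$H3K27ac, H3K4me1 = mc$H3K4me1,
                     H3K4me3 = mc$H3K4me3, H3K27me3 = mc$H3K27me3,
                     background = mc$background)
    cls_df <- data.frame(
      name = mc$name,
      region_class = assign_region_class(chip$regions, chip$tss,
                                         window = config$tss_window),
      active = classify_active_enhancer(rs),
      k27ac_change = classify_signal_change(mc$k27ac_baseline,
                                            mc$k27ac_perturbed,
                                            loss_below = config$loss_below,
                                            gain_above = config$gain_above),
      stringsAsFactors = FALSE)
    emit(cls_df, "enhancer_classes.tsv")
    enh_regions <- chip$regions[mc$element_class == "enhancer"]
    peaks <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(enh_regions)),
      start = GenomicRanges::start(enh_regions) - 1L,
      end = GenomicRanges::end(enh_regions),
      signal = enh_regions$H3K27ac,
      background = enh_regions$background, stringsAsFactors = FALSE)
    ses <- call_super_enhancers(peaks, stitch_bp = config$stitch_bp,
                                tss_exclusion_bp = config$tss_window,
                                tss = chip$tss)
    emit(ses, "superenhancers.tsv")
    counts$n_super <- sum(ses$is_super)
    cod <- codepletion_and_expression(chip$regions, chip$expression_fc,
                                      chip$tss)
    emit(cod$table, "codepletion.tsv")
    counts$frac_reduced <- cod$frac_reduced

    stage <- "survival"
    sv <- cohort$survival_os
    lr <- logrank_test(sv$time, sv$event, sv$stratum)
    emit(sv, "survival_os.tsv")
    emit(km_curve(sv$time, sv$event), "km_os.tsv")
    counts$os_hazard_ratio <- lr$hazard_ratio
    counts$os_logrank_p <- lr$p_value

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("enhmeth")),
      seed = config$seed,
      thresholds = unclass(config)[setdiff(names(config),
                                           c("generator", "out_dir"))],
      counts = counts,
      checksums = as.list(tools::md5sum(sort(written))))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    manifest_path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)
    stage <- "done"
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
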