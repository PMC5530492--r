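# End-to-end orchestration: simulate (or load) -> align -> call -> empirical
# p values -> epigenotype scoring -> flank profiles -> enrichment.

#' Assemble a pipeline configuration
#'
#' Either supply `sim` (simulation parameters; a cohort is generated) or
#' `methylome_paths` + `genotype_path` to load data from disk.
#'
#' @param sim a [sim_params()] object, or NULL to load from files.
#' @param methylome_paths named character vector of per-sample methylome
#'   files (names = sample ids); used when `sim` is NULL.
#' @param methylome_format format for [read_methylome()].
#' @param genotype_path genotype file; `genotype_format` as in
#'   [read_genotypes()].
#' @param genotype_format `"vcf_minimal"` or `"tsv_dosage"`.
#' @param min_cov alignment coverage filter (default 3).
#' @param caller a [caller_params()] object.
#' @param null_replicates binomial-null replicate count (default 1000).
#' @param window_bp,score_threshold SNP scan parameters.
#' @param enrich_sets random sets for enrichment (default 10000; 0 disables
#'   the enrichment stage).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional output directory; when given, all result tables
#'   are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_params(), methylome_paths = NULL,
                       methylome_format = "bismark_cov",
                       genotype_path = NULL, genotype_format = "tsv_dosage",
                       min_cov = 3, caller = caller_params(),
                       null_replicates = 1000, window_bp = 6000,
                       score_threshold = 0.9, enrich_sets = 10000,
                       seed = 1, out_dir = NULL) {
  if (is.null(sim)) {
    if (is.null(methylome_paths) || length(methylome_paths) < 1)
      stop("need sim params or methylome_paths")
    missing <- methylome_paths[!file.exists(methylome_paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    if (!is.null(genotype_path) && !file.exists(genotype_path))
      stop("missing genotype file: ", genotype_path)
  }
  structure(list(sim = sim, methylome_paths = methylome_paths,
                 methylome_format = methylome_format,
                 genotype_path = genotype_path,
                 genotype_format = genotype_format, min_cov = min_cov,
                 caller = caller, null_replicates = null_replicates,
                 window_bp = window_bp, score_threshold = score_threshold,
                 enrich_sets = enrich_sets, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or load methylomes and genotypes; align the cohort;
#' call DMRs on the extreme-methylome envelope; assign empirical p values
#' from the binomial null; fit the beta mixture and score SNPs in windows
#' around every DMR; profile flanking methylation; test annotation
#' enrichment (simulated annotations only, when a simulated genome is
#' available). Deterministic given the config seed. Any stage failure is
#' re-raised with the stage name.
#'
#' @param config a [run_config()] object.
#' @return list of class `run_result`: `dmrs` (with p values), `scores`,
#'   `mixture`, `flanks`, `enrichment` (or NULL), `cohort`, `truth` (or
#'   NULL), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = config$seed, caller = unclass(config$caller),
                   min_cov = config$min_cov,
                   null_replicates = config$null_replicates,
                   window_bp = config$window_bp,
                   score_threshold = config$score_threshold)

  sim <- NULL
  if (!is.null(config$sim)) {
    sim <- stage("simulate", {
      genome <- simulate_genome(config$sim, seed = config$seed)
      simulate_cohort(genome, seed = config$seed + 1L)
    })
    methylomes <- sim$methylomes
    genotypes <- sim$genotypes
    manifest$sim <- unclass(config$sim)
  } else {
    methylomes <- stage("load", {
      stats::setNames(lapply(config$methylome_paths, read_methylome,
                             format = config$methylome_format),
                      names(config$methylome_paths))
    })
    genotypes <- if (!is.null(config$genotype_path))
      stage("load", read_genotypes(config$genotype_path,
                                   config$genotype_format,
                                   samples = names(methylomes)))
    else NULL
  }

  cohort <- stage("align", align_cohort(methylomes, min_cov = config$min_cov))
  manifest$n_sites <- nrow(cohort$sites)
  manifest$n_samples <- length(cohort$samples)

  dmrs <- stage("call", call_dmrs(cohort, config$caller))
  manifest$n_dmrs <- nrow(dmrs)

  null_fit <- NULL
  if (config$null_replicates > 0 && nrow(dmrs) > 0) {
    null_fit <- stage("pvalue",
      empirical_pvalues(cohort, config$caller, R = config$null_replicates,
                        seed = config$seed + 1000L, dmrs = dmrs))
    dmrs <- null_fit$dmrs
    manifest$null_k <- null_fit$k
  }

  scores <- NULL; mixture <- NULL
  # the mixture is fitted on nrow(dmrs) x n_samples pooled core methylations
  if (!is.null(genotypes) && nrow(dmrs) * length(cohort$samples) >= 9) {
    sc <- stage("score",
      score_all_dmrs(dmrs, genotypes, window_bp = config$window_bp,
                     threshold = config$score_threshold))
    scores <- sc$scores
    mixture <- sc$mixture
    manifest$n_scored_snps <- nrow(scores)
  } else if (!is.null(genotypes) && nrow(dmrs) > 0) {
    manifest$score_note <- "too few DMRs to fit the beta mixture"
  }

  flanks <- stage("flanks", flank_profile(dmrs, cohort))

  enrichment <- NULL
  if (!is.null(sim) && config$enrich_sets > 0 && nrow(dmrs) > 0) {
    enrichment <- stage("enrich",
      enrichment_test(dmrs, sim$genome$states,
                      sim$genome$cpg[c("chrom", "pos")],
                      sim$genome$chrom_lengths, mask = sim$genome$repeats,
                      n_sets = config$enrich_sets,
                      seed = config$seed + 2000L))
  }

  res <- structure(list(dmrs = dmrs, scores = scores, mixture = mixture,
                        flanks = flanks, enrichment = enrichment,
                        cohort = cohort, null_fit = null_fit,
                        truth = if (!is.null(sim)) sim$truth else NULL,
                        manifest = manifest),
                   class = "run_result")
  if (!is.null(config$out_dir)) write_run_result(res, config$out_dir)
  res
}

write_run_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dmrs(res$dmrs, file.path(dir, "dmrs.tsv"), "tsv")
  write_dmrs(res$dmrs, file.path(dir, "dmrs.bed"), "bed")
  if (!is.null(res$scores))
    utils::write.table(res$scores, file.path(dir, "snp_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$mixture))
    write_mixture(res$mixture, file.path(dir, "beta_mixture.yaml"))
  utils::write.table(res$flanks, file.path(dir, "flank_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment))
    utils::write.table(res$enrichment, file.path(dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(res$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
#' @method print run_result
print.run_result <- function(x, ...) {
  cat("hap-ASM pipeline result\n")
  cat("  aligned sites:", x$manifest$n_sites, "x", x$manifest$n_samples,
      "samples\n")
  cat("  DMRs called:", x$manifest$n_dmrs, "\n")
  if (!is.null(x$manifest$null_k))
    cat("  null replicates with >= 1 DMR:", x$manifest$null_k, "of",
        x$manifest$null_replicates, "\n")
  if (!is.null(x$scores))
    cat("  SNPs above score threshold:", nrow(x$scores), "\n")
  invisible(x)
}
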