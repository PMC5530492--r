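# Synthetic WGBS cohorts with planted haplotype-dependent allele-specific
# methylation. Reads are simulated at the allele level so counts are exactly
# binomial given the genotype, which is the same sampling model the empirical
# null uses.

#' Simulation parameters for a synthetic WGBS cohort
#'
#' Defaults emulate a five-donor male-monocyte WGBS cohort: ~100 bp mean
#' inter-CpG spacing (exponential gaps), Poisson coverage with mean 30
#' (truncated at 1), hypermethylated background with mean level 0.72, and
#' planted allele-specific DMRs of 4-20 CpGs whose causal SNP genotypes
#' follow Hardy-Weinberg equilibrium at the given minor allele frequency.
#'
#' @param n_samples number of individuals (default 5).
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param cpg_spacing mean inter-CpG gap in bp (exponential, minimum 2 bp).
#' @param coverage_lambda Poisson mean of per-site read coverage (>= 1 after
#'   truncation).
#' @param bg_alpha,bg_beta Beta shape parameters of the per-CpG background
#'   methylation mean; defaults Beta(7.2, 2.8), mean 0.72.
#' @param n_planted_dmrs number of planted allele-specific DMRs.
#' @param dmr_width_cpgs length-2 integer range of planted DMR widths in CpGs.
#' @param maf minor allele frequency of each causal SNP (default 0.5, the
#'   most detectable configuration for a 5-sample design).
#' @param m_hi,m_lo per-read methylation probability on the methylated /
#'   unmethylated epiallele (defaults 0.95 / 0.05).
#' @param epsilon epigenetic mosaicism: probability that a cell's allele
#'   carries the opposite epiallele state (default 0).
#' @param bg_snp_per_mb density of non-causal background SNPs (default 50).
#' @param dmr_internal_gap maximum bp between consecutive CpGs of a planted
#'   DMR (default 250): hap-ASM regions lie in locally CpG-dense sequence.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 5,
                       chrom_lengths = c(chrS1 = 1e6),
                       cpg_spacing = 100,
                       coverage_lambda = 30,
                       bg_alpha = 7.2, bg_beta = 2.8,
                       n_planted_dmrs = 10,
                       dmr_width_cpgs = c(4L, 20L),
                       maf = 0.5,
                       m_hi = 0.95, m_lo = 0.05,
                       epsilon = 0,
                       bg_snp_per_mb = 50,
                       dmr_internal_gap = 250) {
  p <- list(n_samples = as.integer(n_samples),
            chrom_lengths = chrom_lengths,
            cpg_spacing = cpg_spacing,
            coverage_lambda = coverage_lambda,
            bg_alpha = bg_alpha, bg_beta = bg_beta,
            n_planted_dmrs = as.integer(n_planted_dmrs),
            dmr_width_cpgs = as.integer(dmr_width_cpgs),
            maf = maf, m_hi = m_hi, m_lo = m_lo, epsilon = epsilon,
            bg_snp_per_mb = bg_snp_per_mb,
            dmr_internal_gap = dmr_internal_gap)
  stopifnot(p$n_samples >= 1, all(p$chrom_lengths > 0),
            p$cpg_spacing > 0, p$coverage_lambda > 0,
            p$bg_alpha > 0, p$bg_beta > 0, p$n_planted_dmrs >= 0,
            length(p$dmr_width_cpgs) == 2, p$dmr_width_cpgs[1] >= 2)
  probs <- c(p$maf, p$m_hi, p$m_lo, p$epsilon)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  class(p) <- "sim_params"
  p
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  force(code)
}

#' Simulate a CpG landscape with planted DMR positions and annotations
#'
#' CpG positions are laid down with exponential inter-CpG gaps (mean
#' `cpg_spacing`, minimum 2 bp). Planted DMRs occupy non-overlapping runs of
#' consecutive CpGs; each gets a causal SNP within +/- 2 kb of its centre and
#' a random orientation (which allele carries the methylated epiallele).
#' Chromatin-state, gene-feature and repeat-mask annotations tile each
#' chromosome so region-level statistics can be exercised.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `sim_genome` with elements `cpg` (data.frame chrom,
#'   pos, bg_level), `planted` (data.frame of planted DMR skeletons),
#'   `chrom_lengths`, `states`, `features`, `repeats` (region sets).
#' @export
simulate_genome <- function(params = sim_params(), seed = 1) {
  with_seed(seed, {
    cpg <- do.call(rbind, lapply(names(params$chrom_lengths), function(ch) {
      len <- params$chrom_lengths[[ch]]
      n_guess <- ceiling(len / params$cpg_spacing * 1.3) + 50
      gaps <- pmax(2, round(stats::rexp(n_guess, 1 / params$cpg_spacing)))
      pos <- cumsum(c(1 + gaps[1], gaps[-1]))
      pos <- pos[pos <= len - 1]
      data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
    }))
    cpg$bg_level <- stats::rbeta(nrow(cpg), params$bg_alpha, params$bg_beta)

    planted <- plant_dmrs(cpg, params)
    states <- tile_annotation(params$chrom_lengths,
                              labels = c("TssA", "TssFlnk", "Tx", "Enh",
                                         "ReprPC", "Quies"),
                              mean_len = 20000)
    features <- tile_annotation(params$chrom_lengths,
                                labels = c("promoter", "exon", "intron",
                                           "intergenic"),
                                mean_len = 30000)
    repeats <- random_mask(params$chrom_lengths, frac = 0.15,
                           mean_len = 2000, cpg = cpg, planted = planted)
    structure(list(cpg = cpg, planted = planted,
                   chrom_lengths = params$chrom_lengths,
                   states = states, features = features, repeats = repeats,
                   params = params, seed = seed),
              class = "sim_genome")
  })
}

plant_dmrs <- function(cpg, params) {
  n <- params$n_planted_dmrs
  empty <- data.frame(dmr = integer(), chrom = character(), start = integer(),
                      end = integer(), first_idx = integer(),
                      n_cpgs = integer(), snp_id = character(),
                      snp_pos = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  widths <- sample(seq(params$dmr_width_cpgs[1], params$dmr_width_cpgs[2]),
                   n, replace = TRUE)
  # place DMRs on a per-chromosome grid of CpG indices, keeping a margin of
  # >= 20 CpGs between planted regions (room for flank profiling)
  out <- empty
  used <- rep(FALSE, nrow(cpg))
  margin <- 20L
  attempts <- 0L
  i <- 1L
  while (i <= n && attempts < 1000L * n) {
    attempts <- attempts + 1L
    w <- widths[i]
    start_idx <- sample(nrow(cpg) - w, 1)
    idx <- start_idx:(start_idx + w - 1L)
    guard <- max(1, start_idx - margin):min(nrow(cpg), start_idx + w - 1L + margin)
    if (any(used[guard])) next
    if (length(unique(cpg$chrom[idx])) != 1) next
    # planted DMRs live in locally CpG-dense sequence: reject runs with
    # large internal gaps
    if (any(diff(cpg$pos[idx]) > params$dmr_internal_gap)) next
    used[guard] <- TRUE
    ch <- cpg$chrom[start_idx]
    span <- range(cpg$pos[idx])
    center <- floor(mean(span))
    snp_pos <- center + sample(-2000:2000, 1)
    out <- rbind(out, data.frame(
      dmr = i, chrom = ch, start = span[1], end = span[2],
      first_idx = start_idx, n_cpgs = w,
      snp_id = sprintf("snp_dmr%02d", i), snp_pos = as.integer(snp_pos),
      orientation = sample(c("alt_methylated", "ref_methylated"), 1),
      stringsAsFactors = FALSE))
    i <- i + 1L
  }
  if (nrow(out) < n)
    stop("chromosome too short to place ", n, " non-overlapping planted DMRs")
  out[order(out$chrom, out$start), , drop = FALSE]
}

tile_annotation <- function(chrom_lengths, labels, mean_len) {
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    cuts <- c(0L)
    while (cuts[length(cuts)] < len) {
      cuts <- c(cuts, min(len, cuts[length(cuts)] +
                            max(500L, stats::rgeom(1, 1 / mean_len) + 1L)))
    }
    region_set(ch, cuts[-length(cuts)], cuts[-1],
               sample(labels, length(cuts) - 1, replace = TRUE))
  }))
}

# Random repeat mask avoiding planted DMRs (so planted regions stay eligible
# for matched-region sampling comparisons).
random_mask <- function(chrom_lengths, frac, mean_len, cpg, planted) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n <- ceiling(len * frac / mean_len)
    starts <- sort(sample(len - mean_len, n))
    ends <- pmin(len, starts + pmax(200L, stats::rpois(n, mean_len)))
    keep <- rep(TRUE, n)
    pl <- planted[planted$chrom == ch, , drop = FALSE]
    if (nrow(pl)) {
      for (j in seq_len(nrow(pl)))
        keep <- keep & !(starts < pl$end[j] + 1000 & ends > pl$start[j] - 1000)
    }
    if (!any(keep)) return(NULL)
    region_set(ch, starts[keep], ends[keep], "repeat")
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(region_set(character(), integer(), integer())[0, ])
  do.call(rbind, out)
}

#' Simulate a WGBS cohort over a synthetic genome
#'
#' Genotypes at each causal SNP are drawn from Hardy-Weinberg equilibrium at
#' the configured allele frequency. At planted CpGs each read originates from
#' one of the two alleles with probability 1/2 and is methylated with
#' probability `m_hi` or `m_lo` according to that allele's epiallele state
#' (flipped with mosaicism probability `epsilon`); marginally the methylated
#' count is Binomial. Background CpGs are methylated per read at the site's
#' background mean. Coverage is Poisson(`coverage_lambda`) truncated >= 1.
#'
#' @param genome a [simulate_genome()] result.
#' @param seed integer seed.
#' @return list of class `sim_cohort`: `methylomes` (named list), `cohort`
#'   (pre-aligned `cohort_matrix` over all simulated sites), `genotypes`
#'   (`genotype_table` of causal + background SNPs), `truth` (data.frame of
#'   planted DMRs with per-sample genotype and expected epigenotype columns),
#'   `genome`.
#' @export
simulate_cohort <- function(genome, seed = 1) {
  params <- genome$params
  with_seed(seed, {
    n <- params$n_samples
    samples <- sprintf("S%02d", seq_len(n))
    cpg <- genome$cpg
    ns <- nrow(cpg)

    cov <- matrix(truncated_pois(ns * n, params$coverage_lambda), ns, n,
                  dimnames = list(NULL, samples))
    prob <- matrix(rep(cpg$bg_level, n), ns, n)

    planted <- genome$planted
    geno <- matrix(NA_integer_, nrow(planted), n,
                   dimnames = list(planted$snp_id, samples))
    if (nrow(planted)) {
      for (j in seq_len(nrow(planted))) {
        g <- stats::rbinom(n, 2, params$maf)  # ALT dosage under HWE
        geno[j, ] <- g
        a <- if (planted$orientation[j] == "alt_methylated") g else 2L - g
        # per-read methylation probability given a methylated alleles
        mh <- params$m_hi * (1 - params$epsilon) + params$m_lo * params$epsilon
        ml <- params$m_lo * (1 - params$epsilon) + params$m_hi * params$epsilon
        pr <- (a / 2) * mh + (1 - a / 2) * ml
        idx <- planted$first_idx[j]:(planted$first_idx[j] + planted$n_cpgs[j] - 1L)
        prob[idx, ] <- matrix(pr, length(idx), n, byrow = TRUE)
      }
    }
    meth <- matrix(stats::rbinom(ns * n, as.vector(cov), as.vector(prob)),
                   ns, n, dimnames = list(NULL, samples))

    methylomes <- stats::setNames(lapply(seq_len(n), function(j)
      methylome(cpg$chrom, cpg$pos, meth[, j], cov[, j])), samples)

    gt <- build_genotype_table(genome, geno, samples, params)
    truth <- build_truth(planted, geno, samples)
    cohort <- cohort_from_matrices(cpg[c("chrom", "pos")], meth, cov, samples)
    structure(list(methylomes = methylomes, cohort = cohort, genotypes = gt,
                   truth = truth, genome = genome, seed = seed),
              class = "sim_cohort")
  })
}

truncated_pois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

build_genotype_table <- function(genome, geno, samples, params) {
  planted <- genome$planted
  causal <- data.frame(snp_id = planted$snp_id, chrom = planted$chrom,
                       pos = planted$snp_pos, stringsAsFactors = FALSE)
  if (nrow(causal)) causal <- cbind(causal, as.data.frame(geno))
  bg <- do.call(rbind, lapply(names(genome$chrom_lengths), function(ch) {
    len <- genome$chrom_lengths[[ch]]
    nb <- stats::rpois(1, params$bg_snp_per_mb * len / 1e6)
    if (nb == 0) return(NULL)
    pos <- sort(sample(len, nb))
    maf <- stats::runif(nb, 0.05, 0.5)
    d <- data.frame(snp_id = sprintf("snp_bg_%s_%d", ch, seq_len(nb)),
                    chrom = ch, pos = as.integer(pos),
                    stringsAsFactors = FALSE)
    g <- matrix(stats::rbinom(nb * length(samples), 2, rep(maf, length(samples))),
                nb, length(samples), dimnames = list(NULL, samples))
    cbind(d, as.data.frame(g))
  }))
  out <- rbind(causal, bg)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genotype_table", "data.frame")
  out
}

build_truth <- function(planted, geno, samples) {
  if (!nrow(planted)) return(planted)
  out <- planted
  # expected epigenotype class per sample: number of methylated alleles
  for (s in seq_along(samples)) {
    g <- geno[, s]
    a <- ifelse(planted$orientation == "alt_methylated", g, 2L - g)
    out[[paste0("g_", samples[s])]] <- g
    out[[paste0("class_", samples[s])]] <- a
  }
  out
}

#' Simulate a null cohort with no planted methylation differences
#'
#' Convenience wrapper: [simulate_cohort()] on a genome with
#' `n_planted_dmrs = 0`; any DMR detected downstream is a false positive.
#'
#' @param params a [sim_params()] object (its `n_planted_dmrs` is ignored).
#' @param seed integer seed.
#' @return a `sim_cohort` with empty truth table.
#' @export
simulate_null_cohort <- function(params = sim_params(), seed = 1) {
  params$n_planted_dmrs <- 0L
  genome <- simulate_genome(params, seed = seed)
  simulate_cohort(genome, seed = seed + 1L)
}

#' Simulate per-read allele-sorted methylation at a planted DMR
#'
#' For one heterozygous individual, emits one row per sequenced read at each
#' member CpG with the allele it came from and its methylation call; sorting
#' reads by allele reproduces the allele-specific methylation contrast that
#' targeted bisulfite sequencing shows at true hap-ASM loci.
#'
#' @param genome a `sim_genome` with at least one planted DMR.
#' @param dmr_index which planted DMR to sample (default 1).
#' @param coverage number of reads per CpG (default 100).
#' @param seed integer seed.
#' @return data.frame: pos, read, allele ("M" methylated epiallele, "U"
#'   unmethylated), methylated (0/1).
#' @export
simulate_allele_reads <- function(genome, dmr_index = 1, coverage = 100,
                                  seed = 1) {
  params <- genome$params
  pl <- genome$planted
  if (dmr_index > nrow(pl)) stop("no such planted DMR")
  idx <- pl$first_idx[dmr_index]:(pl$first_idx[dmr_index] + pl$n_cpgs[dmr_index] - 1L)
  pos <- genome$cpg$pos[idx]
  with_seed(seed, {
    mh <- params$m_hi * (1 - params$epsilon) + params$m_lo * params$epsilon
    ml <- params$m_lo * (1 - params$epsilon) + params$m_hi * params$epsilon
    do.call(rbind, lapply(pos, function(p) {
      allele <- sample(c("M", "U"), coverage, replace = TRUE)
      meth <- stats::rbinom(coverage, 1, ifelse(allele == "M", mh, ml))
      data.frame(pos = p, read = seq_len(coverage), allele = allele,
                 methylated = meth, stringsAsFactors = FALSE)
    }))
  })
}

#' Write a simulated cohort to disk in standard formats
#'
#' Methylomes as Bismark coverage files, genotypes as a TSV dosage matrix,
#' truth as BED + TSV, parameters as YAML.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$methylomes))
    write_methylome(sim$methylomes[[s]], file.path(dir, paste0(s, ".cov")),
                    "bismark_cov")
  gt <- sim$genotypes
  utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  if (nrow(tr)) {
    writeLines(sprintf("%s\t%d\t%d\tplanted_dmr%02d", tr$chrom,
                       tr$start - 1L, tr$end, tr$dmr),
               file.path(dir, "truth.bed"))
  } else writeLines(character(), file.path(dir, "truth.bed"))
  utils::write.table(tr[, setdiff(names(tr), "sites")],
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$genome$params), file.path(dir, "params.yaml"))
  invisible(dir)
}
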