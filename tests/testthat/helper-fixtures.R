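# Shared fixtures: tiny cohorts built in code, and an independent
# brute-force DMR reference used as oracle.

# cohort_matrix from a levels matrix (sites x samples) at unit coverage
# scale: counts are level * cov so arithmetic is exact
toy_cohort <- function(levels, pos = NULL, chrom = "chrT", cov = 100L) {
  levels <- as.matrix(levels)
  n <- nrow(levels)
  if (is.null(pos)) pos <- seq_len(n) * 50L
  samples <- paste0("S", seq_len(ncol(levels)))
  meth <- round(levels * cov)
  covm <- matrix(cov, n, ncol(levels), dimnames = list(NULL, samples))
  storage.mode(meth) <- "integer"
  hapasm:::cohort_from_matrices(
    data.frame(chrom = rep(chrom, n), pos = as.integer(pos),
               stringsAsFactors = FALSE),
    meth, covm, samples)
}

random_small_cohort <- function(n_sites, n_samples = 3, seed = 1) {
  set.seed(seed)
  # mix of background noise and occasional strong bimodal stretches so the
  # caller has something to find
  lv <- matrix(runif(n_sites * n_samples), n_sites, n_samples)
  n_blocks <- rpois(1, 1.5)
  for (b in seq_len(n_blocks)) {
    w <- sample(2:8, 1)
    st <- sample(max(1, n_sites - w), 1)
    hi <- sample(n_samples, 1)
    lo <- sample(setdiff(seq_len(n_samples), hi), 1)
    lv[st:(st + w - 1), hi] <- runif(w, 0.93, 1)
    lv[st:(st + w - 1), lo] <- runif(w, 0, 0.07)
  }
  gaps <- sample(c(rep(50L, 8), 500L), n_sites, replace = TRUE)
  toy_cohort(lv, pos = cumsum(gaps))
}

# Independent brute-force DMR reference: enumerates qualifying runs directly
# from the level matrix with plain loops; deliberately shares no code with
# call_dmrs().
brute_force_dmrs <- function(cohort, v = 0.5, min_cpgs = 4,
                             min_core_diff = 0.8, max_gap = 300) {
  lv <- cohort$level
  n <- nrow(lv)
  rng <- apply(lv, 1, function(x) max(x) - min(x))
  ok <- rng > v
  out <- list()
  i <- 1
  while (i <= n) {
    if (!ok[i]) { i <- i + 1; next }
    j <- i
    while (j < n && ok[j + 1] &&
           cohort$sites$chrom[j + 1] == cohort$sites$chrom[j] &&
           cohort$sites$pos[j + 1] - cohort$sites$pos[j] <= max_gap) j <- j + 1
    run <- i:j
    if (length(run) >= min_cpgs) {
      sg <- numeric(length(run))
      for (q in seq_along(run)) {
        x <- lv[run[q], ]
        sg[q] <- sqrt(sum((x - mean(x))^2) / length(x))
      }
      hi <- lo <- numeric(length(run))
      for (q in seq_along(run)) {
        hi[q] <- max(lv[run[q], ]); lo[q] <- min(lv[run[q], ])
      }
      d <- if (sum(sg) == 0) mean(hi) - mean(lo)
           else sum(sg * hi) / sum(sg) - sum(sg * lo) / sum(sg)
      if (d >= min_core_diff)
        out[[length(out) + 1]] <- data.frame(
          chrom = cohort$sites$chrom[run[1]],
          start = cohort$sites$pos[run[1]],
          end = cohort$sites$pos[run[length(run)]],
          n_cpgs = length(run), envelope_diff = d,
          stringsAsFactors = FALSE)
    }
    i <- j + 1
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      envelope_diff = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# planted-truth bookkeeping: which planted DMRs have both homozygote
# epigenotype classes among the sampled genotypes
detectable_planted <- function(truth) {
  if (!nrow(truth)) return(logical(0))
  cls <- as.matrix(truth[, grep("^class_", names(truth)), drop = FALSE])
  apply(cls, 1, function(x) any(x == 0) && any(x == 2))
}

# enumeration oracle: exhaustively sum HWE probabilities of cohorts that
# contain both homozygote classes
enumerate_detection <- function(p, n) {
  q <- 1 - p
  probs <- c(hom_a = p^2, het = 2 * p * q, hom_b = q^2)
  combos <- expand.grid(rep(list(1:3), n))
  tot <- 0
  for (i in seq_len(nrow(combos))) {
    g <- as.integer(combos[i, ])
    if (any(g == 1) && any(g == 3)) tot <- tot + prod(probs[g])
  }
  tot
}

write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1/1",
    "chr1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "chr2\t150\trs4\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"),
    path)
  path
}
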