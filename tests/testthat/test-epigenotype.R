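fixture_mixture <- function() {
  # hand-specified three-component mixture used where a fitted one is not
  # the object under test
  structure(list(pi = c(1, 1, 1) / 3, alpha = c(2, 12, 18),
                 beta = c(18, 12, 2), means = c(0.1, 0.5, 0.9),
                 loglik = NA_real_, n_iter = 0L, converged = TRUE,
                 eps = 1e-6),
            class = "beta_mixture")
}

test_that("EM recovers the components of a known beta mixture", {
  set.seed(101)
  v <- c(rbeta(280, 2, 18), rbeta(240, 12, 12), rbeta(280, 18, 2))
  fit <- fit_beta_mixture(v)
  expect_true(all(abs(fit$means - c(0.10, 0.50, 0.90)) < 0.05))
  expect_true(all(diff(fit$means) > 0))      # sorted by mean
  expect_equal(sum(fit$pi), 1)
  expect_true(all(fit$alpha > 0 & fit$beta > 0))
})

test_that("EM log-likelihood is non-decreasing and responsibilities normalise", {
  set.seed(103)
  x <- c(rbeta(60, 2, 10), rbeta(60, 10, 2))
  init <- hapasm:::mom_init(pmin(1 - 1e-6, pmax(1e-6, x)),
                            c(0, 1 / 3, 2 / 3, 1), 3)
  # track the log-likelihood trace by running EM step-by-step
  lls <- numeric(0)
  fit <- init
  for (it in 1:25) {
    one <- hapasm:::beta_em(pmin(1 - 1e-6, pmax(1e-6, x)), fit,
                            max_iter = 1, tol = 0)
    lls <- c(lls, one$loglik)
    fit <- one[c("pi", "alpha", "beta")]
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  }
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("degenerate or insufficient input is rejected loudly", {
  expect_error(fit_beta_mixture(rep(0.5, 100)), "identical")
  expect_error(fit_beta_mixture(runif(5)), "at least")
  expect_error(fit_beta_mixture(c(runif(20), NA)), "non-finite")
})

test_that("posteriors follow the mixture formula and normalise over classes", {
  mx <- fixture_mixture()
  mus <- c(0.05, 0.3, 0.5, 0.9, 0.99)
  for (mu in mus) {
    ps <- vapply(0:2, function(g) posterior_epigenotype(mx, g, mu), numeric(1))
    expect_equal(sum(ps), 1, tolerance = 1e-12)
    # independent direct evaluation of the normalised densities
    direct <- dbeta(mu, mx$alpha, mx$beta) / 3
    expect_equal(ps, direct / sum(direct), tolerance = 1e-12)
  }
  # all components identical and uniform weights: posterior is 1/3 regardless
  same <- structure(list(pi = rep(1 / 3, 3), alpha = rep(5, 3),
                         beta = rep(5, 3), means = rep(0.5, 3),
                         loglik = NA_real_, n_iter = 0L, converged = TRUE,
                         eps = 1e-6), class = "beta_mixture")
  for (g in 0:2)
    expect_equal(posterior_epigenotype(same, g, 0.77), 1 / 3,
                 tolerance = 1e-12)
})

test_that("SNP-DMR score is the product of per-sample posteriors", {
  mx <- fixture_mixture()
  mu <- c(0.05, 0.5, 0.95)
  g <- c(0L, 1L, 2L)
  sc <- score_snp_dmr(mx, g, mu, orientation = "alt_methylated")
  expect_equal(sc$score, prod(posterior_epigenotype(mx, g, mu)))
  expect_lte(sc$score, min(sc$factors))
  # one sample: score equals that sample's posterior
  one <- score_snp_dmr(mx, 2L, 0.9, orientation = "alt_methylated")
  expect_equal(one$score, posterior_epigenotype(mx, 2L, 0.9))
  # adding a sample never increases the score
  more <- score_snp_dmr(mx, c(g, 1L), c(mu, 0.5),
                        orientation = "alt_methylated")
  expect_lte(more$score, sc$score)
  # invariant to sample order
  ord <- c(3, 1, 2)
  expect_equal(score_snp_dmr(mx, g[ord], mu[ord])$score,
               score_snp_dmr(mx, g, mu)$score)
})

test_that("orientation policy evaluates both allele assignments", {
  mx <- fixture_mixture()
  mu <- c(0.05, 0.5, 0.95)
  g_ref <- c(2L, 1L, 0L)  # methylated on the REF allele
  fixed <- score_snp_dmr(mx, g_ref, mu, orientation = "alt_methylated")
  both <- score_snp_dmr(mx, g_ref, mu, orientation = "both")
  expect_gt(both$score, fixed$score)
  expect_equal(both$orientation, "ref_methylated")
})

test_that("missing genotypes drop out of the product and are flagged", {
  mx <- fixture_mixture()
  sc <- score_snp_dmr(mx, c(0L, NA, 2L), c(0.05, 0.5, 0.95))
  expect_equal(sc$n_used, 2L)
  expect_equal(sc$n_missing, 1L)
  expect_true(is.na(sc$factors[2]))
  all_na <- score_snp_dmr(mx, c(NA, NA), c(0.1, 0.9))
  expect_true(is.na(all_na$score))
  expect_equal(all_na$n_used, 0L)
})

test_that("scan_window respects the +-6 kb boundary around the DMR center", {
  mx <- fixture_mixture()
  dmr <- data.frame(dmr_id = "D1", chrom = "c1", start = 9000L, end = 11000L,
                    mu_A = 0.05, mu_B = 0.5, mu_C = 0.95,
                    stringsAsFactors = FALSE)
  # center = 10000; SNPs at 5999 and 6001 bp away
  gt <- data.frame(snp_id = c("near", "far"), chrom = "c1",
                   pos = c(10000L - 5999L, 10000L + 6001L),
                   A = c(0L, 0L), B = c(1L, 1L), C = c(2L, 2L),
                   stringsAsFactors = FALSE)
  class(gt) <- c("genotype_table", "data.frame")
  hits <- scan_window(dmr, gt, mx, threshold = 0)
  expect_equal(hits$snp_id, "near")
  # empty window is a valid result
  gt_far <- gt[gt$snp_id == "far", ]
  class(gt_far) <- c("genotype_table", "data.frame")
  expect_equal(nrow(scan_window(dmr, gt_far, mx)), 0)
})

test_that("concordant SNPs score above threshold, discordant ones do not", {
  mx <- fixture_mixture()
  dmr <- data.frame(dmr_id = "D1", chrom = "c1", start = 9000L, end = 11000L,
                    mu_A = 0.04, mu_B = 0.52, mu_C = 0.96,
                    stringsAsFactors = FALSE)
  gt <- data.frame(snp_id = c("concordant", "discordant"), chrom = "c1",
                   pos = c(9500L, 10500L),
                   A = c(0L, 2L), B = c(1L, 2L), C = c(2L, 0L),
                   stringsAsFactors = FALSE)
  class(gt) <- c("genotype_table", "data.frame")
  hits <- scan_window(dmr, gt, mx, threshold = 0.9)
  expect_equal(hits$snp_id, "concordant")
})

test_that("causal SNPs score high and permuted genotypes do not, across cohorts", {
  # one shared mixture fitted on pooled core methylations from a large run,
  # then 60 small cohorts scored against it
  p_big <- sim_params(chrom_lengths = c(chrS1 = 2e6), n_planted_dmrs = 12)
  big <- simulate_cohort(simulate_genome(p_big, seed = 201), seed = 202)
  co_big <- align_cohort(big$methylomes)
  d_big <- call_dmrs(co_big)
  pool <- unlist(d_big[paste0("mu_", co_big$samples)], use.names = FALSE)
  expect_gte(length(pool), 9)
  mx <- fit_beta_mixture(pool)
  expect_true(all(abs(mx$means - c(0.05, 0.5, 0.95)) < 0.08))

  p <- sim_params(chrom_lengths = c(chrS1 = 1e5), n_planted_dmrs = 1)
  causal_hi <- 0L; causal_n <- 0L; perm_hi <- 0L; perm_n <- 0L
  for (seed in 1:60) {
    sim <- simulate_cohort(simulate_genome(p, seed = 300 + seed),
                           seed = 700 + seed)
    if (!any(detectable_planted(sim$truth))) next
    co <- align_cohort(sim$methylomes)
    d <- call_dmrs(co)
    tr <- sim$truth[1, ]
    hit <- which(d$chrom == tr$chrom & d$start <= tr$end & d$end >= tr$start)
    if (length(hit) != 1) next
    mu <- as.numeric(d[hit, paste0("mu_", co$samples)])
    g <- as.integer(tr[, paste0("g_", co$samples)])
    causal_n <- causal_n + 1L
    if (score_snp_dmr(mx, g, mu)$score > 0.9) causal_hi <- causal_hi + 1L
    set.seed(9000 + seed)
    for (r in 1:5) {
      gp <- sample(g)
      perm_n <- perm_n + 1L
      if (score_snp_dmr(mx, gp, mu)$score > 0.9) perm_hi <- perm_hi + 1L
    }
  }
  expect_gte(causal_n, 20)
  expect_gte(causal_hi / causal_n, 0.9)
  # permutations that happen to reproduce the causal assignment can still
  # score high; they are a small minority
  expect_lte(perm_hi / perm_n, 0.3)
})
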