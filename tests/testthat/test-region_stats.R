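test_that("flank profile skips a buffer and classifies by strict comparison", {
  # 30 sites: flanks at 0.9, a 4-CpG trough at 0.1 in sites 14-17
  lv <- matrix(0.9, 30, 2)
  lv[14:17, 1] <- 0.1
  lv[14:17, 2] <- 0.1
  co <- toy_cohort(lv, cov = 10L)
  # hand-build a dmr_table row over sites 14-17
  d <- hapasm:::empty_dmr_table(co$samples)
  d[1, c("dmr_id", "chrom")] <- c("D1", "chrT")
  d$start <- co$sites$pos[14]; d$end <- co$sites$pos[17]
  d$n_cpgs <- 4L; d$envelope_diff <- 0; d$p_value <- NA_real_
  d$mu_S1 <- 0.1; d$mu_S2 <- 0.1
  d$sites <- I(list(14:17))
  fp <- flank_profile(d, co)
  expect_equal(fp$class, "lower_than_both")
  expect_equal(fp$upstream_mean, 0.9)
  expect_equal(fp$downstream_mean, 0.9)
  expect_equal(fp$dmr_mean, 0.1)
})

test_that("ties classify as intermediate and short flanks as incomplete", {
  lv <- matrix(0.5, 40, 2)
  co <- toy_cohort(lv, cov = 10L)
  d <- hapasm:::empty_dmr_table(co$samples)
  d[1, c("dmr_id", "chrom")] <- c("D1", "chrT")
  d$start <- co$sites$pos[18]; d$end <- co$sites$pos[21]
  d$n_cpgs <- 4L; d$envelope_diff <- 0; d$p_value <- NA_real_
  d$mu_S1 <- 0.5; d$mu_S2 <- 0.5
  d$sites <- I(list(18:21))
  expect_equal(flank_profile(d, co)$class, "intermediate")
  # DMR 5 CpGs from the chromosome start: upstream flank incomplete
  d2 <- d
  d2$start <- co$sites$pos[5]; d2$end <- co$sites$pos[8]
  d2$sites <- I(list(5:8))
  expect_equal(flank_profile(d2, co)$class, "incomplete")
})

test_that("recovered DMRs on default synthetic landscapes are mostly methylation troughs", {
  n_lower <- 0L; n_tot <- 0L
  for (seed in 1:5) {
    p <- sim_params(chrom_lengths = c(chrS1 = 6e5), n_planted_dmrs = 6)
    sim <- simulate_cohort(simulate_genome(p, seed = 600 + seed),
                           seed = 650 + seed)
    co <- align_cohort(sim$methylomes)
    d <- call_dmrs(co)
    if (!nrow(d)) next
    fp <- flank_profile(d, co)
    n_lower <- n_lower + sum(fp$class == "lower_than_both")
    n_tot <- n_tot + sum(fp$class != "incomplete")
  }
  expect_gt(n_tot, 5)
  expect_gt(n_lower / n_tot, 0.5)
})

test_that("matched random regions satisfy size, CpG and mask constraints", {
  set.seed(5)
  sites <- data.frame(chrom = "c1", pos = sort(sample(1e5, 2000)))
  mask <- region_set("c1", c(20000, 60000), c(25000, 65000), "repeat")
  sizes <- c(500L, 1000L, 1500L)
  rnd <- sample_matched_regions(sites, sizes, c(c1 = 1e5), mask = mask,
                                n_sets = 50, regions_per_set = 10, seed = 6)
  expect_equal(nrow(rnd), 500)
  expect_true(all((rnd$end - rnd$start) %in% sizes))
  # >= 4 CpGs per region
  for (i in sample(nrow(rnd), 50)) {
    ncpg <- sum(sites$pos >= rnd$start[i] & sites$pos <= rnd$end[i])
    expect_gte(ncpg, 4)
  }
  # no overlap with the mask (mask is 0-based half-open)
  overlaps_mask <- (rnd$start <= 25000 & rnd$end > 20000) |
    (rnd$start <= 65000 & rnd$end > 60000)
  expect_false(any(overlaps_mask))
  # impossible constraints error out
  expect_error(sample_matched_regions(sites[1:3, ], sizes, c(c1 = 1e5),
                                      n_sets = 2, regions_per_set = 5,
                                      min_cpgs = 4, seed = 7,
                                      max_tries = 5),
               "constraints")
})

test_that("region midpoints are uniform when unconstrained", {
  set.seed(8)
  sites <- data.frame(chrom = "c1", pos = seq(50, 2e5, by = 50))
  rnd <- sample_matched_regions(sites, 1000L, c(c1 = 2e5), n_sets = 1000,
                                regions_per_set = 1, seed = 9)
  mids <- (rnd$start + rnd$end) / 2
  ks <- suppressWarnings(ks.test(mids, "punif", min(mids), max(mids)))
  expect_gt(ks$p.value, 0.001)
})

test_that("enrichment p values match hand-counted fractions", {
  expect_equal(empirical_overlap_p(3, c(1, 2, 3, 4)),
               list(p_over = 0.25, p_under = 0.5))
  # boundary: observed above every null count
  expect_equal(empirical_overlap_p(9, c(1, 2, 3, 4)),
               list(p_over = 0, p_under = 1))
  # p_over + p_under <= 1 with ties contributing to neither
  res <- empirical_overlap_p(2, c(2, 2, 3))
  expect_lte(res$p_over + res$p_under, 1)
})

test_that("enrichment test detects a label the regions were placed in", {
  set.seed(10)
  sites <- data.frame(chrom = "c1", pos = seq(20, 2e5, by = 40))
  ann <- region_set("c1", c(0, 50000), c(50000, 200000),
                    c("inside", "outside"))
  # "DMRs" all inside the first label
  d <- hapasm:::empty_dmr_table("S1")
  starts <- seq(2000, 42000, by = 5000)
  for (i in seq_along(starts)) {
    d[i, "dmr_id"] <- paste0("D", i)
    d[i, "chrom"] <- "c1"
    d[i, "start"] <- starts[i]
    d[i, "end"] <- starts[i] + 600L
    d[i, "n_cpgs"] <- 4L
    d[i, "envelope_diff"] <- 1
    d[i, "mu_S1"] <- 0.5
  }
  d$sites <- I(rep(list(1:4), nrow(d)))
  res <- enrichment_test(d, ann, sites, c(c1 = 2e5), n_sets = 200, seed = 11)
  inside <- res[res$label == "inside", ]
  expect_equal(inside$observed, length(starts))
  expect_lt(inside$p_over, 0.05)
  expect_gt(inside$p_under, 0.5)
})

test_that("self-null p_over is approximately uniform", {
  set.seed(12)
  sites <- data.frame(chrom = "c1", pos = seq(25, 1e5, by = 25))
  ann <- region_set("c1", seq(0, 9e4, 1e4), seq(1e4, 1e5, 1e4),
                    rep(c("a", "b"), 5))
  ann_gr <- hapasm:::regions_to_granges(ann)
  labels <- c("a", "b")
  pvals <- numeric(200)
  draws <- sample_matched_regions(sites, c(800L, 1200L), c(c1 = 1e5),
                                  n_sets = 201, regions_per_set = 10,
                                  seed = 13)
  # each set in turn plays the observed DMRs against the remaining 200
  allc <- t(vapply(split(seq_len(nrow(draws)), draws$set), function(ix)
    hapasm:::overlap_counts(draws$chrom[ix], draws$start[ix], draws$end[ix],
                            ann_gr, labels), integer(2)))
  for (r in 1:200) {
    obs <- allc[r, "a"]
    null <- allc[-r, "a"]
    pvals[r] <- mean(null > obs)
  }
  # grid-valued but roughly uniform: mean near 0.5 minus half the tie mass
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.65)
  expect_gt(stats::sd(pvals), 0.1)
})

test_that("state-difference partition uses label-set disjointness", {
  d <- hapasm:::empty_dmr_table("S1")
  for (i in 1:3) {
    d[i, "dmr_id"] <- paste0("D", i)
    d[i, "chrom"] <- "c1"
    d[i, "start"] <- i * 1000L
    d[i, "end"] <- i * 1000L + 500L
    d[i, "n_cpgs"] <- 4L
    d[i, "envelope_diff"] <- 1
    d[i, "mu_S1"] <- 0.5
  }
  d$sites <- I(rep(list(1:4), 3))
  # donor A: D1 enhancer, D2 {enhancer+transcribed}, D3 enhancer
  a <- region_set("c1", c(900, 1900, 2200, 2900), c(1600, 2200, 2600, 3600),
                  c("enhancer", "enhancer", "transcribed", "enhancer"))
  # donor B: D1 repressed (disjoint), D2 transcribed (shared), D3 enhancer
  b <- region_set("c1", c(900, 1900, 2900), c(1600, 2600, 3600),
                  c("repressed", "transcribed", "enhancer"))
  md <- c(0.8, 0.4, 0.1)
  parts <- state_difference_partition(d, a, b, md)
  expect_equal(parts$different, 0.8)
  expect_equal(sort(parts$same), c(0.1, 0.4))
  # identical annotations: nothing is "different"
  parts2 <- state_difference_partition(d, a, a, md)
  expect_length(parts2$different, 0)
  # a DMR with no state in one donor is excluded with a warning
  b_missing <- region_set("c1", c(900, 1900), c(1600, 2600),
                          c("repressed", "transcribed"))
  expect_warning(parts3 <- state_difference_partition(d, a, b_missing, md),
                 "excluded")
  expect_equal(parts3$excluded, "D3")
})

test_that("rank-sum comparison is exact for small samples and rank-invariant", {
  rs <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 1 / 3)
  # enumeration oracle: all C(4,2)=6 assignments, U=0 has probability 1/6,
  # two-sided doubles it
  expect_equal(rs$p_value, 2 * 1 / 6)
  # invariant under strictly monotone transforms
  a <- c(0.1, 0.7, 0.3); b <- c(0.9, 0.5, 0.8)
  expect_equal(rank_sum_compare(a, b)$p_value,
               rank_sum_compare(exp(a), exp(b))$p_value)
  # identical large groups: p ~ 1
  set.seed(14)
  x <- rnorm(100)
  expect_gt(rank_sum_compare(x, x)$p_value, 0.9)
  expect_error(rank_sum_compare(numeric(0), 1:3), "non-empty")
})
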