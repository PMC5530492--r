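# Empirical significance via a pooled-rate binomial null, and the
# Hardy-Weinberg model of the DMR detection rate.

#' Pooled per-site methylation rates
#'
#' p_c = (sum of methylated counts over samples) / (sum of coverages): the
#' common rate under the null hypothesis that samples do not differ.
#'
#' @param cohort a `cohort_matrix`.
#' @return numeric vector, one rate per aligned site.
#' @export
pooled_rates <- function(cohort) {
  tot <- rowSums(cohort$cov)
  stopifnot(all(tot > 0))
  rowSums(cohort$meth) / tot
}

#' Simulate one coverage-matched binomial null replicate
#'
#' For every observed sample s a null sample o is built with identical
#' coverage n_o,c = n_s,c and methylated count M_o,c ~ Binomial(n_o,c, p_c)
#' drawn independently, so any cross-sample difference is finite-sampling
#' noise only.
#'
#' @param cohort a `cohort_matrix`.
#' @param p_c per-site pooled rates from [pooled_rates()].
#' @param seed optional integer seed.
#' @return a `cohort_matrix` of the same shape with simulated counts.
#' @export
simulate_null_replicate <- function(cohort, p_c = pooled_rates(cohort),
                                    seed = NULL) {
  with_seed(seed, {
    n <- nrow(cohort$cov)
    k <- ncol(cohort$cov)
    meth <- matrix(stats::rbinom(n * k, as.vector(cohort$cov), rep(p_c, k)),
                   n, k, dimnames = dimnames(cohort$cov))
    cohort_from_matrices(cohort$sites, meth, cohort$cov, cohort$samples,
                         sd_type = cohort$sd_type, min_cov = cohort$min_cov)
  })
}

#' Empirical per-DMR p values from the binomial null
#'
#' Runs the DMR caller on `R` null replicate cohorts. With k = the number of
#' replicates in which the caller reports at least one qualifying DMR
#' anywhere, every observed DMR receives the family-level empirical p = k/R;
#' when k = 0 the value is reported as the bound 1/R (printed "< 1/R"). The
#' `per_region` method instead counts, per observed DMR, replicates yielding
#' a qualifying call overlapping that DMR's span. The `add_one` estimator
#' (k+1)/(R+1) is available for users preferring a never-zero estimate.
#'
#' @param cohort a `cohort_matrix`.
#' @param params a [caller_params()] object.
#' @param R number of null replicates (default 1000).
#' @param seed integer seed; replicate r uses `seed + r` so any single
#'   replicate is reproducible in isolation.
#' @param dmrs observed DMR table; called internally if NULL.
#' @param method `"any_region"` (default) or `"per_region"`.
#' @param estimator `"plugin"` (k/R, default) or `"add_one"` ((k+1)/(R+1)).
#' @return list of class `empirical_null`: `dmrs` (table with `p_value` and
#'   `p_label` filled), `k`, `R`, `null_dmr_counts` (per-replicate counts).
#' @export
empirical_pvalues <- function(cohort, params = caller_params(), R = 1000,
                              seed = 1, dmrs = NULL,
                              method = c("any_region", "per_region"),
                              estimator = c("plugin", "add_one")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (R < 1) stop("R must be >= 1")
  if (is.null(dmrs)) dmrs <- call_dmrs(cohort, params)
  p_c <- pooled_rates(cohort)
  counts <- integer(R)
  hit <- matrix(0L, nrow(dmrs), R)
  for (r in seq_len(R)) {
    null_cohort <- simulate_null_replicate(cohort, p_c, seed = seed + r)
    nd <- call_dmrs(null_cohort, params)
    counts[r] <- nrow(nd)
    if (method == "per_region" && nrow(nd) && nrow(dmrs)) {
      for (i in seq_len(nrow(dmrs))) {
        hit[i, r] <- as.integer(any(nd$chrom == dmrs$chrom[i] &
                                      nd$start <= dmrs$end[i] &
                                      nd$end >= dmrs$start[i]))
      }
    }
  }
  k <- sum(counts > 0)
  est <- function(kk) if (estimator == "plugin") kk / R else (kk + 1) / (R + 1)
  if (nrow(dmrs)) {
    kk <- if (method == "any_region") rep(k, nrow(dmrs)) else rowSums(hit)
    p <- est(kk)
    lab <- ifelse(kk == 0 & estimator == "plugin",
                  sprintf("< %g", 1 / R), sprintf("%g", p))
    p[kk == 0 & estimator == "plugin"] <- 1 / R  # reported bound
    dmrs$p_value <- p
    dmrs$p_label <- lab
  }
  structure(list(dmrs = dmrs, k = k, R = R, null_dmr_counts = counts,
                 method = method, estimator = estimator),
            class = "empirical_null")
}

#' Probability of detecting an allele-specific DMR in n samples
#'
#' Under Hardy-Weinberg equilibrium with allele frequencies p and q = 1 - p,
#' an allele-specific DMR is detectable only if the cohort contains at least
#' one individual homozygous for each epiallele. By inclusion-exclusion on
#' the complementary event,
#' P(p, q) = 1 - [(1 - p^2)^n + (1 - q^2)^n - (2pq)^n].
#'
#' @param p allele frequency (vectorised).
#' @param n number of samples.
#' @return detection probability in [0, 1].
#' @export
detection_probability <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), n >= 1)
  q <- 1 - p
  val <- 1 - ((1 - p^2)^n + (1 - q^2)^n - (2 * p * q)^n)
  pmin(1, pmax(0, val))
}

#' Cohort-level DMR detection rate over an allele-frequency spectrum
#'
#' Weighted mean of [detection_probability()] over a spectrum of causal-SNP
#' allele frequencies (e.g. the dbSNP minor-allele-frequency spectrum above
#' 0.05), assuming a causal SNP's frequency is independent of its chance of
#' being causal.
#'
#' @param spectrum data.frame with column `maf` and optional column `weight`
#'   (normalised internally), or a numeric vector of frequencies.
#' @param n number of samples.
#' @return scalar detection rate in [0, 1].
#' @export
detection_rate <- function(spectrum, n) {
  if (is.numeric(spectrum)) spectrum <- data.frame(maf = spectrum)
  if (nrow(spectrum) == 0) stop("empty allele-frequency spectrum")
  w <- if ("weight" %in% names(spectrum)) spectrum$weight
       else rep(1, nrow(spectrum))
  w <- w / sum(w)
  sum(w * detection_probability(spectrum$maf, n))
}

#' Read an allele-frequency spectrum
#'
#' Two-column TSV: maf, optional weight. Header optional.
#'
#' @param path file path.
#' @return data.frame with `maf` (and `weight` if present).
#' @export
read_maf_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = "\t")
  names(df)[1] <- "maf"
  if (ncol(df) >= 2) names(df)[2] <- "weight"
  df
}

#' Extrapolate the total number of DMRs in the population
#'
#' If only a fraction `rate` of allele-specific DMRs is detectable in a
#' cohort of the given size, the population total is estimated as
#' detected / rate.
#'
#' @param n_detected number of DMRs detected.
#' @param rate detection rate in (0, 1].
#' @return list: `total` (unrounded), `total_rounded`.
#' @export
extrapolate_total <- function(n_detected, rate) {
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]")
  tot <- n_detected / rate
  list(total = tot, total_rounded = round(tot))
}
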