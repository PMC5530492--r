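# Epigenotype classification by a three-component beta mixture and SNP-DMR
# co-variation scoring.
#
# At an allele-specific DMR a sample's core methylation concentrates near 0,
# 0.5 or 1 depending on how many of its two alleles carry the methylated
# epiallele. Instead of fixed thresholds, the pooled core methylations of
# all called DMRs are decomposed into a three-component beta mixture
# ("unmethylated", "half-methylated", "full-methylated") and class
# membership is expressed as posterior probabilities.

#' Fit a beta mixture by expectation-maximisation
#'
#' Values are clamped to [eps, 1-eps]. Initialisation is method-of-moments
#' on a partition of [0,1] at 1/3 and 2/3 (plus jittered restarts); the
#' M-step maximises each component's weighted beta log-likelihood
#' numerically, starting from the current parameters, so the observed-data
#' log-likelihood is non-decreasing. Components are sorted by mean.
#'
#' @param values numeric vector in [0, 1]; at least 3 per component.
#' @param k number of components (default 3).
#' @param eps clamping margin (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param n_restarts jittered initialisations (default 5); best final
#'   log-likelihood wins. Deterministic given `seed`.
#' @param seed integer seed for the jitter.
#' @return object of class `beta_mixture`: `pi`, `alpha`, `beta`, `means`,
#'   `loglik`, `n_iter`, `converged`.
#' @export
fit_beta_mixture <- function(values, k = 3, eps = 1e-6, max_iter = 500,
                             tol = 1e-8, n_restarts = 5, seed = 1) {
  if (any(!is.finite(values))) stop("non-finite values")
  if (length(values) < 3 * k)
    stop("need at least ", 3 * k, " values to fit ", k, " components")
  x <- pmin(1 - eps, pmax(eps, values))
  if (stats::sd(x) < 1e-12)
    stop("degenerate input: all values identical; no mixture is identifiable")
  cuts0 <- seq(0, 1, length.out = k + 1)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cuts <- cuts0
      if (r > 1) {
        jit <- stats::runif(k - 1, -0.08, 0.08)
        cuts[2:k] <- sort(pmin(0.95, pmax(0.05, cuts0[2:k] + jit)))
      }
      init <- mom_init(x, cuts, k)
      fit <- try(beta_em(x, init, max_iter, tol), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) stop("beta mixture fit failed in all restarts")
  ord <- order(best$alpha / (best$alpha + best$beta))
  structure(list(pi = best$pi[ord], alpha = best$alpha[ord],
                 beta = best$beta[ord],
                 means = (best$alpha / (best$alpha + best$beta))[ord],
                 loglik = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, eps = eps),
            class = "beta_mixture")
}

mom_init <- function(x, cuts, k) {
  grp <- cut(x, breaks = cuts, include.lowest = TRUE, labels = FALSE)
  pi <- alpha <- beta <- numeric(k)
  for (j in seq_len(k)) {
    xs <- x[grp == j]
    if (length(xs) < 2) xs <- c(cuts[j] + 0.1, cuts[j + 1] - 0.1)
    ab <- beta_mom(mean(xs), max(stats::var(xs), 1e-4))
    alpha[j] <- ab[1]; beta[j] <- ab[2]
    pi[j] <- max(length(x[grp == j]), 1) / length(x)
  }
  list(pi = pi / sum(pi), alpha = alpha, beta = beta)
}

beta_mom <- function(m, v) {
  v <- min(v, m * (1 - m) * 0.99)
  common <- m * (1 - m) / v - 1
  c(max(m * common, 0.05), max((1 - m) * common, 0.05))
}

beta_em <- function(x, init, max_iter, tol) {
  pi <- init$pi; alpha <- init$alpha; beta <- init$beta
  k <- length(pi)
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(pi[j]) + stats::dbeta(x, alpha[j], beta[j], log = TRUE),
      numeric(n))
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    resp <- exp(logd - lse)          # responsibilities, rows sum to 1
    ll <- sum(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    for (j in seq_len(k)) {
      w <- resp[, j]
      sw <- sum(w)
      pi[j] <- sw / n
      # weighted beta MLE; warm start at current parameters keeps the
      # complete-data objective (and hence the log-likelihood) non-decreasing
      obj <- function(th) {
        a <- exp(th[1]); b <- exp(th[2])
        -(sum(w * stats::dbeta(x, a, b, log = TRUE)))
      }
      opt <- stats::optim(log(c(alpha[j], beta[j])), obj, method = "BFGS",
                          control = list(maxit = 50))
      alpha[j] <- exp(opt$par[1]); beta[j] <- exp(opt$par[2])
    }
  }
  list(pi = pi, alpha = alpha, beta = beta, loglik = ll_old, n_iter = it,
       converged = converged)
}

#' Component densities of a beta mixture at given values
#' @param mixture a `beta_mixture`.
#' @param mu methylation levels in [0, 1] (clamped).
#' @return matrix length(mu) x k of pi_k * b_{alpha_k, beta_k}(mu).
#' @export
mixture_weighted_densities <- function(mixture, mu) {
  mu <- pmin(1 - mixture$eps, pmax(mixture$eps, mu))
  vapply(seq_along(mixture$pi), function(j)
    mixture$pi[j] * stats::dbeta(mu, mixture$alpha[j], mixture$beta[j]),
    numeric(length(mu)))
}

#' Posterior probability of an epigenotype class given a methylation level
#'
#' L(g, mu) = pi_g b_{alpha_g, beta_g}(mu) / sum_k pi_k b_{alpha_k, beta_k}(mu),
#' with component g = 0 the unmethylated, 1 the half-methylated and 2 the
#' full-methylated class.
#'
#' @param mixture a fitted `beta_mixture` with 3 components.
#' @param g class in \{0, 1, 2\} (vectorised with mu).
#' @param mu core methylation level(s).
#' @return posterior probabilities in [0, 1]; for fixed mu they sum to 1
#'   over g.
#' @export
posterior_epigenotype <- function(mixture, g, mu) {
  stopifnot(all(g %in% 0:2))
  wd <- mixture_weighted_densities(mixture, mu)
  if (is.null(dim(wd))) wd <- matrix(wd, nrow = 1)
  (wd / rowSums(wd))[cbind(seq_along(mu), g + 1L)]
}

#' Score co-variation between one SNP and one DMR
#'
#' score(s, d) = prod_i L(g_i(s), mu_i(d)) over samples i: the joint
#' posterior probability that every sample's epigenotype class equals its
#' genotype. Because the methylated epiallele may ride on either allele,
#' the default policy evaluates both orientations (class = dosage and
#' class = 2 - dosage) and keeps the larger score. Samples with missing
#' genotype are omitted from the product and flagged.
#'
#' @param mixture a fitted `beta_mixture`.
#' @param genotypes integer dosages in \{0, 1, 2, NA\}, one per sample.
#' @param mu core methylation levels, one per sample (same order).
#' @param orientation `"both"` (default), `"alt_methylated"` (class =
#'   dosage) or `"ref_methylated"` (class = 2 - dosage).
#' @return list: `score`, `orientation`, `factors` (per-sample posteriors),
#'   `n_used`, `n_missing`.
#' @export
score_snp_dmr <- function(mixture, genotypes, mu,
                          orientation = c("both", "alt_methylated",
                                          "ref_methylated")) {
  orientation <- match.arg(orientation)
  if (length(genotypes) != length(mu))
    stop("genotypes and mu must have the same length")
  ok <- !is.na(genotypes)
  if (!any(ok))
    return(list(score = NA_real_, orientation = NA_character_,
                factors = rep(NA_real_, length(mu)), n_used = 0L,
                n_missing = length(mu)))
  g <- genotypes[ok]; m <- mu[ok]
  one <- function(cls) {
    f <- posterior_epigenotype(mixture, cls, m)
    list(score = prod(f), factors = f)
  }
  res <- switch(orientation,
    alt_methylated = c(one(g), orientation = "alt_methylated"),
    ref_methylated = c(one(2L - g), orientation = "ref_methylated"),
    both = {
      a <- one(g); b <- one(2L - g)
      if (a$score >= b$score) c(a, orientation = "alt_methylated")
      else c(b, orientation = "ref_methylated")
    })
  factors <- rep(NA_real_, length(mu))
  factors[ok] <- res$factors
  list(score = res$score, orientation = res$orientation, factors = factors,
       n_used = sum(ok), n_missing = sum(!ok))
}

#' Scan SNPs around a DMR and return those above the score threshold
#'
#' Every SNP whose position lies within `window_bp` of the DMR centre (the
#' midpoint of the member-CpG span; `anchor = "border"` measures from the
#' nearest border instead) is scored with [score_snp_dmr()]; SNPs scoring
#' above `threshold` are returned sorted by decreasing score.
#'
#' @param dmr one row of a `dmr_table`.
#' @param genotypes a `genotype_table`.
#' @param mixture a fitted `beta_mixture`.
#' @param samples sample ids in the order of the DMR's `mu_` columns;
#'   default: derived from the column names.
#' @param window_bp half-window in bp (default 6000).
#' @param threshold minimum score to report (default 0.9; use 0 to get all).
#' @param orientation see [score_snp_dmr()].
#' @param anchor `"center"` (default) or `"border"`.
#' @return data.frame: snp_id, chrom, pos, distance, score, orientation,
#'   n_missing.
#' @export
scan_window <- function(dmr, genotypes, mixture, samples = NULL,
                        window_bp = 6000, threshold = 0.9,
                        orientation = "both", anchor = c("center", "border")) {
  anchor <- match.arg(anchor)
  if (is.null(samples))
    samples <- sub("^mu_", "", grep("^mu_", names(dmr), value = TRUE))
  missing <- setdiff(samples, names(genotypes))
  if (length(missing))
    stop("genotype table lacks sample(s): ", paste(missing, collapse = ", "))
  mu <- as.numeric(dmr[paste0("mu_", samples)])
  center <- floor((dmr$start + dmr$end) / 2)
  gsub <- genotypes[genotypes$chrom == dmr$chrom, , drop = FALSE]
  dist <- if (anchor == "center") abs(gsub$pos - center)
          else pmax(0, pmax(dmr$start - gsub$pos, gsub$pos - dmr$end))
  gsub <- gsub[dist <= window_bp, , drop = FALSE]
  dist <- dist[dist <= window_bp]
  out <- data.frame(snp_id = character(), chrom = character(),
                    pos = integer(), distance = integer(), score = numeric(),
                    orientation = character(), n_missing = integer(),
                    stringsAsFactors = FALSE)
  if (!nrow(gsub)) return(out)
  rows <- lapply(seq_len(nrow(gsub)), function(i) {
    sc <- score_snp_dmr(mixture, as.integer(gsub[i, samples]), mu,
                        orientation)
    data.frame(snp_id = gsub$snp_id[i], chrom = gsub$chrom[i],
               pos = gsub$pos[i], distance = dist[i], score = sc$score,
               orientation = if (is.na(sc$score)) NA_character_ else sc$orientation,
               n_missing = sc$n_missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$score) & out$score > threshold, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score all DMRs against all SNPs in their windows
#'
#' Pools the core methylations of all DMRs across samples, fits the
#' three-component beta mixture on them (unless one is supplied), and runs
#' [scan_window()] for every DMR.
#'
#' @param dmrs a `dmr_table`.
#' @param genotypes a `genotype_table`.
#' @param mixture optional pre-fitted `beta_mixture`.
#' @param ... passed to [scan_window()].
#' @return list: `scores` (data.frame with dmr_id column), `mixture`.
#' @export
score_all_dmrs <- function(dmrs, genotypes, mixture = NULL, ...) {
  samples <- sub("^mu_", "", grep("^mu_", names(dmrs), value = TRUE))
  if (is.null(mixture)) {
    pool <- unlist(dmrs[paste0("mu_", samples)], use.names = FALSE)
    mixture <- fit_beta_mixture(pool)
  }
  res <- lapply(seq_len(nrow(dmrs)), function(i) {
    s <- scan_window(dmrs[i, ], genotypes, mixture, samples = samples, ...)
    if (nrow(s)) cbind(dmr_id = dmrs$dmr_id[i], s, stringsAsFactors = FALSE)
    else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  scores <- if (length(res)) do.call(rbind, res) else
    data.frame(dmr_id = character(), snp_id = character(), chrom = character(),
               pos = integer(), distance = integer(), score = numeric(),
               orientation = character(), n_missing = integer(),
               stringsAsFactors = FALSE)
  list(scores = scores, mixture = mixture)
}

#' Serialise a beta mixture to YAML
#' @param mixture a `beta_mixture`.
#' @param path output path.
#' @export
write_mixture <- function(mixture, path) {
  yaml::write_yaml(list(pi = mixture$pi, alpha = mixture$alpha,
                        beta = mixture$beta, loglik = mixture$loglik), path)
  invisible(path)
}

#' @export
#' @method print beta_mixture
print.beta_mixture <- function(x, ...) {
  cat("beta_mixture:", length(x$pi), "components\n")
  for (j in seq_along(x$pi))
    cat(sprintf("  comp %d: pi=%.3f alpha=%.2f beta=%.2f mean=%.3f\n",
                j - 1, x$pi[j], x$alpha[j], x$beta[j], x$means[j]))
  cat(sprintf("  loglik %.3f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}
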