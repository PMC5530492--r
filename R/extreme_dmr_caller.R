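# DMR discovery via synthetic extreme methylomes.
#
# Two synthetic methylomes are formed per cohort: one taking the highest and
# one the lowest methylation level of each CpG across samples. The per-CpG
# statistic t(c) = max(c) - min(c) replaces a two-group smoothed
# signal-to-noise statistic; candidate regions are maximal runs of CpGs with
# t(c) > v, then filtered by length and by the difference of the
# sigma-weighted core methylations of the two extremes.

#' DMR caller parameters
#'
#' @param v segmentation threshold on t(c) = max - min (default 0.5).
#' @param min_cpgs minimum member CpGs per DMR (default 4).
#' @param min_core_diff minimum difference between the core methylation of
#'   the max- and min-envelope over the region (default 0.8; implies at least
#'   one near-homozygously methylated and one near-homozygously unmethylated
#'   sample).
#' @param max_gap maximum bp between consecutive member CpGs (default 300).
#' @param core_norm `"sum_sigma"` normalises the sigma-weighted core
#'   methylation by the sum of weights so it is a convex combination staying
#'   in [0,1] (default; required by the beta-mixture stage);
#'   `"count"` divides by the number of member CpGs instead.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(v = 0.5, min_cpgs = 4, min_core_diff = 0.8,
                          max_gap = 300, core_norm = c("sum_sigma", "count")) {
  core_norm <- match.arg(core_norm)
  stopifnot(v > 0, v < 1, min_cpgs >= 2, min_core_diff > 0,
            min_core_diff <= 1, max_gap > 0)
  structure(list(v = v, min_cpgs = as.integer(min_cpgs),
                 min_core_diff = min_core_diff, max_gap = as.integer(max_gap),
                 core_norm = core_norm),
            class = "caller_params")
}

#' Build the extreme-methylome envelope of a cohort
#'
#' @param cohort a `cohort_matrix`.
#' @return data.frame: chrom, pos, max, min, t (= max - min) per aligned site.
#' @export
build_envelope <- function(cohort) {
  lv <- cohort$level
  mx <- do.call(pmax, as.data.frame(lv))
  mn <- do.call(pmin, as.data.frame(lv))
  data.frame(chrom = cohort$sites$chrom, pos = cohort$sites$pos,
             max = mx, min = mn, t = mx - mn, stringsAsFactors = FALSE)
}

#' Segment an envelope into candidate regions
#'
#' Maximal runs of consecutive CpGs with t(c) > v, broken at chromosome
#' boundaries and wherever the gap to the next qualifying CpG exceeds
#' `max_gap` bp.
#'
#' @param envelope from [build_envelope()].
#' @param params a [caller_params()] object.
#' @return list of integer vectors of site indices (rows of `envelope`).
#' @export
segment_envelope <- function(envelope, params = caller_params()) {
  keep <- envelope$t > params$v
  if (!any(keep)) return(list())
  idx <- which(keep)
  new_run <- c(TRUE,
               envelope$chrom[idx[-1]] != envelope$chrom[idx[-length(idx)]] |
                 envelope$pos[idx[-1]] - envelope$pos[idx[-length(idx)]] >
                   params$max_gap |
                 diff(idx) > 1L)
  split(idx, cumsum(new_run))
}

#' Core methylation of a region
#'
#' Cross-sample-standard-deviation-weighted average methylation over the
#' member CpGs: sites where samples disagree most carry the most weight, so
#' the value is robust to imprecise region borders. With `core_norm =
#' "sum_sigma"` the weights are normalised to sum to one (a convex
#' combination); if all weights are zero the unweighted mean is used.
#'
#' @param levels methylation levels at the member CpGs (one sample or one
#'   envelope track).
#' @param sigma per-site cross-sample standard deviations (same length).
#' @param core_norm see [caller_params()].
#' @return numeric scalar.
#' @export
core_methylation <- function(levels, sigma, core_norm = "sum_sigma") {
  if (length(levels) == 0) stop("empty region")
  if (length(levels) != length(sigma)) stop("levels/sigma length mismatch")
  if (core_norm == "count") return(sum(sigma * levels) / length(levels))
  s <- sum(sigma)
  if (s == 0) mean(levels) else sum(sigma * levels) / s
}

#' Call DMRs on an aligned cohort
#'
#' Segments the extreme-methylome envelope, keeps candidates with at least
#' `min_cpgs` member CpGs whose max-envelope and min-envelope core
#' methylations differ by at least `min_core_diff`, and computes the core
#' methylation of every sample over each retained region.
#'
#' @param cohort a `cohort_matrix`.
#' @param params a [caller_params()] object.
#' @return data.frame of class `dmr_table`, one row per DMR sorted by
#'   coordinate: dmr_id, chrom, start, end (member-CpG span, 1-based
#'   inclusive), n_cpgs, envelope_diff, p_value (NA until
#'   [empirical_pvalues()]), one `mu_<sample>` column per sample, and a
#'   `sites` list-column of member site indices into `cohort$sites`.
#' @export
call_dmrs <- function(cohort, params = caller_params()) {
  env <- build_envelope(cohort)
  runs <- segment_envelope(env, params)
  runs <- runs[lengths(runs) >= params$min_cpgs]
  keep <- list()
  for (r in runs) {
    sg <- cohort$sigma[r]
    d <- core_methylation(env$max[r], sg, params$core_norm) -
         core_methylation(env$min[r], sg, params$core_norm)
    if (d >= params$min_core_diff) keep[[length(keep) + 1L]] <- list(r = r, d = d)
  }
  out <- empty_dmr_table(cohort$samples)
  if (length(keep) == 0) return(out)
  rows <- lapply(seq_along(keep), function(i) {
    r <- keep[[i]]$r
    sg <- cohort$sigma[r]
    mus <- vapply(seq_along(cohort$samples), function(j)
      core_methylation(cohort$level[r, j], sg, params$core_norm), numeric(1))
    c(list(dmr_id = NA_character_,
           chrom = cohort$sites$chrom[r[1]],
           start = cohort$sites$pos[r[1]],
           end = cohort$sites$pos[r[length(r)]],
           n_cpgs = length(r), envelope_diff = keep[[i]]$d,
           p_value = NA_real_),
      stats::setNames(as.list(mus), paste0("mu_", cohort$samples)))
  })
  out <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  out$sites <- I(lapply(keep, `[[`, "r"))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$dmr_id <- sprintf("DMR%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("dmr_table", "data.frame")
  out
}

empty_dmr_table <- function(samples) {
  out <- data.frame(dmr_id = character(), chrom = character(),
                    start = integer(), end = integer(), n_cpgs = integer(),
                    envelope_diff = numeric(), p_value = numeric(),
                    stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("mu_", s)]] <- numeric()
  out$sites <- I(list())
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Smooth methylation levels with a coverage-weighted kernel (optional)
#'
#' Replaces each site's level by the coverage-weighted mean level over a
#' centred window of `width_bp`; counts are untouched. Off by default in the
#' pipeline: the envelope statistic and the binomial null operate on raw
#' levels.
#'
#' @param my a `methylome`.
#' @param width_bp window width in bp.
#' @return the methylome with smoothed `level`.
#' @export
smooth_methylome <- function(my, width_bp) {
  stopifnot(width_bp > 0)
  half <- width_bp / 2
  for (ch in unique(my$chrom)) {
    i <- which(my$chrom == ch)
    pos <- my$pos[i]
    w <- my$cov[i]
    lv <- my$level[i]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    cw <- cumsum(c(0, w))
    cwl <- cumsum(c(0, w * lv))
    my$level[i] <- (cwl[hi + 1L] - cwl[lo]) / (cw[hi + 1L] - cw[lo])
  }
  my
}

#' Export a DMR table
#'
#' BED6+ (chrom, 0-based start, end, id, envelope difference, ".", per-sample
#' core methylation, p value) or plain TSV.
#'
#' @param dmrs a `dmr_table`.
#' @param path output path.
#' @param format `"bed"` or `"tsv"`.
#' @export
write_dmrs <- function(dmrs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  df <- dmrs[, setdiff(names(dmrs), "sites"), drop = FALSE]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    mu <- df[, grep("^mu_", names(df)), drop = FALSE]
    mustr <- apply(mu, 1, function(x) paste(format(x, digits = 4), collapse = "\t"))
    if (nrow(df) == 0) mustr <- character()
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%s", df$chrom,
                       df$start - 1L, df$end, df$dmr_id,
                       format(df$envelope_diff, digits = 4), mustr,
                       ifelse(is.na(df$p_value), "NA",
                              format(df$p_value, digits = 4))),
               path)
  }
  invisible(path)
}
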