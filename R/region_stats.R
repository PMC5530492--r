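# Flanking-methylation profiles and annotation enrichment of DMRs against
# matched random region sets.

#' Flanking methylation profile of called DMRs
#'
#' Per DMR and side, the first `skip` CpGs beyond the border are ignored (to
#' avoid border effects) and the next `n_flank` CpGs are averaged; the flank
#' and DMR means are the cross-sample mean level (pooled; set
#' `per_sample = TRUE` for per-sample columns). Classification uses strict
#' inequalities: `lower_than_both` / `higher_than_both` when the DMR mean is
#' strictly below / above both flank means, `incomplete` when a flank has
#' fewer than `n_flank` CpGs available on its chromosome, `intermediate`
#' otherwise (ties included).
#'
#' @param dmrs a `dmr_table` called on `cohort`.
#' @param cohort the `cohort_matrix` the DMRs were called on.
#' @param skip CpGs to skip beyond each border (default 3).
#' @param n_flank CpGs to average per flank (default 10).
#' @param per_sample also emit per-sample flank/DMR means.
#' @return data.frame: dmr_id, dmr_mean, upstream_mean, downstream_mean,
#'   class.
#' @export
flank_profile <- function(dmrs, cohort, skip = 3, n_flank = 10,
                          per_sample = FALSE) {
  pooled <- rowMeans(cohort$level)
  n <- nrow(cohort$sites)
  rows <- lapply(seq_len(nrow(dmrs)), function(i) {
    r <- dmrs$sites[[i]]
    ch <- cohort$sites$chrom[r[1]]
    lo <- r[1]; hi <- r[length(r)]
    up_idx <- seq(lo - skip - n_flank, lo - skip - 1)
    dn_idx <- seq(hi + skip + 1, hi + skip + n_flank)
    up_ok <- all(up_idx >= 1) && all(cohort$sites$chrom[up_idx] == ch)
    dn_ok <- all(dn_idx <= n) && all(cohort$sites$chrom[dn_idx] == ch)
    up <- if (up_ok) mean(pooled[up_idx]) else NA_real_
    dn <- if (dn_ok) mean(pooled[dn_idx]) else NA_real_
    dm <- mean(pooled[r])
    cls <- if (!up_ok || !dn_ok) "incomplete"
      else if (dm < up && dm < dn) "lower_than_both"
      else if (dm > up && dm > dn) "higher_than_both"
      else "intermediate"
    out <- data.frame(dmr_id = dmrs$dmr_id[i], dmr_mean = dm,
                      upstream_mean = up, downstream_mean = dn, class = cls,
                      stringsAsFactors = FALSE)
    if (per_sample) {
      for (j in seq_along(cohort$samples)) {
        out[[paste0("dmr_mean_", cohort$samples[j])]] <- mean(cohort$level[r, j])
        out[[paste0("up_mean_", cohort$samples[j])]] <-
          if (up_ok) mean(cohort$level[up_idx, j]) else NA_real_
        out[[paste0("down_mean_", cohort$samples[j])]] <-
          if (dn_ok) mean(cohort$level[dn_idx, j]) else NA_real_
      }
    }
    out
  })
  if (!length(rows))
    return(data.frame(dmr_id = character(), dmr_mean = numeric(),
                      upstream_mean = numeric(), downstream_mean = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample random region sets matched to an observed size distribution
#'
#' Each set contains `regions_per_set` intervals whose lengths are resampled
#' with replacement from `sizes`; placements are uniform over the genome,
#' rejected unless the region covers at least `min_cpgs` CpGs and does not
#' intersect the repeat mask. Used to build the empirical null for
#' annotation enrichment.
#'
#' @param genome_sites data.frame chrom, pos of all CpGs.
#' @param sizes observed region lengths in bp (resampled with replacement).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param mask optional `region_set` of excluded (repeat) intervals.
#' @param n_sets number of random sets.
#' @param regions_per_set regions per set (default: length(sizes)).
#' @param min_cpgs minimum CpGs a region must cover (default 4).
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget as a multiple of the number of
#'   regions needed (default 200).
#' @return data.frame: set, chrom, start (1-based), end.
#' @export
sample_matched_regions <- function(genome_sites, sizes, chrom_lengths,
                                   mask = NULL, n_sets = 1000,
                                   regions_per_set = length(sizes),
                                   min_cpgs = 4, seed = 1, max_tries = 200) {
  stopifnot(length(sizes) >= 1, n_sets >= 1, regions_per_set >= 1)
  need <- n_sets * regions_per_set
  chroms <- names(chrom_lengths)
  site_pos <- split(genome_sites$pos, genome_sites$chrom)
  site_pos <- lapply(site_pos, sort)
  mask_gr <- if (!is.null(mask) && nrow(mask)) regions_to_granges(mask) else NULL
  with_seed(seed, {
    got <- 0L
    acc_chrom <- character(need); acc_start <- integer(need); acc_end <- integer(need)
    tries <- 0L
    batch <- max(need, 1000L)
    while (got < need && tries < max_tries * need) {
      m <- min(batch, (need - got) * 4L)
      tries <- tries + m
      ln <- sample(sizes, m, replace = TRUE)
      ch <- sample(chroms, m, replace = TRUE,
                   prob = chrom_lengths / sum(chrom_lengths))
      maxstart <- chrom_lengths[ch] - ln
      ok0 <- maxstart >= 1
      if (!any(ok0)) next
      ln <- ln[ok0]; ch <- ch[ok0]; maxstart <- maxstart[ok0]
      st <- as.integer(floor(stats::runif(length(ln), 1, maxstart + 1)))
      en <- st + as.integer(ln)
      # CpG count per candidate
      ncpg <- integer(length(st))
      for (cc in unique(ch)) {
        j <- which(ch == cc)
        sp <- site_pos[[cc]]
        if (is.null(sp)) { ncpg[j] <- 0L; next }
        ncpg[j] <- findInterval(en[j], sp) - findInterval(st[j] - 1L, sp)
      }
      ok <- ncpg >= min_cpgs
      if (!is.null(mask_gr) && any(ok)) {
        gr <- GenomicRanges::GRanges(ch[ok], IRanges::IRanges(st[ok], en[ok]))
        ok[ok] <- GenomicRanges::countOverlaps(gr, mask_gr) == 0
      }
      nk <- sum(ok)
      if (nk == 0) next
      take <- min(nk, need - got)
      sel <- which(ok)[seq_len(take)]
      acc_chrom[got + seq_len(take)] <- ch[sel]
      acc_start[got + seq_len(take)] <- st[sel]
      acc_end[got + seq_len(take)] <- en[sel]
      got <- got + take
    }
    if (got < need)
      stop("could not place ", need, " regions satisfying the constraints; ",
           "the eligible space is too small")
    data.frame(set = rep(seq_len(n_sets), each = regions_per_set),
               chrom = acc_chrom, start = acc_start, end = acc_end,
               stringsAsFactors = FALSE)
  })
}

# count, per label, how many of the query regions (1-based inclusive
# start/end) overlap >= 1 bp of an interval with that label
overlap_counts <- function(chrom, start, end, ann_gr, labels) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(gr, ann_gr)
  lab <- ann_gr$label[S4Vectors::subjectHits(hits)]
  qh <- S4Vectors::queryHits(hits)
  vapply(labels, function(L) length(unique(qh[lab == L])), integer(1))
}

#' Empirical enrichment of DMRs in labelled annotations
#'
#' Observed per-label overlap counts (a DMR overlaps a label if >= 1 bp
#' intersects an interval carrying it) are compared with counts from
#' matched random region sets. p_over is the fraction of random sets with a
#' strictly higher count, p_under the fraction with a strictly lower count;
#' ties count to neither.
#'
#' @param dmrs a `dmr_table`.
#' @param annotation a `region_set` with labels.
#' @param genome_sites data.frame chrom, pos of all CpGs.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param mask optional repeat mask `region_set`.
#' @param n_sets number of random sets (default 10000; values below 100 give
#'   a warning about resolution).
#' @param seed integer seed.
#' @return data.frame per label: label, observed, null_mean, p_over, p_under.
#' @export
enrichment_test <- function(dmrs, annotation, genome_sites, chrom_lengths,
                            mask = NULL, n_sets = 10000, seed = 1) {
  if (n_sets < 100)
    warning("n_sets < 100 gives poor p-value resolution")
  if (nrow(dmrs) == 0) stop("no DMRs to test")
  ann_gr <- regions_to_granges(annotation)
  labels <- sort(unique(annotation$label))
  obs <- overlap_counts(dmrs$chrom, dmrs$start, dmrs$end, ann_gr, labels)
  sizes <- dmrs$end - dmrs$start + 1L
  rnd <- sample_matched_regions(genome_sites, sizes, chrom_lengths,
                                mask = mask, n_sets = n_sets,
                                regions_per_set = nrow(dmrs), seed = seed)
  null_counts <- matrix(0L, n_sets, length(labels),
                        dimnames = list(NULL, labels))
  gr_all <- GenomicRanges::GRanges(rnd$chrom, IRanges::IRanges(rnd$start, rnd$end))
  hits <- GenomicRanges::findOverlaps(gr_all, ann_gr)
  lab <- ann_gr$label[S4Vectors::subjectHits(hits)]
  qh <- S4Vectors::queryHits(hits)
  set_of <- rnd$set
  for (L in labels) {
    q <- unique(qh[lab == L])
    tab <- table(factor(set_of[q], levels = seq_len(n_sets)))
    null_counts[, L] <- as.integer(tab)
  }
  data.frame(label = labels, observed = as.integer(obs),
             null_mean = colMeans(null_counts),
             p_over = colMeans(null_counts > rep(obs, each = n_sets)),
             p_under = colMeans(null_counts < rep(obs, each = n_sets)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical p values from explicit null counts
#'
#' @param observed observed count.
#' @param null_counts vector of counts from random sets.
#' @return list: p_over (fraction of null counts strictly above observed),
#'   p_under (strictly below); ties contribute to neither.
#' @export
empirical_overlap_p <- function(observed, null_counts) {
  list(p_over = mean(null_counts > observed),
       p_under = mean(null_counts < observed))
}

#' Partition DMR methylation differences by chromatin-state agreement
#'
#' A DMR is "different" between two donors iff the sets of state labels
#' overlapping it in the two annotations are disjoint; DMRs overlapping no
#' state in one donor are excluded with a warning. Returns the absolute
#' methylation differences partitioned into the two groups, ready for
#' [rank_sum_compare()].
#'
#' @param dmrs a `dmr_table`.
#' @param states_a,states_b per-donor chromatin-state `region_set`s.
#' @param meth_diffs absolute methylation differences between the donors,
#'   one per DMR.
#' @return list: `different`, `same` (numeric vectors), `excluded` (dmr ids).
#' @export
state_difference_partition <- function(dmrs, states_a, states_b, meth_diffs) {
  stopifnot(length(meth_diffs) == nrow(dmrs))
  gra <- regions_to_granges(states_a)
  grb <- regions_to_granges(states_b)
  gr <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  la <- label_sets(gr, gra)
  lb <- label_sets(gr, grb)
  none <- lengths(la) == 0 | lengths(lb) == 0
  if (any(none))
    warning(sum(none), " DMR(s) overlap no state in one donor; excluded")
  different <- mapply(function(a, b) length(intersect(a, b)) == 0, la, lb)
  use <- !none
  list(different = meth_diffs[use & different],
       same = meth_diffs[use & !different],
       excluded = dmrs$dmr_id[none])
}

label_sets <- function(gr, ann_gr) {
  hits <- GenomicRanges::findOverlaps(gr, ann_gr)
  out <- rep(list(character(0)), length(gr))
  sp <- split(ann_gr$label[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  out[as.integer(names(sp))] <- lapply(sp, unique)
  out
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Mann-Whitney U with the exact null when the combined size is at most 20
#' and there are no ties, the normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return list: statistic (U for group_a), p_value (two-sided).
#' @export
rank_sum_compare <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  exact <- (length(group_a) + length(group_b)) <= 20 &&
    !any(duplicated(c(group_a, group_b)))
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
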