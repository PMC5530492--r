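# Per-CpG methylation I/O and cohort alignment.
#
# A "methylome" is a data.frame with columns chrom, pos (1-based position of
# the C of a CpG on the forward strand, strands merged), meth (methylated
# read count), cov (total coverage) and level (meth/cov, NA when cov = 0).

#' Construct a validated methylome table
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector, 1-based CpG positions.
#' @param meth non-negative integer methylated-read counts.
#' @param cov non-negative integer total coverages; must satisfy `meth <= cov`.
#' @return A `data.frame` of class `methylome`, sorted by (chrom, pos) with
#'   unique positions per chromosome and a `level = meth/cov` column.
#' @export
methylome <- function(chrom, pos, meth, cov) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   meth = as.integer(meth), cov = as.integer(cov),
                   stringsAsFactors = FALSE)
  validate_methylome(df)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[c("chrom", "pos")])) {
    # duplicate positions: merge by summing counts
    key <- paste(df$chrom, df$pos)
    df <- data.frame(
      chrom = tapply(df$chrom, key, `[`, 1)[unique(key)],
      pos   = as.integer(tapply(df$pos, key, `[`, 1)[unique(key)]),
      meth  = as.integer(tapply(df$meth, key, sum)[unique(key)]),
      cov   = as.integer(tapply(df$cov, key, sum)[unique(key)]),
      stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
  }
  df$level <- ifelse(df$cov > 0, df$meth / df$cov, NA_real_)
  rownames(df) <- NULL
  class(df) <- c("methylome", "data.frame")
  df
}

validate_methylome <- function(df) {
  if (any(is.na(df$pos)) || any(is.na(df$meth)) || any(is.na(df$cov)))
    stop("methylome: NA in pos/meth/cov")
  if (any(df$meth < 0) || any(df$cov < 0))
    stop("methylome: negative counts")
  if (any(df$meth > df$cov))
    stop("methylome: methylated count exceeds coverage at ",
         sum(df$meth > df$cov), " site(s)")
  invisible(df)
}

#' Read a per-CpG methylation table
#'
#' Supported formats:
#' \describe{
#'   \item{`bismark_cov`}{Bismark coverage: chrom, start (1-based), end,
#'     methylation percentage, count methylated, count unmethylated.}
#'   \item{`bedgraph_counts`}{bedGraph dialect with counts: chrom, start
#'     (0-based), end, level, meth, cov.}
#' }
#' Records are sorted and deduplicated (counts at identical positions are
#' summed). With `merge_strands = TRUE`, a record at position p+1 immediately
#' following one at p is treated as the reverse-strand G of the same CpG and
#' its counts are added to the forward-strand C record.
#'
#' @param path file path.
#' @param format one of `"bismark_cov"`, `"bedgraph_counts"`.
#' @param merge_strands merge adjacent-position records (default FALSE; the
#'   supported formats do not carry a strand column, so merging is inferred
#'   from adjacency).
#' @return a `methylome` data.frame.
#' @export
read_methylome <- function(path, format = c("bismark_cov", "bedgraph_counts"),
                           merge_strands = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(methylome(character(), integer(), integer(), integer()))
  }
  nexp <- 6L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nexp)) {
    bad <- which(nf != nexp)[1]
    stop(sprintf("parse error in %s line %d: expected %d tab-separated fields, got %d",
                 path, bad, nexp, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = nexp, byrow = TRUE)
  if (format == "bismark_cov") {
    pos  <- suppressWarnings(as.integer(m[, 2]))
    meth <- suppressWarnings(as.integer(m[, 5]))
    unm  <- suppressWarnings(as.integer(m[, 6]))
    cov  <- meth + unm
  } else {
    pos  <- suppressWarnings(as.integer(m[, 2])) + 1L
    meth <- suppressWarnings(as.integer(m[, 5]))
    cov  <- suppressWarnings(as.integer(m[, 6]))
  }
  bad <- which(is.na(pos) | is.na(meth) | is.na(cov))
  if (length(bad))
    stop(sprintf("parse error in %s line %d: non-numeric coordinate or count",
                 path, bad[1]))
  my <- methylome(m[, 1], pos, meth, cov)
  if (merge_strands) my <- merge_cpg_strands(my)
  my
}

# Collapse p/p+1 adjacent records (C and G of one CpG) onto the C position.
merge_cpg_strands <- function(my) {
  keep <- rep(TRUE, nrow(my))
  i <- 1L
  while (i < nrow(my)) {
    if (my$chrom[i + 1] == my$chrom[i] && my$pos[i + 1] == my$pos[i] + 1L) {
      my$meth[i] <- my$meth[i] + my$meth[i + 1]
      my$cov[i] <- my$cov[i] + my$cov[i + 1]
      keep[i + 1] <- FALSE
      i <- i + 2L
    } else i <- i + 1L
  }
  methylome(my$chrom[keep], my$pos[keep], my$meth[keep], my$cov[keep])
}

#' Write a methylome table
#'
#' Output is canonical (sorted, deduplicated) and re-readable by
#' [read_methylome()] with equality of chrom/pos/meth/cov. For
#' `bedgraph_counts`, a zero-coverage record is written with level `NA`.
#'
#' @param my methylome data.frame (any object with chrom/pos/meth/cov).
#' @param path output path.
#' @param format as in [read_methylome()].
#' @return `path`, invisibly.
#' @export
write_methylome <- function(my, path, format = c("bismark_cov", "bedgraph_counts")) {
  format <- match.arg(format)
  my <- methylome(my$chrom, my$pos, my$meth, my$cov)
  if (format == "bismark_cov") {
    out <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", my$chrom, my$pos, my$pos,
                   ifelse(my$cov > 0, format(100 * my$meth / my$cov, digits = 10),
                          "NA"),
                   my$meth, my$cov - my$meth)
  } else {
    out <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", my$chrom, my$pos - 1L, my$pos,
                   ifelse(my$cov > 0, format(my$meth / my$cov, digits = 10), "NA"),
                   my$meth, my$cov)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a genotype table
#'
#' Supported formats:
#' \describe{
#'   \item{`vcf_minimal`}{VCF v4.x; only CHROM, POS, ID, REF, ALT and the GT
#'     subfield are used. Multiallelic sites are skipped with a warning;
#'     missing genotypes (`./.`) become `NA`.}
#'   \item{`tsv_dosage`}{header `snp_id chrom pos <sample...>`; dosages in
#'     \{0, 1, 2\} or NA.}
#' }
#'
#' @param path file path.
#' @param format one of `"vcf_minimal"`, `"tsv_dosage"`.
#' @param samples optional character vector; if given, the table must contain
#'   all of them (error listing any missing) and is restricted to them.
#' @return data.frame of class `genotype_table`: snp_id, chrom, pos, then one
#'   integer dosage column per sample (count of ALT alleles).
#' @export
read_genotypes <- function(path, format = c("vcf_minimal", "tsv_dosage"),
                           samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf_minimal") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      warning(sum(multi), " multiallelic site(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                       dimnames = list(NULL, colnames(v@gt)[-1]))
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    dos <- apply(gt, 2, gt_to_dosage)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(fix),
                                         dimnames = list(NULL, colnames(gt)))
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[is.na(ids) | ids == ".", "CHROM"], ":",
             fix[is.na(ids) | ids == ".", "POS"])
    out <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(dos))
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(out)))
      stop("tsv_dosage requires columns: ", paste(need, collapse = ", "))
    scol <- setdiff(names(out), need)
    for (s in scol) {
      d <- out[[s]]
      if (!all(is.na(d) | d %in% c(0, 1, 2)))
        stop("invalid dosage in column '", s, "': values must be 0, 1, 2 or NA")
      out[[s]] <- as.integer(d)
    }
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(out))
    if (length(missing))
      stop("genotype table lacks sample(s): ", paste(missing, collapse = ", "))
    out <- out[, c("snp_id", "chrom", "pos", samples)]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genotype_table", "data.frame")
  out
}

gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == "." | is.na(a)) || length(a) != 2) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
}

#' Sample columns of a genotype table
#' @param gt a `genotype_table`.
#' @return character vector of sample names.
#' @export
genotype_samples <- function(gt) setdiff(names(gt), c("snp_id", "chrom", "pos"))

#' Read a labelled region set (BED)
#'
#' BED3+label: chrom, start (0-based), end, label. Stored 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame of class `region_set`: chrom, start, end, label.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs >= 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    label = if (ncol(df) >= 4) as.character(df[[4]]) else ".",
                    stringsAsFactors = FALSE)
  region_set(out$chrom, out$start, out$end, out$label)
}

#' Construct a region set (0-based half-open intervals)
#' @param chrom,start,end,label interval fields; `start < end` required.
#' @return data.frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, label = ".") {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("region_set: start must be < end")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Write a region set to BED
#' @param rs `region_set`.
#' @param path output path.
#' @export
write_regions <- function(rs, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", rs$chrom, rs$start, rs$end, rs$label),
             path)
  invisible(path)
}

regions_to_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1L, end = rs$end),
                         label = rs$label)
}

#' Align multiple methylomes into a cohort matrix
#'
#' Keeps the intersection of CpG positions covered with at least `min_cov`
#' reads in every sample; per-site methylation level and the cross-sample
#' standard deviation sigma are computed on the retained sites. Sites missing
#' (or under-covered) in any sample are dropped, not imputed, because the
#' extreme-envelope statistic needs the max and min over all samples.
#'
#' @param methylomes named list of methylome data.frames (names = sample ids).
#' @param min_cov minimum per-sample coverage for a site to be retained
#'   (default 3).
#' @param sd_type `"population"` (divide by n; default, defined for 2 samples
#'   and bounded by 0.5) or `"sample"` (n - 1).
#' @return object of class `cohort_matrix`: list with `samples`, `sites`
#'   (data.frame chrom, pos), matrices `meth`, `cov`, `level` (sites x
#'   samples), and vector `sigma`.
#' @export
align_cohort <- function(methylomes, min_cov = 3,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(methylomes) < 1) stop("need at least one methylome")
  if (is.null(names(methylomes)) || any(!nzchar(names(methylomes))))
    names(methylomes) <- paste0("sample", seq_along(methylomes))
  keys <- lapply(methylomes, function(m) {
    m <- m[m$cov >= min_cov, , drop = FALSE]
    paste(m$chrom, m$pos, sep = ":")
  })
  common <- Reduce(intersect, keys)
  if (length(common) == 0)
    stop("no CpG site is covered >= ", min_cov,
         " in every sample; consider lowering min_cov")
  ref <- methylomes[[1]]
  refkey <- paste(ref$chrom, ref$pos, sep = ":")
  sel <- refkey %in% common
  sites <- data.frame(chrom = ref$chrom[sel], pos = ref$pos[sel],
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  skey <- paste(sites$chrom, sites$pos, sep = ":")
  n <- nrow(sites)
  k <- length(methylomes)
  meth <- cov <- matrix(0L, n, k, dimnames = list(NULL, names(methylomes)))
  for (j in seq_len(k)) {
    m <- methylomes[[j]]
    idx <- match(skey, paste(m$chrom, m$pos, sep = ":"))
    meth[, j] <- m$meth[idx]
    cov[, j] <- m$cov[idx]
  }
  level <- meth / cov
  structure(list(samples = names(methylomes), sites = sites, meth = meth,
                 cov = cov, level = level,
                 sigma = row_sd(level, sd_type), sd_type = sd_type,
                 min_cov = min_cov),
            class = "cohort_matrix")
}

row_sd <- function(x, type = "population") {
  n <- ncol(x)
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  if (type == "population") sqrt(ss / n)
  else if (n > 1) sqrt(ss / (n - 1)) else rep(0, nrow(x))
}

#' @export
#' @method print cohort_matrix
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", length(x$samples), "samples x", nrow(x$sites),
      "CpG sites (min_cov =", x$min_cov, ")\n")
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

# Build a cohort_matrix directly from matrices (used by the simulator and the
# null-replicate machinery; skips file round-trips).
cohort_from_matrices <- function(sites, meth, cov, samples,
                                 sd_type = "population", min_cov = 0) {
  level <- meth / cov
  structure(list(samples = samples, sites = sites, meth = meth, cov = cov,
                 level = level, sigma = row_sd(level, sd_type),
                 sd_type = sd_type, min_cov = min_cov),
            class = "cohort_matrix")
}
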