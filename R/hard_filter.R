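#' Hard-filter variant records on site quality annotations
#'
#' Applies the three post-calling filters used for resequencing SNP sets:
#' \enumerate{
#'   \item phred-scaled site quality `QUAL < qual_min` (default 30);
#'   \item `MQ0 > mq0_max` (default 4) \emph{and} quality-by-depth
#'     `QD < qd_min` (default 5) jointly;
#'   \item strand-bias Fisher phred score `FS > fs_max` (default 200).
#' }
#' A record is removed iff it violates at least one rule. A missing annotation
#' is treated conservatively as violating the comparison it is needed for
#' (filtering errs toward removing possible false positives); such records are
#' counted in `n_missing_annotation`.
#'
#' @param variants data.frame with numeric columns `qual`, `mq0`, `qd`, `fs`
#'   (as returned by [read_phased_vcf()]); other columns pass through.
#' @param qual_min,mq0_max,qd_min,fs_max rule thresholds.
#' @return A list:
#'   \describe{
#'     \item{passed}{the surviving rows, input order preserved.}
#'     \item{counts}{named integer vector of per-rule violation counts
#'       (`low_qual`, `mq0_qd`, `strand_bias`; not mutually exclusive) and
#'       `removed`, the total removed.}
#'     \item{n_missing_annotation}{rows where a missing annotation decided at
#'       least one rule.}
#'   }
#' @examples
#' v <- data.frame(qual = c(29, 50, 50), mq0 = c(0, 5, 0),
#'                 qd = c(20, 4, 20), fs = c(1, 1, 300))
#' hard_filter(v)$counts
#' @export
hard_filter <- function(variants, qual_min = 30, mq0_max = 4, qd_min = 5,
                        fs_max = 200) {
  need <- c("qual", "mq0", "qd", "fs")
  miss_cols <- setdiff(need, names(variants))
  if (length(miss_cols))
    stop("variants lacks columns: ", paste(miss_cols, collapse = ", "))
  cmp <- function(x, f) ifelse(is.na(x), TRUE, f(x))  # NA fails conservatively
  r1 <- cmp(variants$qual, function(x) x < qual_min)
  r2 <- cmp(variants$mq0, function(x) x > mq0_max) &
        cmp(variants$qd, function(x) x < qd_min)
  r3 <- cmp(variants$fs, function(x) x > fs_max)
  remove <- r1 | r2 | r3
  na_decided <- (is.na(variants$qual) & r1) |
    ((is.na(variants$mq0) | is.na(variants$qd)) & r2) |
    (is.na(variants$fs) & r3)
  list(passed = variants[!remove, , drop = FALSE],
       counts = c(low_qual = sum(r1), mq0_qd = sum(r2), strand_bias = sum(r3),
                  removed = sum(remove)),
       n_missing_annotation = sum(na_decided))
}

#' Genotype concordance between two callsets
#'
#' Fraction of matching diploid genotype calls over the (chrom, pos, sample)
#' triples present in both callsets. Calls are compared as unordered allele
#' pairs, so phase never causes discordance (chip genotypes are unphased).
#' Triples where either call is missing are excluded from the comparison.
#'
#' @param callset_x,callset_y data.frames with columns `chrom`, `pos`,
#'   `sample`, `gt` (as from [read_genotypes()]); `gt` may be `"i/j"` or
#'   `"i|j"` strings.
#' @return A list with `concordance` (matches / comparisons), `n_compared`
#'   and `n_matched`.
#' @export
genotype_concordance <- function(callset_x, callset_y) {
  norm <- function(df) {
    gt <- vapply(strsplit(as.character(df$gt), "[/|]"), function(p) {
      a <- suppressWarnings(as.integer(p))
      if (length(a) != 2L || anyNA(a)) NA_character_
      else paste(sort(a), collapse = "/")
    }, character(1L))
    data.frame(chrom = df$chrom, pos = df$pos, sample = df$sample, gt = gt,
               stringsAsFactors = FALSE)
  }
  m <- merge(norm(callset_x), norm(callset_y),
             by = c("chrom", "pos", "sample"), suffixes = c("_x", "_y"))
  if (!nrow(m))
    stop("callsets share no (chrom, pos, sample) triple")
  ok <- !is.na(m$gt_x) & !is.na(m$gt_y)
  m <- m[ok, , drop = FALSE]
  if (!nrow(m))
    stop("all shared triples have a missing call in one callset")
  matched <- sum(m$gt_x == m$gt_y)
  list(concordance = matched / nrow(m), n_compared = nrow(m),
       n_matched = matched)
}

#' Annotate windows with overlapping gene/QTL intervals
#'
#' A gene is assigned to a window iff the two share at least one bp (partial
#' overlap suffices); each gene is listed once per window. Both inputs use
#' 0-based half-open coordinates. Overlap is computed with
#' \pkg{GenomicRanges}.
#'
#' @param windows data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [make_windows()].
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`,
#'   e.g. from [read_intervals()].
#' @return `windows` with an added character column `genes` (comma-joined
#'   sorted unique names; `""` when none overlap).
#' @export
overlap_annotate <- function(windows, intervals) {
  gw <- GenomicRanges::GRanges(windows$chrom,
          IRanges::IRanges(windows$start + 1L, windows$end))
  gi <- GenomicRanges::GRanges(intervals$chrom,
          IRanges::IRanges(intervals$start + 1L, intervals$end))
  hits <- GenomicRanges::findOverlaps(gw, gi, minoverlap = 1L)
  genes <- character(nrow(windows))
  if (length(hits)) {
    by_win <- split(intervals$name[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    genes[as.integer(names(by_win))] <-
      vapply(by_win, function(g) paste(sort(unique(g)), collapse = ","),
             character(1L))
  }
  windows$genes <- genes
  windows
}
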