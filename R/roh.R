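#' Detect long runs of homozygosity (LROH)
#'
#' Scans each sample/chromosome for maximal runs of consecutive homozygous
#' genotype calls, allowing up to `het_tolerance` heterozygous calls inside
#' a run, and keeps runs spanning at least `min_length` bp (default 50 kb,
#' the long-ROH cutoff). Run boundaries are the first and last homozygous
#' call of the run; length = end - start + 1. Detection is greedy left to
#' right, so reported segments never overlap: when one more heterozygote
#' would exceed the tolerance the run is closed and the next run starts
#' after that heterozygote. Missing calls (`NA`) are ignored (they neither
#' break a run nor count as heterozygous); the ignored count is attached as
#' attribute `n_missing`.
#'
#' @param genotypes data.frame with columns `sample`, `chrom`, `pos`
#'   (1-based bp, sorted within sample/chrom) and `gt` (alternate-allele
#'   dosage 0/1/2, or `NA`), e.g. from [genotypes_from_haplotypes()] or
#'   [read_genotypes()] (string calls `"0/1"` are accepted and converted).
#' @param min_length minimum segment span in bp.
#' @param het_tolerance heterozygous calls tolerated inside one run.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end` (bp,
#'   both inclusive), `length`, `n_snps`; attribute `n_missing`.
#' @examples
#' g <- data.frame(sample = "s1", chrom = "1",
#'                 pos = seq(1000, 120000, by = 1000), gt = 0L)
#' detect_roh(g)
#' @export
detect_roh <- function(genotypes, min_length = 50000, het_tolerance = 0) {
  gt <- genotypes$gt
  if (is.character(gt) || is.factor(gt)) {
    parts <- strsplit(as.character(gt), "[/|]")
    gt <- vapply(parts, function(p) {  # dosage: hom-ref 0, het 1, hom-alt 2
      a <- suppressWarnings(as.integer(p))
      if (length(a) != 2L || anyNA(a)) NA_integer_
      else if (a[1L] != a[2L]) 1L else if (a[1L] == 0L) 0L else 2L
    }, integer(1L))
  }
  n_missing <- sum(is.na(gt))
  keep <- !is.na(gt)
  df <- data.frame(sample = genotypes$sample[keep],
                   chrom = genotypes$chrom[keep],
                   pos = genotypes$pos[keep], gt = gt[keep],
                   stringsAsFactors = FALSE)
  segs <- list()
  for (key in unique(paste(df$sample, df$chrom, sep = "\r"))) {
    sel <- paste(df$sample, df$chrom, sep = "\r") == key
    pos <- df$pos[sel]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions must be sorted strictly increasing within ",
           sub("\r", ":", key))
    het <- df$gt[sel] == 1L
    smp <- df$sample[sel][1L]
    chr <- df$chrom[sel][1L]
    n <- length(pos)
    start <- 1L
    while (start <= n) {
      # extend the run while the heterozygote budget lasts
      cum <- cumsum(het[start:n])
      over <- which(cum > het_tolerance)
      end <- if (length(over)) start + over[1L] - 2L else n
      if (end >= start) {
        hom_idx <- which(!het[start:end]) + start - 1L
        if (length(hom_idx)) {
          a <- hom_idx[1L]
          b <- hom_idx[length(hom_idx)]
          len <- pos[b] - pos[a] + 1
          if (len >= min_length)
            segs[[length(segs) + 1L]] <-
              data.frame(sample = smp, chrom = chr, start = pos[a],
                         end = pos[b], length = len, n_snps = b - a + 1L,
                         stringsAsFactors = FALSE)
        }
      }
      start <- end + 2L  # skip the heterozygote that closed the run
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), length = numeric(0),
               n_snps = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  out
}

#' Per-sample ROH burden summary
#'
#' Counts and total length of detected runs per sample, the two axes of the
#' classic ROH-burden comparison between populations.
#'
#' @param roh data.frame from [detect_roh()].
#' @param samples optional character vector of sample ids to report even
#'   when they carry no run (count and total 0).
#' @return data.frame with columns `sample`, `n_roh`, `total_bp`.
#' @export
roh_summary <- function(roh, samples = NULL) {
  ids <- if (is.null(samples)) unique(roh$sample) else samples
  out <- data.frame(sample = ids,
                    n_roh = vapply(ids, function(s)
                      sum(roh$sample == s), integer(1L)),
                    total_bp = vapply(ids, function(s)
                      sum(roh$length[roh$sample == s]), numeric(1L)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
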