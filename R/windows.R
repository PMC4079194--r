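#' Summarize per-SNP scores into nonoverlapping genomic windows
#'
#' Splits each chromosome into nonoverlapping windows of `window_bp`
#' (default 50 kb), anchored at coordinate 0, and records for each occupied
#' window the number of scored SNPs and the maximum score (the window
#' summary statistic). Windows containing no scored SNP are not ranked; when
#' `chrom_lengths` is supplied they are enumerated in the `empty_windows`
#' attribute and the trailing partial window of each chromosome is clipped
#' and flagged.
#'
#' @param scores data.frame with columns `chrom`, `pos` (bp offset on the
#'   0-based axis, so a SNP at exactly a window boundary opens the next
#'   window; convert 1-based VCF/matrix positions with `pos - 1`) and
#'   `score` (e.g. the `std` column of [xpehh_scan()]).
#' @param window_bp window width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `max_score`, `partial`; attribute
#'   `empty_windows` when `chrom_lengths` is given.
#' @export
make_windows <- function(scores, window_bp = 50000, chrom_lengths = NULL) {
  need <- c("chrom", "pos", "score")
  if (!all(need %in% names(scores)))
    stop("scores needs columns: ", paste(need, collapse = ", "))
  if (anyNA(scores$score)) {
    scores <- scores[!is.na(scores$score), , drop = FALSE]
  }
  win <- scores$pos %/% window_bp  # pos is already on the 0-based axis
  key <- paste(scores$chrom, win, sep = "\r")
  agg <- vapply(split(scores$score, key), max, numeric(1L))
  cnt <- vapply(split(scores$score, key), length, integer(1L))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1L), 1L),
    start = as.numeric(vapply(parts, `[`, character(1L), 2L)) * window_bp,
    stringsAsFactors = FALSE)
  out$end <- out$start + window_bp
  out$n_snps <- as.integer(cnt)
  out$max_score <- as.numeric(agg)
  out$partial <- FALSE
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(chrom_lengths)) {
    empties <- list()
    for (ch in unique(out$chrom)) {
      len <- chrom_lengths[[ch]]
      if (is.null(len)) next
      sel <- out$chrom == ch
      out$end[sel] <- pmin(out$end[sel], len)
      out$partial[sel] <- out$end[sel] - out$start[sel] < window_bp
      all_start <- seq(0, len - 1, by = window_bp)
      miss <- setdiff(all_start, out$start[sel])
      if (length(miss))
        empties[[ch]] <- data.frame(chrom = ch, start = miss,
                                    end = pmin(miss + window_bp, len),
                                    stringsAsFactors = FALSE)
    }
    attr(out, "empty_windows") <-
      if (length(empties)) do.call(rbind, empties) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0))
  }
  out
}

#' Bin windows by SNP count
#'
#' Windows are binned in increments of `bin_snps` SNPs (1--200, 201--400,
#' 401--599 with the defaults) and all windows with `>= top_min` SNPs are
#' combined into one top bin, so that the empirical ranking compares windows
#' of similar SNP density.
#'
#' @param windows data.frame from [make_windows()] (needs `n_snps >= 1`).
#' @param bin_snps bin increment in SNPs.
#' @param top_min SNP count at and above which windows join the combined top
#'   bin.
#' @return `windows` with an integer `bin_id` column (0-based).
#' @export
assign_bins <- function(windows, bin_snps = 200, top_min = 600) {
  if (any(windows$n_snps < 1L)) stop("every window must have n_snps >= 1")
  top_id <- (top_min - 1L) %/% bin_snps + 1L
  windows$bin_id <- ifelse(windows$n_snps >= top_min, top_id,
                           (windows$n_snps - 1L) %/% bin_snps)
  windows
}

#' Rank-based empirical P-values within SNP-count bins
#'
#' Within each bin of N windows, the empirical P of window i is the fraction
#' of bin members whose summary statistic strictly exceeds window i's
#' (`convention = "strict"`; ties share a P, and each bin's best window gets
#' P = 0). `convention = "plus_one"` uses (k+1)/(N+1) instead. Bins with
#' fewer than `min_bin` members are merged into the adjacent lower bin (with
#' a message) so every P rests on a reasonable reference set.
#'
#' When `reference` is supplied (a binned window set, e.g. pooled windows
#' from neutral simulations), each window is ranked against the reference
#' members of its bin instead of against its own set: the reference acts as
#' the empirical null distribution.
#'
#' @param windows data.frame from [assign_bins()].
#' @param min_bin minimum bin occupancy before merging downward.
#' @param reference optional binned window set serving as the null.
#' @param convention `"strict"` (fraction strictly greater) or `"plus_one"`.
#' @return `windows` with columns `bin_id` (after merging) and `emp_p`.
#' @export
empirical_p <- function(windows, min_bin = 50, reference = NULL,
                        convention = c("strict", "plus_one")) {
  convention <- match.arg(convention)
  if (is.null(windows$bin_id)) stop("run assign_bins() first")
  pool <- if (is.null(reference)) windows else reference
  if (is.null(pool$bin_id)) stop("reference must be binned")
  # merge sparse bins downward (by the pool that defines the null)
  repeat {
    occ <- table(factor(pool$bin_id, levels = sort(unique(pool$bin_id))))
    small <- names(occ)[occ < min_bin]
    if (!length(small)) break
    b <- max(as.integer(small))
    lower <- sort(unique(pool$bin_id[pool$bin_id < b]))
    if (!length(lower)) {
      if (length(unique(pool$bin_id)) == 1L) break
      tgt <- min(setdiff(unique(pool$bin_id), b))
    } else tgt <- max(lower)
    message(sprintf("bin %d has %d < %d windows; merging into bin %d",
                    b, occ[[as.character(b)]], min_bin, tgt))
    pool$bin_id[pool$bin_id == b] <- tgt
    windows$bin_id[windows$bin_id == b] <- tgt
  }
  if (any(!windows$bin_id %in% pool$bin_id))
    windows$bin_id[!windows$bin_id %in% pool$bin_id] <- max(pool$bin_id)
  windows$emp_p <- NA_real_
  for (b in unique(windows$bin_id)) {
    ref_scores <- sort(pool$max_score[pool$bin_id == b])
    n_ref <- length(ref_scores)
    if (n_ref < 2L) stop("bin ", b, " has fewer than 2 reference windows")
    sel <- windows$bin_id == b
    greater <- n_ref - findInterval(windows$max_score[sel], ref_scores)
    windows$emp_p[sel] <- switch(convention,
      strict = greater / n_ref,
      plus_one = (greater + 1) / (n_ref + 1))
  }
  windows
}

#' Flag significant windows and build the candidate-region report
#'
#' A window is significant iff its empirical P is strictly below
#' `threshold` (default 0.01, the 1% outlier level). The report lists the
#' flagged windows sorted by empirical P then by descending summary score.
#'
#' @param windows data.frame from [empirical_p()].
#' @param threshold empirical-P significance level.
#' @return list with `windows` (all windows plus a `significant` flag) and
#'   `report` (the flagged subset, sorted).
#' @export
call_significant <- function(windows, threshold = 0.01) {
  if (is.null(windows$emp_p)) stop("run empirical_p() first")
  windows$significant <- windows$emp_p < threshold
  rep_df <- windows[windows$significant, , drop = FALSE]
  rep_df <- rep_df[order(rep_df$emp_p, -rep_df$max_score), , drop = FALSE]
  rownames(rep_df) <- NULL
  list(windows = windows, report = rep_df)
}

#' Ingest externally computed selection scores for empirical ranking
#'
#' Reads a TSV of per-window scores (`chrom`, `start`, `end`, `score`) or
#' per-SNP scores (`chrom`, `pos`, `score`), e.g. cross-population composite
#' likelihood ratio (XP-CLR) output, builds windows with the same machinery
#' when needed, and reports the top-1% empirical threshold: the score at the
#' 99th percentile of the window score distribution (order statistic at rank
#' `ceiling(0.99 N)`); windows strictly above it are the top set.
#'
#' @param path TSV file with a header line.
#' @param window_bp window width used when per-SNP scores are supplied.
#' @param top_fraction outlier fraction (default 0.01).
#' @return list with `windows` (chrom/start/end/n_snps/max_score),
#'   `threshold` (the top-`top_fraction` score cutoff) and `top` (windows
#'   strictly above it).
#' @export
ingest_external_scores <- function(path, window_bp = 50000,
                                   top_fraction = 0.01) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (all(c("chrom", "start", "end", "score") %in% names(df))) {
    bad <- which(!is.finite(df$score) | df$start < 0 | df$end <= df$start)
    if (length(bad))
      stop("malformed score row at line ", bad[1L] + 1L, " of ", path)
    windows <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                          n_snps = NA_integer_, max_score = df$score,
                          stringsAsFactors = FALSE)
  } else if (all(c("chrom", "pos", "score") %in% names(df))) {
    bad <- which(!is.finite(df$score) | df$pos < 0)
    if (length(bad))
      stop("malformed score row at line ", bad[1L] + 1L, " of ", path)
    windows <- make_windows(df, window_bp = window_bp)
  } else {
    stop("expected columns chrom/start/end/score or chrom/pos/score in ",
         path)
  }
  s <- sort(windows$max_score)
  thr <- s[ceiling((1 - top_fraction) * length(s))]
  top <- windows[windows$max_score > thr, , drop = FALSE]
  rownames(top) <- NULL
  list(windows = windows, threshold = thr, top = top)
}

#' Intersection of two window sets
#'
#' Windows identified by identical (chrom, start, end) triples, e.g. for
#' counting regions supported by two independent selection statistics.
#'
#' @param w1,w2 window data.frames with `chrom`, `start`, `end`.
#' @return The rows of `w1` whose (chrom, start, end) also occur in `w2`.
#' @export
window_intersection <- function(w1, w2) {
  k1 <- paste(w1$chrom, w1$start, w1$end)
  k2 <- paste(w2$chrom, w2$start, w2$end)
  out <- w1[k1 %in% k2, , drop = FALSE]
  rownames(out) <- NULL
  out
}
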