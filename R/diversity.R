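#' Windowed nucleotide diversity
#'
#' Nucleotide diversity per window: the average number of pairwise
#' differences per site between haplotypes of one population,
#' `pi = sum_sites 2 p (1-p) n/(n-1) / window_bp`, with p the alternate
#' allele frequency among the population's n haplotypes. The denominator is
#' the full window length (per-site diversity over a fixed grid), so
#' monomorphic windows report 0. The grid is anchored at coordinate 0 and
#' covers the whole `region_bp` of the matrix; a trailing partial window is
#' normalized by its actual width.
#'
#' @param mat a [haplotype_matrix()].
#' @param pop population label (`"A"`/`"B"`); at least 2 haplotypes.
#' @param window_bp window width in bp (10 kb for gene views; use larger
#'   windows for genome-scale summaries).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `pop`, `pi`, `n_sites` (polymorphic sites used).
#' @export
window_pi <- function(mat, pop, window_bp = 10000) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  rows <- which(mat$pop_labels == pop)
  n <- length(rows)
  if (n < 2L) stop("pi needs at least 2 haplotypes in population ", pop)
  p <- colMeans(mat$alleles[rows, , drop = FALSE])
  h <- 2 * p * (1 - p) * n / (n - 1)
  win <- (mat$positions - 1L) %/% window_bp
  n_win <- max(1L, ceiling(mat$region_bp / window_bp))
  pi_sum <- nsite <- numeric(n_win)
  tab_sum <- tapply(h, win, sum)
  tab_n <- tapply(h > 0, win, sum)
  idx <- as.integer(names(tab_sum)) + 1L
  pi_sum[idx] <- tab_sum
  nsite[idx] <- tab_n
  start <- (seq_len(n_win) - 1L) * window_bp
  end <- pmin(start + window_bp, mat$region_bp)
  data.frame(chrom = mat$chrom, start = start, end = end, pop = pop,
             pi = pi_sum / (end - start), n_sites = as.integer(nsite),
             stringsAsFactors = FALSE)
}

#' Contrast windowed diversity between the two populations
#'
#' Joins two [window_pi()] tracks on a shared grid and reports the
#' per-window difference and a reduction flag; optionally summarizes mean
#' diversity inside supplied gene intervals against flanking regions, the
#' signature a completed sweep leaves (local diversity loss relative to the
#' neighbourhood).
#'
#' @param windows_a,windows_b [window_pi()] outputs for populations A and B
#'   on identical grids.
#' @param intervals optional data.frame of gene intervals (`chrom`, `start`,
#'   `end`, `name`, 0-based half-open).
#' @param flank_bp width of the flanking region on each side used for the
#'   gene-level summary.
#' @return list with `windows` (columns `chrom`, `start`, `end`, `pi_a`,
#'   `pi_b`, `diff`, `a_lower`) and, when `intervals` is given, `regions`
#'   (per gene: mean pi inside and in flanks, per population).
#' @export
diversity_contrast <- function(windows_a, windows_b, intervals = NULL,
                               flank_bp = 50000) {
  if (nrow(windows_a) != nrow(windows_b) ||
      !all(windows_a$chrom == windows_b$chrom) ||
      !all(windows_a$start == windows_b$start) ||
      !all(windows_a$end == windows_b$end))
    stop("window grids do not match")
  out <- data.frame(chrom = windows_a$chrom, start = windows_a$start,
                    end = windows_a$end, pi_a = windows_a$pi,
                    pi_b = windows_b$pi,
                    diff = windows_a$pi - windows_b$pi,
                    stringsAsFactors = FALSE)
  out$a_lower <- out$pi_a < out$pi_b
  res <- list(windows = out)
  if (!is.null(intervals)) {
    mean_in <- function(pi, lo, hi) {
      sel <- out$start < hi & out$end > lo
      if (!any(sel)) NA_real_ else mean(pi[sel])
    }
    res$regions <- do.call(rbind, lapply(seq_len(nrow(intervals)),
      function(i) {
        lo <- intervals$start[i]; hi <- intervals$end[i]
        data.frame(
          name = intervals$name[i],
          pi_a_in = mean_in(out$pi_a, lo, hi),
          pi_a_flank = mean(c(mean_in(out$pi_a, lo - flank_bp, lo),
                              mean_in(out$pi_a, hi, hi + flank_bp)),
                            na.rm = TRUE),
          pi_b_in = mean_in(out$pi_b, lo, hi),
          pi_b_flank = mean(c(mean_in(out$pi_b, lo - flank_bp, lo),
                              mean_in(out$pi_b, hi, hi + flank_bp)),
                            na.rm = TRUE),
          stringsAsFactors = FALSE)
      }))
  }
  res
}
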