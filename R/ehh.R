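# Shared EHH kernel. Starting from the haplotype grouping induced by the
# core site, groups are refined marker by marker moving outward; at each
# marker EHH = sum_g C(e_g, 2) / C(n, 2) over current group sizes e_g.
# Haplotypes of both core alleles are pooled (site-pooled EHH, the definition
# the cross-population log-ratio uses). Early exit once EHH < stop_below:
# the returned curve includes the first value below the cutoff.
.ehh_curve <- function(al, core, marker_idx, stop_below = -1) {
  n <- nrow(al)
  denom <- n * (n - 1) / 2
  g <- al[, core] + 1L
  out <- numeric(length(marker_idx))
  for (i in seq_along(marker_idx)) {
    g <- g * 2L + al[, marker_idx[i]]
    g <- match(g, unique(g))
    cnt <- tabulate(g)
    out[i] <- sum(cnt * (cnt - 1) / 2) / denom
    if (out[i] < stop_below) return(out[seq_len(i)])
  }
  out
}

.trapezoid_ihh <- function(core_pos, marker_pos, ehh) {
  x <- c(0, abs(marker_pos - core_pos))
  y <- c(1, ehh)
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Extended haplotype homozygosity decay around a core site
#'
#' EHH at marker k is the probability that two haplotypes drawn without
#' replacement from the subset are identical at every site from the core
#' through k: `EHH(k) = sum_g C(e_g, 2) / C(n, 2)` with `e_g` the sizes of
#' the identity classes. Both core alleles are pooled. EHH at the core
#' itself is defined as 1; the decay is computed separately leftward and
#' rightward.
#'
#' @param mat a [haplotype_matrix()].
#' @param core_index column index of the core site.
#' @param pop population label to restrict to, or `NULL` for the pooled
#'   sample (at least 2 haplotypes required).
#' @return An object of class `EHHDecay`: list with `core_index`, `core_pos`,
#'   `pop`, and data.frames `left` / `right` (columns `pos`, `ehh`) ordered
#'   outward from the core.
#' @export
compute_ehh <- function(mat, core_index, pop = NULL) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  m <- ncol(mat$alleles)
  if (core_index < 1L || core_index > m) stop("core_index out of range")
  rows <- if (is.null(pop)) seq_len(nrow(mat$alleles)) else
    which(mat$pop_labels == pop)
  if (length(rows) < 2L)
    stop("EHH needs at least 2 haplotypes in the chosen subset")
  al <- mat$alleles[rows, , drop = FALSE]
  left_idx <- if (core_index > 1L) seq(core_index - 1L, 1L) else integer(0)
  right_idx <- if (core_index < m) seq(core_index + 1L, m) else integer(0)
  structure(list(
    core_index = core_index, core_pos = mat$positions[core_index],
    pop = if (is.null(pop)) "pooled" else pop,
    left = data.frame(pos = mat$positions[left_idx],
                      ehh = .ehh_curve(al, core_index, left_idx)),
    right = data.frame(pos = mat$positions[right_idx],
                       ehh = .ehh_curve(al, core_index, right_idx))),
    class = "EHHDecay")
}

#' Integration boundary for iHH from the pooled sample
#'
#' The boundary on each side is the outermost marker at which pooled-sample
#' EHH is still `>= cutoff`; the same boundary is applied to both
#' populations' integrals so the cross-population ratio compares like with
#' like. If no marker on a side reaches the cutoff the boundary collapses to
#' the core position (that side contributes nothing); if the chromosome edge
#' is reached before EHH decays below the cutoff, the edge is the boundary
#' and the side is flagged.
#'
#' @param mat a [haplotype_matrix()].
#' @param core_index column index of the core site.
#' @param cutoff EHH truncation level in (0, 1); `cutoff = 0` extends the
#'   boundary to the chromosome edges.
#' @return list with `left`, `right` (boundary positions, bp) and `edge`
#'   (named logical: cutoff not reached before the edge).
#' @export
truncation_boundary <- function(mat, core_index, cutoff = 0.05) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  m <- ncol(mat$alleles)
  core_pos <- mat$positions[core_index]
  side <- function(idx) {
    if (!length(idx))
      return(list(pos = core_pos, edge = TRUE))
    curve <- .ehh_curve(mat$alleles, core_index, idx, stop_below = cutoff)
    n_ok <- sum(curve >= cutoff)  # curve is non-increasing
    list(pos = if (n_ok) mat$positions[idx[n_ok]] else core_pos,
         edge = n_ok == length(idx))
  }
  l <- side(if (core_index > 1L) seq(core_index - 1L, 1L) else integer(0))
  r <- side(if (core_index < m) seq(core_index + 1L, m) else integer(0))
  list(left = l$pos, right = r$pos,
       edge = c(left = l$edge, right = r$edge))
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH decay against physical distance from the
#' core, left side plus right side, truncated at the supplied boundary. The
#' core contributes the anchor point (distance 0, EHH 1). Units: bp x EHH.
#'
#' @param decay an [compute_ehh()] result.
#' @param boundary optional [truncation_boundary()] result; `NULL` integrates
#'   the full decay.
#' @return iHH as a single number.
#' @export
compute_ihh <- function(decay, boundary = NULL) {
  stopifnot(inherits(decay, "EHHDecay"))
  l <- decay$left
  r <- decay$right
  if (!is.null(boundary)) {
    l <- l[l$pos >= boundary$left, , drop = FALSE]
    r <- r[r$pos <= boundary$right, , drop = FALSE]
  }
  .trapezoid_ihh(decay$core_pos, l$pos, l$ehh) +
    .trapezoid_ihh(decay$core_pos, r$pos, r$ehh)
}

#' Cross-population XP-EHH scan
#'
#' For every site: the pooled-sample truncation boundary is found at
#' `cutoff`; EHH decays for populations A and B are integrated over that
#' common boundary; the raw score is `ln(iHH_A / iHH_B)`; raw scores are
#' standardized genome-wide to mean 0 and variance 1 (population variance,
#' denominator n). Extreme positive standardized scores indicate a sweep in
#' A, extreme negative in B. Sites where either iHH is zero are flagged
#' undefined and excluded from standardization.
#'
#' On a genome-wide scan the internal standardization is the statistic's own
#' definition. On a single short simulated region that is entirely under
#' selection it hides the region-wide shift (the region is its own
#' reference); pass `norm = c(mean, sd)` taken from a neutral null (e.g.
#' pooled neutral replicates) to standardize against an external reference
#' instead, the analogue of genome-wide standardization on real data.
#'
#' @param mat a [haplotype_matrix()] with at least 2 haplotypes per
#'   population.
#' @param cutoff pooled-EHH truncation cutoff (default 0.05).
#' @param pops labels of the two populations (numerator first).
#' @param norm optional external normalization `c(mean, sd)` applied to the
#'   raw log-ratios instead of the scan's own moments.
#' @return data.frame with columns `chrom`, `index`, `pos`, `ihh_a`,
#'   `ihh_b`, `raw`, `std`, `defined`, plus attribute `n_undefined`.
#' @examples
#' m <- simulate_neutral(sim_config(seed = 7))
#' head(xpehh_scan(m))
#' @export
xpehh_scan <- function(mat, cutoff = 0.05, pops = c("A", "B"),
                       norm = NULL) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  rows_a <- which(mat$pop_labels == pops[1L])
  rows_b <- which(mat$pop_labels == pops[2L])
  if (length(rows_a) < 2L || length(rows_b) < 2L)
    stop("each population needs at least 2 haplotypes")
  al <- mat$alleles
  al_a <- al[rows_a, , drop = FALSE]
  al_b <- al[rows_b, , drop = FALSE]
  pos <- mat$positions
  m <- ncol(al)
  ihh_a <- ihh_b <- numeric(m)
  for (core in seq_len(m)) {
    for (dir in c(-1L, 1L)) {
      idx <- if (dir < 0L) {
        if (core > 1L) seq(core - 1L, 1L) else integer(0)
      } else {
        if (core < m) seq(core + 1L, m) else integer(0)
      }
      if (!length(idx)) next
      pooled <- .ehh_curve(al, core, idx, stop_below = cutoff)
      n_ok <- sum(pooled >= cutoff)
      if (!n_ok) next
      keep <- idx[seq_len(n_ok)]
      ihh_a[core] <- ihh_a[core] +
        .trapezoid_ihh(pos[core], pos[keep], .ehh_curve(al_a, core, keep))
      ihh_b[core] <- ihh_b[core] +
        .trapezoid_ihh(pos[core], pos[keep], .ehh_curve(al_b, core, keep))
    }
  }
  defined <- ihh_a > 0 & ihh_b > 0
  raw <- ifelse(defined, log(ihh_a / ihh_b), NA_real_)
  if (sum(defined) < 2L)
    stop("fewer than 2 sites with defined XP-EHH; cannot standardize")
  if (is.null(norm)) {
    mu <- mean(raw[defined])
    sdev <- sqrt(mean((raw[defined] - mu)^2))  # population variance
  } else {
    mu <- norm[1L]
    sdev <- norm[2L]
  }
  if (sdev == 0) {
    warning("raw XP-EHH scores are constant; standardized scores set to 0")
    std <- ifelse(defined, 0, NA_real_)
  } else {
    std <- (raw - mu) / sdev
  }
  out <- data.frame(chrom = mat$chrom, index = seq_len(m), pos = pos,
                    ihh_a = ihh_a, ihh_b = ihh_b, raw = raw, std = std,
                    defined = defined, stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(!defined)
  out
}
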