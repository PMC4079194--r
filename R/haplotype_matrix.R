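#' Phased haplotype matrix for two populations
#'
#' The central container of the package: an `n_hap x m_sites` binary matrix of
#' phased alleles (0 = ancestral/reference, 1 = derived/alternate) with strictly
#' increasing physical positions, a chromosome id, and a per-haplotype
#' population label. All haplotype statistics ([compute_ehh()], [xpehh_scan()],
#' [window_pi()]) operate on this object.
#'
#' @param alleles integer or numeric matrix of 0/1 alleles, one row per
#'   haplotype, one column per segregating site.
#' @param positions integer vector of 1-based physical positions (bp), strictly
#'   increasing, one per column of `alleles`.
#' @param chrom chromosome identifier (single string).
#' @param pop_labels character vector of population tags, one per row of
#'   `alleles`; conventionally `"A"` and `"B"`.
#' @param sample_ids optional per-haplotype ids (`<sample>_h<1|2>`); generated
#'   when missing.
#' @param region_bp physical length of the region the matrix spans; defaults to
#'   the last position. Used to place window grids and to normalize positions
#'   when writing ms-format files.
#'
#' @return An object of class `HaplotypeMatrix`: a list with elements
#'   `alleles`, `positions`, `chrom`, `pop_labels`, `sample_ids`, `region_bp`.
#' @examples
#' m <- haplotype_matrix(matrix(c(0, 1, 1, 0), 2, 2), positions = c(100, 200),
#'                       pop_labels = c("A", "B"))
#' dim(m$alleles)
#' @export
haplotype_matrix <- function(alleles, positions, chrom = "1", pop_labels,
                             sample_ids = NULL, region_bp = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L)))
    stop("alleles must be binary (0/1)")
  positions <- as.integer(positions)
  if (length(positions) != ncol(alleles))
    stop("length(positions) must equal ncol(alleles)")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (length(positions) && any(positions < 1L))
    stop("positions are 1-based and must be >= 1")
  if (length(pop_labels) != nrow(alleles))
    stop("one pop label per haplotype row is required")
  if (anyNA(pop_labels)) stop("pop_labels must not contain NA")
  if (is.null(sample_ids)) {
    if (nrow(alleles) %% 2L != 0L)
      stop("n_hap must be even (diploid phased) when sample_ids are generated")
    sample_ids <- paste0(rep(paste0("ind", seq_len(nrow(alleles) / 2L)),
                             each = 2L), "_h", rep(1:2, nrow(alleles) / 2L))
  }
  if (length(sample_ids) != nrow(alleles))
    stop("one sample id per haplotype row is required")
  if (is.null(region_bp))
    region_bp <- if (length(positions)) max(positions) else 0L
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom)[1L],
                 pop_labels = as.character(pop_labels),
                 sample_ids = as.character(sample_ids),
                 region_bp = as.numeric(region_bp)),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  tab <- table(x$pop_labels)
  cat(sprintf("HaplotypeMatrix: %d haplotypes x %d sites on chrom %s (%s bp)\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom,
              format(x$region_bp, big.mark = ",")))
  cat("  populations:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.HaplotypeMatrix <- function(x) dim(x$alleles)

#' Restrict a haplotype matrix to one population
#'
#' @param mat a [haplotype_matrix()].
#' @param pop population label to keep.
#' @return A `HaplotypeMatrix` containing only the rows labelled `pop`.
#' @export
subset_pop <- function(mat, pop) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  keep <- mat$pop_labels == pop
  if (!any(keep)) stop("no haplotypes labelled '", pop, "'")
  haplotype_matrix(mat$alleles[keep, , drop = FALSE], mat$positions,
                   mat$chrom, mat$pop_labels[keep], mat$sample_ids[keep],
                   mat$region_bp)
}

#' Derived-allele frequencies
#'
#' @param mat a [haplotype_matrix()].
#' @param pop optional population label; default uses all haplotypes.
#' @return Numeric vector of per-site derived (alternate) allele frequencies.
#' @export
allele_freqs <- function(mat, pop = NULL) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  rows <- if (is.null(pop)) seq_len(nrow(mat$alleles)) else
    which(mat$pop_labels == pop)
  if (!length(rows)) stop("no haplotypes labelled '", pop, "'")
  colMeans(mat$alleles[rows, , drop = FALSE])
}

#' Collapse phased haplotypes to diploid genotype calls
#'
#' Pairs consecutive haplotype rows sharing a sample prefix (ids of the form
#' `<sample>_h1` / `<sample>_h2`) and returns alternate-allele dosages, the
#' long-format substrate of [detect_roh()].
#'
#' @param mat a [haplotype_matrix()] with an even number of rows per sample.
#' @return data.frame with columns `sample`, `chrom`, `pos`, `gt`
#'   (0/1/2 alternate-allele dosage).
#' @export
genotypes_from_haplotypes <- function(mat) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  samp <- sub("_h[12]$", "", mat$sample_ids)
  if (any(table(samp) != 2L))
    stop("every sample must contribute exactly two haplotypes")
  idx <- split(seq_along(samp), samp)
  out <- lapply(names(idx), function(s) {
    pair <- idx[[s]]
    data.frame(sample = s, chrom = mat$chrom, pos = mat$positions,
               gt = as.integer(mat$alleles[pair[1L], ] +
                               mat$alleles[pair[2L], ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
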