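#' Read phased genotypes and variant annotations from a VCF
#'
#' Loads a single-chromosome VCF (via \pkg{vcfR}), keeps biallelic SNPs only,
#' splits every phased diploid genotype into two haplotype rows and collects
#' the site-level quality annotations used by [hard_filter()].
#'
#' Multiallelic records, indels and records at duplicated positions are
#' skipped (counted, never an error); an unphased genotype is an error because
#' haplotype statistics are meaningless on unphased data.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param pop_assignment named character vector mapping every sample name in
#'   the VCF to a population tag (`"A"` or `"B"`).
#' @return A list with elements:
#'   \describe{
#'     \item{haplotypes}{a [haplotype_matrix()], two rows per sample.}
#'     \item{variants}{data.frame of retained sites with columns `chrom`,
#'       `pos`, `ref`, `alt`, `qual`, `mq0`, `qd`, `fs` (the hard-filter
#'       substrate; missing INFO keys become `NA`).}
#'     \item{n_skipped}{count of non-SNP / multiallelic / duplicate records.}
#'   }
#' @export
read_phased_vcf <- function(path, pop_assignment) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops the dim
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  missing_assign <- setdiff(samples, names(pop_assignment))
  if (length(missing_assign))
    stop("samples without a population assignment: ",
         paste(missing_assign, collapse = ", "))
  if (length(unique(fix$CHROM)) > 1L)
    stop("read_phased_vcf expects a single chromosome per file; found: ",
         paste(unique(fix$CHROM), collapse = ", "))
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  pos_all <- as.integer(fix$POS)
  keep <- is_snp & !duplicated(pos_all)
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in ", path)

  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key,
                                             as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, nrow(fix)) else as.numeric(x)
  }
  variants <- data.frame(
    chrom = fix$CHROM[keep], pos = pos_all[keep],
    ref = fix$REF[keep], alt = fix$ALT[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL))[keep],
    mq0 = info_num("MQ0")[keep], qd = info_num("QD")[keep],
    fs = info_num("FS")[keep], stringsAsFactors = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (anyNA(gt) || any(gt == "."))
    stop("missing genotypes are not allowed in phased haplotype input")
  unph <- grepl("/", gt, fixed = TRUE)
  dim(unph) <- dim(gt)  # grepl drops the matrix dims
  unphased <- which(unph, arr.ind = TRUE)
  if (nrow(unphased))
    stop(sprintf("unphased genotype at %s:%d sample %s (phased '|' required)",
                 variants$chrom[unphased[1L, 1L]],
                 variants$pos[unphased[1L, 1L]],
                 colnames(gt)[unphased[1L, 2L]]))
  h1 <- apply(gt, 2L, function(g) as.integer(substr(g, 1L, 1L)))
  h2 <- apply(gt, 2L, function(g) as.integer(substr(g, 3L, 3L)))
  if (anyNA(h1) || anyNA(h2) || any(h1 > 1L) || any(h2 > 1L))
    stop("genotypes must be biallelic 0|0, 0|1, 1|0 or 1|1")
  h1 <- matrix(h1, ncol = length(samples))
  h2 <- matrix(h2, ncol = length(samples))

  al <- matrix(0L, nrow = 2L * length(samples), ncol = sum(keep))
  ids <- character(2L * length(samples))
  pops <- character(2L * length(samples))
  for (j in seq_along(samples)) {
    al[2L * j - 1L, ] <- h1[, j]
    al[2L * j, ] <- h2[, j]
    ids[c(2L * j - 1L, 2L * j)] <- paste0(samples[j], "_h", 1:2)
    pops[c(2L * j - 1L, 2L * j)] <- pop_assignment[[samples[j]]]
  }
  ord <- order(variants$pos)
  list(haplotypes = haplotype_matrix(al[, ord, drop = FALSE],
                                     variants$pos[ord],
                                     variants$chrom[1L], pops, ids),
       variants = variants[ord, , drop = FALSE],
       n_skipped = n_skipped)
}

#' Read diploid genotype calls from a VCF
#'
#' Long-format genotype reader for [genotype_concordance()] and
#' [detect_roh()]; phase is ignored (calls are compared as unordered allele
#' pairs). Non-biallelic records are skipped.
#'
#' @param path path to a VCF file.
#' @return data.frame with columns `chrom`, `pos`, `sample`, `gt`, where `gt`
#'   is the normalized unordered call (`"0/1"`; missing calls are `NA`).
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L
  keep[is.na(keep)] <- FALSE
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  norm <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(p) {
      if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p))))
        return(NA_character_)
      paste(sort(as.integer(p)), collapse = "/")
    }, character(1L))
  }
  out <- data.frame(
    chrom = rep(fix$CHROM[keep], times = length(samples)),
    pos = rep(as.integer(fix$POS[keep]), times = length(samples)),
    sample = rep(samples, each = sum(keep)),
    gt = as.vector(apply(gt, 2L, norm)),
    stringsAsFactors = FALSE)
  out
}

#' Read gene/QTL intervals from BED or GFF3
#'
#' Thin wrapper over \pkg{rtracklayer} returning the package's internal
#' 0-based half-open interval convention.
#'
#' @param path path to a BED (3+ columns, optional name) or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `name`, sorted by chrom then start.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else
    "GFF3")
  nm <- if (!is.null(gr$Name) && !all(is.na(gr$Name))) as.character(gr$Name)
    else if (!is.null(gr$name)) as.character(gr$name)
    else if (!is.null(gr$ID)) as.character(gr$ID)
    else paste0("ivl", seq_along(gr))
  nm[is.na(nm) | !nzchar(nm)] <- paste0("ivl", which(is.na(nm) | !nzchar(nm)))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    name = nm, stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("intervals must satisfy start < end")
  out[order(out$chrom, out$start), , drop = FALSE]
}
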