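#' Write a haplotype matrix as ms-format text
#'
#' Emits the classic coalescent-simulator text layout: a command-like header,
#' one replicate block with `segsites:` and `positions:` lines (positions as
#' fractions of `region_bp`, full double precision so physical positions
#' round-trip exactly) followed by one 0/1 string per haplotype. Population-A
#' rows are written first; the header records the A count so [read_ms()] can
#' restore labels.
#'
#' @param mat a [haplotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(mat, path) {
  stopifnot(inherits(mat, "HaplotypeMatrix"))
  ord <- order(match(mat$pop_labels, c("A", "B")), seq_along(mat$pop_labels))
  al <- mat$alleles[ord, , drop = FALSE]
  n_a <- sum(mat$pop_labels == "A")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ms %d 1 -s %d -I 2 %d %d -r 0 %d",
            nrow(al), ncol(al), n_a, nrow(al) - n_a, as.integer(mat$region_bp)),
    "0 0 0", "", "//",
    sprintf("segsites: %d", ncol(al)),
    paste("positions:",
          paste(sprintf("%.17g", mat$positions / mat$region_bp),
                collapse = " ")),
    apply(al, 1L, paste, collapse = "")), con)
  invisible(path)
}

#' Read ms-format haplotype text
#'
#' Parses the first replicate block of an ms-style file. Positions (fractions
#' in (0,1]) are mapped back to integer bp on a region of length `region_bp`;
#' when `region_bp` is `NULL` it is recovered from a [write_ms()] header if
#' present, otherwise defaults to 1e6.
#'
#' @param path input file path.
#' @param n_pop_a number of leading rows labelled population A; when `NULL`,
#'   recovered from a `-I 2` header or defaulting to half the rows.
#' @param region_bp region length in bp used to scale positions.
#' @param chrom chromosome id to stamp on the result.
#' @return A [haplotype_matrix()].
#' @export
read_ms <- function(path, n_pop_a = NULL, region_bp = NULL, chrom = "1") {
  lines <- readLines(path)
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (is.null(region_bp)) {
    r_at <- which(head_tok == "-r")
    region_bp <- if (length(r_at) && length(head_tok) >= r_at + 2L)
      as.numeric(head_tok[r_at + 2L]) else 1e6
  }
  if (is.null(n_pop_a)) {
    i_at <- which(head_tok == "-I")
    n_pop_a <- if (length(i_at) && length(head_tok) >= i_at + 2L)
      as.integer(head_tok[i_at + 2L]) else NA_integer_
  }
  seg_at <- grep("^segsites:", lines)[1L]
  if (is.na(seg_at)) stop("no 'segsites:' line found in ", path)
  m <- as.integer(sub("^segsites:\\s*", "", lines[seg_at]))
  pos_at <- grep("^positions:", lines)[1L]
  frac <- as.numeric(strsplit(trimws(sub("^positions:", "", lines[pos_at])),
                              "\\s+")[[1L]])
  if (length(frac) != m) stop("positions line length does not match segsites")
  hap_lines <- lines[seq(pos_at + 1L, length(lines))]
  hap_lines <- hap_lines[nzchar(hap_lines)]
  hap_lines <- hap_lines[grepl("^[01]+$", hap_lines)]
  if (!length(hap_lines)) stop("no haplotype rows found in ", path)
  al <- do.call(rbind, lapply(strsplit(hap_lines, ""), as.integer))
  if (ncol(al) != m) stop("haplotype row width does not match segsites")
  n <- nrow(al)
  if (is.na(n_pop_a)) n_pop_a <- n %/% 2L
  pos <- as.integer(round(frac * region_bp))
  # distinct fractions can collide on the integer grid; nudge minimally
  while (any(dup <- duplicated(pos))) pos[dup] <- pos[dup] + 1L
  haplotype_matrix(al, pos, chrom,
                   rep(c("A", "B"), c(n_pop_a, n - n_pop_a)),
                   region_bp = region_bp)
}
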