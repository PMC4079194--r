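# Fixture builders and independent brute-force oracles. Oracles are written
# from the definitions, not from the package internals, so that equivalence
# tests are genuinely two routes to the same quantity.

random_hapmat <- function(n_hap = 10, m = 20, region_bp = 1e5,
                          n_a = n_hap %/% 2, maf = NULL) {
  al <- matrix(rbinom(n_hap * m, 1L, 0.5), n_hap, m)
  # ensure every site polymorphic
  for (j in seq_len(m)) {
    if (all(al[, j] == al[1L, j])) al[sample(n_hap, 1L), j] <- 1L - al[1L, j]
  }
  pos <- sort(sample.int(region_bp, m))
  haplotype_matrix(al, pos, chrom = "chrTest",
                   pop_labels = rep(c("A", "B"), c(n_a, n_hap - n_a)),
                   sample_ids = paste0("h", seq_len(n_hap)),
                   region_bp = region_bp)
}

# EHH by explicit all-pairs shared-segment counting
oracle_ehh <- function(al, core, k) {
  n <- nrow(al)
  lo <- min(core, k); hi <- max(core, k)
  same <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (all(al[i, lo:hi] == al[j, lo:hi])) same <- same + 1L
  }
  same / (n * (n - 1L) / 2L)
}

# empirical P by explicit pairwise comparison
oracle_emp_p <- function(scores) {
  vapply(scores, function(s) sum(scores > s), numeric(1L)) / length(scores)
}

# interval-window overlap by all-pairs check (0-based half-open)
oracle_overlap <- function(windows, intervals) {
  lapply(seq_len(nrow(windows)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(intervals))) {
      if (windows$chrom[i] == intervals$chrom[j] &&
          windows$start[i] < intervals$end[j] &&
          intervals$start[j] < windows$end[i])
        hits <- c(hits, intervals$name[j])
    }
    sort(unique(hits))
  })
}

# pi by all-pairs Hamming distance, averaged over pairs, per window length
oracle_window_pi <- function(al, pos, lo, hi, width) {
  sel <- which(pos > lo & pos <= hi)  # positions 1-based, window (lo, hi]
  n <- nrow(al)
  tot <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    tot <- tot + sum(al[i, sel] != al[j, sel])
  tot / (n * (n - 1L) / 2L) / width
}

# maximal homozygous runs via a run-length scan of the hom/het string
oracle_roh <- function(pos, het, min_length) {
  r <- rle(het)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    a <- pos[starts[k]]; b <- pos[ends[k]]
    if (b - a + 1 >= min_length)
      out[[length(out) + 1L]] <- c(start = a, end = b)
  }
  out
}

write_test_vcf <- function(path, records, samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"mq0\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(pos, gts, ref = "A", alt = "G", qual = 50,
                       info = "MQ0=0;QD=20;FS=1", chrom = "1") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT", gts),
        collapse = "\t")
}
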