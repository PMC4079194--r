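# Structured-coalescent engine for two demes with a split and an optional
# piecewise bottleneck. Internal time unit: 2*Ne generations, so k lineages
# in a deme of relative size x coalesce at rate choose(k,2)/x, and the
# per-tree mutation intensity for theta = 4*Ne*mu is theta_locus/2 per unit
# branch length (E[S] = theta_locus * sum 1/i).

# Returns list(leafsets = list of integer vectors, lengths = numeric):
# one entry per non-root branch, leafset = sample indices below the branch.
.coalescent_branches <- function(cfg, n_a = cfg$n_hap_a, n_b = cfg$n_hap_b) {
  n <- n_a + n_b
  if (n < 2L) stop("need at least two sampled haplotypes")
  two_ne <- 2 * cfg$n_e
  tau_split <- cfg$split_gen / two_ne
  has_bn <- !is.null(cfg$bottleneck)
  tb_start <- if (has_bn) cfg$bottleneck$start_gen / two_ne else Inf
  tb_end <- if (has_bn) cfg$bottleneck$end_gen / two_ne else Inf
  intensity <- if (has_bn) cfg$bottleneck$intensity else 1
  boundaries <- sort(unique(c(tau_split,
                              if (has_bn) c(tb_end, tb_start))))

  leafsets <- as.list(seq_len(n))
  deme <- rep(1:2, c(n_a, n_b))
  birth <- numeric(n)
  out_sets <- vector("list", 2L * (n - 1L))
  out_len <- numeric(2L * (n - 1L))
  bi <- 0L
  tau <- 0

  while (length(leafsets) > 1L) {
    k1 <- sum(deme == 1L)
    k2 <- length(deme) - k1
    # deme 1 carries the bottleneck; after the split the merged (ancestral)
    # lineage is deme 1, so an interval older than the split acts ancestrally
    size1 <- if (has_bn && tau >= tb_end && tau < tb_start) intensity else 1
    rate1 <- if (k1 >= 2L) k1 * (k1 - 1) / 2 / size1 else 0
    rate2 <- if (k2 >= 2L) k2 * (k2 - 1) / 2 else 0
    total <- rate1 + rate2
    nxt <- boundaries[boundaries > tau]
    nxt <- if (length(nxt)) nxt[1L] else Inf
    t_wait <- if (total > 0) stats::rexp(1L, total) else Inf
    if (tau + t_wait >= nxt) {
      tau <- nxt
      if (tau >= tau_split) deme[] <- 1L
      next
    }
    tau <- tau + t_wait
    d <- if (stats::runif(1L) * total < rate1) 1L else 2L
    in_d <- which(deme == d)
    pair <- in_d[sample.int(length(in_d), 2L)]
    for (ch in pair) {
      bi <- bi + 1L
      out_sets[[bi]] <- leafsets[[ch]]
      out_len[bi] <- tau - birth[ch]
    }
    merged <- c(leafsets[[pair[1L]]], leafsets[[pair[2L]]])
    keep <- -pair
    leafsets <- c(leafsets[keep], list(merged))
    birth <- c(birth[keep], tau)
    deme <- c(deme[keep], d)
  }
  list(leafsets = out_sets[seq_len(bi)], lengths = out_len[seq_len(bi)],
       n = n)
}

# Drops S mutations on the branches (probability proportional to length) and
# assembles the 0/1 matrix. Positions: distinct uniform integers in
# [1, region_bp], infinite-sites style on a bp grid.
.place_mutations <- function(br, cfg) {
  total_len <- sum(br$lengths)
  s_count <- if (!is.null(cfg$fixed_s)) as.integer(cfg$fixed_s)
    else stats::rpois(1L, cfg$theta * cfg$region_bp / 2 * total_len)
  n <- br$n
  if (s_count == 0L)
    return(list(alleles = matrix(0L, n, 0L), positions = integer(0L)))
  if (s_count > cfg$region_bp)
    stop("more segregating sites requested than bp in the region")
  b_idx <- sample.int(length(br$lengths), s_count, replace = TRUE,
                      prob = br$lengths)
  pos <- sort(sample.int(cfg$region_bp, s_count))
  al <- matrix(0L, n, s_count)
  for (j in seq_len(s_count)) al[br$leafsets[[b_idx[j]]], j] <- 1L
  list(alleles = al, positions = pos)
}

.matrix_from_sim <- function(sim, cfg, n_a = cfg$n_hap_a,
                             n_b = cfg$n_hap_b) {
  n <- n_a + n_b
  ids <- c(paste0("A_ind", rep(seq_len(ceiling(n_a / 2)), each = 2L),
                  "_h", rep(1:2, ceiling(n_a / 2)))[seq_len(n_a)],
           paste0("B_ind", rep(seq_len(ceiling(n_b / 2)), each = 2L),
                  "_h", rep(1:2, ceiling(n_b / 2)))[seq_len(n_b)])
  haplotype_matrix(sim$alleles, sim$positions, chrom = "sim1",
                   pop_labels = rep(c("A", "B"), c(n_a, n_b)),
                   sample_ids = ids, region_bp = cfg$region_bp)
}
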