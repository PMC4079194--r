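test_that("windowed pi handles monomorphic and two-haplotype cases", {
  al <- matrix(0L, 2, 3)
  al[1, 2] <- 1L  # one difference between the two haplotypes
  m <- haplotype_matrix(al, positions = c(1000, 5000, 9000),
                        pop_labels = c("A", "A"),
                        sample_ids = c("s_h1", "s_h2"), region_bp = 10000)
  p <- window_pi(m, "A", window_bp = 10000)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pi, 1 / 10000)  # one pairwise difference per 10 kb
  mono <- haplotype_matrix(matrix(c(1L, 1L, 0L, 0L), 2, 2),
                           positions = c(100, 200),
                           pop_labels = c("A", "A"),
                           sample_ids = c("s_h1", "s_h2"), region_bp = 10000)
  # both sites monomorphic within the subset of interest
  expect_equal(window_pi(mono, "A", 10000)$pi, 0)
})

test_that("windowed pi equals the all-pairs Hamming oracle", {
  set.seed(51)
  for (trial in 1:15) {
    m <- random_hapmat(n_hap = sample(4:16, 1), m = 60, region_bp = 50000,
                       n_a = 0)
    m$pop_labels[] <- "B"
    wbp <- 10000
    p <- window_pi(m, "B", window_bp = wbp)
    rows <- m$alleles
    for (k in seq_len(nrow(p)))
      expect_equal(p$pi[k],
                   oracle_window_pi(rows, m$positions, p$start[k], p$end[k],
                                    p$end[k] - p$start[k]))
  }
})

test_that("pi is invariant to allele relabeling and window splitting", {
  set.seed(53)
  m <- random_hapmat(n_hap = 10, m = 40, region_bp = 40000, n_a = 10)
  p1 <- window_pi(m, "A", window_bp = 20000)
  flipped <- m
  flipped$alleles <- 1L - m$alleles
  p2 <- window_pi(flipped, "A", window_bp = 20000)
  expect_equal(p1$pi, p2$pi)
  # split in half: length-weighted average reproduces the parent window
  fine <- window_pi(m, "A", window_bp = 10000)
  for (k in seq_len(nrow(p1))) {
    halves <- fine[fine$start >= p1$start[k] & fine$end <= p1$end[k], ]
    expect_equal(sum(halves$pi * (halves$end - halves$start)) /
                   (p1$end[k] - p1$start[k]), p1$pi[k])
  }
})

test_that("ROH detection enforces the 50-kb length filter exactly", {
  pos <- seq(1000, 150000, by = 1000)
  g <- data.frame(sample = "s1", chrom = "1", pos = pos, gt = 0L)
  r <- detect_roh(g)  # homozygous throughout 149 kb
  expect_equal(nrow(r), 1L)
  expect_gte(r$length, 50000)
  expect_equal(r$start, 1000)
  expect_equal(r$end, 150000)
  # a run spanning 49,999 bp is rejected by the < 50 kb rule
  pos2 <- c(seq(1000, 49999, by = 999), 50500)
  g2 <- data.frame(sample = "s1", chrom = "1", pos = pos2,
                   gt = c(rep(0L, length(pos2) - 1L), 1L))
  expect_equal(nrow(detect_roh(g2)), 0L)
})

test_that("a planted ROH mosaic is recovered exactly at tolerance 0", {
  # 1 Mb with known homozygous blocks separated by single heterozygotes
  set.seed(57)
  pos <- sort(sample.int(1e6, 800))
  het <- rep(FALSE, 800)
  breaks <- sort(sample(2:799, 12))
  het[breaks] <- TRUE
  g <- data.frame(sample = "s1", chrom = "1", pos = pos,
                  gt = ifelse(het, 1L, sample(c(0L, 2L), 800, TRUE)))
  for (min_len in c(20000, 50000)) {
    r <- detect_roh(g, min_length = min_len)
    want <- oracle_roh(pos, het, min_len)
    expect_equal(nrow(r), length(want))
    for (k in seq_along(want)) {
      expect_equal(r$start[k], unname(want[[k]]["start"]))
      expect_equal(r$end[k], unname(want[[k]]["end"]))
    }
  }
  # raising min_length never increases the segment count; no overlaps
  r1 <- detect_roh(g, min_length = 10000)
  r2 <- detect_roh(g, min_length = 80000)
  expect_lte(nrow(r2), nrow(r1))
  if (nrow(r1) > 1L)
    expect_true(all(r1$start[-1L] > r1$end[-nrow(r1)]))
})

test_that("heterozygote tolerance and missing calls behave as documented", {
  pos <- seq(1000, 120000, by = 1000)
  gt <- rep(0L, length(pos))
  gt[60] <- 1L
  g <- data.frame(sample = "s1", chrom = "1", pos = pos, gt = gt)
  r0 <- detect_roh(g, min_length = 50000, het_tolerance = 0)
  expect_equal(nrow(r0), 2L)  # split at the het
  r1 <- detect_roh(g, min_length = 50000, het_tolerance = 1)
  expect_equal(nrow(r1), 1L)  # the het is absorbed
  expect_equal(r1$length, 120000 - 1000 + 1)
  gt[60] <- NA
  gna <- data.frame(sample = "s1", chrom = "1", pos = pos, gt = gt)
  rna <- detect_roh(gna, min_length = 50000, het_tolerance = 0)
  expect_equal(nrow(rna), 1L)  # missing neither breaks nor counts
  expect_equal(attr(rna, "n_missing"), 1L)
  expect_error(detect_roh(data.frame(sample = "s", chrom = "1",
                                     pos = c(5, 2, 9), gt = 0L)), "sorted")
})

test_that("roh_summary aggregates per-sample burden", {
  pos <- seq(1000, 150000, by = 1000)
  g <- rbind(data.frame(sample = "s1", chrom = "1", pos = pos, gt = 0L),
             data.frame(sample = "s2", chrom = "1", pos = pos,
                        gt = rep(c(0L, 1L), length.out = length(pos))))
  r <- detect_roh(g)
  s <- roh_summary(r, samples = c("s1", "s2"))
  expect_equal(s$n_roh, c(1L, 0L))
  expect_equal(s$total_bp, c(149001, 0))
})

test_that("diversity contrast reports identity and requires matched grids", {
  set.seed(61)
  m <- random_hapmat(n_hap = 12, m = 50, region_bp = 50000, n_a = 6)
  pa <- window_pi(m, "A", 10000)
  pb <- window_pi(m, "B", 10000)
  same <- diversity_contrast(pa, pa)
  expect_true(all(same$windows$diff == 0))
  expect_true(all(!same$windows$a_lower))
  expect_error(diversity_contrast(pa, pb[-1, ]), "match")
  iv <- data.frame(chrom = "chrTest", start = 15000, end = 25000,
                   name = "gene1")
  r <- diversity_contrast(pa, pb, intervals = iv, flank_bp = 10000)
  expect_equal(nrow(r$regions), 1L)
  in_w <- pa$start < 25000 & pa$end > 15000
  expect_equal(r$regions$pi_a_in, mean(pa$pi[in_w]))
})

test_that("under neutrality the diversity-reduction flag is a coin flip", {
  set.seed(63)
  n_rep <- 120
  lower <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    m <- simulate_neutral(sim_config(seed = sample.int(1e8, 1)))
    fa <- colMeans(m$alleles[m$pop_labels == "A", ])
    fb <- colMeans(m$alleles[m$pop_labels == "B", ])
    lower[i] <- sum(2 * fa * (1 - fa) * 20 / 19) <
      sum(2 * fb * (1 - fb) * 22 / 21)
  }
  se <- sqrt(0.25 / n_rep)
  expect_lt(abs(mean(lower) - 0.5), 4 * se)
})

test_that("a strong sweep depresses diversity in the selected population", {
  # with negligible recombination over 10 generations the hitchhiking
  # footprint spans the whole replicate, so the contrast is within-replicate
  # A (swept) vs B (neutral), and swept-A vs neutral-A across scenarios
  set.seed(67)
  n_rep <- 40
  pi_a_sweep <- pi_b_sweep <- pi_a_neut <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    m <- simulate_sweep(sim_config(seed = sample.int(1e8, 1),
                                   selection = list(alpha = 500,
                                                    onset_gen = 10)))
    pi_a_sweep[i] <- mean(window_pi(m, "A", 1e6)$pi)
    pi_b_sweep[i] <- mean(window_pi(m, "B", 1e6)$pi)
    mn <- simulate_neutral(sim_config(seed = sample.int(1e8, 1)))
    pi_a_neut[i] <- mean(window_pi(mn, "A", 1e6)$pi)
  }
  expect_lt(mean(pi_a_sweep), mean(pi_b_sweep))
  expect_lt(mean(pi_a_sweep), mean(pi_a_neut))
  expect_gt(mean(pi_a_sweep < pi_b_sweep), 0.5)
})
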