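test_that("window assignment respects half-open 50-kb bounds", {
  sc <- data.frame(chrom = "1", pos = c(10, 49999, 50000),
                   score = c(1, 2, 3))
  w <- make_windows(sc)
  expect_equal(nrow(w), 2L)
  expect_equal(w$n_snps, c(2L, 1L))       # 50000 starts window 1
  expect_equal(w$start, c(0, 50000))
  expect_equal(w$max_score, c(2, 3))
  # singleton window carries its score
  w1 <- make_windows(data.frame(chrom = "1", pos = 70000, score = 3.2))
  expect_equal(w1$n_snps, 1L)
  expect_equal(w1$max_score, 3.2)
})

test_that("window bucketing matches brute-force assignment and conserves SNPs", {
  set.seed(19)
  sc <- data.frame(chrom = sample(c("1", "2"), 10000, replace = TRUE),
                   pos = sample.int(2e6, 10000, replace = TRUE),
                   score = rnorm(10000))
  w <- make_windows(sc)
  expect_equal(sum(w$n_snps), nrow(sc))  # conservation
  for (i in sample.int(nrow(w), 50)) {
    sel <- sc$chrom == w$chrom[i] & sc$pos >= w$start[i] &
      sc$pos < w$end[i]
    expect_equal(w$n_snps[i], sum(sel))
    expect_equal(w$max_score[i], max(sc$score[sel]))
  }
})

test_that("SNP-count bins follow 200-SNP increments with a combined top bin", {
  w <- data.frame(chrom = "1", start = 0, end = 50000,
                  n_snps = c(16L, 200L, 201L, 400L, 401L, 599L, 600L, 900L),
                  max_score = 0)
  b <- assign_bins(w)
  expect_equal(b$bin_id, c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("empirical P is the within-bin fraction of strictly greater scores", {
  set.seed(23)
  n <- 1000
  w <- data.frame(chrom = "1", start = (seq_len(n) - 1) * 50000,
                  end = seq_len(n) * 50000, n_snps = 10L,
                  max_score = sample(rnorm(n)))
  w <- empirical_p(assign_bins(w), min_bin = 50)
  top2 <- order(w$max_score, decreasing = TRUE)[1:2]
  expect_equal(w$emp_p[top2[1]], 0)
  expect_equal(w$emp_p[top2[2]], 0.001)
  expect_equal(w$emp_p, oracle_emp_p(w$max_score))
  expect_true(all(w$emp_p >= 0 & w$emp_p < 1))
  # all-tied bin: every window has P = 0
  wt <- w
  wt$max_score <- 5
  wt <- empirical_p(assign_bins(wt[, setdiff(names(wt), c("bin_id", "emp_p"))]),
                    min_bin = 50)
  expect_true(all(wt$emp_p == 0))
})

test_that("empirical P is invariant to monotone transforms and bin-bounded", {
  set.seed(29)
  for (trial in 1:10) {
    n <- sample(60:200, 1)
    w <- data.frame(chrom = "1", start = (seq_len(n) - 1) * 50000,
                    end = seq_len(n) * 50000,
                    n_snps = sample(c(5L, 250L), n, replace = TRUE),
                    max_score = rnorm(n))
    w <- assign_bins(w)
    p1 <- suppressMessages(empirical_p(w, min_bin = 20))
    w2 <- w
    w2$max_score <- exp(w$max_score)  # monotone increasing transform
    p2 <- suppressMessages(empirical_p(w2, min_bin = 20))
    expect_equal(p1$emp_p, p2$emp_p)
    # oracle within each (possibly merged) bin
    for (b in unique(p1$bin_id)) {
      sel <- p1$bin_id == b
      expect_equal(p1$emp_p[sel], oracle_emp_p(p1$max_score[sel]))
      # rank bound: fraction below q never exceeds q + 1/N_bin
      for (q in c(0.01, 0.05, 0.1))
        expect_lte(mean(p1$emp_p[sel] < q), q + 1 / sum(sel))
    }
  }
})

test_that("sparse bins merge downward before ranking", {
  w <- data.frame(chrom = "1", start = (0:99) * 50000,
                  end = (1:100) * 50000,
                  n_snps = c(rep(10L, 95L), rep(250L, 5L)),
                  max_score = rnorm(100))
  w <- assign_bins(w)
  expect_message(p <- empirical_p(w, min_bin = 50), "merging")
  expect_equal(unique(p$bin_id), 0L)
  expect_equal(p$emp_p, oracle_emp_p(p$max_score))
})

test_that("significance calls at 1% flag exactly the top 1% of distinct scores", {
  set.seed(31)
  n <- 1000
  w <- data.frame(chrom = "1", start = (seq_len(n) - 1) * 50000,
                  end = seq_len(n) * 50000, n_snps = 10L,
                  max_score = sample(rnorm(n)))
  w <- empirical_p(assign_bins(w), min_bin = 50)
  r <- call_significant(w, threshold = 0.01)
  expect_equal(sum(r$windows$significant), 10L)
  expect_equal(nrow(r$report), 10L)
  expect_true(all(diff(r$report$emp_p) >= 0))  # sorted by P
  r0 <- call_significant(w, threshold = 0)
  expect_equal(sum(r0$windows$significant), 0L)
})

test_that("reference-based ranking uses the null set as the comparison pool", {
  set.seed(37)
  ref <- data.frame(chrom = "1", start = (0:199) * 50000,
                    end = (1:200) * 50000, n_snps = 10L,
                    max_score = rnorm(200))
  ref <- assign_bins(ref)
  obs <- data.frame(chrom = "2", start = (0:9) * 50000,
                    end = (1:10) * 50000, n_snps = 10L,
                    max_score = c(rnorm(9), 100))
  obs <- assign_bins(obs)
  p <- empirical_p(obs, min_bin = 50, reference = ref)
  expect_equal(p$emp_p[10], 0)  # nothing in the null exceeds 100
  for (i in 1:9)
    expect_equal(p$emp_p[i], mean(ref$max_score > obs$max_score[i]))
})

test_that("external scores rank with an order-statistic threshold", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(41)
  n <- 1000
  df <- data.frame(chrom = "1", start = (seq_len(n) - 1) * 50000,
                   end = seq_len(n) * 50000, score = sample(rnorm(n)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- ingest_external_scores(path)
  expect_equal(r$threshold, sort(df$score)[990])  # sorted-order oracle
  expect_equal(nrow(r$top), 10L)
  # constant scores: threshold equals the constant, nothing strictly above
  df2 <- df
  df2$score <- 7
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  r2 <- ingest_external_scores(path)
  expect_equal(r2$threshold, 7)
  expect_equal(nrow(r2$top), 0L)
  # malformed row reported with its line number
  df3 <- df
  df3$score[5] <- NA
  utils::write.table(df3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(ingest_external_scores(path), "line 6")
})

test_that("window intersection equals the set oracle", {
  set.seed(43)
  w1 <- data.frame(chrom = "1", start = sample(0:50, 30) * 50000)
  w1$end <- w1$start + 50000
  w2 <- data.frame(chrom = "1", start = sample(0:50, 30) * 50000)
  w2$end <- w2$start + 50000
  got <- window_intersection(w1, w2)
  want <- intersect(w1$start, w2$start)
  expect_setequal(got$start, want)
})

test_that("the whole scan pipeline is deterministic for fixed input", {
  set.seed(47)
  sc <- data.frame(chrom = "1", pos = sample.int(1e6, 300), score = rnorm(300))
  run <- function() {
    w <- empirical_p(assign_bins(make_windows(sc)), min_bin = 5)
    call_significant(w)$windows
  }
  expect_identical(run(), run())
})
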