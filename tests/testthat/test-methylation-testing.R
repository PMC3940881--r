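test_that("bh_fdr matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.3), 0.3)                 # m = 1
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_fdr equals the brute-force definition and is monotone", {
  set.seed(5)
  for (i in 1:200) {
    m <- sample(1:100, 1)
    p <- runif(m)^sample(1:3, 1)   # vary the p-value distribution shape
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("the coverage filter applies the >=10-reads-in-90%-of-samples rule", {
  # 10 samples; CpG 1 covered >= 10 in 9 samples -> retained with one
  # missing entry; CpG 2 covered in 8 -> dropped; CpG 3 fully covered
  coverage <- rbind(
    c(rep(15L, 9), 5L),
    c(rep(15L, 8), 5L, 5L),
    rep(20L, 10)
  )
  m <- toy_matrix(coverage)
  f <- filter_cpgs(m, min_coverage = 10, min_sample_fraction = 0.9)
  expect_setequal(unique(f$pos), c(0L, 200L))
  expect_equal(sum(f$missing[f$pos == 0]), 1L)
  expect_true(is.na(f$percent[f$pos == 0 & f$missing]))
  # min_coverage 0 retains everything with nothing missing
  f0 <- filter_cpgs(m, min_coverage = 0)
  expect_equal(dplyr::n_distinct(f0$pos), 3L)
  expect_false(any(f0$missing))
})

test_that("the coverage filter is idempotent and monotone in min_coverage", {
  m <- simulate_rrbs_matrix(rrbs_sim_params(n_cpgs = 200, coverage_mean = 12,
                                            coverage_dispersion = 0.3,
                                            n_per_group = 5, seed = 3))
  f10 <- filter_cpgs(m, 10, 0.9)
  expect_identical(filter_cpgs(f10, 10, 0.9), f10)
  f5 <- filter_cpgs(m, 5, 0.9)
  expect_true(all(unique(f10$pos) %in% unique(f5$pos)))
})

test_that("group tests reproduce hand-enumerated examples", {
  vals <- rbind(c(1:3, 4:6))
  m <- toy_matrix(matrix(100L, 1, 6))
  m$percent <- as.numeric(vals)
  res <- test_group_difference(m, sprintf("S%02d", 1:3), sprintf("S%02d", 4:6))
  # Wilcoxon exact: 2 of the 20 rank assignments are as extreme
  expect_equal(res$p_w, 0.1, tolerance = 1e-12)
  expect_equal(res$p_w, wilcoxon_enum_oracle(1:3, 4:6), tolerance = 1e-12)
  expect_equal(res$diff, -3)
  # identical groups: difference 0, p = 1
  m$percent <- rep(c(10, 20, 30), 2)
  res0 <- test_group_difference(m, sprintf("S%02d", 1:3),
                                sprintf("S%02d", 4:6))
  expect_equal(res0$diff, 0)
  expect_equal(res0$p_w, 1)
  expect_equal(res0$p_t, 1)
})

test_that("the Student t-test matches stats::t.test with equal variances", {
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(sample(3:10, 1), 50, 5)
    y <- rnorm(sample(3:10, 1), 52, 5)
    expect_equal(methdiff:::student_t_test(x, y)$p,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p equals full enumeration for all sizes up to 6+6", {
  set.seed(9)
  for (na in 2:6) {
    for (nb in 2:6) {
      vals <- sample(seq_len(50), na + nb)   # tie-free
      x <- vals[seq_len(na)]
      y <- vals[na + seq_len(nb)]
      expect_equal(methdiff:::wilcoxon_test(x, y),
                   wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
    }
  }
})

test_that("CpGs without two non-missing samples per group are skipped", {
  coverage <- rbind(
    c(5L, 5L, 5L, 20L, 20L, 20L),   # group A entirely below threshold
    matrix(20L, 1, 6)
  )
  m <- filter_cpgs(toy_matrix(coverage), min_coverage = 10,
                   min_sample_fraction = 0.5)
  m$percent[!m$missing] <- rnorm(sum(!m$missing), 50, 5)
  expect_message(
    res <- test_group_difference(m, sprintf("S%02d", 1:3),
                                 sprintf("S%02d", 4:6)),
    "skipped"
  )
  expect_equal(nrow(res), 1L)
  expect_equal(res$pos, 100L)
})

test_that("volcano tables carry the difference, -log10 p and the FDR flag", {
  res <- tibble::tibble(
    chrom = "c1", pos = c(0, 100, 200), diff = c(-5, 0, 5),
    p_t = c(0.001, 1, 0.5)
  )
  res$q_t <- bh_fdr(res$p_t)
  v <- volcano_table(res, test = "t")
  expect_equal(v$neg_log10_p, c(3, 0, log10(2)))
  expect_equal(v$significant, v$q < 0.05)
  expect_equal(nrow(v), nrow(res))
  expect_error(volcano_table(res, test = "wilcoxon"), "p_w")
})

test_that("amplicon FDR is corrected jointly across all loci", {
  loci <- tibble::tibble(chrom = "c1", start = c(0, 1000),
                         end = c(900, 1900), name = c("L1", "L2"))
  cpgs <- list(L1 = seq(0, 400, 100), L2 = seq(1000, 1400, 100))
  set.seed(12)
  pct <- tibble::tibble(
    sample = sprintf("s%d", 1:8),
    group = rep(c("A", "B"), each = 4),
    percent = c(rnorm(4, 30, 3), rnorm(4, 70, 3))
  )
  amp <- simulate_amplicon_calls(loci, cpgs, pct, depth = 300, seed = 2)
  agg <- aggregate_locus(amp, pct$sample[1:4], pct$sample[5:8])
  # family is the union of the 10 CpGs across both loci
  expect_equal(nrow(agg$cpg), 10L)
  expect_equal(agg$cpg$q_t, bh_oracle(agg$cpg$p_t), tolerance = 1e-12)
  expect_equal(nrow(agg$locus), 2L)
  # a strong planted difference is visible per locus
  expect_true(all(agg$locus$diff < -30))

  # single locus, single CpG: q equals p
  one <- aggregate_locus(
    simulate_amplicon_calls(loci[1, ], list(L1 = 100), pct, depth = 300,
                            seed = 4),
    pct$sample[1:4], pct$sample[5:8]
  )
  expect_equal(one$cpg$q_t, one$cpg$p_t)
})

test_that("CpGs outside every locus are rejected", {
  m <- toy_matrix(matrix(50L, 2, 4))
  loci <- tibble::tibble(chrom = "c1", start = 0, end = 50, name = "L1")
  expect_error(aggregate_locus(m, c("S01", "S02"), c("S03", "S04"),
                               loci = loci), "maps to 0 loci")
})

test_that("cytosine reports round-trip through write and read", {
  m <- simulate_rrbs_matrix(rrbs_sim_params(n_cpgs = 30, n_per_group = 2,
                                            seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(m, "A01", path)
  back <- read_cytosine_report(path, sample = "A01")
  orig <- dplyr::filter(m, sample == "A01")
  expect_equal(back$pos, orig$pos)
  expect_equal(back$meth, orig$meth)
  expect_equal(back$total, orig$total)
  expect_equal(back$percent, orig$percent)
})

test_that("cytosine report parsing follows the stated conventions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t1001\t+\t7\t3\tCG\tCGG", path)
  rec <- read_cytosine_report(path)
  expect_equal(rec$pos, 1000)      # 1-based on disk -> 0-based in memory
  expect_equal(rec$meth, 7L)
  expect_equal(rec$total, 10L)
  expect_equal(rec$percent, 70)

  # empty file -> empty result
  writeLines(character(), path)
  expect_equal(nrow(read_cytosine_report(path)), 0L)

  # duplicate (chrom, pos, strand) rows are rejected
  writeLines(c("chr1\t1001\t+\t7\t3\tCG\tCGG",
               "chr1\t1001\t+\t2\t8\tCG\tCGG"), path)
  expect_error(read_cytosine_report(path), "Duplicate")

  # malformed row -> error naming the line
  writeLines(c("chr1\t1001\t+\t7\t3\tCG\tCGG",
               "chr1\tnotanumber\t+\t1\t1\tCG\tCGG"), path)
  expect_error(read_cytosine_report(path), "row")
})

test_that("strand merging folds CpG dyads onto the plus-strand cytosine", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1001\t+\t7\t3\tCG\tCGG",
               "chr1\t1002\t-\t5\t5\tCG\tCGA"), path)
  merged <- read_cytosine_report(path, merge_strands = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$pos, 1000)
  expect_equal(merged$meth, 12L)
  expect_equal(merged$total, 20L)
  unmerged <- read_cytosine_report(path, merge_strands = FALSE)
  expect_equal(nrow(unmerged), 2L)
})
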