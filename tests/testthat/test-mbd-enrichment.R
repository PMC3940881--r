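test_that("dedup keeps one read per (chrom, start, strand) key", {
  r <- tibble::tibble(chrom = "c1", start = c(100, 100, 100),
                      strand = c("+", "+", "-"))
  expect_equal(nrow(dedup_reads(r)), 2L)
  # idempotent and order-independent
  expect_identical(dedup_reads(dedup_reads(r)), dedup_reads(r))
  expect_identical(dedup_reads(r[c(3, 1, 2), ]), dedup_reads(r))
  empty <- r[0, ]
  expect_equal(nrow(dedup_reads(empty)), 0L)
  # with a sample column the key is per sample
  r2 <- tibble::tibble(sample = c("a", "b"), chrom = "c1",
                       start = 100, strand = "+")
  expect_equal(nrow(dedup_reads(r2)), 2L)
})

test_that("genome tiling covers every base exactly once", {
  g <- genome_spec("chr1", 1000)
  w <- tile_genome(g, 100)
  expect_equal(nrow(w), 10L)
  expect_equal(w$start, seq(0, 900, 100))
  expect_equal(w$end, seq(100, 1000, 100))

  w2 <- tile_genome(genome_spec("chr1", 1050), 100)
  expect_equal(nrow(w2), 11L)
  expect_equal(w2$end[11], 1050)
  expect_equal(w2$start[11], 1000)

  expect_equal(nrow(tile_genome(genome_spec("chr1", 1000), 1000)), 1L)
  expect_error(tile_genome(g, 0), "> 0")
})

test_that("reads are assigned to windows by 5' start under half-open bounds", {
  g <- genome_spec("c1", 1000)
  w <- tile_genome(g, 100)
  r <- tibble::tibble(chrom = "c1", start = c(150, 200), strand = "+")
  cnt <- count_reads_in_windows(r, w)
  expect_equal(cnt$count[cnt$start == 100], 1L)   # 150 -> [100,200)
  expect_equal(cnt$count[cnt$start == 200], 1L)   # boundary -> [200,300)
  expect_equal(sum(cnt$count), 2L)
})

test_that("window counting matches a brute-force double loop", {
  set.seed(17)
  g <- genome_spec(c("c1", "c2"), c(1000, 750))
  w <- tile_genome(g, 100)
  r <- tibble::tibble(
    sample = sample(c("s1", "s2"), 300, replace = TRUE),
    chrom = sample(c("c1", "c2"), 300, replace = TRUE),
    start = sample(0:999, 300, replace = TRUE),
    strand = "+"
  ) |> dplyr::filter(!(chrom == "c2" & start >= 750))
  cnt <- count_reads_in_windows(r, w)
  brute <- vapply(seq_len(nrow(cnt)), function(i) {
    sum(r$sample == cnt$sample[i] & r$chrom == cnt$chrom[i] &
          r$start >= cnt$start[i] & r$start < cnt$end[i])
  }, numeric(1))
  expect_equal(cnt$count, as.integer(brute))
  expect_equal(sum(cnt$count), nrow(r))   # every read lands in some window
})

test_that("Poisson window p-values agree with pmf summation", {
  g <- genome_spec("c1", 1000)
  w <- tile_genome(g, 100)
  r <- tibble::tibble(chrom = "c1",
                      start = c(rep(50, 3), rep(150, 4), rep(950, 3)),
                      strand = "+")
  st <- call_methylated_windows(count_reads_in_windows(r, w))
  expect_equal(unique(st$lambda), 1)  # 10 reads / 10 windows
  # count 0 -> upper tail at 0 is 1
  expect_equal(st$p[st$count == 0][1], 1)
  # lambda 1, count 3 -> 1 - e^-1 (1 + 1 + 1/2)
  expect_equal(st$p[st$count == 3][1], 1 - exp(-1) * 2.5, tolerance = 1e-12)
  expect_equal(st$p[st$count == 3][1], poisson_tail_oracle(3, 1),
               tolerance = 1e-12)
  # q >= p and the call flag is q < threshold
  expect_true(all(st$q >= st$p - 1e-15))
  expect_identical(st$called, st$q < 0.05)
})

test_that("adding reads to a window never increases its p-value", {
  g <- genome_spec("c1", 10000)
  w <- tile_genome(g, 100)
  counts <- tibble::tibble(
    chrom = "c1", start = w$start, end = w$end, source = w$source,
    sample = "s1", count = 0:99
  )
  st <- call_methylated_windows(counts)
  expect_true(all(diff(st$p[order(st$count)]) <= 1e-15))
})

test_that("a uniform background yields (almost) no calls at FDR 5%", {
  g <- genome_spec("c1", 2e6)
  r <- simulate_mbd_reads(g, NULL, background_rate = 0.02, seed = 31)
  st <- count_reads_in_windows(dedup_reads(r), tile_genome(g, 100)) |>
    call_methylated_windows()
  # BH under the global null controls the family-wise error near alpha:
  # with 20k windows expect zero calls in most runs, tolerate a couple
  expect_lte(sum(st$called), 2L)
})

test_that("qualitative hits are exactly the all-versus-none call patterns", {
  # all 2^8 call patterns for 4 + 4 samples, one window per pattern
  samples <- sprintf("s%d", 1:8)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  stats <- tibble::tibble(
    chrom = "c1",
    start = rep((seq_len(nrow(grid)) - 1) * 100, each = 8),
    end = rep(seq_len(nrow(grid)) * 100, each = 8),
    source = "tiled-100",
    sample = rep(samples, times = nrow(grid)),
    count = 0L,
    called = as.vector(t(as.matrix(grid)))
  )
  res <- qualitative_group_difference(stats, samples[1:4], samples[5:8])
  expected <- apply(as.matrix(grid), 1, function(z) {
    (all(z[1:4]) && !any(z[5:8])) || (!any(z[1:4]) && all(z[5:8]))
  })
  res <- dplyr::arrange(res, start)
  expect_identical(res$qualitative_hit, expected)
  # definition spot checks: one dissenting sample breaks a hit
  expect_equal(sum(expected), 2L)
  # symmetry in group labels
  res_flip <- qualitative_group_difference(stats, samples[5:8], samples[1:4])
  expect_identical(sort(res_flip$start[res_flip$qualitative_hit]),
                   sort(res$start[res$qualitative_hit]))
})

test_that("qualitative comparison rejects mismatched window sets", {
  stats <- tibble::tibble(
    chrom = "c1", start = c(0, 100, 0), end = c(100, 200, 100),
    source = "tiled-100", sample = c("a", "a", "b"), count = 0L,
    called = FALSE
  )
  expect_error(qualitative_group_difference(stats, "a", "b"), "same window")
})

test_that("the NB exact test reproduces hand-enumerated conditional p-values", {
  # one sample per group, equal libraries, dispersion 0: conditional
  # Binomial(10, 1/2), two-sided p = 2/2^10
  r <- nb_exact_test(matrix(0), matrix(10), library_sizes = c(1e6, 1e6),
                     dispersion = 0)
  expect_equal(r$p, 2 / 1024, tolerance = 1e-12)
  # identical counts in both groups: the modal symmetric outcome
  r2 <- nb_exact_test(matrix(c(5, 7), ncol = 1), matrix(c(5, 7), ncol = 1),
                      library_sizes = rep(1e6, 2))
  expect_equal(r2$p, c(1, 1))
  # all-zero window by convention
  r3 <- nb_exact_test(matrix(0), matrix(0), library_sizes = c(1e6, 1e6))
  expect_equal(r3$p, 1)
})

test_that("the NB conditional distribution matches a Monte-Carlo oracle", {
  phi <- 0.5
  mu <- 3
  t_obs <- 8
  set.seed(123)
  for (sa in c(0, 2, 4)) {
    p_pkg <- nb_exact_test(matrix(sa), matrix(t_obs - sa),
                           library_sizes = c(1e6, 1e6), dispersion = phi)$p
    p_mc <- nb_conditional_mc_oracle(sa, t_obs, mu, phi)
    expect_lt(abs(p_pkg - p_mc), 0.02)
  }
})

test_that("library-size scaling equalises unequal sequencing depths", {
  # same underlying rate, one library twice as deep: scaling should make
  # the test see no difference
  r <- nb_exact_test(matrix(rep(20, 3), ncol = 3),
                     matrix(rep(10, 3), ncol = 3),
                     library_sizes = c(2e6, 2e6, 2e6, 1e6, 1e6, 1e6))
  expect_gt(r$p, 0.5)
  expect_lt(abs(r$log_fc), 0.2)
})

test_that("method-of-moments dispersion is recovered on simulated counts", {
  set.seed(11)
  phi <- 0.2
  y <- matrix(rnbinom(8000, mu = 20, size = 1 / phi), ncol = 8)
  est <- methdiff:::estimate_common_dispersion(y[, 1:4], y[, 5:8])
  expect_lt(abs(est - phi) / phi, 0.25)
  # Poisson data floors at zero
  y0 <- matrix(rpois(8000, 20), ncol = 8)
  est0 <- methdiff:::estimate_common_dispersion(y0[, 1:4], y0[, 5:8])
  expect_lt(est0, 0.02)
})

test_that("compare_mbd_groups produces volcano-ready, BH-corrected output", {
  g <- genome_spec("c1", 5e4)
  r <- simulate_mbd_reads(g, NULL, background_rate = 0.05, n_samples = 4,
                          seed = 41)
  st <- count_reads_in_windows(dedup_reads(r), tile_genome(g, 1000)) |>
    call_methylated_windows()
  ids <- sort(unique(st$sample))
  cmp <- compare_mbd_groups(st, ids[1:2], ids[3:4])
  expect_equal(nrow(cmp), 50L)
  expect_true(all(c("log_fc", "p_nb", "q_nb", "neg_log10_p",
                    "qualitative_hit") %in% names(cmp)))
  expect_equal(cmp$q_nb, bh_oracle(cmp$p_nb), tolerance = 1e-12)
  expect_equal(cmp$neg_log10_p, -log10(cmp$p_nb))
})
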