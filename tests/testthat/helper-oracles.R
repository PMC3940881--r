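# Independent oracles used across the suite. Each re-derives the quantity it
# checks by brute force (term-by-term summation, full enumeration, Monte
# Carlo), never by calling the code path under test.

# Upper-tail Poisson probability by direct pmf summation.
poisson_tail_oracle <- function(k, lambda) {
  sum(dpois(seq.int(k, k + 3000L), lambda))
}

# Benjamini-Hochberg step-up by its textbook definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(k) {
    j <- k:m
    min(1, min(m * p[o][j] / j))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n, n_a) group assignments (tie-free inputs only). Two-sided p is
# twice the smaller tail of the symmetric U distribution, capped at 1 --
# the same convention as the exact test.
wilcoxon_enum_oracle <- function(x, y) {
  n_a <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(length(r), n_a)
  u_all <- apply(sets, 2, function(idx) sum(r[idx])) - n_a * (n_a + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Conditional distribution of the group-A count given the total, estimated
# by rejection sampling from two independent negative binomials; returns the
# two-sided exact p for the observed group-A count.
nb_conditional_mc_oracle <- function(sa, t, mu, phi, n_draws = 4e5) {
  a <- rnbinom(n_draws, size = 1 / phi, mu = mu)
  b <- rnbinom(n_draws, size = 1 / phi, mu = mu)
  keep <- (a + b) == t
  stopifnot(sum(keep) > 2000)
  g <- tabulate(a[keep] + 1L, nbins = t + 1L) / sum(keep)
  obs <- g[sa + 1L]
  # 5% relative slack so Monte-Carlo noise cannot flip exact probability
  # ties in or out of the rejection set
  sum(g[g <= obs * 1.05])
}

# Deterministic toy methylation matrix from a coverage matrix (CpGs x
# samples) and a constant percent; used for hand-computable filter checks.
toy_matrix <- function(coverage, percent = 50) {
  n_cpg <- nrow(coverage)
  n_s <- ncol(coverage)
  total <- as.vector(t(coverage))
  meth <- as.integer(round(total * percent / 100))
  tibble::tibble(
    chrom = "chr1",
    pos = rep((seq_len(n_cpg) - 1L) * 100L, each = n_s),
    strand = "+",
    sample = rep(sprintf("S%02d", seq_len(n_s)), times = n_cpg),
    total = as.integer(total),
    meth = meth,
    percent = ifelse(total > 0, 100 * meth / total, NA_real_),
    missing = total == 0
  )
}
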