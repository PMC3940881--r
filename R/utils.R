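#' @importFrom rlang .data .env abort warn inform %||%
#' @importFrom stats rpois rbinom rnbinom runif qnorm pnorm ppois dpois
#'   dnbinom dbinom pt qt p.adjust t.test wilcox.test sd var setNames
#' @importFrom utils head
NULL

# Truncated-normal draws by inverse CDF. Degenerate cases (sd = 0, or the
# whole mass outside [lo, hi]) collapse to the clamped mean.
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 100) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- pmin(pmax(mean, lo), hi)
  pos <- sd > 0
  if (any(pos)) {
    a <- pnorm(lo, mean[pos], sd[pos])
    b <- pnorm(hi, mean[pos], sd[pos])
    u <- runif(sum(pos), a, b)
    out[pos] <- pmin(pmax(qnorm(u, mean[pos], sd[pos]), lo), hi)
  }
  out
}

# Pooled-variance (Student) two-sample t-test, vectorised over rows of two
# matrices (one replicate per row). Shared by test_group_difference() and
# estimate_power() so power statements apply to the pipeline's actual test.
student_t_rows <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  na <- ncol(a)
  nb <- ncol(b)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  stat <- (ma - mb) / se
  p <- 2 * pt(-abs(stat), df)
  p[se == 0 & ma == mb] <- 1        # identical constant groups: no evidence
  list(statistic = stat, df = df, p = p)
}

student_t_test <- function(x, y) {
  res <- student_t_rows(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(statistic = res$statistic[1L], df = res$df, p = res$p[1L])
}

# Wilcoxon rank-sum, two-sided: exact null distribution when both groups are
# small and tie-free, otherwise normal approximation with tie correction
# (stats::wilcox.test implements exactly this contract).
wilcoxon_test <- function(x, y, exact_max = 12L) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}
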