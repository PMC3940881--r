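#' Per-CpG mean and standard deviation of percent methylation in one group
#'
#' Summarises a methylation matrix into the per-CpG sample mean and sample
#' standard deviation (denominator `n - 1`) of percent methylation across
#' the samples of one group, the raw material for the power simulation.
#'
#' @param matrix Long methylation matrix (after [filter_cpgs()]).
#' @param group Character vector of sample ids.
#' @return Tibble: `chrom`, `pos`, `n`, `mean`, `sd`, one row per CpG with
#'   at least two non-missing samples.
#' @export
summarize_group <- function(matrix, group) {
  if (!"missing" %in% names(matrix)) matrix$missing <- FALSE
  group_ids <- group   # avoid capture by the data-mask `group` column
  matrix |>
    dplyr::filter(.data$sample %in% .env$group_ids, !is.na(.data$percent),
                  !.data$missing) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$percent),
      sd = sd(.data$percent),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 2L)
}

#' Restrict CpG summaries to the low-variability quantile
#'
#' Keeps the `floor(quantile * m)` summaries with the smallest standard
#' deviation; ties are broken by input order, so the selection is
#' deterministic.
#'
#' @param summaries Tibble with an `sd` column, e.g. from
#'   [summarize_group()].
#' @param quantile Fraction to retain (default 0.10, the lowest SD decile).
#' @return The selected rows of `summaries`, in input order.
#' @export
select_low_variability <- function(summaries, quantile = 0.10) {
  m <- nrow(summaries)
  if (m < 10L) abort("Need at least 10 summaries to take a quantile.")
  k <- floor(quantile * m)
  ord <- order(summaries$sd)          # stable: ties keep input order
  summaries[sort(ord[seq_len(k)]), ]
}

#' Monte-Carlo power of the per-CpG Student's t-test
#'
#' Each replicate draws one (mean, SD) pair from the supplied summaries,
#' simulates `n_per_group` values per group from Normal(mean, SD) and
#' Normal(mean + delta, SD), both truncated to `[0, 100]`, and applies the
#' same two-sided equal-variance Student's t-test used by
#' [test_group_difference()]. Power is the fraction of replicates with
#' `p < alpha`. Replicates with SD = 0 and delta = 0 are degenerate and are
#' skipped.
#'
#' @param summaries Tibble with `mean` and `sd` columns (per-CpG percent
#'   methylation summaries).
#' @param delta True between-group difference in percentage points (`>= 0`).
#' @param n_per_group Samples per group (default 10).
#' @param alpha Two-sided per-test significance level (default 0.05).
#' @param n_sim Number of Monte-Carlo replicates (default 10000).
#' @param seed Integer seed; fixed seed gives identical estimates.
#' @return The estimated power (a single fraction in `[0, 1]`).
#' @examples
#' s <- tibble::tibble(mean = 50, sd = 8.3)
#' estimate_power(s, delta = 11, n_sim = 2000, seed = 1)
#' @export
estimate_power <- function(summaries, delta, n_per_group = 10, alpha = 0.05,
                           n_sim = 10000, seed = 1) {
  if (delta < 0) abort("`delta` must be >= 0.")
  if (nrow(summaries) == 0L) abort("`summaries` must be non-empty.")
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  set.seed(check_seed(seed))
  pick <- sample.int(nrow(summaries), n_sim, replace = TRUE)
  mu <- summaries$mean[pick]
  sigma <- summaries$sd[pick]
  keep <- !(sigma == 0 & delta == 0)
  if (!all(keep)) {
    inform(paste0(sum(!keep), " replicate(s) skipped: SD = 0 with delta = 0."))
    mu <- mu[keep]
    sigma <- sigma[keep]
  }
  n_rep <- length(mu)
  if (n_rep == 0L) abort("All replicates degenerate (SD = 0, delta = 0).")
  a <- matrix(rnorm_trunc(n_rep * n_per_group, rep(mu, n_per_group),
                          rep(sigma, n_per_group)), nrow = n_rep)
  b <- matrix(rnorm_trunc(n_rep * n_per_group, rep(mu + delta, n_per_group),
                          rep(sigma, n_per_group)), nrow = n_rep)
  mean(student_t_rows(a, b)$p < alpha)
}

#' Power curve over a grid of methylation differences
#'
#' Estimates [estimate_power()] at each grid point and reports the minimal
#' detectable difference: the smallest grid delta whose power reaches
#' `target`, plus a linearly interpolated value between the bracketing grid
#' points.
#'
#' @inheritParams estimate_power
#' @param delta_grid Strictly increasing vector of differences (percentage
#'   points).
#' @param target Target power for the minimal detectable difference
#'   (default 0.80).
#' @return A `power_curve` object: list with `curve` (tibble `delta`,
#'   `power`), `mdd` (smallest grid delta with power >= target, `NA` when
#'   unreached), `mdd_interpolated`, and the simulation settings.
#' @export
power_curve <- function(summaries, delta_grid, n_per_group = 10,
                        alpha = 0.05, n_sim = 10000, seed = 1,
                        target = 0.80) {
  if (any(diff(delta_grid) <= 0)) abort("`delta_grid` must be strictly increasing.")
  seed <- check_seed(seed)
  pow <- purrr::map_dbl(seq_along(delta_grid), function(i) {
    estimate_power(summaries, delta_grid[i], n_per_group = n_per_group,
                   alpha = alpha, n_sim = n_sim, seed = seed + i - 1L)
  })
  reached <- which(pow >= target)
  if (length(reached) > 0L) {
    k <- reached[1L]
    mdd <- delta_grid[k]
    mdd_int <- if (k == 1L) delta_grid[1L] else {
      d0 <- delta_grid[k - 1L]
      d1 <- delta_grid[k]
      d0 + (target - pow[k - 1L]) / (pow[k] - pow[k - 1L]) * (d1 - d0)
    }
  } else {
    mdd <- NA_real_
    mdd_int <- NA_real_
  }
  structure(
    list(
      curve = tibble::tibble(delta = delta_grid, power = pow),
      mdd = mdd, mdd_interpolated = mdd_int, target = target,
      n_per_group = n_per_group, alpha = alpha, n_sim = n_sim, seed = seed
    ),
    class = "power_curve"
  )
}

#' @export
print.power_curve <- function(x, ...) {
  cat("Monte-Carlo power curve (", x$n_sim, " replicates, n = ",
      x$n_per_group, "/group, alpha = ", x$alpha, ")\n", sep = "")
  print(x$curve, n = Inf)
  if (is.na(x$mdd)) {
    cat("Minimal detectable difference at power ", x$target,
        ": above grid max\n", sep = "")
  } else {
    cat("Minimal detectable difference at power ", x$target, ": ",
        x$mdd, " (interpolated ", round(x$mdd_interpolated, 2), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy a power curve into one row per grid point
#'
#' @param x A `power_curve` object.
#' @param ... Unused.
#' @return Tibble with `delta` and `power`.
#' @method tidy power_curve
#' @export
tidy.power_curve <- function(x, ...) x$curve

#' One-row summary of a power curve
#'
#' @param x A `power_curve` object.
#' @param ... Unused.
#' @return Tibble with the simulation settings and the minimal detectable
#'   difference.
#' @method glance power_curve
#' @export
glance.power_curve <- function(x, ...) {
  tibble::tibble(
    n_per_group = x$n_per_group, alpha = x$alpha, n_sim = x$n_sim,
    target = x$target, mdd = x$mdd, mdd_interpolated = x$mdd_interpolated,
    max_power = max(x$curve$power)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
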