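#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR q-values: with the p-values sorted ascending,
#' `q(k) = min over j >= k of m * p(j) / j`, mapped back to input order and
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return The q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.9))
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Filter CpGs by the minimum-coverage / sample-fraction rule
#'
#' Keeps a CpG when the fraction of samples with coverage of at least
#' `min_coverage` reads is at least `min_sample_fraction`; in retained CpGs,
#' samples below the coverage threshold are flagged as missing data (their
#' `percent` is set to `NA`).
#'
#' @param matrix Long methylation matrix (`chrom`, `pos`, `sample`, `meth`,
#'   `total`, `percent`, ...), e.g. from [simulate_rrbs_matrix()] or
#'   [build_methylation_matrix()].
#' @param min_coverage Minimum reads per CpG per sample (default 10).
#' @param min_sample_fraction Minimum fraction of samples meeting
#'   `min_coverage` (default 0.9).
#' @return The filtered matrix with an updated `missing` column.
#' @export
filter_cpgs <- function(matrix, min_coverage = 10, min_sample_fraction = 0.9) {
  if (nrow(matrix) == 0L) return(matrix)
  matrix |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::filter(mean(.data$total >= min_coverage) >= min_sample_fraction) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      missing = .data$total < min_coverage,
      percent = ifelse(.data$missing, NA_real_,
                       100 * .data$meth / .data$total)
    )
}

#' Per-CpG two-group tests of percent methylation
#'
#' At each CpG the per-sample percent methylation values of the two groups
#' are compared with a two-sided equal-variance Student's t-test and/or a
#' two-sided Wilcoxon rank-sum test (exact when both groups have at most 12
#' non-missing samples and no ties, normal approximation with tie correction
#' otherwise). Missing samples are dropped; CpGs with fewer than two
#' non-missing samples in either group are skipped (the number skipped is
#' reported via a message and the `n_a`/`n_b` columns).
#'
#' @param matrix Long methylation matrix (after [filter_cpgs()]).
#' @param group_a,group_b Character vectors of sample ids.
#' @param method Tests to run: subset of `c("t", "wilcoxon")`.
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return One row per tested CpG: `chrom`, `pos`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `diff` (A - B, percentage points), `p_t`, `p_w`, `q_t`, `q_w`
#'   (BH across the tested CpGs, per test family; columns present for the
#'   methods requested).
#' @export
test_group_difference <- function(matrix, group_a, group_b,
                                  method = c("t", "wilcoxon"),
                                  welch = FALSE) {
  method <- match.arg(method, several.ok = TRUE)
  if (length(intersect(group_a, group_b)) > 0L) abort("Groups must be disjoint.")
  if (!"missing" %in% names(matrix)) matrix$missing <- FALSE
  dat <- matrix |>
    dplyr::filter(.data$sample %in% c(group_a, group_b),
                  !is.na(.data$percent),
                  !.data$missing) |>
    dplyr::mutate(in_a = .data$sample %in% group_a)

  n_all <- dplyr::n_distinct(matrix$chrom, matrix$pos)
  res <- dat |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      n_a = sum(.data$in_a),
      n_b = sum(!.data$in_a),
      vals_a = list(.data$percent[.data$in_a]),
      vals_b = list(.data$percent[!.data$in_a]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_a >= 2L, .data$n_b >= 2L)

  n_skipped <- n_all - nrow(res)
  if (n_skipped > 0L) {
    inform(paste0(n_skipped, " CpG(s) skipped: fewer than 2 non-missing ",
                  "samples in a group."))
  }
  if (nrow(res) == 0L) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          n_a = integer(), n_b = integer(),
                          mean_a = numeric(), mean_b = numeric(),
                          diff = numeric()))
  }

  res <- res |>
    dplyr::mutate(
      mean_a = purrr::map_dbl(.data$vals_a, mean),
      mean_b = purrr::map_dbl(.data$vals_b, mean),
      diff = .data$mean_a - .data$mean_b
    )
  if ("t" %in% method) {
    res$p_t <- purrr::map2_dbl(res$vals_a, res$vals_b, function(a, b) {
      if (welch) t.test(a, b)$p.value else student_t_test(a, b)$p
    })
    res$q_t <- bh_fdr(res$p_t)
  }
  if ("wilcoxon" %in% method) {
    res$p_w <- purrr::map2_dbl(res$vals_a, res$vals_b, wilcoxon_test)
    res$q_w <- bh_fdr(res$p_w)
  }
  dplyr::select(res, -"vals_a", -"vals_b")
}

#' Volcano-plot table for per-CpG test results
#'
#' One row per tested CpG with the group difference in mean percent
#' methylation, `-log10(p)` and the BH q-value for the chosen test family,
#' and a significance flag at the given FDR.
#'
#' @param results Output of [test_group_difference()] or [aggregate_locus()].
#' @param test Which p-value family to plot: `"t"` or `"wilcoxon"`.
#' @param fdr_threshold Significance flag level (default 0.05).
#' @return Tibble: `chrom`, `pos` (and `locus` if present), `diff`,
#'   `neg_log10_p`, `q`, `significant`.
#' @export
volcano_table <- function(results, test = c("t", "wilcoxon"),
                          fdr_threshold = 0.05) {
  test <- match.arg(test)
  pcol <- if (test == "t") "p_t" else "p_w"
  qcol <- if (test == "t") "q_t" else "q_w"
  if (!pcol %in% names(results)) {
    abort(paste0("Results carry no `", pcol, "` column; run the `", test,
                 "` test first."))
  }
  keep <- intersect(c("locus", "chrom", "pos", "diff"), names(results))
  results |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(keep)),
      neg_log10_p = -log10(.data[[pcol]]),
      q = .data[[qcol]],
      significant = .data[[qcol]] < fdr_threshold
    )
}

#' Per-locus amplicon analysis with joint FDR across loci
#'
#' Runs the per-CpG group tests on targeted amplicon data and corrects for
#' multiple testing jointly across all CpGs of all loci (one FDR family for
#' the whole amplicon panel), then summarises per-locus group means.
#'
#' @param matrix Long amplicon methylation matrix with a `locus` column
#'   (e.g. from [simulate_amplicon_calls()]), or a locus-free matrix plus
#'   `loci` intervals to assign CpGs to loci.
#' @param group_a,group_b Character vectors of sample ids.
#' @param loci Optional tibble of intervals (`chrom`, `start`, `end`,
#'   `name`) used to assign CpGs to loci when `matrix` has no `locus`
#'   column; every CpG must fall in exactly one locus.
#' @param method Tests to run, as in [test_group_difference()].
#' @return List with `cpg` (per-CpG results with joint q-values and `locus`)
#'   and `locus` (per-locus mean percent per group and minimum q).
#' @export
aggregate_locus <- function(matrix, group_a, group_b, loci = NULL,
                            method = c("t", "wilcoxon")) {
  if (!"locus" %in% names(matrix)) {
    if (is.null(loci)) abort("Need a `locus` column or a `loci` table.")
    idx <- purrr::map_int(seq_len(nrow(matrix)), function(i) {
      hits <- which(loci$chrom == matrix$chrom[i] &
                      matrix$pos[i] >= loci$start &
                      matrix$pos[i] < loci$end)
      if (length(hits) != 1L) {
        abort(paste0("CpG ", matrix$chrom[i], ":", matrix$pos[i],
                     " maps to ", length(hits), " loci (need exactly 1)."))
      }
      hits
    })
    matrix$locus <- loci$name[idx]
  }
  cpg_map <- dplyr::distinct(matrix, .data$chrom, .data$pos, .data$locus)
  if (anyDuplicated(cpg_map[c("chrom", "pos")])) {
    abort("Each CpG must belong to exactly one locus.")
  }
  res <- test_group_difference(matrix, group_a, group_b, method = method) |>
    dplyr::left_join(cpg_map, by = c("chrom", "pos")) |>
    dplyr::relocate("locus")
  # q-values above are already computed over the joint family (all loci);
  # recompute defensively in case of subsetting upstream
  if ("p_t" %in% names(res)) res$q_t <- bh_fdr(res$p_t)
  if ("p_w" %in% names(res)) res$q_w <- bh_fdr(res$p_w)

  qcol <- if ("q_t" %in% names(res)) "q_t" else "q_w"
  locus_summary <- res |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_cpgs = dplyr::n(),
      mean_a = mean(.data$mean_a),
      mean_b = mean(.data$mean_b),
      diff = mean(.data$diff),
      min_q = min(.data[[qcol]]),
      .groups = "drop"
    )
  list(cpg = res, locus = locus_summary)
}
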