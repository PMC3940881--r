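#' Remove putative PCR duplicates from aligned reads
#'
#' Keeps at most one read per (chromosome, 5' start, strand) key — per sample
#' when a `sample` column is present. The result is independent of input
#' order.
#'
#' @param reads Tibble of reads with columns `chrom`, `start`, `strand`, and
#'   optionally `sample`.
#' @return The deduplicated reads, sorted by (sample,) chrom, start, strand.
#' @examples
#' r <- tibble::tibble(chrom = "c1", start = c(100, 100, 100),
#'                     strand = c("+", "+", "-"))
#' dedup_reads(r)
#' @export
dedup_reads <- function(reads) {
  keys <- intersect(c("sample", "chrom", "start", "strand"), names(reads))
  reads |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Tile a genome into non-overlapping fixed-size windows
#'
#' Windows start at 0 and step by `window_size`; a trailing partial window is
#' kept if it spans at least 1 bp.
#'
#' @param genome A [genome_spec()] tibble.
#' @param window_size Window width in bp (`> 0`).
#' @return Tibble of windows: `chrom`, `start`, `end`, `source` (e.g.
#'   `"tiled-100"`).
#' @examples
#' tile_genome(genome_spec("chr1", 1050), 100)
#' @export
tile_genome <- function(genome, window_size) {
  if (window_size <= 0) abort("`window_size` must be > 0.")
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = window_size)
    tibble::tibble(
      chrom = genome$chrom[i],
      start = starts,
      end = pmin(starts + window_size, genome$length[i]),
      source = paste0("tiled-", window_size)
    )
  })
}

#' Use intervals from a BED-like table as counting windows
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   e.g. annotated CpG islands from [read_bed()].
#' @param source Label recorded in the `source` column.
#' @return A window tibble as from [tile_genome()].
#' @export
windows_from_intervals <- function(intervals, source = "interval-file") {
  if (any(intervals$start >= intervals$end)) abort("Intervals require start < end.")
  tibble::tibble(
    chrom = as.character(intervals$chrom),
    start = as.numeric(intervals$start),
    end = as.numeric(intervals$end),
    source = source
  )
}

check_windows_disjoint <- function(windows) {
  ovl <- windows |>
    dplyr::group_by(.data$source, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(bad = .data$start < dplyr::lag(.data$end, default = -1)) |>
    dplyr::ungroup()
  if (any(ovl$bad)) abort("Windows must be non-overlapping within a source.")
  invisible(windows)
}

#' Count reads in windows by their 5' start position
#'
#' A read is assigned to the (unique) window containing its 5' start; window
#' boundaries are half-open, so a read starting exactly at `end` belongs to
#' the next window. Every window appears in the output, including zero-count
#' windows.
#'
#' @param reads Read tibble (`chrom`, `start`, optionally `sample`).
#' @param windows Window tibble from [tile_genome()] or
#'   [windows_from_intervals()]; must be non-overlapping within each source.
#' @return Long tibble: `chrom`, `start`, `end`, `source`, `sample`, `count`.
#' @export
count_reads_in_windows <- function(reads, windows) {
  check_windows_disjoint(windows)
  if (!"sample" %in% names(reads)) reads$sample <- "S01"
  samples <- sort(unique(reads$sample))
  if (length(samples) == 0L) samples <- "S01"

  counts_one <- function(win, rd) {
    # win: one source, one chrom, sorted; rd: reads on that chrom
    out <- matrix(0L, nrow(win), length(samples),
                  dimnames = list(NULL, samples))
    if (nrow(rd) > 0L) {
      idx <- findInterval(rd$start, win$start)
      ok <- idx >= 1L & rd$start < win$end[pmax(idx, 1L)]
      if (any(ok)) {
        tab <- table(factor(idx[ok], levels = seq_len(nrow(win))),
                     factor(rd$sample[ok], levels = samples))
        out <- out + unclass(tab)
      }
    }
    out
  }

  purrr::map_dfr(split(windows, windows$source), function(win_src) {
    purrr::map_dfr(split(win_src, win_src$chrom), function(win) {
      win <- dplyr::arrange(win, .data$start)
      rd <- reads[reads$chrom == win$chrom[1L], ]
      cnt <- counts_one(win, rd)    # windows x samples
      tibble::tibble(
        chrom = rep(win$chrom, times = length(samples)),
        start = rep(win$start, times = length(samples)),
        end = rep(win$end, times = length(samples)),
        source = rep(win$source, times = length(samples)),
        sample = rep(samples, each = nrow(win)),
        count = as.integer(cnt)     # column-major matches sample blocks
      )
    })
  }) |>
    dplyr::arrange(.data$source, .data$sample, .data$chrom, .data$start)
}

#' Call significantly methylated windows with a Poisson null
#'
#' Under the null every window of a source receives reads at a common rate, so
#' the expected count is `lambda = total reads / number of windows` (computed
#' per sample within each source, over all windows including empty ones). The
#' per-window p-value is the upper tail `P(Poisson(lambda) >= count)`;
#' Benjamini-Hochberg q-values are computed across all windows of the source,
#' and a window is called methylated when `q < fdr_threshold`.
#'
#' @param counts Long count tibble from [count_reads_in_windows()].
#' @param fdr_threshold FDR level for calling (default 0.05).
#' @return `counts` with added columns `lambda`, `p`, `q`, `called`.
#' @export
call_methylated_windows <- function(counts, fdr_threshold = 0.05) {
  if (nrow(counts) == 0L) abort("No windows to test.")
  if (fdr_threshold <= 0 || fdr_threshold > 1) {
    abort("`fdr_threshold` must be in (0, 1].")
  }
  counts |>
    dplyr::group_by(.data$source, .data$sample) |>
    dplyr::mutate(
      lambda = sum(.data$count) / dplyr::n(),
      p = ppois(.data$count - 1L, .data$lambda, lower.tail = FALSE),
      q = bh_fdr(.data$p),
      called = .data$q < fdr_threshold
    ) |>
    dplyr::ungroup()
}

#' Qualitative (all-versus-none) group difference in methylation calls
#'
#' A window is a qualitative hit when it is called methylated in every sample
#' of one group and in no sample of the other group. The test is symmetric in
#' the group labels; the direction of the hit is recorded.
#'
#' @param stats Per-sample window calls from [call_methylated_windows()].
#' @param group_a,group_b Character vectors of sample ids.
#' @return One row per window: coordinates, `n_called_a`, `n_called_b`,
#'   `qualitative_hit`, `direction` (`"A"`, `"B"` or `NA`).
#' @export
qualitative_group_difference <- function(stats, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0L) abort("Groups must be disjoint.")
  stats <- dplyr::filter(stats, .data$sample %in% c(group_a, group_b))
  per_sample <- stats |>
    dplyr::count(.data$sample, name = "n_windows")
  if (length(unique(per_sample$n_windows)) != 1L ||
      !setequal(per_sample$sample, c(group_a, group_b))) {
    abort("Every sample must carry calls on the same window set.")
  }
  res <- stats |>
    dplyr::mutate(in_a = .data$sample %in% group_a) |>
    dplyr::group_by(.data$source, .data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      n_called_a = sum(.data$called & .data$in_a),
      n_called_b = sum(.data$called & !.data$in_a),
      .groups = "drop"
    )
  na <- length(group_a)
  nb <- length(group_b)
  if (any(res$n_called_a + res$n_called_b +
          (na - res$n_called_a) + (nb - res$n_called_b) != na + nb)) {
    abort("Window sets differ across samples.")   # defensive; caught above
  }
  res |>
    dplyr::mutate(
      qualitative_hit = (.data$n_called_a == na & .data$n_called_b == 0L) |
        (.data$n_called_a == 0L & .data$n_called_b == nb),
      direction = dplyr::case_when(
        .data$qualitative_hit & .data$n_called_a == na ~ "A",
        .data$qualitative_hit ~ "B",
        TRUE ~ NA_character_
      )
    )
}

# Conditional two-sided exact p-value for one window.
# sa, t: group-A sum and total (integers after scaling); na, nb: group sizes;
# phi: common dispersion (0 = Poisson -> conditional Binomial).
nb_exact_p_one <- function(sa, t, na, nb, phi) {
  if (t == 0L) return(1)
  s <- 0:t
  if (phi <= 0) {
    logg <- dbinom(s, t, na / (na + nb), log = TRUE)
  } else {
    mu <- t / (na + nb)
    logg <- dnbinom(s, size = na / phi, mu = na * mu, log = TRUE) +
      dnbinom(t - s, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  g <- exp(logg - max(logg))
  obs <- g[sa + 1L]
  sum(g[g <= obs * (1 + 1e-12)]) / sum(g)
}

# Method-of-moments common dispersion on library-size-scaled counts:
# var = mu + phi mu^2 pooled across windows, floored at 0.
estimate_common_dispersion <- function(scaled_a, scaled_b) {
  na <- ncol(scaled_a)
  nb <- ncol(scaled_b)
  m <- (rowSums(scaled_a) + rowSums(scaled_b)) / (na + nb)
  if (na < 2L && nb < 2L) return(0)
  ss <- rowSums((scaled_a - rowMeans(scaled_a))^2) +
    rowSums((scaled_b - rowMeans(scaled_b))^2)
  v <- ss / (na + nb - 2L)
  keep <- m > 0
  if (!any(keep)) return(0)
  max(0, sum(v[keep] - m[keep]) / sum(m[keep]^2))
}

#' Negative-binomial exact test for a group difference in window counts
#'
#' A conditional exact test for two-group count data, in the spirit of the
#' exact tests used for digital gene expression. Counts are first scaled to a
#' common effective library size (the geometric mean of the supplied library
#' sizes) and rounded; a single common dispersion is then estimated across
#' windows by the method of moments (`var = mu + phi * mu^2`, floored at 0).
#' For each window the two-sided p-value sums, over the conditional
#' distribution of the group-A total given the overall total (Binomial when
#' `phi = 0`, a ratio of negative binomials otherwise), the probabilities of
#' all outcomes no more likely than the observed one.
#'
#' @param counts_a,counts_b Numeric matrices of window counts, one column per
#'   sample (rows are windows, aligned between the two matrices).
#' @param library_sizes Total (deduplicated) read counts per sample, group A
#'   columns first then group B.
#' @param dispersion Optional fixed common dispersion; estimated when `NULL`.
#' @return Tibble with one row per window: `sum_a`, `sum_b`, `log_fc` (log2
#'   fold change of mean scaled counts, 0.5 prior per group), `p`, and the
#'   `dispersion` used.
#' @examples
#' nb_exact_test(matrix(0), matrix(10), library_sizes = c(1e6, 1e6))
#' @export
nb_exact_test <- function(counts_a, counts_b, library_sizes, dispersion = NULL) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  na <- ncol(counts_a)
  nb <- ncol(counts_b)
  if (na < 1L || nb < 1L) abort("Need at least one sample per group.")
  if (nrow(counts_a) != nrow(counts_b)) abort("Row (window) counts must match.")
  if (length(library_sizes) != na + nb || any(library_sizes <= 0)) {
    abort("`library_sizes` must be positive, one per sample (A then B).")
  }
  f <- exp(mean(log(library_sizes))) / library_sizes
  sa_scaled <- sweep(counts_a, 2, f[seq_len(na)], `*`)
  sb_scaled <- sweep(counts_b, 2, f[na + seq_len(nb)], `*`)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(sa_scaled, sb_scaled)
  }
  ya <- round(sa_scaled)
  yb <- round(sb_scaled)
  sum_a <- as.integer(rowSums(ya))
  sum_b <- as.integer(rowSums(yb))
  p <- purrr::map2_dbl(sum_a, sum_a + sum_b, nb_exact_p_one,
                       na = na, nb = nb, phi = dispersion)
  tibble::tibble(
    sum_a = sum_a,
    sum_b = sum_b,
    log_fc = log2((sum_a / na + 0.5) / (sum_b / nb + 0.5)),
    p = p,
    dispersion = dispersion
  )
}

#' Full MBD group comparison: qualitative hits plus the NB exact test
#'
#' Combines, per window, the all-versus-none qualitative comparison of
#' significance calls with the quantitative negative-binomial exact test on
#' the read counts, BH-corrected within each window source.
#'
#' @param stats Per-sample window calls from [call_methylated_windows()].
#' @param group_a,group_b Character vectors of sample ids.
#' @param dispersion Optional fixed NB dispersion (estimated when `NULL`).
#' @return One row per window with qualitative columns (see
#'   [qualitative_group_difference()]) plus `log_fc`, `p_nb`, `q_nb` and
#'   `neg_log10_p` (volcano-ready).
#' @export
compare_mbd_groups <- function(stats, group_a, group_b, dispersion = NULL) {
  qual <- qualitative_group_difference(stats, group_a, group_b)
  purrr::map_dfr(split(stats, stats$source), function(st) {
    wide <- st |>
      dplyr::select("chrom", "start", "end", "source", "sample", "count") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "count")
    lib <- st |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(lib = sum(.data$count), .groups = "drop")
    libs <- setNames(lib$lib, lib$sample)
    nb <- nb_exact_test(
      as.matrix(wide[, group_a, drop = FALSE]),
      as.matrix(wide[, group_b, drop = FALSE]),
      library_sizes = c(libs[group_a], libs[group_b]),
      dispersion = dispersion
    )
    dplyr::bind_cols(
      wide[, c("chrom", "start", "end", "source")],
      nb[, c("sum_a", "sum_b", "log_fc")],
      tibble::tibble(p_nb = nb$p, q_nb = bh_fdr(nb$p),
                     neg_log10_p = -log10(nb$p))
    )
  }) |>
    dplyr::left_join(qual,
                     by = c("chrom", "start", "end", "source")) |>
    dplyr::arrange(.data$source, .data$chrom, .data$start)
}
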