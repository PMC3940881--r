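#' Demo configuration: the two-group, three-assay design at toy scale
#'
#' Builds a fully synthetic run configuration mirroring a two-maternal-diet
#' comparison: MBD-seq on 4 vs 4 samples with enriched domains, RRBS on
#' 10 vs 10 samples, a targeted amplicon panel, and the power simulation.
#' No group effect is planted, so the expected demo outcome is a null
#' result in every quantitative comparison.
#'
#' @param seed Integer seed controlling every stage.
#' @param out_dir Output directory for the run.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("methdiff_run_")) {
  list(
    seed = check_seed(seed),
    out_dir = out_dir,
    assays = c("mbd", "rrbs", "amplicon", "power"),
    fdr = 0.05,
    min_coverage = 10,
    min_sample_fraction = 0.9,
    mbd = list(
      synthetic = TRUE, n_per_group = 4,
      genome = list(chrom = "chr1", length = 2e5),
      window_size = 100,
      background_rate = 0.02, duplicate_rate = 0.10,
      domains = list(list(chrom = "chr1", start = 50000, end = 52000,
                          enrichment = 10))
    ),
    rrbs = list(
      synthetic = TRUE, n_cpgs = 300, n_per_group = 10,
      mean = 50, sd = 5, effect = 0,
      coverage_mean = 30, coverage_dispersion = 0.2
    ),
    amplicon = list(
      synthetic = TRUE, n_loci = 6, cpgs_per_locus = 3, depth = 200,
      n_per_group = 10, mean = 50, sd = 5, effect = 0
    ),
    power = list(deltas = c(5, 8, 11, 15, 20), n_sim = 2000, target = 0.8)
  )
}

#' Validate a run configuration and its input files
#'
#' Checks thresholds, group sizes and referenced files without mutating
#' anything; fatal issues stop [run_pipeline()] before any stage runs.
#'
#' @param config Configuration list (or path to a YAML file).
#' @return Tibble of issues with columns `severity` (`"fatal"`/`"warning"`)
#'   and `message`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  issues <- list()
  add <- function(severity, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(severity = severity,
                                                     message = message)
  }
  if (is.null(config$seed)) add("fatal", "No seed in config.")
  if (!is.null(config$fdr) && (config$fdr <= 0 || config$fdr > 1)) {
    add("fatal", "fdr must be in (0, 1].")
  }
  if (!is.null(config$min_sample_fraction) &&
      (config$min_sample_fraction < 0 || config$min_sample_fraction > 1)) {
    add("fatal", "min_sample_fraction must be in [0, 1].")
  }
  for (assay in c("mbd", "rrbs", "amplicon")) {
    cfg <- config[[assay]]
    if (is.null(cfg) || !assay %in% (config$assays %||% character())) next
    if (isTRUE(cfg$synthetic)) {
      npg <- cfg$n_per_group %||% 0
      if (npg < 2) add("fatal", paste0(assay, ": group size < 2, tests undefined."))
    } else {
      sheet_path <- cfg$sample_sheet
      if (is.null(sheet_path) || !file.exists(sheet_path)) {
        add("fatal", paste0(assay, ": sample sheet missing."))
        next
      }
      sheet <- readr::read_tsv(sheet_path, show_col_types = FALSE,
                               progress = FALSE)
      if (!all(c("sample", "group", "path") %in% names(sheet))) {
        add("fatal", paste0(assay, ": sample sheet needs sample/group/path."))
        next
      }
      absent <- !file.exists(sheet$path)
      if (any(absent)) {
        add("fatal", paste0(assay, ": file absent for sample ",
                            paste(sheet$sample[absent], collapse = ", "), "."))
      }
      if (any(table(sheet$group) < 2)) {
        add("fatal", paste0(assay, ": a group has fewer than 2 samples."))
      }
    }
  }
  if (length(issues) == 0L) {
    tibble::tibble(severity = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Run the full methylation-comparison pipeline
#'
#' Executes the configured assays (MBD window analysis, RRBS per-CpG tests,
#' amplicon panel, power simulation) end to end, writing every stage's
#' result table as TSV plus a YAML config snapshot and a log of filter
#' attrition to the run directory. Re-running with the same configuration
#' reproduces byte-identical result tables.
#'
#' @param config Configuration list (see [demo_config()]) or path to a YAML
#'   file with the same structure.
#' @return Invisibly, a list with the run directory, per-stage result
#'   objects and output paths.
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_config(seed = 1))
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  issues <- validate_inputs(config)
  if (any(issues$severity == "fatal")) {
    abort(paste0("Invalid configuration:\n  ",
                 paste(issues$message[issues$severity == "fatal"],
                       collapse = "\n  ")))
  }
  out_dir <- config$out_dir %||% tempfile("methdiff_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
    inform(line)
  }

  seed <- check_seed(config$seed)
  fdr <- config$fdr %||% 0.05
  results <- list(dir = out_dir)
  assays <- config$assays %||% c("mbd", "rrbs", "amplicon", "power")

  if ("mbd" %in% assays) {
    cfg <- config$mbd
    if (isTRUE(cfg$synthetic)) {
      genome <- genome_spec(cfg$genome$chrom, cfg$genome$length)
      domains <- if (length(cfg$domains) > 0L) {
        purrr::map_dfr(cfg$domains, tibble::as_tibble)
      } else NULL
      reads <- simulate_mbd_reads(
        genome, domains, background_rate = cfg$background_rate,
        duplicate_rate = cfg$duplicate_rate %||% 0,
        n_samples = 2L * cfg$n_per_group, seed = seed
      )
      ids <- sort(unique(reads$sample))
      group_a <- ids[seq_len(cfg$n_per_group)]
      group_b <- ids[cfg$n_per_group + seq_len(cfg$n_per_group)]
    } else {
      sheet <- readr::read_tsv(cfg$sample_sheet, show_col_types = FALSE,
                               progress = FALSE)
      reads <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
        r <- read_reads_bed(sheet$path[i])
        r$sample <- sheet$sample[i]
        r
      })
      genome <- genome_spec(cfg$genome$chrom, cfg$genome$length)
      group_a <- sheet$sample[sheet$group == unique(sheet$group)[1L]]
      group_b <- sheet$sample[sheet$group == unique(sheet$group)[2L]]
    }
    n_before <- nrow(reads)
    reads <- dedup_reads(reads)
    log_msg("mbd: ", n_before - nrow(reads), " duplicate reads removed (",
            n_before, " -> ", nrow(reads), ")")
    windows <- tile_genome(genome, cfg$window_size %||% 100)
    stats <- count_reads_in_windows(reads, windows) |>
      call_methylated_windows(fdr_threshold = fdr)
    comparison <- compare_mbd_groups(stats, group_a, group_b)
    log_msg("mbd: ", sum(stats$called), " window calls across samples; ",
            sum(comparison$qualitative_hit), " qualitative hits; ",
            sum(comparison$q_nb < fdr), " NB hits at FDR ", fdr)
    readr::write_tsv(stats, file.path(out_dir, "mbd_windows.tsv"),
                     progress = FALSE)
    readr::write_tsv(comparison, file.path(out_dir, "mbd_comparison.tsv"),
                     progress = FALSE)
    results$mbd <- list(stats = stats, comparison = comparison,
                        group_a = group_a, group_b = group_b)
  }

  rrbs_matrix <- NULL
  if ("rrbs" %in% assays) {
    cfg <- config$rrbs
    if (isTRUE(cfg$synthetic)) {
      params <- rrbs_sim_params(
        n_cpgs = cfg$n_cpgs, mean_a = cfg$mean,
        mean_b = pmin(100, cfg$mean + (cfg$effect %||% 0)), sd = cfg$sd,
        coverage_mean = cfg$coverage_mean,
        coverage_dispersion = cfg$coverage_dispersion %||% 0,
        n_per_group = cfg$n_per_group, seed = seed + 1L
      )
      mat <- simulate_rrbs_matrix(params)
    } else {
      sheet <- readr::read_tsv(cfg$sample_sheet, show_col_types = FALSE,
                               progress = FALSE)
      mat <- build_methylation_matrix(sheet)
    }
    groups <- split(unique(mat[c("sample", "group")])$sample,
                    unique(mat[c("sample", "group")])$group)
    n_cpg_before <- dplyr::n_distinct(mat$chrom, mat$pos)
    mat <- filter_cpgs(mat, config$min_coverage %||% 10,
                       config$min_sample_fraction %||% 0.9)
    n_cpg_after <- dplyr::n_distinct(mat$chrom, mat$pos)
    log_msg("rrbs: ", n_cpg_before - n_cpg_after, " CpGs dropped by the ",
            "coverage filter (", n_cpg_before, " -> ", n_cpg_after, ")")
    res <- test_group_difference(mat, groups[[1L]], groups[[2L]])
    volcano <- volcano_table(res, fdr_threshold = fdr)
    log_msg("rrbs: ", nrow(res), " CpGs tested; ",
            sum(res$q_t < fdr), " significant (t, FDR ", fdr, "); ",
            sum(res$q_w < fdr), " significant (Wilcoxon)")
    readr::write_tsv(res, file.path(out_dir, "rrbs_results.tsv"),
                     progress = FALSE)
    readr::write_tsv(volcano, file.path(out_dir, "rrbs_volcano.tsv"),
                     progress = FALSE)
    results$rrbs <- list(matrix = mat, results = res, volcano = volcano,
                         groups = groups)
    rrbs_matrix <- mat
    rrbs_groups <- groups
  }

  if ("amplicon" %in% assays) {
    cfg <- config$amplicon
    if (isTRUE(cfg$synthetic)) {
      loci <- tibble::tibble(
        chrom = "chr2",
        start = (seq_len(cfg$n_loci) - 1L) * 1000L,
        end = (seq_len(cfg$n_loci) - 1L) * 1000L + 500L,
        name = sprintf("locus%02d", seq_len(cfg$n_loci))
      )
      cpg_positions <- setNames(
        purrr::map(seq_len(cfg$n_loci), function(i) {
          loci$start[i] + 100L * seq_len(cfg$cpgs_per_locus)
        }),
        loci$name
      )
      ids <- c(sprintf("A%02d", seq_len(cfg$n_per_group)),
               sprintf("B%02d", seq_len(cfg$n_per_group)))
      set.seed(seed + 2L)
      percents <- tibble::tibble(
        sample = ids,
        group = rep(c("A", "B"), each = cfg$n_per_group),
        percent = rnorm_trunc(
          length(ids),
          cfg$mean + ifelse(rep(c(TRUE, FALSE), each = cfg$n_per_group),
                            0, cfg$effect %||% 0),
          cfg$sd
        )
      )
      amp <- simulate_amplicon_calls(loci, cpg_positions, percents,
                                     depth = cfg$depth, seed = seed + 3L)
      amp_groups <- split(percents$sample, percents$group)
    } else {
      sheet <- readr::read_tsv(cfg$sample_sheet, show_col_types = FALSE,
                               progress = FALSE)
      amp <- build_methylation_matrix(sheet)
      loci <- read_bed(cfg$loci)
      if (!"name" %in% names(loci)) loci$name <- paste0("locus", seq_len(nrow(loci)))
      amp_groups <- split(sheet$sample, sheet$group)
      amp <- aggregate_locus_assign(amp, loci)
    }
    agg <- aggregate_locus(amp, amp_groups[[1L]], amp_groups[[2L]])
    log_msg("amplicon: ", nrow(agg$cpg), " CpGs in ",
            nrow(agg$locus), " loci; ", sum(agg$cpg$q_t < fdr),
            " significant after joint FDR")
    readr::write_tsv(agg$cpg, file.path(out_dir, "amplicon_cpg.tsv"),
                     progress = FALSE)
    readr::write_tsv(agg$locus, file.path(out_dir, "amplicon_locus.tsv"),
                     progress = FALSE)
    results$amplicon <- agg
  }

  if ("power" %in% assays) {
    if (is.null(rrbs_matrix)) {
      abort("The power stage needs the rrbs stage in the same run.")
    }
    cfg <- config$power
    summaries <- summarize_group(rrbs_matrix, rrbs_groups[[1L]]) |>
      select_low_variability(quantile = cfg$quantile %||% 0.10)
    pc <- power_curve(
      summaries, delta_grid = as.numeric(cfg$deltas),
      n_per_group = config$rrbs$n_per_group %||% 10,
      alpha = cfg$alpha %||% 0.05, n_sim = cfg$n_sim %||% 10000,
      seed = seed + 4L, target = cfg$target %||% 0.8
    )
    log_msg("power: minimal detectable difference at power ", pc$target,
            " = ", ifelse(is.na(pc$mdd), "above grid max", pc$mdd))
    readr::write_tsv(tidy(pc), file.path(out_dir, "power_curve.tsv"),
                     progress = FALSE)
    results$power <- pc
  }

  invisible(results)
}

# assign a locus column by interval membership (user-data amplicon path)
aggregate_locus_assign <- function(matrix, loci) {
  idx <- purrr::map_int(seq_len(nrow(matrix)), function(i) {
    hits <- which(loci$chrom == matrix$chrom[i] &
                    matrix$pos[i] >= loci$start &
                    matrix$pos[i] < loci$end)
    if (length(hits) != 1L) {
      abort(paste0("CpG ", matrix$chrom[i], ":", matrix$pos[i],
                   " maps to ", length(hits), " loci."))
    }
    hits
  })
  matrix$locus <- loci$name[idx]
  matrix
}
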