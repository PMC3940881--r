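#' Describe a (toy or real) genome as a table of chromosome lengths
#'
#' A genome specification is the coordinate universe for read simulation and
#' window tiling: one row per chromosome with its length in base pairs. All
#' coordinates in the package are 0-based, half-open.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all `> 0`).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(1e5, 5e4))
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (anyDuplicated(chrom)) abort("Chromosome names must be unique.")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("All chromosome lengths must be positive.")
  }
  tibble::tibble(chrom = chrom, length = length)
}

#' Define enriched (densely methylated) domains for read simulation
#'
#' Domains are genomic intervals in which the MBD read rate is multiplied by
#' an enrichment factor relative to the genomic background, emulating densely
#' methylated regions captured by MBD proteins.
#'
#' @param chrom,start,end Interval coordinates (0-based, half-open).
#' @param enrichment Rate ratio inside vs. outside the domain (`>= 1`).
#' @return A tibble with columns `chrom`, `start`, `end`, `enrichment`.
#' @export
domain_spec <- function(chrom, start, end, enrichment = 10) {
  d <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    enrichment = as.numeric(rep_len(enrichment, length(chrom)))
  )
  if (any(d$start < 0) || any(d$start >= d$end)) {
    abort("Domains require 0 <= start < end.")
  }
  if (any(d$enrichment < 1)) abort("Enrichment factors must be >= 1.")
  d
}

validate_domains <- function(domains, genome) {
  if (is.null(domains) || nrow(domains) == 0L) {
    return(domain_spec(character(), numeric(), numeric() + 1))
  }
  bad <- !domains$chrom %in% genome$chrom
  if (any(bad)) {
    abort(paste0("Domain chromosome(s) not in genome: ",
                 paste(unique(domains$chrom[bad]), collapse = ", ")))
  }
  len <- genome$length[match(domains$chrom, genome$chrom)]
  if (any(domains$end > len)) {
    abort("Domain extends beyond its chromosome.")
  }
  ovl <- domains |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(overlaps = .data$start < dplyr::lag(.data$end, default = -1)) |>
    dplyr::ungroup()
  if (any(ovl$overlaps)) abort("Domains must not overlap.")
  domains
}

#' Simulate MBD-seq read placements with background and enriched rates
#'
#' Read 5' starts follow an inhomogeneous Poisson process: a homogeneous
#' background at `background_rate` reads/bp, multiplied inside each domain by
#' its enrichment factor. A fraction `duplicate_rate` of the emitted reads are
#' exact copies (same chromosome, start and strand) of earlier reads,
#' emulating PCR duplicates.
#'
#' @param genome A [genome_spec()] tibble.
#' @param domains A [domain_spec()] tibble of enriched intervals, or `NULL`.
#' @param background_rate Background read rate in reads per bp (`> 0` unless
#'   you want an empty read set).
#' @param duplicate_rate Fraction of final reads that are PCR duplicates
#'   (`0 <= duplicate_rate < 1`).
#' @param n_samples Number of independent samples to simulate.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return A tibble of aligned reads: `sample`, `chrom`, `start` (0-based 5'
#'   position), `strand`.
#' @examples
#' g <- genome_spec("chr1", 1e5)
#' d <- domain_spec("chr1", 5e4, 5.1e4, enrichment = 10)
#' reads <- simulate_mbd_reads(g, d, background_rate = 0.01, seed = 1)
#' @export
simulate_mbd_reads <- function(genome, domains = NULL, background_rate,
                               duplicate_rate = 0, n_samples = 1, seed) {
  if (background_rate < 0) abort("`background_rate` must be >= 0.")
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    abort("`duplicate_rate` must be in [0, 1).")
  }
  domains <- validate_domains(domains, genome)
  set.seed(check_seed(seed))

  segment_table <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    len <- genome$length[i]
    dom <- dplyr::filter(domains, .data$chrom == !!chrom) |>
      dplyr::arrange(.data$start)
    # cut the chromosome into alternating background / domain segments
    edges <- sort(unique(c(0, dom$start, dom$end, len)))
    seg <- tibble::tibble(
      chrom = chrom,
      start = edges[-length(edges)],
      end = edges[-1]
    )
    seg$factor <- 1
    if (nrow(dom) > 0L) {
      hit <- findInterval(seg$start, dom$start)
      inside <- hit >= 1L & seg$start < dom$end[pmax(hit, 1L)]
      seg$factor[inside] <- dom$enrichment[hit[inside]]
    }
    seg
  })

  one_sample <- function(sample_id) {
    n_seg <- rpois(nrow(segment_table),
                   background_rate * segment_table$factor *
                     (segment_table$end - segment_table$start))
    starts <- purrr::map2(seq_len(nrow(segment_table)), n_seg, function(i, n) {
      if (n == 0L) return(numeric())
      floor(runif(n, segment_table$start[i], segment_table$end[i]))
    })
    reads <- tibble::tibble(
      sample = sample_id,
      chrom = rep(segment_table$chrom, n_seg),
      start = as.numeric(unlist(starts)),
      strand = sample(c("+", "-"), sum(n_seg), replace = TRUE)
    )
    if (duplicate_rate > 0 && nrow(reads) > 0L) {
      n_dup <- round(nrow(reads) * duplicate_rate / (1 - duplicate_rate))
      if (n_dup > 0L) {
        reads <- dplyr::bind_rows(
          reads, reads[sample.int(nrow(reads), n_dup, replace = TRUE), ]
        )
      }
    }
    dplyr::arrange(reads, .data$chrom, .data$start, .data$strand)
  }

  ids <- sprintf("S%02d", seq_len(n_samples))
  purrr::map_dfr(ids, one_sample)
}

#' Parameters for the RRBS-like count simulator
#'
#' Defines a two-group RRBS design: per-CpG group mean percent methylation, a
#' within-group standard deviation on the percent scale, a negative-binomial
#' per-sample coverage model, and the group sizes.
#'
#' @param n_cpgs Number of CpGs to simulate.
#' @param mean_a,mean_b Group mean percent methylation (scalar or length
#'   `n_cpgs`, in `[0, 100]`). `mean_b` defaults to `mean_a` (no group
#'   effect).
#' @param sd Within-group standard deviation of the latent percent, in
#'   percentage points (scalar or per-CpG, `>= 0`).
#' @param coverage_mean,coverage_dispersion Mean and dispersion of the
#'   negative-binomial per-sample read depth at a CpG (`dispersion = 0` gives
#'   Poisson coverage).
#' @param n_per_group Samples per group (`>= 2`).
#' @param seed Integer seed.
#' @return A list of class `rrbs_sim_params`.
#' @export
rrbs_sim_params <- function(n_cpgs, mean_a = 50, mean_b = mean_a, sd = 5,
                            coverage_mean = 30, coverage_dispersion = 0.2,
                            n_per_group = 10, seed = 1) {
  mean_a <- rep_len(as.numeric(mean_a), n_cpgs)
  mean_b <- rep_len(as.numeric(mean_b), n_cpgs)
  sd <- rep_len(as.numeric(sd), n_cpgs)
  if (any(mean_a < 0 | mean_a > 100) || any(mean_b < 0 | mean_b > 100)) {
    abort("Group means must lie in [0, 100] percent.")
  }
  if (any(sd < 0)) abort("`sd` must be >= 0.")
  if (coverage_mean <= 0) abort("`coverage_mean` must be > 0.")
  if (coverage_dispersion < 0) abort("`coverage_dispersion` must be >= 0.")
  if (n_per_group < 2) abort("`n_per_group` must be >= 2 (group tests are undefined below that).")
  structure(
    list(n_cpgs = as.integer(n_cpgs), mean_a = mean_a, mean_b = mean_b,
         sd = sd, coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         n_per_group = as.integer(n_per_group), seed = check_seed(seed)),
    class = "rrbs_sim_params"
  )
}

#' Simulate an RRBS-style per-CpG methylation count matrix
#'
#' For every CpG and sample a latent percent methylation is drawn from a
#' Normal(group mean, SD) truncated to `[0, 100]`; per-sample coverage is
#' negative-binomial; the methylated count is Binomial(coverage, latent/100).
#'
#' @param params An [rrbs_sim_params()] object.
#' @return A methylation matrix in long form: one row per CpG x sample with
#'   columns `chrom`, `pos` (0-based), `strand`, `sample`, `group`, `meth`,
#'   `total`, `percent` (`NA` at zero coverage), `missing`.
#' @examples
#' m <- simulate_rrbs_matrix(rrbs_sim_params(n_cpgs = 50, seed = 7))
#' @export
simulate_rrbs_matrix <- function(params) {
  stopifnot(inherits(params, "rrbs_sim_params"))
  set.seed(params$seed)
  n <- params$n_cpgs
  ids <- c(sprintf("A%02d", seq_len(params$n_per_group)),
           sprintf("B%02d", seq_len(params$n_per_group)))
  groups <- rep(c("A", "B"), each = params$n_per_group)

  grid <- tidyr::expand_grid(
    cpg = seq_len(n),
    idx = seq_along(ids)
  )
  gmean <- ifelse(groups[grid$idx] == "A",
                  params$mean_a[grid$cpg], params$mean_b[grid$cpg])
  latent <- rnorm_trunc(nrow(grid), gmean, params$sd[grid$cpg])
  total <- if (params$coverage_dispersion > 0) {
    rnbinom(nrow(grid), mu = params$coverage_mean,
            size = 1 / params$coverage_dispersion)
  } else {
    rpois(nrow(grid), params$coverage_mean)
  }
  meth <- rbinom(nrow(grid), total, latent / 100)

  tibble::tibble(
    chrom = "chr1",
    pos = (grid$cpg - 1L) * 100L,
    strand = "+",
    sample = ids[grid$idx],
    group = groups[grid$idx],
    meth = meth,
    total = total,
    percent = ifelse(total > 0, 100 * meth / total, NA_real_),
    missing = total == 0L
  )
}

#' Simulate targeted bisulfite-amplicon methylation calls
#'
#' Emulates deep amplicon sequencing of a set of loci: each CpG in each
#' sample receives `depth` reads and a Binomial(depth, percent/100)
#' methylated count. The per-sample latent percent is constant across the
#' CpGs of a locus (supply a `locus` column in `percents` for per-locus
#' values).
#'
#' @param loci Tibble of target intervals: `chrom`, `start`, `end`, `name`
#'   (0-based, half-open).
#' @param cpg_positions Named list (by locus name) of 0-based CpG positions;
#'   every position must lie inside its locus interval.
#' @param percents Tibble with columns `sample`, `percent` (in `[0, 100]`)
#'   and optionally `group` and `locus`. Without a `locus` column the percent
#'   applies to every locus.
#' @param depth Reads per CpG per sample (`>= 1`).
#' @param seed Integer seed.
#' @return A long methylation matrix as in [simulate_rrbs_matrix()], with an
#'   additional `locus` column.
#' @export
simulate_amplicon_calls <- function(loci, cpg_positions, percents, depth, seed) {
  if (depth < 1) abort("`depth` must be >= 1.")
  if (!all(c("sample", "percent") %in% names(percents))) {
    abort("`percents` needs `sample` and `percent` columns.")
  }
  if (any(percents$percent < 0 | percents$percent > 100)) {
    abort("Percents must lie in [0, 100].")
  }
  missing_loci <- setdiff(loci$name, names(cpg_positions))
  if (length(missing_loci) > 0L) {
    abort(paste0("No CpG positions given for locus: ",
                 paste(missing_loci, collapse = ", ")))
  }
  cpgs <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    pos <- cpg_positions[[loci$name[i]]]
    if (any(pos < loci$start[i] | pos >= loci$end[i])) {
      abort(paste0("CpG position outside locus ", loci$name[i], "."))
    }
    tibble::tibble(locus = loci$name[i], chrom = loci$chrom[i], pos = pos)
  })
  set.seed(check_seed(seed))
  per_locus <- "locus" %in% names(percents)
  out <- tidyr::expand_grid(cpgs, sample = unique(percents$sample))
  key <- if (per_locus) paste(out$sample, out$locus) else out$sample
  pkey <- if (per_locus) paste(percents$sample, percents$locus) else percents$sample
  idx <- match(key, pkey)
  if (anyNA(idx)) abort("`percents` must cover every sample (and locus, if per-locus).")
  out$percent_true <- percents$percent[idx]
  out$group <- if ("group" %in% names(percents)) percents$group[idx] else NA_character_
  out$total <- as.integer(depth)
  out$meth <- rbinom(nrow(out), depth, out$percent_true / 100)
  out |>
    dplyr::mutate(
      strand = "+",
      percent = 100 * .data$meth / .data$total,
      missing = FALSE
    ) |>
    dplyr::select("locus", "chrom", "pos", "strand", "sample", "group",
                  "meth", "total", "percent", "missing")
}
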