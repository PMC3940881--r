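#' Read a BED3/BED6 interval or read file
#'
#' Plain tab-separated BED with no header: `chrom`, `start`, `end` and
#' optionally `name`, `score`, `strand`. Coordinates are 0-based half-open,
#' as throughout the package.
#'
#' @param path Path to the BED file.
#' @return A tibble with the columns present in the file.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 3L) abort("BED needs at least 3 columns (chrom, start, end).")
  names(x) <- cols[seq_len(min(ncol(x), 6L))]
  x
}

#' Write aligned reads as BED6
#'
#' Each read becomes one interval `[start, start + read_length)` with its
#' sample id in the name column.
#'
#' @param reads Read tibble (`chrom`, `start`, `strand`, optionally
#'   `sample`).
#' @param path Output path.
#' @param read_length Read length in bp used for the interval end.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path, read_length = 36L) {
  if (!"sample" %in% names(reads)) reads$sample <- "S01"
  out <- tibble::tibble(
    chrom = reads$chrom,
    start = as.integer(reads$start),
    end = as.integer(reads$start) + as.integer(read_length),
    name = reads$sample,
    score = 0L,
    strand = reads$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read aligned reads from BED6
#'
#' @param path Path to a BED6 file written by [write_reads_bed()] or any
#'   aligner post-processing; the name column is taken as the sample id when
#'   present.
#' @return Read tibble: `sample`, `chrom`, `start`, `strand`.
#' @export
read_reads_bed <- function(path) {
  x <- read_bed(path)
  tibble::tibble(
    sample = if ("name" %in% names(x)) as.character(x$name) else "S01",
    chrom = as.character(x$chrom),
    start = as.numeric(x$start),
    strand = if ("strand" %in% names(x)) as.character(x$strand) else "+"
  )
}

#' Write reads as a minimal SAM file
#'
#' Emits an `@HD`/`@SQ` header from the genome specification and one
#' alignment line per read; only the fields a downstream window analysis
#' needs (flag for strand, reference name, 1-based position) carry
#' information.
#'
#' @param reads Read tibble (`chrom`, `start`, `strand`).
#' @param genome A [genome_spec()] tibble for the `@SQ` header lines.
#' @param path Output path.
#' @param read_length Read length reported in the CIGAR.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, genome, path, read_length = 36L) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, as.integer(genome$length))
  )
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)), flag, reads$chrom,
                  as.integer(reads$start) + 1L, as.integer(read_length))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal SAM file (chromosome, position and strand flag only)
#'
#' Parses only the fields the window analysis uses: reference name, 1-based
#' leftmost position (converted to 0-based) and the reverse-strand bit of the
#' flag. Unmapped reads (flag bit 0x4) are dropped.
#'
#' @param path Path to a SAM file.
#' @param sample Sample id to attach to the reads.
#' @return Read tibble: `sample`, `chrom`, `start`, `strand`.
#' @export
read_reads_sam <- function(path, sample = "S01") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L) {
    abort(paste0("Malformed SAM line ", bad[1L], ": fewer than 4 fields."))
  }
  flag <- as.integer(purrr::map_chr(fields, 2L))
  keep <- bitwAnd(flag, 4L) == 0L
  tibble::tibble(
    sample = sample,
    chrom = purrr::map_chr(fields, 3L)[keep],
    start = as.numeric(purrr::map_chr(fields, 4L))[keep] - 1,
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+")
  )
}

#' Write one sample of a methylation matrix as a cytosine report
#'
#' Bismark-style cytosine report TSV: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context (`"CG"`), trinucleotide.
#'
#' @param matrix Long methylation matrix.
#' @param sample Sample id to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(matrix, sample, path) {
  m <- matrix[matrix$sample == sample, ]
  if (nrow(m) == 0L) abort(paste0("No rows for sample ", sample, "."))
  out <- tibble::tibble(
    chrom = m$chrom,
    pos = as.integer(m$pos) + 1L,          # 1-based on disk
    strand = m$strand,
    meth = as.integer(m$meth),
    unmeth = as.integer(m$total - m$meth),
    context = "CG",
    tri = "CGG"
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' Expects seven tab-separated columns: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide. Positions
#' are converted to 0-based. With `merge_strands = TRUE` (the default) the
#' minus-strand cytosine of each CpG dyad is folded onto the plus-strand C
#' (position minus one) and the counts are summed, so each CpG appears once.
#'
#' @param path Path to the report.
#' @param sample Sample id to attach.
#' @param merge_strands Merge CpG dyads across strands.
#' @return Tibble of CpG records: `chrom`, `pos` (0-based), `strand`,
#'   `sample`, `meth`, `total`, `percent`.
#' @export
read_cytosine_report <- function(path, sample = "S01", merge_strands = TRUE) {
  x <- suppressWarnings(readr::read_tsv(
    path, col_names = c("chrom", "pos", "strand", "meth", "unmeth",
                        "context", "tri"),
    col_types = "ciciicc",
    progress = FALSE
  ))
  if (nrow(x) == 0L) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          strand = character(), sample = character(),
                          meth = integer(), total = integer(),
                          percent = numeric()))
  }
  prob <- readr::problems(x)
  if (nrow(prob) > 0L) {
    abort(paste0("Malformed cytosine report row at line ", prob$row[1L],
                 " of ", path, "."))
  }
  if (anyNA(x$pos) || anyNA(x$meth) || anyNA(x$unmeth)) {
    bad <- which(is.na(x$pos) | is.na(x$meth) | is.na(x$unmeth))[1L]
    abort(paste0("Malformed cytosine report row at line ", bad, " of ",
                 path, "."))
  }
  if (anyDuplicated(x[c("chrom", "pos", "strand")])) {
    abort(paste0("Duplicate (chrom, pos, strand) rows in ", path, "."))
  }
  x$pos <- x$pos - 1L                      # to 0-based
  if (merge_strands) {
    x <- x |>
      dplyr::mutate(pos = ifelse(.data$strand == "-", .data$pos - 1L,
                                 .data$pos)) |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                       .groups = "drop") |>
      dplyr::mutate(strand = "+")
  }
  x |>
    dplyr::transmute(
      chrom = .data$chrom, pos = as.numeric(.data$pos),
      strand = .data$strand, sample = sample,
      meth = as.integer(.data$meth),
      total = as.integer(.data$meth + .data$unmeth),
      percent = ifelse(.data$meth + .data$unmeth > 0,
                       100 * .data$meth / (.data$meth + .data$unmeth),
                       NA_real_)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Assemble a methylation matrix from a sample sheet
#'
#' Reads one cytosine report per sample and binds them into the long
#' methylation matrix the testing functions consume.
#'
#' @param sample_sheet Tibble with columns `sample`, `group`, `path`.
#' @param merge_strands Passed to [read_cytosine_report()].
#' @return Long methylation matrix with `group` and `missing` columns.
#' @export
build_methylation_matrix <- function(sample_sheet, merge_strands = TRUE) {
  need <- c("sample", "group", "path")
  if (!all(need %in% names(sample_sheet))) {
    abort("`sample_sheet` needs columns sample, group, path.")
  }
  absent <- !file.exists(sample_sheet$path)
  if (any(absent)) {
    abort(paste0("File missing for sample ",
                 sample_sheet$sample[absent][1L], ": ",
                 sample_sheet$path[absent][1L]))
  }
  purrr::map_dfr(seq_len(nrow(sample_sheet)), function(i) {
    read_cytosine_report(sample_sheet$path[i], sample_sheet$sample[i],
                         merge_strands = merge_strands) |>
      dplyr::mutate(group = sample_sheet$group[i])
  }) |>
    dplyr::mutate(missing = .data$total == 0L) |>
    dplyr::relocate("group", .after = "sample")
}
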