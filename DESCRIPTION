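Package: methdiff
Title: Differential DNA Methylation Analysis for MBD-Seq, RRBS and
    Bisulfite Amplicon Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for group comparisons of DNA methylation in
    sequencing-based assays. Implements window-based enrichment calling for
    MBD (methyl-CpG binding domain) capture sequencing with Poisson
    statistics and Benjamini-Hochberg false discovery rates, qualitative
    (all-versus-none) and quantitative (negative-binomial exact test) group
    comparisons, per-CpG coverage filtering and Student/Wilcoxon testing for
    reduced representation bisulfite sequencing (RRBS) and targeted
    bisulfite amplicon data, and a Monte-Carlo power simulation that
    estimates the minimal detectable methylation difference for a two-group
    design. Includes synthetic-data generators with known ground truth so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
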