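---
title: "Models and design choices in methdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiff)
library(dplyr)
```

methdiff compares DNA methylation between two groups of samples across three
assay types — MBD capture sequencing, RRBS, and targeted bisulfite
amplicons — and quantifies what the design can and cannot detect. This
vignette states the statistical models, the parameters that matter, the
numerical conventions, and the places where the design was genuinely open
and a choice had to be made.

All genomic coordinates in the package are 0-based and half-open, in every
function and on every BED file it writes; cytosine reports are 1-based on
disk (the field convention) and converted on read.

## The MBD window model

MBD capture enriches densely methylated DNA, so methylated regions appear
as read pile-ups. After discarding putative PCR duplicates — at most one
read per (chromosome, 5′ start, strand) key — the genome is tiled into
non-overlapping windows and each window's read count is compared against a
Poisson null:

$$ p_w = P\{\,\mathrm{Poisson}(\lambda) \ge k_w\,\}, \qquad
   \lambda = \frac{\text{total reads in the sample}}{\text{number of windows}} . $$

The null rate deliberately averages over *all* windows of the tiling,
including empty ones: the question each window answers is "more reads than
expected by chance anywhere in the genome", and dropping zero-count windows
would inflate $\lambda$ and mask weak enrichment. Benjamini–Hochberg
q-values are computed within each window source (100 bp, 1000 bp, CpG
islands are three separate analyses with three separate FDR families), and
a window is called methylated at q < 0.05 by default. $\lambda$ is
estimated genome-wide rather than per chromosome; a per-chromosome null
would only matter if chromosomes differed systematically in capture
efficiency, which the assay gives no handle on.

Reads are assigned to windows by their 5′ start under the half-open
convention — a read starting exactly on a boundary belongs to the window to
its right. With short reads on windows at least ~3× the read length, any
single unambiguous rule gives near-identical counts; the start rule is the
simplest one that needs no read-length bookkeeping.

Two group comparisons are built on the per-sample calls:

* **Qualitative**: a window is a hit when it is called in *every* sample of
  one group and in *no* sample of the other. "Lacking methylation" is
  interpreted as *not called* rather than zero reads — the calls are what
  define methylation status in this assay — but the definition is strict in
  both directions, so a single dissenting sample cancels the hit.
* **Quantitative**: a conditional exact test under a negative-binomial
  model, described next.

### The negative-binomial exact test

Counts are scaled to a common effective library size — the geometric mean
of the per-sample totals — and a single common dispersion $\phi$ is
estimated across windows by the method of moments on the scaled counts
(pooled within-group variance $v_w$ and grand mean $m_w$ per window;
$\hat\phi = \sum_w (v_w - m_w) / \sum_w m_w^2$, floored at 0). For each
window the test conditions on the total scaled count $t$: writing $n_A$,
$n_B$ for the group sizes, the group-A sum given $t$ follows

$$ P(S_A = s \mid T = t) \propto
   f_{NB}\!\left(s;\ \tfrac{n_A}{\phi},\ n_A\mu\right)
   f_{NB}\!\left(t - s;\ \tfrac{n_B}{\phi},\ n_B\mu\right), $$

with $\mu = t/(n_A+n_B)$, reducing to a Binomial$(t, n_A/(n_A+n_B))$ when
$\phi = 0$. The two-sided p-value sums the probabilities of all outcomes no
more likely than the observed one; outcomes tied with the observed
probability (within a relative $10^{-12}$) are included, the standard
exact-test convention. An all-zero window has $p = 1$ by convention.
Scaled counts are rounded to integers for the conditional enumeration;
with the scaling factors near 1 that rounding perturbs sums by at most one
count. Method-of-moments estimation was chosen over conditional maximum
likelihood because it is transparent and directly checkable against a
brute-force variance decomposition; the test itself is a plain conditional
exact test without quantile adjustment, which calibration simulations (in
the test suite) show holds its nominal type-I error within [0.03, 0.07] at
$\phi = 0.1$, 4 vs 4 samples.

## The RRBS / amplicon per-CpG model

Each sample contributes methylated and total read counts per CpG; percent
methylation is $100\,m/t$. The package computes percent *per sample* and
compares samples — it never pools counts across samples, because pooling
would weight samples by coverage and hide between-animal variability,
which is exactly what the group tests must respect.

The coverage filter keeps a CpG when at least a fraction
`min_sample_fraction` (default 0.9) of samples have `min_coverage` reads
(default 10); in retained CpGs, samples below the threshold are missing
data. The boundary is inclusive: 9 of 10 samples covered is retained.
Tests drop missing samples and require at least two non-missing samples
per group, else the CpG is skipped and logged — with fewer than two values
a variance, hence either test, is undefined.

Group differences use a two-sided equal-variance Student's t-test (Welch
available as an option) and a two-sided Wilcoxon rank-sum test: exact when
both groups have at most 12 values and no ties, normal approximation with
tie correction otherwise. FDR families follow the analysis structure: RRBS
CpGs are corrected per pairwise group comparison; amplicon CpGs are
corrected jointly across all loci of the panel, since the panel is one
experiment and one decision.

CpG dyads are merged across strands by default (the minus-strand C is
folded onto the plus-strand C one base to its left and counts are summed);
an unmerged mode exists. Merging is the right default for CpG methylation,
which is symmetric in mammals, and doubles the effective coverage.

## The power simulation

The power module answers: given the observed per-CpG variability, what
group difference could this design detect? From one group's data it takes
per-CpG (mean, SD) summaries of percent methylation, restricts to the
lowest-SD decile (`floor(0.1 m)` smallest SDs, ties broken by input order),
and then, for each of `n_sim = 10000` replicates, draws one (mean, SD)
pair, simulates `n = 10` values per group from Normal(mean, SD) and
Normal(mean + δ, SD) truncated to [0, 100], and applies the *same* Student
t code path the pipeline uses on real data — so the power statement is
about the pipeline's actual test, not an idealised one. Power is the
fraction of replicates with p < α at the nominal per-test α = 0.05; the
minimal detectable difference is the smallest grid δ reaching the target
power (0.80), with a linear interpolation between the bracketing grid
points reported alongside.

Two open choices were resolved as follows. The latent distribution behind
a (mean, SD) pair is Gaussian truncated to the percent scale — the minimal
model consistent with a mean/SD parameterisation; simulation at the count
scale (binomial reads around a latent percent) is available through the
RRBS generator for users who want coverage noise included. And α is the
nominal per-test 0.05, not an FDR-adjusted level: the question posed is
per-CpG sensitivity, and an FDR-adjusted α would make power depend on the
(unknown) number of true effects. When mean ± 4 SD lies inside [0, 100]
the truncation is inactive and the estimate agrees with the closed-form
noncentral-t power ($\mathrm{ncp} = \delta / (\sigma\sqrt{2/n})$, df
$= 2n-2$) within Monte-Carlo error, which the test suite checks.

## What the synthetic generators emulate — and what they do not

The MBD generator places read 5′ starts by an inhomogeneous Poisson
process: a homogeneous background rate multiplied, inside each enriched
domain, by that domain's enrichment factor; a chosen fraction of the final
reads are exact (chromosome, start, strand) copies of earlier reads,
matching the dedup key. The RRBS generator draws, per CpG and sample, a
latent percent from a truncated Normal around the group mean, a coverage
from a negative binomial (two parameters suffice to mimic the order-of-
magnitude depth heterogeneity of real libraries), and a methylated count
from a Binomial(coverage, latent/100). The amplicon generator fixes depth
and draws binomial counts around per-sample latent percents.

None of the generators models read sequences, bisulfite conversion errors,
alignment artefacts, mappability, GC or CpG-density bias in MBD affinity,
or spatial correlation of methylation along the genome. Passing tests on
synthetic data therefore demonstrate that the *statistics* behave as
specified (calibration, recall, FDR control, unbiasedness) — not that the
pipeline is robust to upstream artefacts real data can carry. Fixed seeds
make every generator bit-reproducible.

One consequence worth knowing: binomial read sampling adds variance on the
percent scale, roughly $100^2\,\bar p(1-\bar p)\,\mathrm{E}[1/n]$, on top
of the latent SD. At 50% methylation and 30–50× coverage this contributes
≈ 7 points of SD — often *more* than the biological component. Tests that
state a within-group SD condition therefore simulate at high coverage
(200×) where the sampling term is negligible, so the realised SD is the
stated one.

## Problem sizes and runtime conventions

The test suite exercises calibration at 5,000 CpGs/windows per test family,
null-pipeline behaviour over 20 independent 2,000-CpG datasets, MBD recall
on a 1-Mb genome with 20 planted 1-kb domains at 10× enrichment over a
λ ≈ 5 background, and power oracles at 4,000–10,000 replicates — sizes at
which Monte-Carlo error is small relative to every asserted margin while
the whole suite stays fast. The headline power computation in
`scripts/acceptance.R` uses the full 10,000 replicates.

## Known limitations

* The MBD model has no mappability or copy-number correction; regions of
  anomalous alignability will violate the uniform Poisson null.
* The NB exact test uses a single common dispersion; strongly
  window-specific dispersion (for example, copy-number variable regions)
  will be mis-calibrated there.
* No DMR-level smoothing or beta-binomial regression: the unit of inference
  is the window or the single CpG, and evidence is not shared across
  neighbours.
* The qualitative all-versus-none comparison is intentionally strict; with
  small groups it has low power and is best read as a screen for large,
  consistent differences.
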