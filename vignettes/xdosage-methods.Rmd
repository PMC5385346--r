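---
title: "Methods: X-dosage statistics and the calibrated simulation profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X-dosage statistics and the calibrated simulation profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdosage)
```

## The scientific setting

Female mammals normally silence one X chromosome (X-chromosome
inactivation, XCI) so that X dosage matches males. In bovine blastocysts
XCI has not yet happened: both X chromosomes are active in female embryos,
so X-linked transcripts run close to two-fold above males while autosomes
stay balanced. Cloned embryos produced by somatic-cell nuclear transfer
(SCNT) start from a differentiated female nucleus with one *inactive* X and
must reactivate it during reprogramming; how completely they do so is
visible in the same dosage statistics. `xdosage` implements those
statistics for gene-level FPKM matrices of sexed single blastocysts
(IVF, SCNT, sham-manipulated controls) and the fibroblast donor cells,
together with a synthetic-data generator that reproduces the statistical
structure of such data so the whole pipeline is testable without raw
sequencing data.

## Dosage statistics

**Group means and F:M ratios.** For each gene, the arithmetic mean FPKM is
taken per (sex, group) cell. Within a group, the per-gene female:male ratio
is `log2((f + pc) / (m + pc))`; with the default pseudocount `pc = 0`, a
gene with a zero sex mean has an undefined ratio and is dropped from ratio
statistics (an optional `pseudocount` keeps it). Ratio statistics are
restricted to genes whose larger sex mean exceeds `min_fpkm = 1`, the
expression filter conventional for this kind of comparison.

**The aggregate fold.** `fm_mean_ratio()` reports
`mean(female means) / mean(male means)` over qualifying genes — the ratio
of aggregates, not the mean of per-gene ratios. Per-gene ratios explode
when a male mean is small, so their average is dominated by denominators
near zero; the aggregate form is stable and is the package's calibrated
default. The per-gene form remains available (`mode = "per_gene"`) for
sensitivity analysis.

**XIST handling.** XIST is expressed from the inactive/silencing X in
females only. With a male mean of zero it drops out of every F:M ratio
statistic automatically, but it *does* contribute to a female sample's mean
X-linked expression and therefore to her X:A ratio — a real property of
these transcriptomes, not an artifact. X-linked aggregates therefore
include XIST by default, with `exclude_xist` flags throughout because a
single abundant female-specific transcript materially shifts aggregate
statistics and users should be able to see by how much. Pseudoautosomal
genes (default list: ZBED1, CD99) are counted as X-linked — they are
annotated on X — with `exclude_par` available since their two-copy status
in males exempts them from X dosage logic.

**X:A ratios.** Per sample: mean FPKM over X-linked genes passing the
per-sample expression filter (`FPKM > 0.1`) divided by the same quantity
over autosomal genes. One active X against biallelic autosomes gives ~0.5;
two active X give ~1. The 0.1 threshold is the only expression cutoff the
source study states ("transcripts expressed, FPKM > 0.1") and is also used
for the expressed-gene counts, where sexes are pooled by taking each gene's
larger sex mean.

**Distribution comparisons.** F:M ratio lists are compared with the
two-sided Mann-Whitney and two-sample Kolmogorov-Smirnov tests, exact at
small n where the underlying tests permit (no ties). Male and female X:A
values within a group are *unpaired*, so `sexed_xa_test()` defaults to the
Mann-Whitney rank-sum test; a signed-rank mode exists only for genuinely
paired designs (the IT/TE module uses it). Degenerate fully-tied input
yields p = 1 with a warning rather than an error.

## Sliding-window profiles

Each chromosome is tiled into fixed 1-Mb windows (0-based half-open;
1-based inclusive input coordinates are converted internally). Every mapped
gene goes to exactly one window by its start coordinate — midpoint or
overlap-weighted assignment would smear a gene across windows and break the
conservation property that window sums add up to the chromosome's total
expression. Window sums are divided by the male-IVF reference profile
(windows with a zero reference are missing, not infinite) and smoothed by a
centred 30-window moving average that shrinks at chromosome edges and skips
missing windows. Whether the original analysis centred its average or
trailed it is unknowable from the text; centring avoids a half-window phase
shift and is fixed here. The XIST locus shows up as a genuine spike on the
female X profile; chromosome-wide fold assertions in the test suite drop
that single gene first.

## Differential expression

Within a group, genes passing mean FPKM > 0.1 in at least one sex are
tested with a two-sided Welch two-sample *t*-test on log2(FPKM + 1),
vectorised over genes; a rank-sum alternative is available. The upstream
study quantified with the Tuxedo pipeline whose differential engine works
from read-level models unavailable at matrix level, so absolute DEG counts
are not comparable — the package treats direction proportions and set
overlaps as the meaningful outputs. P-values are deliberately unadjusted at
α = 0.05 to mirror the nominal-p DEG convention of small single-embryo
designs; `adjust = "BH"` switches on FDR control. Display fold changes use
a 0.01 pseudocount to stay finite.

## Trajectories, clustering, heatmap

Per gene, log2 relative expression against the male-IVF group mean is
assembled across donor → SCNT → IVF (per sex, since the sexes behave
differently and are clustered separately by default). K-means uses
`stats::kmeans` with 10 random starts at a fixed seed, k = 9; genes with a
zero reference mean are excluded with a logged count. The heatmap matrix
orders genes by average-linkage hierarchical clustering on Euclidean
distance; each dendrogram branch is re-oriented by its mean value so the
leaf order does not depend on input row order. Linkage and distance are
fixed choices for determinism — the source figures do not state theirs.

## IT/TE lineage comparison

Dissected blastocysts contribute one IT part (inner cell mass + TE cells,
~1:1) and one TE-only part. Reported IT/TE means are normalised so the IT
group mean is exactly 1; per-embryo IT:TE ratios are computed before
normalisation. X:A and XIST comparisons use two-sided paired signed-rank
tests (the design is genuinely paired); XIST is compared at α = 0.01, on
the FPKM scale of the matrix rather than raw read counts. Under imprinted
paternal-X inactivation confined to the TE, the *observable* IT:TE fold is
diluted by the IT part's TE cells: `imprinted_lineage_effect(icm_fraction)`
returns `1 + icm_fraction` (1.5 at a 1:1 mixture, not 2). The test suite
verifies both directions: a null simulation stays near ratio 1 with
non-significant paired tests, and an imprinted simulation at fold 1.5 is
detected in ≥95% of runs — so a negative finding from this analysis is
informative.

## Gene-set categories

Curated sets (the bundled stand-in for the 29 testes-specific X genes is
synthetic; users supply their own symbol list) are labelled none-to-weak
(mean FPKM < 0.1), weak-to-moderate ([0.1, 0.5]) or moderate-to-high
(> 0.5). Boundary values fall in the lower category — an arbitrary but
fixed convention, stated here because the thresholds are the published ones
while the boundary rule is not.

## The synthetic-data generator

`generate_dataset()` draws, deterministically from an integer seed:

- **Genes**: 12,000 autosomal genes on 29 autosomes, 700 X-linked (one
  XIST, two pseudoautosomal, 29 testes-specific), 30 Y-linked; placed
  uniformly along chromosomes (1.2e8 bp autosomes, 1.5e8 bp X). Real gene
  coordinates are irrelevant to the statistics being recovered.
- **Baselines**: per-gene FPKM `2^N(2, 2)` — log-normal, the standard model
  for FPKM-scale bulk data. Housekeeping and Y marker genes are forced to
  robustly expressed regimes so QC logic is exercised; testes-specific
  genes to a somatically silenced regime (`2^N(-3.6, 1)`).
- **Sex structure**: non-pseudoautosomal X and Y genes carry a single-copy
  factor (0.479, calibrated so male X:A ≈ 0.49 after the per-sample
  expression filter's selection effect); XIST is female-only at a
  group-specific calibrated level; Y genes are male-only.
- **Female X upregulation**: a per-group *responder fraction* of X genes
  carries a fold drawn from a per-group shape — a left-skewed "up"
  component (capped exponential, or zero-truncated normal for the sham
  group) plus a minority "down" (male-high) component sized from the
  published male-high xDEG shares (6% IVF, 18% SCNT). A single global fold
  cannot simultaneously match the aggregate fold and the F:M > 1 / > 2
  proportions; for SCNT even fraction + single fold is infeasible (the > 2
  proportion exceeds what any one fold allows at the printed aggregate).
  Folds are linearly rescaled so the expected aggregate equals
  `x_upregulation[group]` exactly — setting a group's fold to 1 collapses
  every responder fold to 1, giving a clean null. Responder membership and
  magnitudes derive from shared per-gene latents, so responder sets are
  nested across groups (SCNT ⊂ SHAM ⊂ IVF at default fractions) and the
  same gene behaves coherently along the donor → SCNT → IVF trajectory.
- **Donor cells**: no reactivation fold; instead a symmetric per-gene log2
  sex divergence (sd 1.41) emulating clonal XCI skewing between the two
  fibroblast lines — this reproduces the near-50% F:M > 1 proportion
  together with the heavy > 2 tail (24.2%) of somatic cells.
- **Noise**: multiplicative log-normal biological noise (sd 0.35 log2) per
  measurement; a global per-sample scale jitter (sd 0.09 log2) emulating
  imperfect library-size normalisation; a per-blastocyst female X-activity
  factor (sd 0.40 log2, mean-one) reflecting variable X reactivation among
  embryos — this is what makes female X:A spread (±~0.3) while male X:A
  stays tight. Cells below the per-sample 25% expression quantile drop to
  zero with probability 0.05, mimicking low-input library sparsity (a hard
  quantile cutoff would delete the entire low-expression regime of the
  heavy-tailed baseline distribution, including the testes-specific set).
- **Design**: 6 samples per sex per group. `generate_lineage_dataset()`
  splits each of 19 simulated female embryos into IT and TE parts that
  share the embryo's expression (including its X-activity factor) and
  differ by split-measurement noise (sd 0.10 log2); X genes of the IT part
  are multiplied by `lineage_effect` (default 1: no imprinting).

**Calibration.** The profile's free constants (responder fractions and
shapes, the single-copy factor, XIST levels, donor divergence) were fitted
once, by moment matching plus simulation, against the published effect
sizes: aggregate folds 1.8 / 1.5 / 1.9, X:A 0.49 / 1.01 / 0.80 / 0.64,
F:M > 1 proportions 78.7 / 66.7 / 78.1 / 51.2% and > 2 proportions
46.7 / 36.2 / 33.1 / 24.2%, and the > 50%-expressed property of the
testes-specific set. They are data, documented here and versioned with the
package. The published per-embryo dispersions are not printed anywhere, so
the noise scales are chosen as realistic for FPKM-scale single-embryo bulk
data rather than extracted.

**What the generator does not emulate**: read-level sampling, gene length
and GC effects, correlated co-expression modules, isoforms, batch
structure, or real bovine gene coordinates. Passing recovery tests
therefore demonstrates that the *pipeline* measures what it claims on data
with the published effect structure — not that it would be robust to every
artifact of real libraries.

## Numerical conventions

- Coordinates: 1-based inclusive on input (GTF convention), 0-based
  half-open internally for windowing.
- Histogram bins: left-closed, right-open, width 0.2 in log2, aligned at 0.
- Ratios with zero denominators are missing, never infinite; fully tied
  test input gives p = 1 with a warning.
- Zero p-values are clipped to the smallest representable double for
  volcano coordinates.
- Correlation matrices keep a unit diagonal; zero-variance samples yield
  missing off-diagonal entries.
- Every output table carries a comment header with the package version,
  parameters and the run-configuration hash; `write_report()` refuses to
  mix files from different hashes.

## Problem sizes used by the test suite

Recovery checks run the full design (12,730 genes, 6 samples per sex per
group) averaged over 25 seeds; the paired-lineage checks use 19 embryos ×
25 seeds; type-I calibration uses 200 seeds of a reduced null profile (380
genes), which is ample for a rejection-rate estimate; fast property loops
use a reduced profile (800 autosomal + 150 X genes) that keeps every
distributional feature. These sizes are the package's choices for a
convergent yet quick default suite.

## Known limitations

- Input FPKM is taken as already normalised; no re-normalisation or batch
  correction is attempted.
- Absolute DEG counts depend strongly on the test engine and n; only
  direction proportions and overlaps are treated as reproducible.
- The bundled pseudoautosomal and testes-specific lists are small synthetic
  stand-ins; analyses of real data should supply curated lists.
- The Welch test on log2(FPKM + 1) loses power for genes expressed near the
  filter threshold; the power guarantee in the test suite applies to
  responder genes passing the FPKM > 1 expression filter.
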