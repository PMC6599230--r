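---
title: "Models and methods behind medipdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind medipdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`medipdmr` implements the downstream analysis of a MeDIP-seq study of
placental DNA methylation across gestational age: from per-replicate
peak calls and counts, through consensus peak construction and
negative-binomial differential testing, to genomic annotation,
window-based feature enrichment and gene-set comparison. This vignette
explains the statistical model, the conventions, and the design choices
that were genuinely open, in the order the pipeline runs.

## Coordinates and the width convention

All intervals are 0-based half-open; the width of an interval is
`end - start`, and two intervals overlap only if they share at least
one base (touching end-to-start is not overlap). The published DMR
tables print locations as `chrN:start–end` with digit grouping; the
package ingests those coordinates verbatim, because that convention —
and only that one — reproduces every printed "DMR Width" as
`end - start` (all 88 rows of the two shipped tables). A 1-based
inclusive reading would make every width one larger than printed.
Canonical output locations use a plain hyphen and no digit grouping.

Merging intervals joins book-ended neighbours (one ending exactly where
the next starts): consensus regions should not fragment at abutting
peaks, mirroring the default of common merge tools.

## Consensus peaks

For each individual, the union of the three technical replicates' peak
calls is merged, and a merged interval is retained only if it overlaps
at least one peak from *every* replicate — the consensus set contains
only peaks present in all technical replicates. The retained interval
is the merged union span (not the intersection), so downstream counts
capture the full enriched region. "Present" means at least 1 bp of
overlap; fractional-overlap thresholds were rejected as an unstated
extra parameter.

At the cohort level, individual consensus sets are merged the same way
and an interval is kept when peaks from at least `min_overlap` distinct
individuals support it. The default is 2, the common default of
consensus peak-set tools; it is an explicit argument everywhere it
matters. Counts for each master peak and individual are the sums of
all replicate count rows whose region overlaps the master peak, over
the three technical replicates; regions missing from a replicate table
count as zero.

## The count model

Peak counts for individual $j$ and region $i$ are modelled as negative
binomial with mean $s_j \mu_{ij}$ and dispersion $\alpha_i$
(variance $\mu + \alpha\mu^2$), with a log-linear predictor:

* dichotomous model: $\log_2 \mu_{ij} = \beta_{0i} + \beta_{1i} x_j$,
  where $x_j$ indicates a *term* birth;
* continuous model: $\log_2 \mu_{ij} = \beta_{0i} + \beta_{1i} g_j$,
  with $g_j$ the gestational age in weeks, uncentered, so
  $\beta_{1i}$ is a per-week log2 slope.

**Sign convention.** Coding the indicator on the term group makes a
positive `log2FoldChange` mean higher methylation at term, i.e. the
region is *hypo*-methylated in preterm placentas. This convention is
reverse-engineered from the published tables: 13 of the 21 printed
preterm DMRs have positive log2 fold change, and the study reports 62%
hypo-methylated in preterm — and 13/21 = 62%. The `direction` column
simply labels positive fold changes `hypo` and negative ones `hyper`.
Which group the original analysis used as fold-change numerator is not
stated anywhere, so this inference is documented rather than assumed
silently.

**Size factors** are median-of-ratios: for each sample, the median over
all-positive regions of the ratio between the sample's count and the
region's geometric mean, rescaled so the factors' geometric mean is 1.
A `pseudo_reference` flag handles matrices without any all-positive
region by building the reference from positive counts only.

**Dispersion** is estimated in three stages, deliberately simpler than
the reference count-model packages: (1) a raw per-region estimate
maximizing the NB likelihood at the Poisson-fitted means; (2) a trend
$\alpha(\mu) = a_0 + a_1/\mu$ fitted by least squares across regions
(coefficients clamped to be non-negative); (3) a final value that is
the equal-weight log-space average — the geometric mean — of raw and
trend, floored at $10^{-8}$. The equal-weight shrinkage is fixed rather
than estimated: it is stated, testable, and adequate at the scale this
package targets. Raw estimates that hit the floor (near-Poisson
regions) stay at the floor before shrinkage, so Poisson-generated data
collapse to effectively zero dispersion.

**Testing.** Each region is fitted by iteratively reweighted least
squares at its final dispersion; standard errors come from the observed
information matrix, and the non-intercept coefficient is tested with a
two-sided normal (Wald) statistic. There is no outlier handling
(Cook's distance), no fold-change shrinkage, and no likelihood-ratio
alternative; these are documented divergences from the original
package's internals, which is why exact reproduction of the deposited
discovery counts is a non-goal.

**Independent filtering.** Raw p-values are BH-adjusted after
discarding low-information regions: thresholds at the `baseMean`
quantiles 0, 0.01, ..., 0.95 are scanned, only surviving regions are
adjusted at each, and the threshold maximizing the number of adjusted
p-values below the target FDR (default 0.05) is chosen. Ties break
toward the smallest threshold, retaining the most records; filtered
records get `NA` adjusted p-values. With the grid collapsed to {0}
this reduces exactly to plain BH.

## Annotation

Gene models are BED12; the transcription start site is strand-aware,
and UTRs are the exonic sequence outside the coding (thick) span.
Classification is by the DMR midpoint with fixed precedence:
Promoter (≤1 kb) > Promoter (1–2 kb) > Promoter (2–3 kb) > 5' UTR >
3' UTR > Exon > 1st Intron > Intron > Downstream (≤3 kb) > Distal
Intergenic. Promoter bins measure distance upstream of the TSS; the
bins end at 3 kb, mirroring the printed category labels. The annotation
tool used in the original study does not state its internal rule, so
midpoint classification was chosen as the simplest testable rule; the
published tables print the single string "Intron" while the text
distinguishes first introns, so the classifier separates `1st Intron`
from `Intron` and both count as intronic. The nearest gene is the
same-chromosome gene with the closest TSS to the DMR midpoint (distance
zero inside a transcript, ties to the lexicographically smaller
symbol); whether the original used midpoint, edge or whole-region
distance is unstated.

CpG shores are the 0–2 kb flanks of the islands and shelves the
2–4 kb flanks, the standard reading of "2 kb and 4 kb up and
downstream"; island > shore > shelf precedence applies where flanks of
neighbouring islands collide, and all three sets are pairwise disjoint
by construction (tested against a per-base labelling oracle).

## Enrichment

The genome is tiled into 500-bp windows (final partial tile kept), and
each window is flagged for a feature if any overlap exists. The
enrichment of a feature among a DMR set is

$$\text{score} = \frac{\text{fraction of DMRs overlapping flagged
windows}}{\text{fraction of all windows flagged}}$$

computed separately for hyper- and hypo-methylated DMRs. DMR-feature
overlap is deliberately mediated through the flagged windows rather
than by direct intersection — the two differ at window boundaries, and
the window formulation is the one the study describes. No significance
test is attached to these scores, since none is reported for them. By
default the enrichment step runs on the nominally significant
(p < 0.01) set, with the FDR set available by filtering the results
table; which of the two the original figure used is not stated.

## Gene sets

Overlap between a query gene list and a target set is summarized by the
observed intersection, the chance expectation
$|q||t|/|U|$, and an upper-tail hypergeometric p-value
$P(X \ge \text{obs})$. The original text reports "greater than
expected by chance" without naming a test; the hypergeometric
over-representation test is the field's default for that sentence, and
the universe is an explicit argument because the original universe is
equally unstated. Symbol matching is exact after upper-casing — alias
resolution would need an external database and is out of scope.

## The synthetic-data generator

The generator exists so that every downstream stage is testable
offline; its defaults emulate the study design:

| parameter | default | meaning |
|---|---|---|
| `n_preterm`, `n_term` | 6, 3 | cohort shape; GA drawn uniform in 25–34 / 37–41 wk |
| `n_replicates` | 3 | technical replicates per individual |
| `n_peaks` | 2000 | shared peak regions (widths 0.8–3 kb, disjoint) |
| `chrom_lengths` | 12 + 8 Mb | toy genome carrying genes, islands, chromatin states |
| `frac_ptb_effect`, `frac_ga_effect`, `frac_both` | 0.05, 0.05, 0.02 | fractions of regions with planted effects |
| `lfc_ptb` | 1.5 | planted \|log2FC\| of the group effect, sign random per region |
| `slope_ga` | 0.08 | planted \|per-week log2 slope\|, sign random |
| `dispersion` | 0.1 | NB dispersion of the replicate-summed counts |
| `base_mean_range` | 100–2000 | baseline expected counts |
| `replicate_dropout` | 0.05 | chance a true peak is missing from one replicate's call set |

Counts are drawn once per region and individual at the summed level
and split multinomially into the three replicates, so the
replicate-summed matrix is *exactly* negative binomial — the model the
test assumes. (Independent NB draws per replicate were rejected:
summation would change the dispersion.) Size factors are drawn
log-uniform in [0.5, 2] to exercise normalization. GA effects are
planted centered at 33 weeks so baseline means stay inside
`base_mean_range`; this only re-parameterizes the intercept. GA is
sampled uniformly within the two group ranges with no additional
confounding beyond the structural one (preterm implies lower GA), which
intentionally reproduces the partial overlap between the two models'
results. The study reports no read depth or dispersion estimates, so
`dispersion` and `base_mean_range` are chosen for test power rather
than fitted realism.

What the generator does **not** emulate: GC and mappability biases,
correlated neighbouring peaks, peak-boundary jitter between replicates,
sample covariates (sex, preeclampsia — the original analysis does not
state whether it adjusted for any, and none are included), or sequence
content of any kind. Passing tests on synthetic data therefore
demonstrate correctness of the computation under the stated model, not
robustness to everything real MeDIP-seq data can do.

## Numerical choices and degenerate inputs

* IRLS runs to a $10^{-10}$ relative change in coefficients (at most
  100 iterations); non-convergence flags the record (its p-value
  becomes `NA`) instead of raising.
* All-zero count rows get `NA` statistics and are filtered.
* Dispersion is floored at $10^{-8}$; fitted means are capped at
  $10^{12}$ to keep weights finite.
* `independent_filter` on an empty table returns an empty result;
  `cohort_consensus` validates `min_overlap` against the number of
  individuals; BED readers report the offending line number.
* Nearest-gene ties break lexicographically; a DMR on a gene-free
  chromosome gets `NA`.

## Problem sizes

The shipped analysis scripts and the acceptance script run the full
pipeline at the generator's default scale (2000 regions, 9 samples,
3 replicates); the null-calibration check averages five such runs and
the test suite's FDR-control property uses twenty. These sizes give
stable Monte-Carlo estimates (the binomial standard error on a 5%
fraction at 2000 regions is about 0.5 percentage points) while keeping
a complete run in tens of seconds on one CPU.

## Known limitations

* Wald tests with nine samples rely on the normal approximation;
  p-values for weakly expressed regions are approximate.
* The dispersion trend $a_0 + a_1/\mu$ is cruder than parametric
  gamma-family fits; with few regions (< 10 informative) it falls back
  to the median raw dispersion.
* Replicate peak-call dropout is independent per peak and replicate —
  real replicate disagreement is structured.
* Exact reproduction of the deposited discovery counts (427/21 and
  667/67) would require the original raw data and bit-level parity
  with the reference package's internals, both out of scope; the
  shipped printed tables serve as fixtures instead.
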