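---
title: "Region-gene fusion features and the multimodal random forest: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-gene fusion features and the multimodal random forest: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfusion)
```

## The analysis in one paragraph

mrfusion implements a multimodal fusion analysis for two-group
classification (Alzheimer's disease patients, label $-1$, versus normal
controls, $+1$) from paired genotype and resting-state fMRI data. Genotype
calls pass four chip-QC filters and are grouped into genes; each gene's SNP
sequence is truncated to a common length $L$ and digitally encoded
($A\to1, T\to2, C\to3, G\to4$). Each of the $R$ atlas regions contributes a
mean BOLD time series whose first $L$ points are correlated (Pearson)
against each of the $G$ encoded gene sequences, giving a subjects
$\times (R \cdot G)$ *fusion-feature* matrix. A random-subspace ensemble of
CART trees — the *multimodal random forest* (MRF) — classifies subjects by
majority vote; the classification accuracy is
$C = \sum_i s_i / T$ over the $T$ test subjects with $s_i = 1$ for a correct
prediction. Feature selection counts how often each fusion feature occurs in
the random subsets of the individually best trees, scans nested prefixes of
that frequency ranking, and keeps the smallest prefix maximizing held-out
accuracy. Finally, region and gene frequencies inside the optimal subset
rank disease-associated brain regions and genes.

Because the cohort this design targets is access-restricted, the package
ships a seeded synthetic generator that emulates the study structure and
plants known region-gene couplings, so every stage can be validated against
ground truth.

## Quality control and encoding

The four filters run in a fixed order — subject call rate ($\ge 0.95$), SNP
genotyping rate ($\ge 0.999$), minor allele frequency ($\ge 0.04$), and the
Hardy-Weinberg exact test ($p \ge 10^{-4}$) — because the order matters: the
subject filter changes the cohort on which all per-SNP statistics are
computed. The order used here is the conventional one (samples before
variants). A subtlety worth recording: tightening a SNP-level threshold can
only shrink the surviving SNP set (the subject set is unchanged), but
tightening the *subject* threshold changes per-SNP call rates, MAF and HWE
counts downstream, so SNP-set nesting is not guaranteed in that direction.
The test suite asserts exactly the monotonicity that holds.

The Hardy-Weinberg test is the exact conditional test (the p-value sums the
probabilities of heterozygote counts no more probable than the observed one,
given the allele counts), computed from log-factorials. The chi-square
approximation is deliberately not used: at 72 subjects and MAFs near the 4%
threshold the expected homozygous-minor count is far below the usual
validity rule of thumb.

Gene groups keep strictly more than `min_snps = 30` SNPs — the boundary gene
with exactly 30 is dropped — and all retained genes are truncated to the
smallest group size $L$, taking each gene's *first* $L$ SNPs in genomic
position order. Truncation-from-the-start was chosen over windowing because
it is deterministic, reportable, and no positional information suggests any
better alignment.

Two gaps in the construction are policy decisions, not inferences:

* **Diploid to haploid.** Chips report two alleles per SNP, the encoding
  consumes one letter. The default `major_allele` policy keeps homozygous
  calls as-is and resolves heterozygotes to the cohort-major allele (ties
  broken alphabetically); `first_allele` and `seeded_random` are available.
  The default maximizes the stability of the encoded sequence across
  subjects, which is what lets a planted coupling survive encoding.
* **Missing after QC.** The encoding has no "missing" code, so calls that
  survive QC missing are imputed to the cohort-major allele and the
  imputation count is logged in the run manifest.

## Fusion features

Fusion feature $(r, g)$ of a subject is the Pearson correlation between the
first $L$ points of region $r$'s series and the encoded sequence of gene
$g$. Columns are ordered region-major (all genes of region 1, then region
2, ...) and the canonical feature identity is the string
`"<region>|<gene>"`. Correlating an ordinal nucleotide code with a BOLD
series is the framework's stated construction; the package implements it
verbatim and attaches no biological meaning to the coefficient itself — its
usefulness is purely discriminative.

Degenerate correlations (a zero-variance series or a constant encoded
sequence) are set to 0 with a warning instead of being dropped, so the
matrix always has exactly $R \cdot G$ columns (3,240 for the default
$90 \times 36$) and downstream bookkeeping never shifts.

## The multimodal random forest

Each of the $a$ trees draws (i) a bootstrap sample of the training subjects
(with replacement, full training size) and (ii) a random subset of $m$
features, drawn **once per tree** — a random-subspace ensemble, not a
per-node-mtry forest. This is the pinned reading of trees being "formed"
from $m$ randomly selected features, and it is also what makes the
frequency-based feature selection meaningful: a tree's feature subset is a
well-defined object to count over. The default
$m = \mathrm{round}(\sqrt{M})$ reproduces the reference value 57 at
$M = 3240$.

Trees are CART: greedy binary splits minimizing weighted Gini impurity over
midpoint thresholds, grown to purity (no depth cap, minimum leaf 1) unless
capped. All ties — leaf labels and exact vote ties — resolve to $-1$, the
patient class, deterministically; tie events are counted and logged.

The forest size is chosen by scanning 10, 20, ..., 600 trees (an empty
forest is undefined, so the scan starts at the step) with an independently
seeded forest per grid point, then detecting the accuracy plateau: the
chosen size is the smallest grid point from which every subsequent rolling
mean (window 5) stays within $\varepsilon = 0.02$ of the plateau mean (the
final window's mean). Isolated spikes above the plateau are treated as
random fluctuation, not optima. If the final window itself is not flat
(points further than $5\varepsilon$ from its mean) the curve has no plateau
and the grid maximum is returned with a warning; the wider point-level band
exists because single-grid-point accuracies move in steps of $1/T$, which
can exceed $\varepsilon$ at small test sizes.

## Feature selection and factor extraction

The 100 individually most accurate trees (ties at the cutoff broken by tree
index) are retained; tree accuracy is measured on the held-out test split of
the 6:4 partition — the natural reading of re-classifying the test set once
the forest is fixed (out-of-bag evaluation would be the alternative, and is
deliberately not the default so that selection uses exactly the reported
evaluation data). Feature frequency is the number of retained trees whose
subset contains the feature; the top 400 features are kept, ties broken by
canonical feature order so discoveries are reproducible. Nested subsets are
prefixes of this single global ranking (sizes 70, 75, ..., 400 give the 67
reference subsets); each subset is re-evaluated with a freshly trained
forest whose $m$ is recomputed as $\mathrm{round}(\sqrt{s})$ capped at the
subset size $s$ — a fixed $m = 57$ would exceed the smaller subsets. The
optimal subset is the smallest prefix attaining the maximum accuracy.

Factor extraction counts regions and genes inside the optimal subset; each
ranking's counts sum to the subset size by construction. The hypergeometric
overlap test reports $P(X \ge x)$ for the overlap of two fixed-size feature
sets drawn from a universe of $N$ features. $N$ is an explicit argument:
published overlap p-values of this kind cannot be reproduced without knowing
the universe their computation assumed, so the package refuses to guess.
The unimodal baseline is a Welch two-sample $t$ filter per feature (the
plain "t-test" is underspecified; the unequal-variance form is the safer
default at 37 + 35 subjects), with top-$k$ or $\alpha$-level selection and a
small-sample guard for zero-variance columns.

## The synthetic generator

The generator emulates the study conditions: 37 patients and 35 controls, 90
regions, 36 genes of 40-50 chip SNPs each, 140-timepoint series, true MAFs
uniform on $[0.1, 0.5]$, per-call missingness $10^{-3}$, unit noise.
Missingness and the MAF floor were set once so that genes of 40+ SNPs
survive the strict 99.9% genotyping filter with their >30-SNP retention
intact at 72 subjects — at this cohort size a single missing call already
fails a SNP — which mirrors how heavily the same filters prune real chip
data. Genotypes follow Hardy-Weinberg proportions; genes listed in
`hwe_violation_genes` get excess homozygosity with inbreeding coefficient
$F = 0.5$. At $n = 72$ the exact test then catches the *majority* of
violating SNPs (power depends on the MAF), and essentially all of them by
$n \approx 500$; per-SNP detection at 72 subjects is not certain and the
tests assert exactly that.

For each planted coupling $(r, g, e)$, patients' region-$r$ series has its
first $L$ points set to $e \cdot z_g + (1 - e) \cdot \mathcal{N}(0,
\sigma^2)$, where $z_g$ is the subject's standardized encoded gene-$g$
sequence *as the downstream pipeline will compute it* (same QC defaults,
same policy, same $L$) — at $e = 1$ the fusion feature is exactly 1 for
every patient, tying the generator to the fusion stage. Controls and
uncoupled regions are pure noise. When couplings share a region their
standardized codes superpose (noise weighted by $1 - \max e$): a literal
one-at-a-time assignment would overwrite earlier couplings and silently
delete their signal, while superposition reduces to the single-coupling
formula exactly and lets designs concentrate several gene couplings on one
region. Noise is i.i.d. Gaussian with no temporal autocorrelation: the
method only ever computes pointwise correlations against a non-temporal
code vector, so AR structure would add nothing the pipeline could detect.

What passing tests on this generator do **not** show: that real BOLD series
(autocorrelated, globally correlated across regions) or real LD structure
between SNPs behave the same way, nor that real effect sizes resemble the
planted ones — the effect sizes are chosen for testability, since no
empirical estimate of region-gene correlation effects is available.

One emergent property is worth knowing when reading factor rankings: the
encoded sequences of *all* genes share the cohort-major backbone, so a
planted region's series (an affine image of one gene's code) has a small
systematic correlation with *every* gene's code, identical in sign across
patients. Planted regions therefore accumulate frequency across many gene
pairings — convenient for region recovery, and a reminder that factor
counts measure association concentration, not per-pair effects.

## Numerical and reproducibility choices

* Every random stage (simulation, split, scan, training, subset evaluation)
  draws a named seed from the master seed; no stage reads global RNG state.
  Re-running a configuration reproduces every artifact byte-for-byte, and
  the run manifest (config hash, seeds, input digests, stage summaries,
  warnings) contains no timestamps so manifests of identical runs are
  byte-identical.
* Tables are TSV, UTF-8, Unix newlines, floats at 9 significant digits —
  enough to round-trip the analysis losslessly at reproducible file digests.
* Vote ties, leaf-label ties, frequency ties and tie-breaks at the top-$k$
  tree cutoff are all deterministic and logged.
* Problem sizes in the test suite are chosen for desk-scale runs: the
  recovery experiments use the full 72-subject, 3,240-feature geometry with
  a 600-tree selection forest. 600 (the top of the searched interval) rather
  than 350 is used there because frequency selection needs each feature's
  expected tree-membership count ($a \cdot m / M \approx 10.6$ at 600 trees)
  to clear the top-400 count cutoff of the noise features (about 3-4);
  at 350 trees the expected count (6.2) sits close enough to that cutoff
  that recovery of *all* planted features becomes a coin flip even at
  maximal signal — an intrinsic granularity limit of frequency-based
  selection worth stating explicitly. For the same reason the recovery
  experiments scan nested subsets from size 5: with only three informative
  features, count-based factor rankings inside a 70-feature subset are
  dominated by noise collisions among 90 regions and 36 genes.
* The nested-subset accuracy curve is computed from a single 6:4 split
  (repeat-split averaging is a flag away in the evaluation loop's seed
  handling but not the default), matching the single-split evaluation the
  procedure describes.

## Known limitations

* No LD pruning, strand harmonization or genotype imputation beyond
  major-allele fill; no VCF ingestion beyond PLINK-style text in this
  version.
* No per-node feature resampling mode, regression trees, or probability
  calibration.
* The comparison classifiers of the original study design (SVM variants,
  CCA/distance-correlation fusion) are out of scope; the t-test filter is
  the only baseline, evaluated with the MRF classifier.
* Published hypergeometric overlap p-values are not reproducible without
  the universe size; the test takes $N$ explicitly.
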