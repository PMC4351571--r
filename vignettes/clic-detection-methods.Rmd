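---
title: "Detecting 3D hotspots of recurrent insertions: models and methods"
author: "clichunter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 3D hotspots of recurrent insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clichunter)
```

# The problem

Retroviral insertional mutagenesis screens accumulate thousands of viral
integration sites across hundreds of independent tumours. Selection
concentrates the causal insertions near cancer genes, producing clusters
along the linear genome. Because viral long terminal repeats carry strong
enhancers that can act through chromatin loops, insertions that deregulate
one gene may be dispersed over several loci that are far apart on the
chromosome but adjacent in the nucleus. `clichunter` asks, for every pair
of insertion clusters on a chromosome, whether their mutual Hi-C contact
exceeds what bins at the same genomic distance show — and assembles the
significant pairs (CLICs) into a map of 3D insertion hotspots.

# Models and procedures

## Rank-based distance normalization

Contact counts decay roughly as a power law with genomic distance, and
their distribution at fixed distance is heavily skewed and varies with
distance, so z-score-style normalizations are poorly calibrated. We
therefore make no distributional assumption at all: within the vector of
all scores at bin distance $d$ (the $k$-th superdiagonal), each score is
replaced by its average-tie rank, divided by the pool size. The result
$\hat h_{ij} \in (0,1]$ is, by construction, invariant under any strictly
monotone transform of the raw scores, and approximately Uniform(0,1) at
every distance.

Long-range superdiagonals are short, so pools are extended to a target
length $L$ by appending *whole* neighbouring superdiagonals, alternating
$k-1, k+1, k-2, k+2, \dots$ until the pool holds at least $L$ scores.
Appending whole diagonals (rather than truncating at exactly $L$) avoids
an arbitrary rule for which elements to keep; ranks are divided by the
actual pool size so scores remain comparable across distances. $L$
defaults to twice the bin count of the longest chromosome in the run.
Two caveats follow from pooling under distance decay and are intentional:

* where a pool borrows asymmetrically (distance 1, and distances near the
  chromosome end), the head entries are biased away from 0.5 because their
  neighbours are systematically smaller or larger — the flatness property
  of the normalization therefore holds for distances whose pool is fully
  their own superdiagonal, and tests assert it there;
* zero counts are treated as observed zeros, not missing data; the
  diagonal ($d = 0$) carries an `NA` sentinel and is excluded everywhere.

## Compartments

The first principal component of the bin-by-bin correlation matrix of
$\hat h$ separates the two chromatin compartments. The eigenvector sign is
arbitrary, so the track is oriented to correlate positively with per-bin
total contact, a data-internal proxy for the open compartment; on
perfectly balanced synthetic plaids this proxy carries no information and
the orientation flag records that the sign is conventional. Compartment
*assignment* (the partition) is invariant to the sign, and tests compare
partitions, not signs. Bins with zero contact variance are masked.

## Insertion clusters

The insertion positions of a chromosome are convolved with a Gaussian
kernel, $f(x) = \sum_m e^{-(x - p_m)^2 / 2\sigma^2}$ with $2\sigma =$
80 kb, evaluated on a 10 kb grid ($\sigma/4$, fine enough that peak
positions are accurate at 40 kb bin resolution). No kernel-area
normalization is applied, so an isolated insertion has height exactly 1
and peak heights read as effective overlapping-insertion counts. Clusters
are strict local maxima of $f$; since the raw data define no natural
cluster boundary, we take the parameter-free choice of the flanking local
minima of $f$, aligned outward to bin boundaries. Clusters under 3 bins
are expanded one bin on each side so every cluster pair later yields at
least $3 \times 3 = 9$ contact scores. Clusters above the median peak
height over all detected clusters (strict inequality, as for every
threshold here) form the high-scoring set; the median is computed over
peaks, not over all of $f(x)$ (the grid is dominated by near-zero values
between clusters, which would make an all-of-$f$ median degenerate), and
a config switch exposes the alternative.

## The CLIC test

For high-scoring clusters $IC_i$ ($n$ bins) and $IC_j$ ($m$ bins) on one
chromosome, the positive distribution is the $n \times m$ block of
normalized scores between them. The negative distribution collects all
normalized scores at bin distances within $[d_{\min}, d_{\max}]$ (the
distance range spanned by the pair), excluding the positive entries
themselves so the null is not diluted by the signal being tested, and is
widened one distance at a time — alternating below $d_{\min}$ and above
$d_{\max}$, clipped at the chromosome — until it holds at least $L$
scores. A one-tailed Wilcoxon rank-sum test (exact by enumeration when
both samples have fewer than 10 tie-free values, the tie-corrected normal
approximation otherwise; the choice is recorded in the output) gives the
raw p-value. Holm's step-down over the whole family of tested pairs
controls the family-wise error rate; a pair is a CLIC when its adjusted
p-value is at or below $\alpha = 10^{-5}$ (the adjusted scale is used
because the family size is run-dependent). Pairs whose extents overlap
after expansion are not testable and are skipped with a count.

## Downstream statistics

* **Mutual exclusion.** For two loci, the Mean-Manhattan distance is the
  fraction of *all* samples whose two occupancy indicators disagree — the
  literal Mean-Manhattan distance between binary vectors. (A variant
  normalizing by samples hitting at least one locus is a reasonable
  alternative reading; the all-samples form is the default because it
  keeps the metric a true distance on occupancy vectors.) CLIC pairs are
  compared with non-significant pairs by a two-sided rank-sum test.
* **Enrichment.** All overlap questions (cluster loci vs gene sets,
  high- vs low-scoring interaction counts, TFBS carriers) reduce to one
  2 × 2 membership cross-classification tested with Fisher's exact test.
* **TFBS carriers.** A locus carries TF binding sites when its peak count
  per base pair (midpoint containment — the simplest unambiguous overlap
  rule) strictly exceeds the median density over all clusters.
* **Expression association.** $T^A$ is the Welch two-sample $t$-statistic
  (no equal-variance assumption, since group sizes and variances differ
  freely) for a gene's expression between samples with and without
  insertions in its own locus, signed so that positive means the inserted
  group is higher; $T^{AB}$ repeats this with the partner locus included
  in the grouping. When the partner locus is never inserted the groupings
  coincide and $T^{AB} = T^A$ exactly. The spatial association score
  $\mathrm{sign}(T^A)(T^{AB} - T^A)$ is positive when distal insertions
  amplify the local effect, whatever its direction; $T^A = 0$ is resolved
  as $|T^{AB}|$ with a zero-sign flag.

# The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, so planted signal is recoverable and null behaviour measurable:

* **Contact maps.** Expected contact $(|i-j|+1)^{-\gamma}$ with $\gamma=1$,
  times a same-compartment factor (default 3) on deterministic alternating
  1 Mb blocks, times unit-mean log-normal noise (sdlog 0.3). The
  multiplicative noise keeps matrices positive and exercises the rank
  normalization under heteroscedasticity; deterministic blocks give the
  compartment tests an exact ground truth.
* **Cohorts.** One synthetic chromosome per call (multi-chromosome runs
  derive seeds per chromosome); 100 samples with Poisson(1) background
  insertions placed uniformly — roughly the per-chromosome background of a
  ~20-insertions-per-tumour screen — plus four planted clusters of 40
  expected hits drawn without replacement, positions Gaussian around the
  cluster centre with sd = width/4. For a planted pair with exclusivity
  $e$, the overlap of the two hit-sample sets is the hypergeometric
  (independence) overlap thinned binomially by $1-e$: $e=0$ reproduces
  independence, $e=1$ perfect exclusion; the default 0.8 reflects the
  strong but imperfect exclusion patterns seen in real screens.
* **Planted contacts.** The contact block between the two loci of a pair
  is multiplied by a boost (default 5). The planted locus is the insertion
  interval padded by 160 kb — the 4σ skirt that the kernel smoother adds
  to a cluster's extent — so the boosted region matches the footprint the
  cluster caller will assign; without the pad the positive distribution is
  dominated by unboosted entries and no realistic boost is recoverable.
* **Expression.** Baseline 8 plus effect size × indicator(insertion in the
  gene's locus or its planted partner) plus Gaussian noise (sd 1), one
  gene per planted locus plus unaffected filler genes.

What the generator does *not* emulate: TADs and loop anchors, coverage and
mappability bias fields, cell-type mixtures, copy-number effects on
expression, and clustered background insertion preferences (real
integration favours transcription start sites). Passing tests therefore
demonstrate the statistical correctness and calibration of the machinery
on data satisfying its assumptions, not robustness to every artefact of
real Hi-C or expression data.

# Calibration choices in the validation suite

The end-to-end recovery and family-wise-error checks run the generator
without the plaid (contrast 1). This is deliberate: compartment structure
is itself genuine, biology-wide spatial co-localization, so same-
compartment cluster pairs are truly elevated against a distance-matched
null that mixes compartments — on plaid genomes the "false" positives are
not false. The analysis of real data addresses this with
compartment-restricted score subsets (supported via the `binSubset`
argument of `categoryPairScores()`); the recovery criteria isolate the
planted-pair signal instead. Problem sizes used by the test suite: 500-bin
chromosomes and 50 seeds for recovery, 200-bin chromosomes and 200 seeds
for the family-wise error rate at a testable level of 0.05, 100 cohorts
for mutual exclusion, 20 seeds for compartment recovery.

# Numerical and degenerate-input conventions

* All coordinates are 0-based half-open in files; bins are 1-based
  inclusive intervals in R objects (an insertion exactly at a bin width
  falls in the second bin).
* All threshold comparisons (peak height, category counts, carrier
  density) are strict.
* Fully tied rank-sum inputs return p = 1 (no evidence) rather than the
  NaN of the tie-corrected normal approximation.
* Flat densities yield no clusters; constant contact profiles are a
  degenerate-input error for the compartment step; zero-variance
  expression or undersized groups are errors for the $t$-scores.
* Bin categories: non-inserted ($S=0$), inserted ($0 < S \le N_m$, default
  $N_m = 2$), recurrently inserted ($S > N_r$, default $N_r = 5$); the gap
  $N_m < S \le N_r$ is deliberately unassigned and excluded from category
  tests.

# Known limitations

* Inter-chromosomal contacts are out of scope; CLICs are intra-chromosomal.
* The pipeline assumes bias-corrected contact maps; no iterative or
  probabilistic bias correction is performed.
* Whether ranking should use exactly-L truncated pools rather than
  whole-superdiagonal pools is undecidable from first principles; the
  whole-superdiagonal contract is used and is the natural target for a
  sensitivity analysis.
* Control pair sets for mutual exclusion and enrichment are not matched on
  genomic distance; distance matching is a worthwhile extension for real
  data where distance correlates with co-occupancy.

```{r example}
cfg <- simulationConfig(seed = 1, compartmentContrast = 1)
st <- simulateStudy(cfg)
bundle <- runPipeline(st$insertions, st$map, seed = 1)
unlist(bundle$manifest$counts)
subset(bundle$clics, significant,
       c(startBpA, endBpA, startBpB, endBpB, nPos, pHolm))
```
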