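---
title: "Models and methods behind srnaplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnaplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaplast)
```

# The analysis problem

Plants can transmit the imprint of a parental stress, such as leaf wounding,
to their offspring. One candidate channel is small non-coding RNA: 24-nt
siRNAs direct DNA methylation (RdDM), are stress-responsive and can move
between tissues, so a wound-induced shift in siRNA populations could in
principle seed heritable methylation changes. `srnaplast` implements a
complete desk-scale analysis of this hypothesis for a wounding experiment in
*Mimulus guttatus*-style designs: 34 small-RNA libraries covering the wounded
second leaf pair at 1 h and 72 h, the unwounded third leaf pair at 72 h, and
second-leaf samples from selfed offspring of wounded and control plants
(two siblings from each of four maternal lines per treatment).

The pipeline has four analysis stages — locus calling, classification,
differential-abundance screening and association modelling — plus a
synthetic-data generator that reproduces the statistical structure of the
study so that every stage can be exercised and validated without any
sequencing data.

# Locus calling

Reads from all libraries are pooled and merged into coverage islands: two
reads belong to the same locus when the gap between them is at most `pad`
nucleotides (transitively), and islands with total read weight below
`min_reads` are dropped. Defaults are `pad = 75` and `min_reads = 5`; the
upstream literature delegates cluster definition to ShortStack without
printing its parameters, so both are exposed, logged in the run report, and
not treated as sacred. Locus ids are `chrom:start-end` strings, so a rerun on
the same input is bit-identical. Per-sample counts are then accumulated
against the fixed locus set, which is how a single locus universe is shared
by all 34 libraries.

All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
convention is converted exactly once at I/O. Strand is carried but ignored
in overlap and distance computations; only tRF side-calling consults it.

# Classification

A locus's read-length profile (15–35 nt) determines its class:

* **miRNA** — flagged by upstream annotation. De-novo miRNA identification
  (hairpin criteria) is out of scope, so the flag is an input.
* **siRNA20 … siRNA24** — "dicer-derived": at least 80% of read weight at
  20–24 nt. The size call is the modal dicer length; ties break toward the
  longer length, i.e. toward the 24-nt RdDM class. The boundary case of
  exactly 0.8 is classified siRNA (a closed boundary had to be chosen; it is
  documented and tested).
* **ndsRNA** — everything else ("non-dicer").

Analysis strata pool the dicer sizes as {miRNA, siRNA20–23, siRNA24, ndsRNA};
per-size rows are kept for the class summary table.

Context annotation records CDS and TE overlap (any shared base) and the
distance class to the nearest protein-coding gene: O (overlapping,
edge-to-edge distance 0), N (within 5 kb) and F (beyond 5 kb). "Within 5 kb"
is an edge-to-edge gap, matching the interval semantics of "overlapping",
not a midpoint distance.

tRNA-derived fragments (tRFs) are classified per locus by where their reads
sit relative to the tRNA anticodon: entirely 5′ of the anticodon interval,
entirely 3′ of it, or spanning it. Orientation follows the tRNA's strand (on
the minus strand the genomic end of the gene is its 5′ end). The locus-level
call is a read-weight majority vote with ties going to `anticodon_spanning`;
whether side-calling should be per read or per locus is genuinely open, and
the majority vote is the rule adopted here.

# Differential abundance

Loci passing a global mean-RPM filter (RPM ≥ 2 across all samples, boundary
inclusive) are screened for a treatment effect per contrast with a
negative-binomial GLM likelihood-ratio test, written in the package
(iteratively reweighted least squares, log link, log size-factor offsets,
at most 100 iterations, relative log-likelihood tolerance 1e-8, no
pseudocounts — the NB handles zeros natively). The statistic is
\(2(\ell_{full}-\ell_{reduced})\) against \(\chi^2_1\); the reported LFC is
the maximum-likelihood \(\log_2\) fold change (no shrinkage). Size factors
are median-of-ratios. Four contrasts are run — parent 1 h and 72 h second
leaf, parent 72 h third leaf, and offspring second leaf — each stratified
into the four classes, with Benjamini–Hochberg adjustment within each
stratum, because the mean-variance relationships differ strongly between
strata.

**Dispersion.** Each stratum gets per-locus method-of-moments estimates on
normalized counts, floored near zero, shrunk toward a trend formed by the
mean estimate within 20 equal-occupancy baseMean bins. The shrinkage weight
on the per-locus estimate is 0.3: at three samples per group the per-locus
estimate has only four residual degrees of freedom, and because the LRT's
rejection probability is convex in the dispersion error, weaker shrinkage
makes the test anticonservative (empirically ~6.2–6.4% at nominal 5% with
weight 0.5, versus 5.2–5.5% with weight 0.3 in the null calibration
simulations shipped with the package). The weight is an exposed argument.

**Offspring design.** The offspring contrast adds maternal-line terms
sum-coded within each treatment level to both the full and the reduced
model, so the LRT still tests treatment with 1 df while sibling
non-independence is absorbed by line means. This mirrors the fixed-effect
nested-design idiom of NB GLM tools; it is not a random-effects denominator,
so when true between-line variance is large the treatment test leans on the
dispersion estimate (which, being computed within treatment groups,
partially absorbs line variance). The calibration guarantee stated below is
for the 3-vs-3 parent design.

# Association models

All association fits go through base R's `lm`/`glm`/`aov`/`chisq.test`
(no continuity correction) and `car::Anova`; the package fixes encodings
and wraps results uniformly:

* Pearson correlations of per-locus LFCs between contrasts, with
  \(t = r\sqrt{n-2}/\sqrt{1-r^2}\), and a one-sample *t* (raw-vector and
  summary-statistic forms) for directional shifts such as the tRF
  parent-to-offspring reversal.
* OLS of offspring LFC on the two parental LFCs (second and third leaf),
  with rank-deficiency reported as an error rather than silently dropped.
* Logistic regression of DMR overlap on log locus length, distance class
  and dicer/non-dicer class, each term tested by a likelihood-ratio
  chi-square (single-term deletion); complete separation is flagged.
* A 3×2 contingency chi-square of DMR methylation direction (up/down in
  progeny of wounded plants) against overlap group (none/siRNA/ndsRNA),
  with per-group up-proportions.
* For loci within 20 kb of a DMR, a linear model of LFC on the direction of
  the **nearest** DMR (the choice among multiple qualifying DMRs is not
  specified upstream; nearest is the rule adopted), F-tested, per class and
  contrast.
* A 2×2 chi-square of gene DE status against sRNA-locus proximity (within
  5 kb), with rates and the exact odds ratio; and a logistic model of DE
  direction on log mean expression and overlap class, with non-DE genes
  excluded from the direction model (their direction coding is undefined).
* A factorial OLS of sRNA LFC on mRNA transgenerational change
  (up/none/down), locus type (siRNA/ndsRNA) and their interaction, fitted
  separately for gene-overlapping and near (<5 kb, non-overlapping)
  locus–gene pairs, reported with partial (Type-II) sums of squares —
  the upstream software and SS type are unnamed, so Type II is the default
  and sequential SS is available via `ss_type = "I"`.
* Hypergeometric enrichment of an annotation among loci in a chosen LFC
  tail (default upper 5%); this is a surrogate formulation for
  outlier-enrichment recipes used in related work and is labelled as such.
* One-way ANOVAs of expression/length over the seven class labels and of
  expression/methylation over gene-context categories.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions, chosen once:

* Class mix and per-class mean lengths and mean log10(rpm) follow the
  reference class-summary table (44 miRNA / 26,052 siRNA dominated by the
  24-nt class / 3,775 nd-sRNA out of 29,884 loci; nd-sRNA longest at
  774 bp mean; miRNA most expressed at log10 rpm 1.4). Lengths are
  lognormal (sdlog 0.6, floored at 40 bp); expression is normal on the
  log10 rpm scale (sd 0.45). With a 5-million-read library this yields
  roughly half the loci passing the RPM ≥ 2 filter, matching the shape of
  the real screen.
* Geometry is slot-based: each locus owns a 30 kb slot containing its
  companion gene (placed to realize an exact planted O/N/F context), a TE
  overlap drawn at the class rate (0.90 for 24-nt siRNA), and — for tRF
  loci — a 75 bp tRNA gene with a 3 bp anticodon interval drawn from a
  12-isoacceptor catalogue that includes Leu-CAA, Gly-CCC and Ala-GGC.
  The slot construction guarantees that each locus's nearest gene is its
  own slot's gene, so planted context classes are exact.
* Wound responses are concentrated in nd-sRNA loci at the 72 h wounded
  leaf (responsive fraction 377/3775, sign mix 328 up / 49 down, magnitude
  N(1.6, 0.5) on the log2 scale); the 1 h response is a correlated subset
  (retention 53/377, slope 0.8). The third leaf gets no planted response.
  Offspring LFCs are constructed to realize a parent–offspring correlation
  of −0.2 within nd-sRNA loci (offspring sd 0.3). Maternal lines
  contribute lognormal random effects with sd 0.2 on the natural-log
  scale — the magnitude is not reported upstream; 0.2 is a moderate
  between-family effect chosen once.
* Counts are NB with dispersion 0.1 (0 gives Poisson); library sizes are
  lognormal around the target with CV 0.15.
* DMRs (3,731 by default) are assigned an overlap group with probabilities
  (none 0.55, siRNA 0.30, ndsRNA 0.15) and placed accordingly; direction
  is drawn with up-probabilities 0.659 / 0.418 / 0.488 for
  siRNA / ndsRNA / none. DEG status is drawn at 13.2% for genes within
  5 kb of an sRNA locus versus 8.4% otherwise, with direction following a
  logistic model in log expression (slope −0.7) and overlap class.
* Per-read simulation (used by the `tiny` profile) allocates each
  library's reads multinomially over loci, draws lengths from
  class-conditional distributions placed well off the 0.8 dicer boundary
  (siRNA classes: 0.85 of mass at the class length, 0.95 within 20–24 nt;
  nd-sRNA: broad with dicer mass 0.4), and places tRF reads strictly on
  the planted side of the anticodon.

Two profiles are provided: `tiny` (200 loci, 20,000 reads per library,
seconds end-to-end, includes BED-level reads) and `paper-shaped` (the
full-size locus universe with counts simulated at the locus level;
per-read simulation at 5 million reads per library would be pointlessly
heavy and is skipped, a deliberate design choice). Everything is
deterministic given the seed.

**What the generator does not emulate:** sequence content (no hairpins, no
tRNA cloverleafs), multi-mapping ambiguity, positional autocorrelation of
loci along chromosomes, dispersion trends that vary with expression, or
batch structure. Passing tests therefore demonstrate correctness of the
statistical machinery under the planted model, not robustness to every
artefact of real sRNA-seq data.

# Numerical choices and degenerate inputs

* IRLS linear predictors are clipped to ±30 to keep all-zero loci finite;
  non-converged fits are flagged and report `p = NA`.
* The LRT statistic is floored at 0 (tiny negative values can arise at the
  convergence tolerance).
* The BH step is `stats::p.adjust`, applied within a stratum.
* Chi-squares use no continuity correction (matching the hand formula
  \(\sum (O-E)^2/E\) exactly).
* Degenerate association inputs (all-identical responses, single factor
  levels, collinear predictors) return flagged results or errors, never
  silently wrong numbers.
* The DMR table dialect is declared 0-based half-open; upstream sources do
  not state their convention, so it is fixed by documentation here.
* The RPM ≥ 2 filter is applied globally (once, across all samples), not
  per contrast; the ratio of filtered to called loci in the full-size
  synthetic profile matches the global reading.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
null calibration uses 10,000 loci at 3 vs 3; planted-LFC recovery 500 loci;
the correlation recovery 2,000 nd-sRNA loci; oracle equivalence uses
brute-force union-find, all-pairs scans, a textbook BH implementation,
10,000-draw permutation nulls and exhaustive hypergeometric enumeration at
n ≤ 30; association power and null-uniformity checks use 100–600 replicates
at full-size DMR/locus counts. These sizes give Monte-Carlo error well
inside the asserted tolerances while keeping a complete run to a few
minutes.

# Known limitations

* The NB LRT is a plug-in test: dispersion is estimated, not profiled, so
  calibration guarantees are empirical (and stated for the 3-vs-3 design).
* The nested maternal-line adjustment is a fixed-effect device; it does
  not provide a line-level error stratum, exactly as in the standard NB
  GLM tools it mirrors.
* miRNA identification, target prediction, GO/domain enrichment,
  methylation calling and mRNA DE calling are inputs, not computations —
  the package consumes their tables.
* Exact reproduction of any particular experiment's locus counts would
  require its sequencing data; the synthetic profiles reproduce
  distributions and planted effect structure, not dataset-specific values.
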