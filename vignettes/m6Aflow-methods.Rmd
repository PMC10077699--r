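---
title: "m6Aflow: models and methods"
author: "m6Aflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6Aflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Aflow)
```

# Scope

m6Aflow implements the computational analysis of a two-group MeRIP-seq
(m6A-seq) study of a quantitative trait — modelled on a porcine
intramuscular-fat (IMF) design with High and Low phenotype groups of ten
animals each.  The pipeline covers reference peak-panel construction,
normalized-depth m6A quantification, differential methylation and
expression, transcript-region and motif characterization, weighted
co-expression network analysis with hub-gene screening, and integration
of differential methylation with differential expression.  A
synthetic-data generator with a complete planted-truth manifest makes
every stage testable without sequencing data.

Upstream sequencing steps (QC, trimming, alignment, MACS2 peak calling)
are out of scope: peak calls, count tables and transcript models are
inputs.

# The methylation statistic

For each reference peak $p$ and sample $s$, with $\mathrm{SRN}$ the
summed read depth of the peak region (`samtools bedcov` semantics: the
sum over peak bases of per-base coverage) and $\mathrm{ITR}$ the
library's total reads, the per-peak methylation level is the normalized
depth

$$
d_{ps} \;=\;
\frac{\mathrm{SRN}^{IP}_{ps}/\mathrm{ITR}^{IP}_s \;-\;
      \mathrm{SRN}^{input}_{ps}/\mathrm{ITR}^{input}_s}
     {\mathrm{length}(p)} .
$$

It can be negative when the input fraction exceeds the IP fraction.  The
gene-level comparisons use the plain normalized read count
$\mathrm{SRN}/\mathrm{ITR}$, applied identically to IP and input tracks.

The phrase "reads of Peak Region" admits two readings — an overlapping
read count or a base-depth sum.  The base-depth sum matches the stated
counting tool and is the default (`count_mode: basedepth`); a
read-count alternative is accepted at the interface since both arrive as
per-peak count tables.

## Differential methylation

Each peak is tested by a two-sided two-sample t-test comparing its
normalized depths between High and Low.  The default is the Welch test
(the default of `t.test` in R); a pooled-variance Student variant is one
switch away (`welch = FALSE`) and both are exercised in the tests.  The
fold change is $\log_2(\bar d_{High}/\bar d_{Low})$, oriented High/Low.
Because depths can be negative, group means are floored at zero and
offset by a pseudo-depth $\varepsilon = 10^{-9}$; peaks with both means
non-positive get a zero fold change and are never significant.  This
offset policy is a package decision (configurable); the source analysis
is silent on the case.  Significance requires raw $P < 0.05$ and
$|\log_2 FC| > \log_2 1.5$; no multiple-testing correction is applied by
default, matching the original thresholds, with a Benjamini–Hochberg
option off by default.  Genes are called differentially methylated when
at least one peak is significant; the reported gene-level statistics are
those of the minimum-p peak (a package choice — any-significant and
min-p flagging coincide, only the representative statistic was open).

Under the null (no planted effect, ~2000 peaks, 10 samples per group)
the empirical type-I error of this test sits inside the exact binomial
99% interval around 0.05; at a planted two-unit log2 effect its
sensitivity exceeds 0.8.  Both are recomputed by the test suite and the
acceptance script.

# Expression analysis

Genes with fewer than 10 counts in fewer than 4 samples are filtered
(the Methods-stated rule; the Results of the source study quote an
alternative "at least 16 individuals" variant, reachable via
`min_samples` — the two are contradictory in the source and the Methods
version is the default).  TPM normalization divides counts by gene
length in kb and rescales columns to $10^6$.  Size factors use the
median-of-ratios estimator over zero-free genes, rescaled to geometric
mean one, with a library-size fallback.

Differential expression deliberately uses a simple, transparent engine:
log2 fold changes of normalized group means (pseudocount 1) and a
two-sided t-test on $\log_2(\text{normalized}+1)$, at the same
thresholds as the methylation test.  The negative-binomial GLM machinery
of dedicated DE packages is not re-implemented, and this engine is not a
claim to equivalence with them: the analysis contract here is the
thresholds, and the test suite validates size and power against the
generator's planted truth.

Sample screening mirrors the original PCA-based outlier exclusion, made
explicit: PCA on centred $\log_2(\text{normalized}+1)$, and a sample is
flagged when its Euclidean distance from the PC1–PC2 score centroid
exceeds the median plus three MADs.  The original exclusion (one sample
of twenty) was by visual inspection; the MAD rule is our
operationalization, and the threshold `k = 3` is conventional for
robust outlier flags.

# Transcript regions, metagene and motif

Transcript models are read from GTF (1-based closed, converted at the
boundary to the package's internal GRanges convention; BED I/O converts
its 0-based half-open coordinates likewise).  Each transcript is
segmented strand-awarely into 5'UTR, CDS and 3'UTR in mature-transcript
coordinates; segmentation tiles the mature transcript exactly.  Peaks
are assigned the region of maximal overlap across the longest transcript
per gene, with ties broken 3'UTR > 5'UTR > CDS — the 3'UTR-first
priority reflects where m6A peaks concentrate.

The metagene profile maps each peak midpoint (midpoints, not full peak
widths, keep the construction simple and exactly invertible for
testing) into its region, rescales the position within the region to
$[0,1]$, and histograms the result on a three-segment axis with 30 bins
per region and unit total area.  Region widths on the axis are fixed and
equal; the source figure's axis scaling is unspecified.

The m6A consensus RRACH (R ∈ {A,G}, H ∈ {A,C,U}) is scanned on the
coding strand with overlapping matches; U maps to T and N never matches.
Motif enrichment compares the observed RRACH density (hits per
nucleotide) of peak sequences with its distribution over
dinucleotide-preserving shuffles (random Eulerian-path construction on
the dinucleotide transition graph), reporting an empirical p-value
$(1 + \#\{null \ge obs\})/(1 + n_{shuffles})$.  De novo motif discovery
is out of scope.  Note that shuffling a sequence that is almost entirely
motif regenerates much of its motif content — dinucleotide-preserving
nulls are conservative for such inputs, so the fold is a better-behaved
summary on realistic sequence than on degenerate repeats.

# Weighted co-expression network

The network follows the WGCNA model on genes × samples log2 TPM:

* **Soft threshold.**  For each candidate power $\beta \in 1..20$, the
  unsigned adjacency $a_{ij} = |cor(x_i, x_j)|^\beta$ gives
  connectivities $k_i = \sum_{j \ne i} a_{ij}$; $\log_{10} k$ is binned
  into 10 equal-count bins and $\log_{10} p(k)$ regressed on
  $\log_{10} \bar k$.  The signed fit index is
  $-\mathrm{sign}(slope)\, R^2$, and the chosen $\beta$ is the smallest
  candidate reaching 0.85, else the maximizer.  The unsigned network
  and the 0.85 threshold are the conventional defaults; the source
  states neither.
* **Topological overlap.**
  $TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i, k_j) + 1 -
  a_{ij})$, unit diagonal.  Validated against a triple-loop oracle.
* **Modules.**  Average-linkage hierarchical clustering of $1 - TOM$
  with a static cut at 0.995 of the dendrogram height; clusters smaller
  than 30 genes become label 0 ("grey").  The dynamic hybrid tree cut
  is intentionally not re-implemented: module identity in the
  planted-truth setting is driven by the block structure, which the
  static cut recovers.  No module merging is performed.
* **Eigengenes.**  First principal component across samples of the
  per-gene standardized module submatrix, unit norm, oriented positively
  with the module's mean standardized expression.
* **Module–trait statistics.**  Pearson correlation with two-sided
  p-values from $t = r\sqrt{(n-2)/(1-r^2)}$.
* **MM and GS.**  Module membership is the correlation of a gene with
  its own module's eigengene; gene significance is the absolute
  correlation of the gene with the trait (the absolute convention
  follows the hub-table definition of the source; its scatter plots may
  show signed values).  Hub genes satisfy $|MM| > 0.8$ and $GS > 0.2$
  and are reported sorted by decreasing GS.

The screening rule applied to the published 12-gene module table
(`ldmHubCandidates()`) reproduces all 12 hubs with ADIPOQ first by GS —
the package's worked example.

# Integration and enrichment

Co-differential genes are the intersection of the significant
differential-methylation and differential-expression sets, classified
into hyper/hypo × up/down quadrants by fold-change signs; zero fold
changes are excluded from quadrants and reported.  Over-representation
uses the upper-tail hypergeometric test per gene set against the
post-filter expressed universe (a package choice; a genome-wide universe
would overstate enrichment), with Holm's step-down correction — the
standard reading of "Bonferroni step down" — at $\alpha = 0.05$; plain
Bonferroni is available.  Term-network clustering of enrichment tools is
out of scope; terms are reported flat.

# The synthetic study generator

The generator emulates the study design with every effect planted and
recorded, so each stage has scoreable truth:

* **Design.**  Two groups of 10 samples; 2,000 genes by default, one
  single-exon transcript each (5'UTR 100–300 nt, CDS 300–900, 3'UTR
  200–600, both strands, five chromosomes).  These desk-scale sizes are
  package choices; the original transcriptome-scale counts are not
  reproducible without the sequencing data.
* **m6A sites.**  Half the genes carry one planted 100-nt peak whose
  midpoint falls, with probability 0.8, within ±50 nt of the stop codon
  (matching the canonical stop-codon concentration of m6A), else
  uniformly; an RRACH pentamer is written at every midpoint.  A quarter
  of planted peaks receive a ±2 log2 group effect on IP enrichment
  (baseline enrichment 3–6×).  Per-group peak calls jitter the planted
  intervals by ±10 nt and add 10% false-positive peaks, so that merging
  and Venn logic are exercised.
* **Counts.**  Negative binomial with variance $\mu + \mu^2\phi$,
  $\phi = 0.05$ (typical for outbred animal cohorts), library sizes
  $2\times10^6 \pm 15\%$; input means proportional to gene expression
  and library size, IP means additionally scaled by enrichment and the
  group effect.
* **Expression modules and traits.**  Four modules of 50 genes share
  per-module latent factors; loadings are 0.75–0.9 for module genes and
  0.92–0.99 for a designated hub subset (hub truth = loading > 0.9).
  The factors are orthogonalized in-sample against the intercept, the
  group indicator and each other, and the trait noise is residualized
  against the factor and the group indicator: with $n = 20$, raw draws
  let chance correlations (factor–factor, factor–group, trait–group)
  confound the planted axes — in particular, the planted
  differentially-expressed genes form a coherent cluster whose
  eigengene is the group indicator, which could merge with or
  out-correlate the trait module.  Orthogonalization makes each planted
  effect identifiable and realized at its nominal size, which is what
  the recovery tests quantify.  Trait 1 (IMF %) has correlation +0.62
  with the first module's factor; trait 2 (m6A/A ratio) −0.51,
  mirroring the opposite IMF/m6A trends of the source study.  Ten
  percent of genes get a ±2 log2 expression shift between groups.
* **Determinism.**  One integer seed fixes every output byte.

What the generator does *not* emulate: read-level sequencing noise and
alignment artifacts, fragment-size effects, antibody efficiency,
isoforms and alternative UTRs, correlated gene-gene noise outside
modules, batch effects, and the entanglement of trait, group and
expression axes present in a real extreme-phenotype design (deliberately
removed for identifiability, see above).  Passing recovery tests
therefore demonstrates correctness of the implementations under the
stated model, not performance on real libraries.

# Numerical choices and degenerate inputs

* Internal coordinates are 1-based closed GRanges; BED (0-based
  half-open) and GTF (1-based closed) convert at the boundary —
  one internal convention avoids off-by-one drift.
* t-tests with zero variance in both groups: $t = 0, p = 1$ on equal
  means, else $p = 0$ with the sign of the difference.
* Fold change pseudo-depth $\varepsilon = 10^{-9}$; expression
  pseudocount 1.
* Eigengene sign: positive correlation with module mean expression;
  module labels ordered by decreasing size; assignment ties broken by
  the fixed region priority.
* Constant genes are dropped with a warning in the soft-threshold scan
  and rejected in adjacency construction.
* Size factors fall back to library sizes (with a warning) when no
  zero-free gene exists.

# Problem sizes

The shipped tests and the acceptance script run the generator at its
default scale (2,000 genes, 20 samples, ~1,200 panel peaks) and at a
4,000-gene variant for the null calibration of the methylation test;
network recovery is averaged over ten seeds.  These sizes were chosen so
the full evidence base recomputes in a few minutes on a single core
while keeping every estimate's Monte-Carlo error well inside the
asserted tolerances.

# Known limitations

* The static tree cut occasionally splits a planted module or leaves
  near-threshold genes grey; recovery is asserted on seed averages, and
  single-seed dips below the average are expected behaviour, as they
  are for any clustering heuristic at $n = 20$.
* The DE engine's t-test on log counts is anticonservative for very low
  counts; the default expression filter removes that regime.
* The hypergeometric universe should be the expressed-gene set of the
  same analysis; passing a mismatched universe is rejected only when
  query genes fall outside it.
* Headline counts of the source study (23,250 panel peaks; 1,085 DM
  genes; 422 DE genes; 70 co-differential genes; 33 modules; β = 7)
  depend on its unavailable libraries and are not targets of this
  package's checks.
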