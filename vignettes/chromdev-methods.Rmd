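---
title: "Models and methods behind chromdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdev)
```

`chromdev` analyses three data types produced when a fungal developmental
mutant is profiled against its wild type: an RNA-seq count table, MNase-seq
fragment intervals, and a per-cytosine bisulfite report. This vignette
explains the models each analysis assumes, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the field leaves a choice open.

## Coordinates and annotation

All internal coordinates are 0-based half-open; conversion to the 1-based
conventions of GFF3 and cytosine reports happens only in the readers and
writers, so interval lengths are preserved exactly and there is a single
place where off-by-one errors could live. The TSS of a gene is its `start`
on the plus strand and `end - 1` on the minus strand.

`assign_feature_classes()` derives three feature classes from an
annotation: the gene body (the full primary-transcript span, introns and
UTRs included — no exon-level resolution), a 500 bp upstream window, and
annotated repeats. Upstream windows are strand-aware: they sit on the TSS
side of the gene and are truncated at contig edges rather than dropped.
Whether upstream windows in comparable published analyses were computed
strand-aware is usually not stated; strand-aware is the biologically
meaningful reading of "upstream", and `stranded = FALSE` restores the
naive convention. Overlapping features all retain their memberships — a
cytosine inside both a gene and a repeat counts toward both — because the
downstream boxplots treat each feature instance as one observation, with
no precedence hierarchy.

## Expression analysis

RPKM is `1e9 * count / (gene_length * library_size)` with the library size
the per-sample column sum; it is invariant to rescaling a sample's counts.
Size factors use the median-of-ratios construction over genes with nonzero
counts in every sample. Fold changes are ratios of group means of
normalized counts with a pseudocount of 0.5 added to both means: large
enough to keep zero-count genes finite, small enough to leave genes with
more than a handful of reads essentially untouched; it is a documented,
configurable choice. Differential-expression testing (dispersion
estimation, Wald tests, adjusted p-values) is deliberately out of scope —
the class-stratified fold-change distributions are computed over all
genes, with a `gene_subset` argument for restricting to an externally
supplied significant-gene list.

Expression classes use strict inequalities on mean wild-type RPKM: below 1
is "low", above 5 is "high", boundary values fall in "neither". Quartiles
(here and everywhere boxplot summaries appear) use linear interpolation
between order statistics (`quantile()` type 7), with 1.5 × IQR whiskers.
Sample clustering computes Spearman correlation (average ranks on ties) of
log2 RPKM over genes measured in every sample and clusters on the distance
`1 - rho` with average linkage; samples are sorted lexicographically before
clustering so leaf order is deterministic.

## Nucleosome analysis

Occupancy is represented two ways, for two jobs. Footprint coverage — the
number of fragments overlapping each base — is what "nucleosome occupancy"
means in TSS metaplots. Midpoint density — fragment midpoints, smoothed
with a Gaussian kernel (sd 20 bp, truncated at ±4 sd, reflective
boundaries so mass is conserved) — localizes dyads for calling.

The caller is a deliberately simple positioning heuristic, not a
reimplementation of any published caller's wavelet or shape machinery:
dyads are local maxima of the smoothed density at or above `min_height`
(default a quarter of the track mean over its nonzero region, so sparse
contigs do not flood the call set). Two maxima closer than 110 bp cannot
be two complete nucleosomes (a footprint is ~147 bp) and are merged into a
`MainPeak:doublet` at their height-weighted center; a secondary maximum
75–150 bp from a taller `MainPeak` with relative height in [0.4, 0.8)
becomes a `Shoulder` and promotes its partner to `MainPeak+Shoulder`.
Downstream statistics consume only dyad positions and these labels, so the
heuristic's job is positional recovery, which the tests quantify (≥90% of
true dyads matched within 20 bp at 10 bp jitter and 30
fragments/nucleosome). All thresholds are arguments.

Adjacent-dyad distances are binned at 5 bp with bins centered on multiples
of the bin width (bin *k* covers `[5k - 2.5, 5k + 2.5)`), so integer
repeat lengths are representable as bin centers; the histogram mode, ties
broken toward the smaller distance, estimates the nucleosome repeat length
(footprint + typical linker; 147 + 33 = 180 bp at the defaults). Distances
never cross contigs, and the `mainpeak` filter drops other categories
*before* pairing.

TSS metaplots extract a ±1000 bp window (10 bp bins; the window is an
explicit argument since published figures rarely state theirs), flip
minus-strand genes so downstream is to the right, rescale each gene's
window to maximum 1 — removing per-gene coverage differences before
averaging — and average within expression classes. Genes whose window
leaves the contig or contains no signal are excluded and counted in
attributes, a documented choice rather than silently averaging zeros. NDR
metrics locate the upstream minimum of a class-average profile and measure
the contiguous span around it that stays below half (configurable) of the
upstream-flank maximum.

## Methylation analysis

The conversion rate is estimated by pooling all reads over the control
contig: `100 * sum(unmeth) / sum(meth + unmeth)`. This micro-average
weights cytosines by coverage, which matches how the estimate is then used
(a per-read error probability); a per-cytosine macro-average would weight
a coverage-1 site equally with a coverage-100 site.

A covered cytosine is called methylated when its methylated-read fraction
is at least 5% — inclusive, per "at least" — with a coverage floor of 1 by
default (no coverage filter beyond being observed). The floor is
configurable because the 5% rule is noisy at low coverage: at coverage 20
a single methylated read (5%) triggers the call, so the per-feature
percentages below are percentages of *called* cytosines, not mean
methylation levels. All contexts (CpG/CHG/CHH) are aggregated by default
with an optional context filter.

Per-feature methylation is `100 * n_methylated / n_covered` over the
covered cytosines inside the feature, both strands counted independently.
The covered-cytosine denominator is the only one estimable from count data
(the total cytosine content of a feature is not present in a report
restricted to covered sites); features with no covered cytosine are
excluded and counted. Genotype comparison applies a two-sample Student's
t-test per feature class — pooled-variance by default, Welch as an option,
since published "Student's t-test" statements rarely say which — using
textbook formulas so the degenerate zero-variance case can return a
flagged `p = 0` (different means) or `p = 1` (equal means) instead of
erroring; the implementation is tested against `stats::t.test()` on random
inputs.

## The synthetic-data generator

The generator exists so that every downstream stage has data with the
statistical structure the analyses assume, plus ground truth for recovery
tests. One root seed drives deterministic per-generator substreams, so
regenerating one data type never perturbs another's draws.

* **Genome**: 4 nuclear contigs of 2 Mb with 2000 non-overlapping genes
  (length ~N(1500, 300) bp, intergenic gaps 600–1800 bp, always ≥ the
  500 bp upstream window), 200 repeats of 1 kb placed in a dedicated tail
  region of each contig, and a 100 kb unmethylated control contig — a
  mitochondrial-genome-sized stand-in carrying no genes or repeats.
* **Counts**: per-gene baseline means log-uniform over [2, 5e4] (library
  sizes ~1e7, typical for RNA-seq), negative-binomial with dispersion
  0.05; the mutant upregulates each low-baseline gene (true baseline RPKM
  < 1) by +1 log2 unit with probability 0.5. Ground truth records the
  per-gene effect and noise-free baseline class.
* **MNase fragments**: each gene gets a +1 dyad at `tss + footprint/2`,
  a phased array spaced footprint + linker into the gene body, a hard
  nucleosome-depleted exclusion zone upstream of the TSS whose width
  depends on expression class (120 bp low, 200 bp neither, 300 bp high —
  wider NDRs at higher expression), and three phased upstream nucleosomes
  beyond the NDR; each dyad emits Poisson(30) unstranded fragments with
  N(0, 10 bp) midpoint jitter and ±10 bp length jitter around the 147 bp
  footprint, plus ~1 background fragment per kb. The footprint (147 bp)
  and default fixed linker (33 bp) make the default repeat length 180 bp,
  the value at which fungal adjacent-nucleosome distance distributions
  peak. Both genotypes use identical parameters — chromatin structure
  unaffected by the mutation — differing only in their random substream,
  which is exactly the null the seed-to-seed equivalence tests exercise.
* **Cytosines**: sites scattered at 0.1 per bp; true rates by feature
  class (repeats 0.20, gene bodies 0.02, upstream 0.03, background 0.01 —
  repeats far above genic regions, as in ascomycete methylomes where
  methylation concentrates on repetitive elements), scaled by 0.6 in the
  mutant; coverage ~ Poisson(20); observed methylated counts ~
  Binomial(coverage, r + (1 − r)(1 − c)) with conversion probability
  c = 0.99. Incomplete conversion thus appears only as false methylation
  on unmethylated cytosines, matching how the rate is estimated from a
  fully unmethylated control; sequencing miscalls are not modeled.

What the generator does **not** emulate: sequence composition (cytosine
sites are abstract positions, contexts are labels), alignment artefacts
and mappability, MNase sequence preference and digestion-level effects,
fuzzy or delocalized nucleosomes, copy-number differences, batch effects,
and any coupling between a gene's methylation and its expression. Passing
tests therefore demonstrate that the statistics recover the structure they
target under honest noise models — not that real libraries are free of the
artefacts listed above.

## Problem sizes and determinism

The test suite runs its recovery checks at deliberately modest sizes —
hundreds of genes on megabase contigs, single-digit seconds per property —
which are ample for the effect sizes simulated: e.g. the repeat-length
mode is recovered from >5000 adjacent pairs, and conversion-rate recovery
uses ~200,000 read observations where the binomial standard error is
~0.02 percentage points against a 0.1-point tolerance. All stochastic
tests fix their seeds; all generators are byte-reproducible given a seed.

## Known limitations

* The caller's categories are heuristic labels, useful for filtering, not
  claims about any published caller's internal definitions.
* Percent-methylated values depend strongly on coverage through the 5%
  rule (see above); comparisons between datasets of different depth should
  use a coverage floor.
* `read_gff3()` handles single-span gene features only; multi-isoform
  resolution is out of scope.
* The fold-change analysis is distributional and carries no significance
  statement per gene.
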