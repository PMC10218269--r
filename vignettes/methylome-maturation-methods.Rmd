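---
title: "Methods: methylome maturation analysis for stem-cell-derived neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome maturation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromethylome)
```

## The problem

Neurons maturing in vivo accumulate a distinctive DNA-methylation landscape:
besides CG methylation (mCG), they acquire high levels of non-CG methylation
(mCH, H = A/C/T), dominated by the CA dinucleotide context (mCA). This
package analyses whole-genome bisulfite sequencing (WGBS) count data to ask
how closely neurons differentiated from embryonic stem cells in culture
recapitulate that landscape relative to neurons matured in vivo, using glia
and fetal cortex as non-neuronal references. Inputs are per-cytosine count
tables (one row per strand-resolved cytosine with methylated and total
basecall counts plus its dinucleotide context), BED feature annotations, GMT
gene-set collections and TPM expression tables. Alignment, DMR segmentation
proper (an external caller), motif enrichment and RNA-seq quantification are
out of scope: count tables and intervals are the interface.

## Weighted levels and nonconversion correction

The weighted methylation level of a context within a scope (genome, gene,
bin, window) is the pooled count of methylated basecalls divided by the
pooled total basecalls at reference cytosines of that context in the scope.
It is never a mean of per-site or per-part levels: the level of a union of
regions is the count-pooled value, and the pooled CH level pools CA+CC+CT
counts before dividing. CH is never stored as a context token; it is expanded
to `{CA, CC, CT}` at query time to avoid double counting.

Bisulfite conversion is imperfect, so a fully unmethylated spike-in genome is
sequenced alongside each sample. Its apparent methylation, computed per
context, estimates the nonconversion (false-methylation) rate, and that rate
is subtracted from every raw level of the same sample and context, clipping
at zero. Two numerical points are worth recording:

* **Clipping.** Subtraction can produce slightly negative values in
  near-unmethylated scopes; levels are clipped at 0 so they stay in `[0, 1]`.
* **Estimand of the subtraction correction.** Under the observation model
  used by the generator, `p_obs = p + (1 - p) * nc` (an unconverted
  unmethylated cytosine reads as methylated), the subtracted level has
  expectation `p * (1 - nc)`, not `p`. At realistic rates (`nc ~ 0.005`) the
  relative attenuation is half a percent — invisible at the precision the
  levels are reported with, but detectable by a 3-standard-error test on
  millions of calls. Parameter-recovery tests therefore compare estimates
  against `p * (1 - nc)`. The exactly unbiased alternative
  `(raw - nc) / (1 - nc)` is deliberately not used, because the subtraction
  rule is the procedure under study.

Feature-level aggregation pools counts per feature (a cytosine overlapping
two features contributes to both); features with fewer than `min_calls`
total basecalls (default 20) are flagged missing, never zero-filled, and
kept out of denominators downstream. Cytosines of both strands are pooled
regardless of feature strand. Gene bodies are the full TSS-to-TES span.
Metagene profiles scale each gene body to a fixed number of bins with
fixed-width flanking bins over 10 kb on each side, reverse minus-strand
genes so bins run TSS to TES, and pool counts per bin across genes.

## Comparing the in vitro and in vivo methylomes

Per-gene deltas are differences of corrected gene-body levels (in vitro
minus in vivo, so positive means hypermethylated in culture). Genes are
called hypermethylated when `delta > t` and hypomethylated when
`delta < -t`, with `t = 0.1` for CG and `t = 0.01` for CH, fractions taken
over genes with both levels non-missing (the denominators are a declared
choice; the source procedure does not state them). Heatmap ordering is
descending by delta with lexicographic tie-breaks, so it is invariant to
input order. Pattern comparisons across samples with different overall
levels divide per-gene levels by the sample's global level.

Genome-scale structure is summarised on a 100 kb tiling of the autosomes
(chrX/chrY excluded): per-bin corrected levels per sample, pairwise Spearman
correlation over the unmasked bins common to each pair, distance
`1 - rho`, and average-linkage agglomerative clustering. Average linkage is a
declared choice (the correlation statistic is fixed, the linkage was not);
it is configurable. Clustering uses corrected levels; rank correlations make
this nearly equivalent to using raw levels. Bins are masked per sample below
`min_calls`, and pairs use their common unmasked bins, which maximises
usable bins per pair. A constant sample makes Spearman correlation undefined
and is an explicit error rather than an NA that would silently distort the
tree.

The independence of CG and CH remodelling is quantified by the Pearson
correlation of the two per-gene delta vectors over shared genes.

## Similarity score and preranked GSEA

For each gene with corrected levels in all four samples (two neuron, glia,
fetal), the similarity component is `s_neuron = |y - 1|` where
`y = |level_invitro - level_invivo|` (levels live in `[0, 1]`, so both are in
`[0, 1]` and `s_neuron = 1` means identical neuron states). The
distinctiveness component is the absolute difference between the neuron mean
and the glia/fetal mean. The two components are averaged and, by default,
min-max rescaled over scored genes to `[0, 1]`; the plain average (already in
`[0, 1]`) is available as `rescale = "half"`. How the added components were
rescaled is not stated by the source procedure, so both are offered and the
choice is recorded in the output. The score is symmetric in the two neuron
samples and in the two reference samples.

GSEA is implemented from scratch as the classic weighted Kolmogorov–Smirnov
walk: down the ranked list, a set gene increments the running sum by
`|score|^p` normalised so in-set increments total one (`p = 1` by default),
every other gene decrements by `1/(N - n_set)`, and the enrichment score
(ES) is the signed extremum of the walk. Significance comes from `n_perm`
random same-size gene samples drawn from the ranked list: `NES` divides the
observed ES by the mean `|ES|` of null draws of the matching sign, and the
p-value is add-one corrected within the matching sign,
`(1 + #{same-sign nulls at least as extreme}) / (1 + #{same-sign nulls})`,
so p is never zero and the floor is set by the same-sign null count. Results
are filtered at `p < 0.05` and sorted by decreasing NES. No multilevel
split-sampling refinement of small p-values is implemented: the analysis
only thresholds at 0.05, far above permutation resolution. Each gene set
draws its own substream from the seed, so results do not depend on
collection order. For difference-based rankings the signed delta is used
(positive = hypermethylated in vitro).

## DMR filtering and enrichment

Segmentation proper is out of scope; candidates come either from an external
caller's intervals or from the built-in stand-in, which smooths per-site
level differences with a running mean over three consecutive shared sites
(complete windows only) and merges same-sign runs of smoothed differences at
least 0.1, gaps at most 500 bp, three or more sites. Smoothing matters: with
raw per-site differences, sporadic single-site noise within the gap limit
chains onto true runs and dilutes the pooled effect size below the filter.

The scientifically meaningful step is the filter. A candidate becomes a DMR
when (i) it spans at least 3 cytosines, each covered by at least 5 calls in
*both* samples — the per-cytosine reading of an ambiguous "minimum coverage
of 5 per sample"; a per-region-mean alternative sits behind
`cov_rule = "region_mean"` — (ii) the retained cytosines are denser than 3
per 100 bp (strict inequality, matching "more than"), and (iii) the pooled
level difference is at least 0.2 in magnitude. Every emitted DMR can be
re-checked by an independent validator pass, and tightening any filter
parameter can only shrink the output.

Feature enrichment divides observed by expected counts: a DMR is assigned to
a class when its midpoint lies in any feature of the class (the midpoint
rule partitions DMRs cleanly when the annotation partitions the genome), and
the expected count is the DMR total times the class's share of the genome
(union length of its features over genome length). Developmental DMRs
(regions that gain methylation over in vivo maturation — "adult" — or lose
it — "fetal") are classified in a query sample as low/intermediate/high by
cut points at 1/3 and 2/3 of the corrected level, and summarised as
fractions per class.

## Methylation–expression integration

Genes with both a gene-body mCH level and a TPM value are ordered by
descending TPM and averaged in sliding windows of 20 genes (step 1). The
expression axis is `log10(TPM + 1)`; the transform behind the published
plot is unstated, so the headline statistic is the Spearman rank correlation
of the unwindowed pairs, which is invariant to any monotone transform. A
linear fit on the windowed means is emitted and labelled as exactly that.
Enhancer analysis reports per-enhancer corrected CG levels in both samples,
their delta, and the fraction of covered enhancers with delta above 0.5;
enhancers under the coverage floor leave the denominator. The TF panel
normalises expression and gene-body mCH per gene to the larger of the two
samples' values (the larger is exactly 1); an expression cell with zero
reads is missing, a pair whose maximum is zero is missing entirely, and rows
are ordered by the mCH difference.

## The synthetic study generator

All of the above is exercised end to end on a generator that emulates the
study design rather than real sequence:

* **Layout.** Cytosine sites are laid out deterministically per seed at one
  site per 8 bp with a fixed cyclic context pattern (20% CG; among CH sites
  CA:CC:CT = 2:1:1). The spacing approximates real two-strand dinucleotide
  densities (~1 CA site per 20 bp) — important because the DMR density
  filter (>3 cytosines per 100 bp) presumes realistic site density. All
  samples share the layout, as aligned samples share a reference.
* **Groups.** Six groups (ESC, NPC, in vitro neuron, in vivo neuron, glia,
  fetal cortex) carry set-points: gene-body and CpG-island mCG, global mCH
  and the CA share of it. Defaults place global mCA at 5.3% (in vitro
  neuron, day-38-like), 4.5% (in vivo adult neuron), 1.25% (ESC), ~0.4%
  (NPC) and below 0.1% (glia, fetal), with the in vitro neuron ~8 CG
  percentage points above the in vivo neuron. These mirror the study's
  printed global levels and orderings.
* **Regional structure.** Methylation is modulated at 100 kb scale by
  latent lognormal profiles shared within a class (both neurons share the
  CH profile; glia and fetal share another; one genome-wide CG profile) and
  mixed with idiosyncratic per-group profiles. The in vitro neuron's CG
  profile is mostly idiosyncratic: its hypermethylation is regionally
  uneven. This is the mechanism that separates it in CG-context bin
  clustering — a purely uniform offset could not, because Spearman rank
  correlation is invariant to monotone shifts. Multipliers are renormalised
  to a site-weighted mean of one, so global set-points are preserved
  exactly.
* **Counts.** Depth is Poisson (mean 30, the study's coverage); methylated
  counts are binomial at `p_obs = p + (1 - p) * nc` with nonconversion 0.005
  by default; the spike-in contig has `p = 0` everywhere. Within a feature
  class and bin, sites are homogeneous by default (no beta-binomial
  overdispersion unless requested), keeping analytic binomial standard
  errors available to the tests. One RNG substream per (sample, chromosome)
  derived from the master seed makes generation order irrelevant.
* **Planted truth.** DMR planting shifts the true probability of one sample
  by a delta inside non-overlapping regions and redraws counts, emitting a
  truth BED. Expression follows
  `log(TPM + 1) = a + b * mCH + Normal(0, sd)` with `b < 0` in the study
  configuration (`a = 2.5`, `b = -30`, `sd = 0.4`), anticorrelating
  expression with gene-body mCH; gene-to-gene mCH variation comes from the
  regional profiles.

What passing tests on this generator do **not** show about real data: there
is no sequence context beyond the dinucleotide label, no strand asymmetry,
no replicate-level biological variance (the study's replicate dispersion is
not published, so replicates are independent redraws), no CpG-island-like
clustering of CG sites (CG sites are uniform, so synthetic CG-DMR density
behaves differently from real CGI-dense regions), and real nonconversion can
vary along the genome while here it is a single per-context rate. The
generator validates the statistics, not the biology.

## Problem sizes and numerical conventions

The default study is 2 chromosomes of 2.5 Mb (50 bins of 100 kb), 300 genes,
625k cytosine sites per sample, 6 samples plus spike-ins — chosen so the
full pipeline, the test suite and the acceptance script each run in minutes
on one CPU while keeping per-quantity standard errors well below the effect
sizes of interest. Oracle-equivalence checks run on ~10k-site instances at a
tolerance of 1e-12; statistical recovery checks use 3-standard-error bands
with both binomial components (raw level and subtracted spike-in rate)
included; one borderline bias check averages the standardised error over six
seeds instead of asserting a single 3-SE draw, which a correct
implementation fails for ~1% of seeds. Ties are always broken
lexicographically by name; coordinates are 0-based half-open internally,
with 1-based cytosine-report and 0-based BED conversion at the file
boundary.

## Known limitations

* The CG-context DMR path is structurally disadvantaged on the synthetic
  layout (CG sites at ~2.5 per 100 bp sit below the density filter), so DMR
  recovery is demonstrated in the CA context, where the study's own
  contrasts are sharpest.
* The built-in candidate caller is plumbing, not a reimplementation of an
  entropy-based segmenter; absolute DMR counts on real data are not
  comparable, only the filter/enrichment behaviour downstream of any caller.
* Permutation GSEA resolution is bounded by `1/(1 + same-sign nulls)`;
  analyses thresholding far below 0.05 would need more permutations or a
  multilevel scheme.
* The hypomethylated-in-vitro CH gene fraction is small under the default
  set-points (the in vitro neuron sits globally above the in vivo neuron and
  the groups share most CH regional structure); the study's balanced
  hyper/hypo CH split reflects real regional biology the generator does not
  plant by default.
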