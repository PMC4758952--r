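---
title: "Methods: promoter-level analysis of RNAPII CTD modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-level analysis of RNAPII CTD modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdbalance)
```

## The problem

RNA polymerase II carries its regulatory state on the C-terminal domain
(CTD) of its largest subunit, a tandem array of Y1-S2-P3-T4-S5-P6-S7 heptad
repeats.  Serine-5 and serine-7 phosphorylation (S5p, S7p) mark initiation;
serine-2 phosphorylation (S2p) marks productive elongation and accumulates
toward and beyond the transcription end site (TES).  In vertebrates eight
repeats substitute the seventh serine with a lysine (K7) that can be
acetylated (K7ac) or mono-/di-methylated (K7me1, K7me2).  The analyses in
this package quantify these marks at gene promoters from ChIP tag data and
ask how promoter methylation and acetylation of K7 jointly relate to
elongation output and mRNA levels — in particular, whether K7 methylation
carries a *negative* conditional association with elongation once the
positively coupled initiation marks are accounted for, and whether the
per-gene K7me2/K7ac ratio stratifies genes by expression and by their
response to histone-deacetylase inhibition (TSA).

## Pipeline stages and their conventions

All genomic coordinates are 0-based half-open; windows `[start, end)`
count tag 5' positions.  One chromosome is assumed by the synthetic world;
all window code is chromosome-aware.

**Duplicate filtering.**  The multiplicity of each (chromosome, position,
strand) is capped at the nearest-rank 95th percentile of the multiplicity
distribution over occupied positions (rounded up to an integer).  Capping —
rather than deleting entire stacks — keeps one plausible signal
contribution per site and is the common dedup semantics; `mode = "drop"`
selects the stricter alternative, and the percentile population can be
restricted to duplicated positions.  Deduplication is idempotent.

**Windows and scaling.**  Promoter windows are `tss ± half_width`
(default ±1 kb, i.e. the 2 kb promoter window); the elongation readout is
the 2 kb window immediately after the TES in transcription orientation.
Both ±1 kb and ±2 kb promoter windows are in common use; this package
fixes ±1 kb as the default for counting and the ratio, with `half_width`
exposed everywhere.  Counts are scaled per
10 million non-duplicated mapped tags of their dataset before any ratio or
correlation.

**Enrichment segmentation.**  Positivity is defined against a mock/input
control via Bayesian change-point segmentation of 200 bp binned counts:
Poisson emissions with a conjugate Gamma(1, 1) rate prior integrated out
per block, and a geometric prior on block *lengths* with per-bin change
probability 0.01 (expected block of 100 bins; equivalently a geometric
tail on the number of blocks).  The maximum-a-posteriori partition is
computed exactly by an O(n · L) dynamic program (lookback cap L = 2000
bins = 400 kb, far above any enriched domain the generator produces; the
cap is configurable).  The marginal likelihood supplies the Occam penalty
against spurious splits; the tests verify exact agreement with brute-force
enumeration over all partitions on short tracks.  Blocks whose posterior
mean rate is at least `fold_threshold` (default 2) times the depth-scaled,
Gamma-smoothed local control rate are emitted and merged when adjacent.
Existing change-point callers are not reproduced internally; this module
reproduces its *role* — defining enriched regions for sharp and broad
marks — in an exactly testable form.

**Promoter positivity and gene classes.**  A promoter is positive for a
mark when its window intersects an enriched region *and* its count exceeds
the nearest-rank 10th percentile of counts among region-overlapping
promoters (the "10% tail cut").  The percentile population is the
region-overlapping promoters by default — the population whose
distribution the positivity histograms describe — with the all-promoters
alternative selectable, since the cut can reasonably be drawn on either
distribution.  Exclusion rules only ever set `NA`: positive windows
overlapping other positive windows for the same mark remove both genes;
a positive gene inside another positive gene removes the internal gene.
Classes then combine marks: *active* = S5p+, S7p+, S2p+(post-TES),
FPKM > 1, polycomb-negative; *PRCr* = H3K27me3+, H2Aub1+, S5p+, 8WG16−,
S2p−; *inactive* = negative for all five.  The TSS-anchored cohort keeps
active genes whose maximum total-polymerase (8WG16) peak lies within 50 bp
of the TSS (|offset| ≤ 50 equates the "within 50 bp" and "100 bp window
centered" phrasings); peak ties break toward the TSS.  Top/bottom 15%
cohorts take `floor(0.15 m)` genes by FPKM rank among polycomb-negative
genes.

**Profiles.**  Metagene profiles average tag counts in 10 bp bins over
5 kb windows centered on TSS or TES, reversing minus-strand genes.  Depth
is tag 5'-position counts (no fragment extension — extension is not part
of the stated procedure; the binning is exposed so an extended-coverage
variant can be layered on).  Heatmap matrices use 5 bp bins over ±500 bp
(S2p: −500..+1000) with per-gene z-scores using the sample (n−1) standard
deviation; constant rows map to zeros.  Nascent-transcription windows are
−500..+1000 bp at 10 bp resolution, sense and antisense separated by gene
strand; RPKM is `count × 1e9 / (length × total mapped)` over TSS..TES.
FPKM is log10-transformed after adding the 1e-4 pseudocount.

**Ratio statistic.**  The per-gene ratio divides depth-scaled promoter
K7me (me1 or me2) by depth-scaled promoter K7ac; a zero acetylation count
gives `NA`.  Tertiles split the ranked finite ratios via
`group = ceiling(3·rank/n)` with ties broken by original order, making the
split stable and invariant under monotone transforms.  Group differences
use the two-sided Wilcoxon rank-sum test (exact when the smaller group has
≤ 10 observations and no ties; otherwise normal approximation with tie
correction and continuity correction).  The TSA contingency compares high
vs low tertiles on up (fold ≥ 2) versus down (fold ≤ 0.5) regulation —
"2-fold" is read symmetrically on the treated/control scale — by the
two-sided Fisher exact test using the probability-mass convention; the
odds ratio is the sample cross-product, with the Haldane 0.5 correction
applied only when a cell is zero.

**Dependency modelling.**  The gene × variable mark table holds scaled
promoter counts, the post-TES S2p count, log mRNA, the mock control and
CpG, centered and scaled before modelling.  Spearman matrices are Pearson
correlations of average ranks, ordered by increasing correlation with
mRNA.  Partial correlations use the precision-matrix identity on
rank-transformed columns by default — so marginal and partial analyses
share the Spearman convention; a raw mode matches the alternative reading
of common practice, where the scale of the partial
correlations is a free choice.  p-values come from the t transform with
`n − |given| − 2` degrees of freedom.  Best-subset regression enumerates
all predictor subsets of sizes 1–5, ranking by adjusted R² per size, and
reports coefficient signs, t-test codes (≤0.001 ***, ≤0.01 **, ≤0.05 *),
adjusted R², Mallow's Cp against the 7-predictor full model (the stated
predictor set; mock is not part of it) and Gaussian AIC including the
constant term.  The LASSO path is fit on the 8-predictor set including
mock, with seeded 10-fold cross-validation and the 1-SE rule (largest
penalty within one standard error of the minimum CV error); fold counts
shrink automatically below 3 observations per fold.

## The synthetic world

The generator is a stated world, not a tuning knob: it emulates the
qualitative structure the analyses are meant to recover, at desk scale.

Genes (default 500 active, 100 PRCr, 200 inactive) are placed on one
chromosome with intergenic gaps of 3–8 kb, so neighbouring 2 kb promoter
windows never overlap, and random strands.  Latent per-gene,
per-mark *standardized log masses* follow a one-factor model: each of
S5p, S7p, 8WG16, K7ac and a latent methylation factor M loads 0.85 on a
shared activity factor; K7me1 and K7me2 read out M with loadings 0.97 and
0.93 (giving the observed ~0.9 me1–me2 correlation; K7me1 is deliberately
the slightly stronger readout so sparse selection prefers it, so sparse selection behaves the way the analysis
expects).  The elongation equation is

  S2p = 0.45·S7p + 0.35·K7ac + 0.12·S5p − 0.38·M + ε,  sd(ε) = 0.48.

The magnitude of the negative methylation path is a free parameter of the
world; these defaults are the package's own choice, fixed once so that
the *population* values land in the ranges empirically observed for mouse
embryonic stem cells: marginal K7me2–S2p around 0.3–0.45,
partial(K7ac, S2p | S7p) around 0.25, partial(K7me2, S2p | S5p) near zero,
partial given S7p or given {S5p, S7p, K7ac} clearly negative, an me1–me2
correlation near 0.93, and S7p/K7ac the two strongest predictors.  They
are documented generator parameters, not measurements.

Masses become tags by scaling `exp(0.5 z)` weights to a Poisson total
(default 200 000 tags per mark — a scaled-down stand-in for the tens of
millions of mapped reads of real libraries), allocating tags to genes
multinomially and drawing each tag position from a mark-specific kernel in
transcription orientation: sharp 80 bp Gaussians at the TSS for
K7me1/K7me2; a 250 bp-shifted, 250 bp-wide Gaussian for K7ac (downstream
expansion to ~+500 bp); a bimodal 8WG16 kernel N(0, 60) + N(+140, 60)
(the secondary pausing peak 140 bp downstream); 150 bp Gaussians for
S5p/S7p; for S2p a 30% uniform gene-body component plus a dominant
post-TES component N(TES + 500, 400) so most S2p mass falls in the 2 kb
post-TES window; broad 800 bp Gaussians for the repressive histone marks
at PRCr genes; uniform background (0.002 tags/bp) under every mark, and a
uniform-only mock at full depth.  PRCr genes carry S5p (poised polymerase)
but no S7p/S2p/8WG16/K7 signal; inactive genes carry background only.
FPKM is log-normal around the S2p latent (coupling 0.8), exactly zero for
inactive genes and ≪1 for PRCr genes; GRO-seq-like tags run sense along
gene bodies weighted by expression with a 10% antisense promoter
component; the TSA fold change is `2^(0.9·ratio_z + noise)` so high-ratio
genes are enriched for ≥2-fold up-regulation.

What the generator does *not* emulate — and hence what a green test does
not establish: mappability and GC structure, fragment-length effects,
overlapping and nested real gene annotations, inter-chromosomal structure,
copy-number or input biases, and any causal claim about methylation; signs
and dependencies are planted and recovered descriptively.

## Numerical choices and degenerate inputs

Nearest-rank percentiles (no interpolation) everywhere a cut is taken;
integer caps round up.  Constant columns give `NA` correlations with a
warning; constant heatmap rows give zero rows; an all-zero fine-binned
promoter track gives an undefined peak offset and excludes the gene from
the anchored cohort.  An empty control track falls back to the global
treatment background rate with a warning.  Windows clipped at coordinate 0
are flagged.  Classification with missing mark statuses errors (missing
columns) or yields `NA` (missing values), never silently positive.  All
randomness flows from a single integer seed; sub-streams for genes,
latents, tags and expression are derived by fixed small offsets so
`generate_tags()` and `generate_expression()` see identical latents.

Class-recovery in the acceptance suite is measured as balanced accuracy
over planted active/inactive genes that received a definite call: the 10%
tail cut *by construction* denies positivity to the weakest decile of
region-overlapping promoters, so a planted-active gene in that tail is
deliberately not called rather than misclassified — `NA` is an abstention,
mirroring the exclusion semantics of the classification itself.

## Limitations

The segmentation is a faithful Bayesian change-point model but not a
re-implementation of any particular caller, so absolute region boundaries on real
data may differ; only positivity calls feed downstream stages.  The
best-subset enumeration is exact for the intended ≤ 8 predictors and not
meant for wide tables.  Genome-scale reference numbers (promoter counts,
cohort sizes, exact correlation values) derive from real sequencing data
and are out of reach of the desk-scale synthetic world; the package
recovers their sign and ordering structure instead.
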