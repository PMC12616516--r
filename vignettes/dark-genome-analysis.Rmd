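---
title: "Dark-genome analysis of long-read brain sequencing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-genome analysis of long-read brain sequencing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkgenome)
library(dplyr)
```

This vignette is the package's account of its statistics: what each stage
assumes, which knobs matter, and where genuinely open design points were
settled. The package operates downstream of the standard long-read
callers — its inputs are caller-output *tables*, never reads — and every
stage can be exercised on synthetic data with planted truth.

## Coordinates and the genome layout

All coordinates are 0-based, half-open, BED-style; VCF positions are
converted on read and write. Insertions are point events `(pos, pos + 1)`
at the junction locus, because junction callers report a single cleavage
locus. Overlap is strand-agnostic throughout; strand is carried for
repeat elements but never filters an overlap.

A `genome_layout` holds chromosome sizes, interval tracks keyed by
region-class label, and per-chromosome arm structure. The centromere
span comes from `acen` cytoband rows (or the toy generator); the p arm is
everything left of it, the q arm everything right. The track vocabulary
(`active_HOR`, `inactive_HOR`, `monomeric_alphasat`, `beta_satellite`,
`classical_satellite`, `rDNA_array`, `dark_region`, `repeat_element`) is
deliberately configurable: published centromere-satellite annotations
differ in which sub-classes they merge into "centromere", so the split is
data, not code.

## The insertion filter chain

Tiers are nested — each level must pass everything below it:

1. **high_confidence**: non-empty TSD, UnmapCover ≥ 0.8 (fraction of the
   inserted sequence covered by retrotransposon sequence), intact 3′ end,
   caller PASS.
2. **unique_nonreference**: the locus is seen in exactly one individual.
   Calls within 50 bp on the same chromosome are the same locus
   (`locus_merge_bp`, single-linkage chaining). The 50 bp absorbs
   junction jitter between long-read calls of one polymorphism;
   at typical call densities, chaining two truly distinct loci is rare.
   Locus sharing is witnessed by *all* calls, including rejected ones —
   a filtered-out call in a second individual still proves the locus is
   polymorphic.
3. **singleton**: exactly one supporting read, and ≥ 10 spanning reads in
   the same individual that lack the insertion. One supporting read among
   many spanning reads is what a somatic event in a single post-mitotic
   cell should look like.
4. **l1en_singleton**: TSD length in [5, 31] bp (inclusive both ends),
   the single supporting read ≥ 10 kbp, a polyA tail, and an L1
   endonuclease motif at the junction.

The endonuclease motif test is the one genuinely open operationalisation
in the chain. We require the 6-mer `TTAAAA` (or its reverse complement)
with at most one mismatch, with the matched window touching the ±3 bp
neighbourhood of the cleavage point inside the ±10 bp junction sequence.
The consensus, mismatch budget and anchor distance are all configurable
(`l1en_motif`, `l1en_max_mismatch`, `l1en_anchor_bp`); one mismatch
reflects that the cleavage consensus is degenerate in vivo, and the
anchor keeps a chance 6-mer elsewhere in the flank from counting.

MAPQ is recorded but is deliberately *not* a filter: centromeric
singletons commonly align with MAPQ ≈ 1, and dropping them would empty
the very regions of interest.

Every classification carries its full list of failed criteria, so the
chain is auditable call by call; the test suite checks the pipeline
against an independently coded per-criterion re-evaluation on every
synthetic call.

Counts are normalised to diploid genomes sequenced: `count / (Gbp /
6.4)`, 6.4 Gbp being one diploid human genome. Group comparisons are
fixed-effects one-way ANOVA (or pooled-variance two-sided Student's t for
two groups), with no multiple-comparison correction — raw p-values are
reported, as is conventional for a single planned contrast per measure.

## NAHR windows

Events are kept when the caller score is ≤ 1e-4 *and* the event is a
singleton; the score's null model belongs to the upstream caller and is
treated as opaque. Enrichment is computed on a fixed 100-kbp tiling
(last window of each chromosome may be short):

* each retained event contributes its **two junction endpoints** to their
  respective windows. The alternative (counting an event once) discards
  the two-locus nature of recombination; endpoints also give a clean
  conservation law — endpoint assignments always sum to exactly twice
  the number of events — that the tests verify;
* the repeat count of a window is the number of repeat elements whose
  **midpoint** falls in it, so a boundary-spanning repeat is counted
  exactly once;
* enrichment = endpoints / repeats; windows with zero repeats are
  reported as undefined and excluded from summaries rather than being
  silently zero or infinite.

Geometry follows a declared decision table on the junction orientations:
`++`/`--` inversion, `+-` deletion, `-+` duplication, different
chromosomes interchromosomal. Pair classes collapse subfamilies to
families (L1PA3 and L1Hs are both L1) and are order-insensitive.

## Structural variants

Variants below 50 bp are dropped (breakends with no usable length are
retained but excluded from length-based analyses). Group-uniqueness
requires a genotype in every sample — one `./.` disqualifies a variant
regardless of its pattern — and "found in" means at least one alternate
allele; homozygous reference is absence, and dosage is ignored. The SNP
proximity window defaults to 10 kb ("near" is not otherwise defined) and
is configurable.

## Differential methylation

**Dedup.** The upstream caller groups CpGs within 10 bp into one call, so
a chain of records at ≤ 10 bp spacing is collapsed to its most 5′ member
(transitively: 100, 109, 118 all collapse onto 100). Counts are *not*
summed — the caller already aggregated them, and summing would inflate
depth.

**Support filters.** A per-sample entry needs ≥ 3 supporting reads
(`called_sites`); a site needs entries in ≥ 3 samples. Both filters are
distinct and both apply. Methylated counts are reconstructed as
`round(frequency × called_sites)` when not carried explicitly.

**Outlier screen.** Classical metric MDS on Euclidean distances between
per-sample frequency vectors over sites complete in all samples; a sample
is flagged when its embedding distance to the centroid exceeds
median + 3·MAD. The multiplier is conventional for robust outlier
screens and configurable (`mds_k`).

**The site test.** Counts are modelled beta-binomially with variance
$t\,p(1-p)(1 + (t-1)\varphi)$. Per site:

* group frequency $\hat p_g = \sum m_i / \sum t_i$ (pooled, so deeper
  samples weigh more);
* dispersion $\hat\varphi$ by method of moments, pooled over both groups.
  Because $\hat p_g$ is estimated from the same samples, the naive
  residual moment $\sum (m_i - t_i \hat p)^2$ is biased low by the usual
  within-group degrees-of-freedom loss; we solve the exact finite-sample
  moment equation with per-sample coefficients
  $c_i = 1 - 2t_i/T + \sum_j t_j^2 / T^2$, floor at zero, and shrink
  halfway toward the genome-wide median $\hat\varphi$ (weight
  `dispersion_shrink = 0.5`). Without the bias correction the test is
  visibly anti-conservative at realistic depths (the type-I calibration
  test in the suite would catch it);
* Wald statistic $(\hat p_1 - \hat p_2)/\sqrt{V_1 + V_2}$ with
  $V_g = \sum t_i \tilde p(1-\tilde p)(1+(t_i-1)\hat\varphi) / (\sum t_i)^2$.
  The variance uses a half-count continuity estimate
  $\tilde p = (\sum m + 0.5)/(\sum t + 1)$ so that a fully methylated or
  fully unmethylated group keeps a positive variance and an extreme
  separation yields an extreme, correctly signed statistic; at balanced
  counts (e.g. 5/10 everywhere) $\tilde p$ is exactly $\tfrac12$ and the
  statistic is exactly zero;
* two-sided p from the normal reference, BH q across tested sites. Sites
  with fewer than two called samples in either group are skipped and
  logged.

**DMRs.** Consecutive tested sites with raw p < 0.05 and a common
difference sign chain greedily, tolerating gaps ≤ 100 bp; chains with ≥ 3
CpGs become DMRs. The p < 0.05 aggregation rule is the method's defining
choice; the 3-CpG minimum and 100 bp gap follow the established regional
caller's defaults and are configurable (`dmr_min_cpg`,
`dmr_merge_gap`). `areaStat` is the *exact* sum of member Wald
statistics — splitting a DMR anywhere and summing the parts reproduces
it — and ranks DMRs by combined evidence. Because the gap rule lets a
chain step over an isolated non-significant site, a DMR's site set is
defined as every tested CpG inside its interval, and recovery of planted
DMRs is measured by Jaccard on that set.

**Retroelement loci.** A locus enters the per-locus methylation summary
only if its length *strictly* exceeds its family threshold (HERV-K
6000 bp, LTR5_Hs/A/B 900 bp, LINE1-Hs 5900 bp, AluYa5/Yb8 280 bp, SVA-E/F
1000 bp) and ≥ 10 called CpGs overlap it; the length thresholds exclude
the highly fragmented copies that dominate repeat annotations. A family
with no configured threshold is kept with a warning rather than silently
dropped. Promoters count at most once per methylation direction no
matter how many DMRs land in them, so promoter-level tallies are not
inflated by DMR fragmentation.

The dual-genome intersection workflow (running against two references
and intersecting significant sites) is a pipeline recipe — run twice,
intersect — not core logic here.

## Metachromosome

Windows are ranked by midpoint: p arm from +1 (telomere) down to 0
(centromere), q arm from 0 to −1, arm length normalised per chromosome.
Windows fully inside the active-HOR track rank exactly 0; windows whose
midpoint falls in the centromere span but that are not fully inside
active HOR also sit at 0 (only the fully-contained case is externally
specified; midpoint assignment is the package's tie-break). Ranks map to
meta-bins by `round((rank + 1) × 250)` (half away from zero, clipped to
[0, 500]): bin 0 is the q telomere, 250 the centromere (bins 249–251
marked centromeric), 500 the p telomere. Bins with no contributing
window are missing, not zero. Rolling averages use a centred 11-window
(~1 Mb) span, truncated at arm edges, missing values excluded per local
mean. In `normalized_count` mode the per-bin mean is divided by the
global mean over windows with a positive count, matching the
insertion-profile convention of excluding empty windows from the
normaliser.

## Permutation overlap test

Each query region is re-placed uniformly at random on its own chromosome
(length preserved; placed regions may overlap each other). Same-chromosome
placement is the package's choice where only the test itself is
externally specified: chromosome composition is the dominant confounder
for centromere/rDNA questions, and preserving it makes the null sharper;
genome-wide placement (length-weighted chromosome draw) is available via
`genome_wide = TRUE`. The empirical p is
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, so its floor is
$1/(n_{perm}+1)$ — with the default 10,000 permutations, 9.999e-5. The
permutation count is configurable; 10,000 is the default consistent with
reporting p-values of 1e-4. The implementation is vectorised (merged
expanded-interval boundaries + `findInterval` per placement), and the
RNG stream is consumed in sorted group order so the p-value does not
depend on the input order of the query regions.

## The synthetic-data generators

All generators are pure functions of (parameters, seed); a global seed
fans out to fixed per-generator child streams so modules can be
regenerated independently. What they emulate — and do not:

* **Layout**: mid-chromosome centromere split into an active-HOR core
  (⅓ of the span) flanked symmetrically by inactive-HOR, monomeric,
  beta- and classical-satellite bands (1/12 each side); optional p-arm
  rDNA arrays mimicking acrocentrics; uniform dark regions; a
  genome-wide Alu/L1/SVA/LTR repeat mix at a configurable density. No
  sequence content exists below junction motifs and TSDs.
* **Insertions**: planted singletons satisfy *every* chain criterion;
  noise calls violate exactly one named criterion each, recorded in the
  truth table, so filter failures are attributable. Planted loci sit on
  a 1-kbp lattice so distinct loci can never merge. Per-sample rates
  default to values chosen for test power — the real per-sample rates
  are not publicly tabulated — and the centromere placement bias is a
  single weight.
* **NAHR**: per-window Poisson counts at `base_rate × multiplier`,
  endpoints snapped to matching-family repeats where available; true
  events get scores ≤ 1e-4, planted rejects fail a filter.
* **Methylation**: CpGs on a fixed grid (default 50 bp) plus occasional
  satellite records 3–9 bp downstream to exercise dedup; counts are
  beta-binomial via the (mean, φ) parameterisation that matches the
  test's model; planted DMRs shift the mean by δ in one group only.
  Real nanopore data has spatially correlated dispersion and coverage;
  the generator does not, so passing tests demonstrate correctness of
  the statistics, not field performance on real tissue.
* **SVs**: shared variants span groups; group-unique variants are
  genotyped everywhere and present in one group; a configurable fraction
  carries a missing genotype to exercise the genotyped-everywhere rule.

## Problem sizes in the test suite

The suite runs everything at desk scale, chosen as the smallest sizes at
which each property is sharply testable: 2 × 10 Mb (or 1 × 2 Mb / 4 ×
10 Mb) toy genomes, ~1,000-call insertion sets, 2,000-site null
calibrations, five planted DMRs × 10 seeds, 20 NAHR hotspot replicates,
and 10,000-permutation overlap tests. The type-I band for the site test
([0.035, 0.065] at 2,000 sites) is the exact binomial-width band for a
calibrated test at that size.

## Known limitations

* The site test's normal reference is slightly liberal at very low
  depths (< ~5 reads per sample); the support filters keep such entries
  out by default.
* 5mC and 5hmC are not distinguished — a platform limitation of the
  upstream caller, inherited here.
* The dispersion estimate is per-site with a fixed shrinkage weight, not
  a smoothed empirical Bayes fit; it is deliberately simple and
  auditable.
* `rank_windows` excludes nothing by itself; excluding sex chromosomes
  and the mitochondrion (standard for metachromosome profiles) is the
  caller's responsibility via the `chroms` argument.
* No functional-effect prediction, database search, or pathway
  enrichment: those belong to external tools.
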