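---
title: "Population-scale CNV-region analysis from window read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale CNV-region analysis from window read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

## The problem

Copy-number variants (CNVs) — deletions and duplications of genomic
segments from tens of bases to megabases — are a major source of
heritable variation in livestock genomes, and the loci where their
frequencies differ most between populations are candidates for
selection. Given whole-genome resequencing of a multi-population cohort,
the read depth of fixed genomic windows is, after bias correction,
proportional in expectation to the local copy number. `cnvpop`
implements the downstream analysis chain on such window-depth matrices:

1. **Normalization** — window masking, GC-bias correction, rescaling to
   a diploid copy-number scale.
2. **Discovery** — detection of copy-number-variable windows across the
   cohort, merging into CNV regions (CNVRs), genotyping by 1-D
   clustering with a silhouette quality gate, and type/length filters.
3. **Annotation** — genomic-feature classification of each CNVR against
   a gene model, with length-bin and per-chromosome summaries.
4. **Population structure** — PCA of individuals on the deletion,
   duplication, both-type, or combined CNVR dosage matrices.
5. **Differentiation** — the V~ST~ statistic per CNVR between a focal
   population and each other population, top-percentile outlier
   selection, and mapping of outlier regions to genes.

The raw alignment step (BAM to window counts) is upstream of this
package: its inputs are plain TSV depth matrices, a sample-to-population
map, and a GFF3/BED12 gene model.

## Models and statistics

### Depth to copy number

For individual $i$ and window $w$, the observed read count $x_{iw}$ is
modelled as overdispersed around
$\mu_{iw} = \bar\mu_i \cdot \tfrac{c_{iw}}{2} \cdot g(\mathrm{GC}_w)$,
where $c_{iw}$ is the local copy number and $g$ the GC-bias factor.
Normalization inverts this in three steps, all median-based for
robustness to the CNV-carrying windows themselves:

* **Masking** (`mask_windows`): windows whose cross-sample median count
  falls outside the central quantile band (defaults 0.005–0.995) are
  excluded everywhere. This is a stand-in for the unmappable and
  collapsed-repeat windows that read-level callers remove by read
  similarity; on real data those windows carry either near-zero or
  many-fold-inflated depth in every individual.
* **GC correction** (`gc_correct`): per individual, counts in each GC
  bin (width 0.01, bins with fewer than 20 windows pooled with their
  nearest neighbour) are scaled by global-median / bin-median, so every
  bin's median equals the genome-wide median exactly.
* **Diploid scaling** (`normalize_cn`): $c_{iw} = 2 x_{iw} /
  \mathrm{median}_w(x_{iw})$, anchoring each individual's median copy
  number at exactly 2 (autosomes only; sex chromosomes are out of
  scope).

The composition of GC correction and diploid scaling is invariant to
multiplying an individual's whole count row by a constant, so
differences in sequencing depth between individuals cancel.

### Discovery and genotyping

A window is a **candidate** when at least
$\max(h, \lceil f\,n\rceil)$ individuals deviate from diploid, with
deviation defined as copy number $\le 1.5$ (loss) or $\ge 2.5$ (gain) —
the midpoints between the diploid state and one copy lost or gained.
The defaults $f = 0.1$ and $h = 3$ are the standard population-scale
read-depth settings. Candidates are merged along the chromosome when
their genomic gap is at most one window-step and the Pearson correlation
of their copy-number vectors is at least $r = 0.1$; correlation-gated
merging keeps independently fluctuating neighbours apart.

Each merged region is genotyped on the per-individual mean copy number
over its windows: deterministic 1-D k-means (quantile-spaced initial
centres, 300-iteration cap, tolerance $10^{-6}$) is run for $k \in
\{2, 3\}$, the $k$ with the larger mean silhouette is kept, clusters are
labelled loss/normal/gain by their centre value, and the region kind
(deletion / duplication / both) follows the labels present. Retained
CNVRs must have silhouette strictly above 0.6, deletion/both length at
most 50 kb, and duplication length strictly below 500 kb.

Two additional gates are applied by the pipeline wrapper `call_cnvrs`,
both arising from an explicit failure analysis of the minimal chain:

* **Minimum two candidate windows** (with half-overlapping windows).
  Any true event of at least one window length must be seen by two
  adjacent overlapping windows, so an isolated single-window candidate
  is indistinguishable from a depth fluctuation. Empirically, at 12×
  coverage single-window noise candidates pass the silhouette gate
  often enough (the silhouette of the best split of a conditioned noise
  sample sits near 0.6) that genome-wide precision collapses without
  this rule.
* **Region-level carrier count**: the deviant-frequency rule is
  re-applied to the final genotype classes — a CNVR must have at least
  $\max(h, \lceil f\,n\rceil)$ individuals in a non-normal class. This
  removes regions whose apparent cluster is a single extreme individual
  (a singleton cluster contributes 0, not a penalty, to the mean
  silhouette).

**Boundary refinement.** Windows that only partially overlap an event
carry proportionally diluted signal and would otherwise extend a
region's span up to a window size beyond the true edge. `call_cnvrs`
therefore trims leading and trailing windows whose mean absolute
copy-number deviation is below half the region's core deviation (the
median window deviation — the median, not the maximum, so a single
aberrant window inside the region cannot define the core). This is the
analogue of half-maximum breakpoint trimming and brings boundary errors
below one window step.

### V~ST~

For one CNVR and two populations with $n_A$ and $n_B$ individuals,

$$V_{ST} \;=\; \frac{V_T - V_S}{V_T}, \qquad
V_S = \frac{n_A V_A + n_B V_B}{n_A + n_B},$$

where $V_T$ is the variance of the pooled per-individual copy numbers
and $V_A, V_B$ the within-population variances. Variances use the
denominator-$n$ (population) convention by default: it makes the
size-weighting exact (two identical distributions give $V_{ST} = 0$
identically) and is exposed as an option (`unbiased = TRUE` for
$n-1$) because the convention is rarely stated in applications.
Monomorphic CNVRs ($V_T = 0$) are assigned $V_{ST} = 0$ rather than
dropped or treated as errors, so they cannot poison the outlier
quantile. Negative values are reported as computed; they never rank in
the top percentile. Outliers are selected per population pair at the
$1 - q$ quantile of the pair's $V_{ST}$ values (default $q = 0.01$,
linear interpolation, ties at the threshold included); whether a single
pooled cutoff across pairs would be preferable is not decidable from
published practice, and per-pair keeps the pairs exchangeable.

### PCA

Individuals-by-CNVRs dosage matrices are built per subset: *deletions*
(kinds deletion + both), *duplications* (duplication + both), *both*,
or *all*. Columns are centred and by default variance-standardized
(zero-variance columns dropped with a count in the result), echoing the
normalization of the standard population-genetics PCA tools; the
unscaled mode is exposed because the choice is not universal.
Coordinates come from the SVD of the processed matrix, variance
explained is eigenvalue over trace, and every loading vector is oriented
to have non-negative sum so results are reproducible across platforms.

## The synthetic cohort generator

Everything above is validated against a generator with a known truth
set, at a default scale of two populations × 20 individuals, one 10-Mb
chromosome, 800-bp windows at 400-bp step, and 12-fold coverage — the
per-breed sample sizes and coverage of a realistic resequencing cohort
at desk scale.

* **Reference** (`simulate_reference`): windows tile the chromosome;
  GC fraction follows a bounded AR(1) walk in [0.30, 0.60] centred at
  0.45. Mammalian autosomal GC skews below 0.5, and the skew matters:
  a unimodal bias centred at GC 0.5 has a monotone component over the
  realized range, which is what makes the depth–GC rank correlation a
  meaningful diagnostic. A small fraction of windows (0.4% each by
  default in `simulate_cohort`) are collapsed-repeat windows (3–10×
  inflated depth in every individual) or near-unmappable windows
  (< 0.15×) — the features the quantile mask exists to remove. These
  fractions are deliberately within the default masking budget of 0.5%
  per tail; artifact windows that escape a saturated mask produce
  uniform all-individual "duplications" that no population-frequency
  argument can reject.
* **Truth** (`implant_cnvs`): each individual draws, per event, its
  allele count as Binomial(2, population frequency); the copy-number
  track is 2 plus the carried changes of overlapping events (a −2
  deletion allele removes both copies, so deltas are floored at −2 and
  copy number never drops below 0).
* **Depth** (`simulate_depth`): negative binomial counts with mean
  `depth × (window + read_length) / read_length × dosage/2 × gc_bias`;
  `dispersion` is the NB size (default 150, i.e. variance ≈ 1.4× mean
  at 12×/800 bp, a mid-range value for GC-corrected WGS windows —
  published pipelines report no noise model, so this is an engineering
  default, stated once and not revisited); `Inf` gives the Poisson
  limit. The GC factor is `max(0.1, 1 − a((GC − 0.5)/0.2)²)`, so the
  amplitude `a` is the fractional depth loss 0.2 GC units from the
  optimum; an unscaled quadratic in GC would amount to a sub-2% effect
  over the realistic GC range, far below what real libraries show.
  Edge windows use the event's overlap fraction as effective dosage
  (uniform read sampling); without that dilution the generator would
  quantize every event to whole windows and boundary accuracy could not
  be assessed below one window size.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: counts of overlapping windows are drawn
independently although real half-overlapping windows share reads and
correlate; there is no read-level error, no mappability structure beyond
the per-window multipliers, no linkage disequilibrium between events, no
kinship within populations ("unrelated individuals" is assumed, not
enforced by pruning), and event boundaries are sharp. Recovery rates on
real cohorts will be lower, particularly in repeat-dense regions where
the quantile mask is a weaker instrument than read-level similarity
merging.

`simulate_cnvr_matrix` generates per-CNVR dosage matrices directly
(binomial allele dosage plus Gaussian noise, default sd 0.1 emulating
residual depth noise after averaging over a region's windows) for
differentiation and structure studies at hundreds of loci, which would
not fit in a desk-scale window simulation.

## Validation scale and numerical choices

The test suite validates, among others: exact agreement (to $10^{-12}$)
of `vst` and `silhouette_score` with naive brute-force oracles; CNVR
recovery with recall and precision ≥ 0.9 and boundary error ≤ one
window step on the default 10-Mb cohort (50 events of 2–50 kb, carrier
frequencies ≥ 0.2); GC flattening from |ρ| > 0.3 to < 0.05 at bias
amplitude 0.4; ≥ 4 of 5 implanted differential CNVRs (carrier
frequencies 0.9 vs 0.1 among 500 null loci) in the top 1% of V~ST~ in
≥ 90% of 20 replicates; and PC1-sign recovery of population labels
(≥ 95%) including the contrast that duplication-only differentiation
separates the duplication-subset PCA but not the deletion-subset PCA.
`scripts/acceptance.R` recomputes all of these from scratch for any
seed.

Degenerate inputs are defined, not exceptional: a region whose summary
values are all identical gets silhouette −1 and fails the gate; a
dosage matrix with identical rows yields all-zero PCA coordinates; a
monomorphic CNVR has $V_{ST} = 0$; an all-vst-equal scan flags every
record (all tie the threshold). Ties in k-means assignment go to the
lower-indexed centre; ranks break V~ST~ ties by genomic order.

## Limitations

* Absolute annotation fractions (e.g. the share of intergenic CNVRs)
  depend on the gene model's density and flank conventions and are not
  comparable across builds.
* The discovery thresholds (1.5/2.5) assume diploid autosomes and
  integer-copy events; mosaic or somatic fractions are out of scope.
* With very common events (carrier fraction near 1) the per-individual
  median anchor itself shifts and dosage is underestimated; such loci
  are effectively invisible to any within-cohort read-depth method.
* The quantile mask trades a small loss of genuinely variable windows
  (common duplications sit in the upper depth tail) for robustness to
  artifact windows; fragmented calls over long common duplications are
  the visible cost.
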