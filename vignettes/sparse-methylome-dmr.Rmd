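---
title: "Differential methylation in sparse methylomes: models and methods"
author: "sparseDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation in sparse methylomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Invertebrate methylomes are *mosaic*: global CpG methylation is well below
1%, but what methylation exists is concentrated in short clusters of
consecutive CpGs inside gene bodies, preferentially exons. Detecting
differentially methylated regions (DMRs) between two conditions in such a
genome, from whole-genome bisulphite sequencing (WGBS) at 8–12x coverage,
poses three coupled problems:

1. per-CpG counts are too shallow for stable per-site estimates;
2. biological structure other than treatment — here, the maternal line of
   each clonal replicate — dominates the covariance between replicates;
3. bisulphite conversion failure and C/T polymorphism both mimic
   methylation signal and must be filtered before any statistics.

`sparseDMR` implements the full analysis for a mother-paired two-arm
design (6 normal-food and 6 calorie-restricted replicates, paired by
mother, in the motivating experiment), plus a synthetic-data generator
that reproduces the statistical structure the analysis assumes, so the
whole pipeline can be exercised and validated at desk scale.

## Pre-statistics filters

**Non-conversion filter.** Reads carrying any methylated CHH or CHG call
are removed whole: non-CpG methylation is negligible in these genomes, so
such calls mark reads that escaped bisulphite conversion. The
per-replicate report gives the non-CpG percent methylated; 100 minus that
figure is the conversion efficiency. With a ~3% conversion failure rate
the raw global CpG estimate is inflated by nearly three percentage points
(0.03 × (1 − true level)); the filter removes essentially all of this
bias because an unconverted read is methylated at *every* cytosine and is
therefore identifiable whenever the read covers any non-CpG cytosine.

**Variant hard filter and CpG masking.** Variants are filtered with the
standard hard bounds (fail when QD < 2, FS > 60, MQ < 40,
MQRankSum < −12.5 or ReadPosRankSum < −8). The source text phrases these
as keep-conditions ("QD > 2"); we implement them as exclusion bounds,
which is the convention the thresholds come from. A missing annotation
does not fail its criterion (strict mode is available). A CpG site is
masked when a passing C/T SNP sits on its cytosine — the T allele reads
as unmethylated C — or, because reverse-strand reads report the
complementary G, when a G/A SNP sits on the following base. Whether the
original analysis masked the G side as well is not documented; both the C
and G rules are on by default and the G rule can be disabled
(`gMask = FALSE`).

**Coverage rule.** A site enters the statistics only if at least two
replicates in *each* arm have at least six reads.

## Smoothing

Counts are turned into per-replicate methylation levels by BSmooth-style
local-likelihood smoothing: at each CpG a window is grown symmetrically
(in distance) until it holds at least `minCpgs` sites and spans at least
`minWindowBp`; raw proportions in the window are fitted by weighted least
squares with a local polynomial of degree 2 (degree 0 gives the
kernel-weighted mean), with weights tricube(distance/halfwidth) ×
coverage. The fitted value at the centre, clipped to [0, 1], is the
smoothed level. Zero-coverage sites get weight zero but still receive a
fitted value. The one-step WLS approximation of the binomial local
likelihood is exact for the constant and polynomial test cases and much
simpler; nothing in the source analysis constrains this choice.

Defaults are the published ones for full-scale genomes: 70 CpGs and
1000 bp. At desk scale (the 2 × 10⁴-CpG synthetic genome) we use **15
CpGs / 300 bp**, chosen as roughly twice the expected methylated-cluster
width (clusters average ~6 CpGs, as reported for the motivating data) —
the same relation the 70-CpG default bears to CpG-dense regions of large
genomes. A pilot sweep confirmed recovery of planted DMRs is flat across
10–20-CpG windows and collapses for windows much wider than the clusters
themselves, as expected from signal dilution.

## Paired t statistics and candidate regions

For mother k the pair difference d_k = CR_k − NF_k of smoothed levels is
computed per CpG; the t statistic is mean(d) / (sd_floored / √n) with
n − 1 = 5 degrees of freedom for six pairs. The per-site sd is floored at
the genome-wide 0.75 quantile of per-site sds — the variance-stabilising
"local correction" device of the BSmooth t-statistic, with the quantile
configurable. If the floor itself is zero (degenerate input), sites with
zero sd get t = 0. Pairing removes the mother effect exactly: any
per-site shift shared by a mother's two replicates cancels in d_k.

Candidate DMRs are maximal runs of consecutive CpGs with all t beyond the
symmetric cutoff ±4.6 and a common sign, broken by sign change,
sub-threshold site, scaffold change, or an inter-CpG gap above 300 bp
(the cutoff is from the motivating analysis; the gap default follows the
cited method's convention — the source does not state one). Candidates
are filtered to regions with ≥ 3 CpGs and |region mean difference|
strictly greater than 0.1. Per-CpG q-values (BH, or Storey's smoother-pi0
variant) are computed and each region is annotated with its count of
q < 0.05 members; using that count as an extra filter is available but
off by default, because the source narrative selects regions by the
t-cutoffs.

## Region p-values

Following the comb-p scheme: (1) per-CpG p-values are z-transformed
(upper tail) and their autocorrelation estimated in 50-bp lag bins up to
500 bp (bins with fewer than 10 pairs, or constant z, get ρ = 0); (2)
each *unfiltered* candidate region receives a Stouffer–Liptak–Kechris
combined p-value, z_comb = Σz / √(n + 2Σρ_ij), with ρ looked up by
member-pair distance, negative estimates clipped to 0 (keeping the
denominator ≥ n, conservative) and distances beyond the last bin
contributing 0; (3) BH correction across all combined p-values; (4) the
final DMR set is the intersection: filtered candidates whose region
reaches corrected p < 0.05. The comb-p peak-finding step is replaced, as
in the source analysis, by the candidate regions themselves; a standalone
seed-and-extend peak finder is provided off the main path. p-values of
exactly 0 or 1 are clamped to machine-safe values before the z-transform,
with a message.

## Replicate clustering

Replicates are clustered on 1 − Pearson correlation of raw per-CpG
proportions (zero-coverage cells are missing, excluded pairwise, never
zeros) with Ward.D2 agglomeration as implemented by `stats::hclust`
(tie-breaking is hclust's deterministic behaviour). Bootstrap support
resamples CpG sites with replacement and scores each internal node by the
fraction of resampled trees containing the same bipartition (BP). Rows
are put into a canonical content order before resampling so BP does not
depend on input site order. Approximately-unbiased multiscale support is
not implemented: the motivating study reports BP and AU identical on
these data, so BP suffices; AU is an extension point. In a
mother-dominant world every mother's NF/CR pair appears as a cherry with
BP near 1 — the structure that justifies the paired test.

## Annotation and enrichment

DMRs are intersected with genes and exons (1-based inclusive, strand
ignored for overlap; exon indices follow transcription order, so the
genomically last exon of a minus-strand gene is exon 1). Overlaps are
classed exonic / intronic / mixed, and the first transcription-order exon
hit is reported as "i of n". Gene universes for enrichment are built from
*raw pre-smoothing* counts: a CpG is methylated if its pooled methylated
count exceeds zero (the most literal reading of "greater than 0";
a per-replicate variant is available by flag), and the three universes
are all genes, ≥ 1, and ≥ 3 methylated CpGs — always nested.

Term enrichment is a one-sided hypergeometric (Fisher) test per GO term
after propagating gene annotations to all ancestors, with no
multiple-testing correction (standard for hierarchy-aware GO testing) and
α = 0.01. Two algorithms are provided: `classic`, and `elim`, which
processes terms deepest-first and removes the genes of significantly
enriched children from their ancestors before testing them. The weight01
algorithm used in the motivating study is a hybrid of elim and weighting
whose exact bookkeeping is out of scope here; elim is the published
hierarchy-aware member of that family and degenerates to classic when no
child is significant.

## The synthetic world

The generator's defaults state the world the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| scaffolds × length | 2 × 500 kb | 2 × 10⁴ CpGs at 20 CpG/kbp |
| exon CpG enrichment | 3× | mosaic genomes keep CpGs in gene bodies |
| fracMethylatedSites | 0.008 | gene-body CpGs in high clusters |
| cluster width | 3–20 CpGs | reported cluster range, mean ~6 |
| high / low Beta | (6, 2) / (0.05, 25) | baselines ~0.75 vs ~0.002 |
| pairs | 6 | 12 replicates, paired by mother |
| coverage | Poisson, mean 10 | the reported 8–12× range |
| motherSd | 0.3 | per-site maternal epiallele sd (logit) |
| planted DMRs | 10; effects 0.10–0.35; 3–20 CpGs; 35% hyper | the reported effect and direction conventions |
| conversion failure | 0.03 | reported ~3% raw non-CpG methylation |
| SNP confounds | 50 C/T or G/A sites | polymorphic-CpG masking target |

Choices the source leaves open, decided here once: per-site baselines are
a two-component Beta mixture (the source states no distribution; the
parameters are configuration, not claims); `fracMethylatedSites`
and the low-Beta shape were set so the analytic global methylation of the
default world is ~0.85%, inside the reported 0.7–0.9% band, which also
reproduces ~3.7% raw calls once conversion failure is added. The mother
effect is drawn **per site and mother** on the logit scale and shared by
the mother's two replicates: per-locus epiallelic variation between
maternal lines. A single scalar shift per mother was rejected because at
a ~99%-unmethylated genome it carries almost no correlation signal and
cannot reproduce the observed mother-dominant clustering; the per-site
effect cancels in the paired differences either way. Planted DMR members
are re-drawn from the high component so hypomethylation always has a
methylated host; the treatment shift is additive on the proportion scale
and clipped to [0, 1] *after* the shift, so strong hyper effects on high
baselines saturate — visible in the recovered effect sizes. Planted SNPs
avoid DMR member sites so masking and recovery checks stay orthogonal.
Reads are simplified to one row per read covering one CpG plus 2–6
non-CpG cytosines; unconverted reads call every cytosine methylated.
Coverage is independent across sites and replicates (the pipeline never
uses fragment structure). Identical configuration and seed give
byte-identical output files.

What a green synthetic run does *not* establish: the generator has no
alignment error, no PCR duplicates, no m-bias, no fragment-level
correlation, and its Beta-mixture baselines are a stand-in — so passing
recovery tests validates the statistical machinery, not the upstream
read processing the source performed with external tools.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive throughout; BED output converts to
  0-based half-open at the boundary. Region length is defined as
  end − start, which matches three of the four printed reference
  intervals exactly; the fourth is internally inconsistent in the source
  by one bp and we keep the rule rather than guess intent.
- Forward and reverse CpG calls are not collapsed by default; an explicit
  flag sums p(+) with p+1(−).
- "Mean difference greater than 0.1" is a strict inequality on the
  absolute value.
- Scaffolds with fewer CpGs than the window minimum are smoothed with the
  whole scaffold as window, with a warning; an all-zero-coverage window
  yields NA.
- The Storey pi0 estimate uses the smoother method (spline of
  pi0(λ) over λ = 0.05…0.95, taken at the largest λ, clamped to (0, 1]).
- Ward.D2 is invariant to uniform scaling of the distance matrix; merge
  heights are checked against an explicit Lance–Williams trace in the
  tests.

## Known limitations

- weight01-style GO weighting is not implemented; significant-term
  agreement with the motivating study is not claimed.
- The smoother's iterative local-logistic refinement is not implemented;
  the one-step WLS approximation is the only fitting path.
- The real dataset's headline counts (8,764 candidates → 453 filtered →
  333 final) depend on the full 240-Mb genome and archived reads; they
  serve as conventions here, not targets.
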