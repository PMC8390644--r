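---
title: "Methods: interactor scoring and chromatin-state integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactor scoring and chromatin-state integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statepipe)
```

`statepipe` implements two linked analyses of naive versus primed human
embryonic stem cells (hESCs): calling bait-specific protein interactors
from replicated AP-MS spectral counts, and integrating chromatin
remodeler, transcription factor and histone-mark peak sets into
chromatin-state clusters with differential expression and accessibility
statistics layered on top. This vignette explains the statistical model
behind each stage, the parameters that matter, and the design choices
made where the procedure was genuinely open.

## Interactor scoring from replicated AP-MS

Each of $k$ replicate immunoprecipitation (IP) experiments yields, per
protein, a pull-down spectral count $x$ and a matched-control count $y$.
The scoring cascade is:

1. **Identification filtering.** Records must carry an identification
   score strictly above 10 and strictly more than 2 identified peptides;
   known contaminant families (keratins, actins, tubulins, trypsin) are
   removed by id. Duplicate records for a protein within an experiment
   collapse to the one with most bait counts — a tie rule the upstream
   description leaves open; maximum evidence is the conservative choice
   for a detection gate.
2. **Detection gate.** A candidate must survive step 1 in at least 3 of
   the 4 replicate IPs. This precedes all scoring: a protein seen twice
   with enormous counts is never scored.
3. **Contaminant-frequency filter.** Proteins observed in strictly more
   than 20% of CRAPome-style negative-control runs are removed *before*
   p-value computation, so frequent contaminants do not deflate the
   background either.
4. **Modified enrichment statistic.** $s = \dfrac{x}{y + c}\, x$ with
   control pseudocount $c = 1$ (configurable). Multiplying the
   pull-down/control ratio by the pull-down count rewards abundant bait
   evidence; the pseudocount keeps zero-control ratios defined. $s$ is
   strictly increasing in $x$ and decreasing in $y$.
5. **Empirical p-value.** Within each experiment,
   $p = \#\{s' \ge s\}/N$ over the statistics of all surviving
   candidates in that experiment, query included, so $p \in [1/N, 1]$.
   An experiment in which a (3-of-4) candidate went undetected
   contributes $p = 1$; $k$ is therefore always the roster size, which
   penalizes dropouts conservatively.
6. **Combined cumulative probability (CCP).** With
   $z = \prod_{i=1}^{k} p_i$, the CCP is the null probability that a
   product of $k$ independent $\mathrm{Uniform}(0,1)$ variables falls at
   or below $z$:
   $\mathrm{CCP} = z \sum_{j=0}^{k-1} \frac{(-\ln z)^j}{j!}$,
   computed through the equivalent upper $\mathrm{Gamma}(k, 1)$ tail of
   $-\ln z$ for numerical stability. For $k = 1$ it reduces to $p$; for
   all $p_i = 1$ it is exactly 1. This is the classical distribution of
   a product of uniforms; tests cross-check it against Monte-Carlo tail
   estimates at $10^6$ draws.
7. **FDR.** Benjamini–Hochberg across surviving proteins
   (Benjamini–Yekutieli by flag), call threshold $q \le 0.1$.

Empirical p-values are tied when counts tie; the within-experiment
background makes them mildly conservative (tied blocks inherit the block
maximum), which is visible only in the fourth decimal of the null ECDF
at desk scale.

## Interval algebra and peak accounting

Peaks use 0-based half-open BED coordinates on disk and `GenomicRanges`
in memory. Merging unions overlapping *and book-ended* intervals
(gap 0), matching default `bedtools merge` semantics, and is idempotent.
Reciprocal overlap follows the `-f 0.25 -F 0.25 -e` convention: a pair
qualifies when the intersection covers at least 25% of *either*
interval; the stricter both-intervals (AND) mode is a flag, because the
prose "covered by each other" and the flag semantics disagree and the
flags are the operational record. Two-state peak comparisons report a
single shared count — the merged union of qualifying intervals from both
sets — against both per-set denominators, plus the per-set qualifying
counts, since only the merged reading makes one numerator consistent
with two denominators. Target genes are assigned to the nearest TSS from
the peak midpoint $\lfloor (start+end)/2 \rfloor$ when the distance is
strictly below 20 kb, ties broken by lexicographically smaller gene id.
Overlap enrichment uses the one-sided (greater) Fisher exact test.
Reported percentages round half-up to one decimal, the convention of the
printed ratios this pipeline reproduces.

## Occupancy matrices and chromatin-state clusters

Over the merged peaks, each (mark, state) track contributes a binary
reciprocal-overlap flag and, when supplied, a mean-intensity value.
Clustering uses the intensity layer by default, each track normalized to
its 95th percentile and truncated at 1 to bound outlier peaks (binary
flags work unchanged as a fallback — both layers are supported because
the upstream description mentions both). Partitioning is ordinary
k-means (`stats::kmeans`), best of `n_restarts` random starts with
Lloyd iterations capped at `n_iter_max = 1000`, deterministic under an
explicit mandatory seed. The published configuration used $k = 10$ and
1000 restarts; the package default keeps the iteration cap and uses 50
restarts, which at the matrix sizes exercised here ($\le$ 10,000 rows,
8 tracks) reaches the same optimum in every test while keeping runs
interactive — the faithful restart count is one argument away. Empty
clusters follow `stats::kmeans` semantics (failed starts are simply
dominated by the remaining restarts) rather than bespoke re-seeding.

Cluster annotation is a pure function of centroids. Each centroid track
is first scaled by its maximum across clusters, so the rules read
*relative* enrichment regardless of the feature scale, then thresholded
at $\tau = 0.5$:

| class | OCT4 | H3K27ac | H3K4me3 | H3K27me3 |
|---|---|---|---|---|
| enhancer | high | high | low | low |
| active promoter | high | high | high | low |
| bivalent promoter | — | — | high | high |

A pattern holding in one state only yields a state-specific label
("naive enhancer", "primed enhancer"); holding in both yields "shared";
anything else is "other". On a degenerate structureless landscape all
clusters look alike after relative scaling and no enhancer or promoter
class is produced spuriously by the enhancer rules; annotation of such
input is not meaningful and the generator tests only assert the absence
of planted classes there.

## Differential expression

Expression matrices carry their quantification type: single-end RPKM
takes a +0.1 pseudocount, paired-end FPKM +1, applied exactly once (a
tracked flag). The low-expression filter drops genes with mean
$\log_2(\mathrm{FPKM}+1) < 1$ and must run before the pseudocount. DEGs
are called by an unpaired two-sided $t$-test — pooled variance by
default, Welch by flag — on pseudocounted values, significant when
$p < 0.05$ and the pseudocounted fold change exceeds 2 in either
direction. The fold change is computed on the same pseudocounted means
the test sees, so direction and threshold refer to one scale. Group
comparisons of expression distributions use the two-sided Mann–Whitney
test, exact for small tie-free samples and normal-approximated with tie
correction otherwise.

## Differential accessibility

Per-peak counts are normalized counts-per-million per sample and
$\log_2(x+1)$-transformed — a transparent, scale-invariant transform.
The per-peak test defaults to limma's moderated $t$ (empirical-Bayes
variance shrinkage, `trend = TRUE`): at the three replicates per group
typical of ATAC designs, per-peak variances carry 4 degrees of freedom
and an unmoderated $t$ cannot reach useful sensitivity at FDR < 0.05
after adjustment across thousands of peaks (measured ~0.12 against a
planted 8-fold depletion where the moderated test reaches ~1.0);
moderation is also what the standard differential-binding engines this
stage stands in for actually do. The unmoderated test remains available
as `engine = "t"`. Significance is $q < 0.05$ after BH.

One caveat is compositional: with total-count (CPM) normalization, a
knockout that depletes a large fraction of all peaks shifts the null
peaks' normalized values upward, so some nulls are called "up". At the
planted-landscape scale used in the tests (a third of peaks depleted)
losses still dominate the significant calls but do not reach the
$\ge 99\%$ share seen in real knockout data, where affected peaks are a
few percent of the genome-wide set.

Per-cluster expectations multiply the total significant count by each
cluster's share of all peaks; observed-versus-rest enrichment per
cluster uses the one-sided Fisher test on the (in cluster) ×
(significant) table. Expected counts are reported unrounded and sum to
the significant total exactly.

## The synthetic-data generators

Every generator is a pure function of its config (seed included) and
returns truth labels, so each pipeline stage carries a recovery test.

* **AP-MS**: spectral counts are negative binomial (dispersion $\phi$,
  variance $\mu + \phi\mu^2$; $\phi \to 0$ gives Poisson), background
  mean 20 — the modest counts of a sensitive MS platform — with true
  preys at `enrichment_fold` times that mean and contaminants matched
  between bait and control. 5% of records fail the identification gate;
  true preys drop out of an experiment with probability 0.1; 5% of the
  background is "sticky" with CRAPome frequency planted strictly above
  20%. Defaults mirror the 4-replicate design with ~30 genuine preys.
* **Peak landscape**: a 3-chromosome pseudo-genome (30 Mb) with
  disjoint peaks (one per 3-kb slot, log-normal widths around 500 bp)
  assigned to six planted classes — naive/primed/shared enhancers,
  shared active promoters, shared bivalent promoters, background — whose
  mark patterns follow the annotation rule table. Intensities are gamma
  with CV 0.25 around on/off means (signal/noise 10 by default), the
  variability of mean signal aggregated over a few hundred bp. 70% of
  class peaks get a TSS planted within 20 kb.
* **Expression / ATAC**: log-normal baselines with planted shifts of
  `effect_log2fc` (3 by default) and negative-binomial ATAC counts;
  planted labels can be placed at chosen peaks to emulate class-specific
  knockout effects.

What passing tests show — and what they do not: the generators carry the
*statistical* structure the pipeline assumes (replicated enrichment over
matched backgrounds, block-patterned occupancy, planted shifts), not the
messiness of real data. Real spectral counts share peptides across
proteins; real peaks overlap, vary in width by mark, and cluster along
the genome; real ChIP intensities have heavy tails and batch structure;
real accessibility changes are not binary. Recovery and calibration
results on these simulations validate the implementation, not the
biology of any particular dataset.

## Problem sizes and numerical choices

Test and acceptance runs use 2,000-protein null and 1,000-protein
planted AP-MS studies (20 and 50 seeds), a 3,500-peak six-class
landscape, and 5,000-gene/5,000-peak differential matrices — sizes at
which every Monte-Carlo tolerance in the suite is comfortably resolved
on a single CPU in a couple of minutes. Other numerical conventions:
percentages round half-up (not half-to-even) to one decimal; the CCP is
evaluated through `pgamma` rather than the alternating series; BH is
`stats::p.adjust`; Fisher tests are `stats::fisher.test`; k-means
determinism comes from a locally scoped seed that never touches the
caller's RNG state.

## Known limitations

* The CCP formula is the product-of-uniforms distribution; the original
  scoring description cites an external algorithm without restating it,
  so this is a documented interpretation, not a claimed replication of
  that code.
* The empirical-p background is the within-experiment score
  distribution of surviving candidates; a permutation null is not
  implemented.
* The DAR stage is a transparent substitute for version-dependent
  differential-binding packages; exact numeric replication of published
  DAR counts is not claimed, only the downstream arithmetic and
  enrichment logic.
* Mapping of k-means clusters to named classes is rule-based on
  centroid patterns; clusters with mixed or weak patterns fall to
  "other" rather than being forced into a class.
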