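---
title: "Frequent co-expression network mining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequent co-expression network mining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgcnminer)
```

## Why a frequency network

Co-expression modules inferred from one cohort conflate biology with
cohort-specific noise: batch structure, platform quirks, outlier samples.
When several cohorts profile the same disease, requiring a gene pair to be
strongly co-expressed in *multiple* cohorts is a simple, assumption-light
consensus filter. `fgcnminer` therefore works in three steps per cohort —
gene filtering, pairwise |PCC|, top-percentile edge selection — and then
pools cohorts by counting, not averaging: the consensus network's edge
weight is the *fraction of cohorts* in which the pair was a top-percentile
edge. Averaging correlations would let one enthusiastic cohort dominate;
counting treats cohorts symmetrically and keeps weights on the
interpretable scale \{1/D, …, 1\}.

### Gene filtering

Genes with a zero in **more than** half of a cohort's samples are removed
(the boundary case, exactly half, is retained — the rule is a strict
inequality), and analysis is restricted to protein-coding genes when an
annotation is supplied. Genes missing from the annotation are treated as
non-coding: they are dropped under coding-only filtering, and when kept
(coding filter off) they participate in network mining but never in
cytoband enrichment, where an unannotated gene cannot be assigned to a
band. Filtering is per cohort; the network's node set is the intersection
of the per-cohort filtered gene lists. The alternative order — intersect
first, then filter — is a legitimate choice, but per-cohort filtering uses
each cohort's own detection profile and is what the per-cohort zero rule
naturally implies.

### Edge selection

"Top 5 percentile" is realized as a nearest-rank rule: with `n` gene pairs,
the threshold is the `ceiling(q·n)`-th largest off-diagonal |PCC|, and
**all pairs at or above the threshold are kept**, so ties at the boundary
are included rather than arbitrarily split. On a vector of 100 distinct
values 0.01…1.00 at q = 0.05 this keeps exactly the top five (threshold
0.96). Supersets are the safe direction for a frequency network: a pair
wrongly included in one cohort still needs support elsewhere to carry
weight. Correlations can be computed on the matrix as provided or on
`log2(x + 1)` (the pipeline default for linear-scale input, matching
standard practice for expression data). Zero-variance genes cannot be
correlated; they are excluded from that cohort's edge set with a warning
but still count as network nodes.

## The lmQCM miner

The frequency network is mined with the local maximal quasi-clique merger.
Its tunables, with defaults chosen to produce small, dense modules:

| parameter | default | meaning |
|-----------|---------|---------|
| `gamma`   | 0.7     | an edge may seed a cluster only if its weight is ≥ `gamma · max(w)` |
| `lam` (λ) | 1.0     | density-decay factor: larger λ relaxes admission faster as clusters grow |
| `t`       | 1.0     | size offset in the decay schedule |
| `beta`    | 0.4     | overlap ratio (relative to the smaller cluster) above which two clusters merge |
| `min_size`| 10      | smallest reported module |

Seeds are edges that are **locally maximal** — at least as heavy as every
edge sharing an endpoint, ties counting as maximal — and at least
`gamma · max(w)`. Because `gamma` is relative to the maximum weight, the
miner is invariant to rescaling all weights by a constant: mining raw
occurrence counts or normalized frequencies gives identical modules (this
is asserted as a property test). From each seed `{u, v}` the cluster
greedily admits the outside vertex with the largest total edge weight into
the cluster, accepting while

$$\frac{S(v)}{|C|} \;\ge\; \left(1 - \frac{1}{2\lambda(|C|+t)}\right) d(C),
\qquad d(C) = \frac{2\sum_{e \in C} w_e}{|C|(|C|-1)},$$

and stopping at the first rejection. Ties in candidate connectivity are
broken lexicographically by gene identifier, as are seed-order ties, so
the full procedure is deterministic: identical inputs give byte-identical
outputs.

**Merge order.** Grown clusters smaller than `min_size` are discarded
*before* overlap merging. This ordering matters: a background gene with a
single strong edge into a real module grows into a two-gene cluster whose
overlap with the module is 1/2 — always above `beta` — so merging before
size filtering would systematically leak one-edge noise genes into every
module. Filtering first confines merging to clusters that are themselves
substantive. Merging repeats until no pair of clusters exceeds `beta`,
rescanning from the largest cluster after each union; final modules are
ranked by size, ties by density and then by first gene.

## Differential expression

The two-group test is Welch's unequal-variance t on log2-scale values,
with Welch–Satterthwaite degrees of freedom, BH correction across all
tested genes of a cohort, and a fold-change gate: a gene is `up` only when
`q < 0.05` **and** `log2fc > log2(1.5)` (both strict; `down` symmetric).
The fold change is the difference of group means on the log2 scale. Two
conventions for degenerate genes: identical constant groups give p = 1;
groups constant within but different between are tested with a variance
floor of 1e-12 so the direction still registers. A moderated-variance
model would borrow strength across genes and gain power at small n; the
Welch test was chosen because it is self-contained, exactly testable
against closed-form oracles, and sits behind a single function boundary
(`de_two_group`) where a moderated variant could be substituted. BH runs
genome-wide (all filtered genes of the cohort), and module-level results
subset that one table — computing BH per module would make a gene's
q-value depend on which module is being inspected.

## Enrichment machinery

All enrichment tests share one kernel: the hypergeometric upper tail
`P[X ≥ a]`, i.e. the one-sided (greater) Fisher exact test —
over-representation is the only direction of interest. Three families use
it with deliberately different multiplicity conventions:

- **module–DEG enrichment**: raw p < 0.05 per module; a module is
  "consensus significant" only when enriched in every discovery cohort;
- **cytoband enrichment**: BH FDR < 0.05 across all bands tested for a
  module, since dozens of bands are screened at once;
- **upstream regulators**: raw p < 0.01 plus two structural criteria —
  the regulator must be an annotated transcription factor, and its
  targets must cover strictly more than 10% of the module. Coverage of
  exactly 10% fails; an activation score is deliberately out of scope, so
  these three criteria fully determine candidacy.

The enrichment universe is pinned to the frequency network's node set
(genes that survived filtering in every cohort): these are the only genes
that could have entered a module, so they are the correct background for
"is this module special". A wider universe (all filtered genes) is
available as an option; p-values shrink slightly with universe size, which
is exactly why the default is the defensible smaller set.

## Copy number and concordance

Per-gene differential copy number uses the Wilcoxon rank-sum test — exact
when the combined sample size is at most 12 with no ties (validation-sized
cohorts), otherwise the normal approximation with midranks, tie correction
and continuity correction. Direction comes from the group-mean difference
(medians available as an option), and calls use raw p < 0.05 with no
multiplicity correction: at validation cohort sizes (a dozen samples) the
exact test's granularity already bounds how small p can get, and the
module-level Fisher test is where inference is aggregated. Because only
ranks and mean differences are used, the copy-number scale (absolute
copies vs log-ratio) never needs to be known.

A gene is **concordant** when its copy-number call and expression status
point the same way in the same comparison (amplified & up, or deleted &
down). Concordance is gene-level, so the CN and expression matrices only
need to share genes, not samples.

## The synthetic cohort generator

`generate_cohorts()` emulates a multi-cohort study: `D = 3` discovery
cohorts (20 FN vs 15 FP samples each) plus a validation cohort (8 FN vs
4 FP) carrying a matched gene-level CN matrix — validation group sizes
mirroring the small clinical validation cohorts typical of rare-tumor
studies. Per cohort and sample, each planted module draws a fresh latent
factor `f ~ N(0,1)` shared by its genes; baseline log2 expression is
`Uniform(3, 8)` per gene; residual noise is `N(0, 0.5)`. With unit
loadings this yields within-module correlations near
`1/(1 + 0.5²) = 0.8` — comfortably inside a top-5-percentile regime but
not degenerate. Factors are redrawn per cohort on purpose: individual
correlation *values* do not recur, only the co-expression *structure*
does, so it is the frequency network, not any single cohort, that
identifies consensus modules.

Three planted drivers:

- **cnv**: 30 genes contiguous on one synthetic cytoband gain `amp = +1`
  copy in FN samples (CN noise SD 0.05), with expression coupled at
  `coupling = 0.5` log2 units per copy;
- **tf**: 25 scattered genes track a dedicated regulator gene (excluded
  from its own module, flagged `is_tf`) whose expression shifts by +1.5
  log2 units in FN; targets follow the regulator's per-sample deviation
  with strength 1 — so target co-expression has both a latent-factor and
  a regulator component;
- **neutral**: 20 genes with factor structure only.

Plumbing realism: a designated decoy gene set is zeroed in >50% of
samples (so the zero filter provably fires), ~2% of background entries
are zeroed, a slice of background genes is annotated non-coding, and
decoy TFs with random targets populate the TF→target table. All
randomness flows from the single integer seed; identical seeds give
byte-identical fixture files.

What the generator does **not** emulate: count-based (negative binomial)
noise, batch effects, platform differences, correlated background
structure, or LD-like dependence between nearby background genes. Passing
recovery tests therefore demonstrates the machinery is correct and
calibrated under the stated model — not that real cohorts of this size
would yield equally clean modules.

## Problem sizes used in the test suite

Unit tests run on reduced cohorts (600 genes) for speed; recovery and
calibration properties run at the generator's default scale — 2000 genes,
3 discovery cohorts, 20-seed sweeps, 20 null-cohort sweeps, 1000 null
genes for DE calibration and 100 scattered-module draws for cytoband FDR
control. Oracle-equivalence tests are exhaustive where enumeration is
cheap: all hypergeometric margins with N ≤ 30, all rank-sum splits up to
n = 10, and 100 random graphs of ≤ 12 nodes replayed step by step against
a naive loop-based miner.

## Known limitations

- **Concordance power at default effect sizes.** The planted +1 copy at
  0.5 log2 units per copy implies a true expression shift of 0.5 log2
  units — a linear fold change of 1.41, strictly below the 1.5-fold DEG
  gate. Compounded with per-gene variance from the unit-loading latent
  factor (per-sample SD ≈ 1.12) and the small validation cohort, planted
  cnv-module genes are essentially never called differentially expressed,
  and the measured concordant fraction on the default synthetic cohort is
  ~0 even though ~100% of those genes are correctly called CN-amplified
  and the module-level CNV enrichment is decisive. This is a real
  interaction between the fold-change gate and modest per-copy coupling,
  worth remembering when interpreting concordance counts on real data:
  gene-level concordance demands effects large enough to clear *both*
  gates individually.
- The Welch test does not moderate variances; at very small n it is
  conservative relative to empirical-Bayes approaches.
- Regulator screening conditions on the supplied TF→target table; the
  table's universe (curated database vs dataset) changes p-values, and no
  attempt is made to harmonize the two.
- Occurrence counting uses a fixed denominator `D` (total cohorts); a
  per-pair denominator is available for gene sets that differ wildly
  between cohorts, at the cost of comparability between edges.
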