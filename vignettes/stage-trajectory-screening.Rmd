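---
title: "Stage-trajectory screening: model, parameters and design choices"
author: "trajscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-trajectory screening: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscreen)
```

## The screening model

Tumor progression is treated as an ordered series of disease stages — here
the seven-group colorectal-cancer design: normal mucosa, primary-tumor
stages I–IV, liver metastasis, lung metastasis. The screen asks, for each
gene, how far along that series its expression keeps moving in one
direction.

For every adjacent stage pair (transition) $j$ the two groups are compared
with a two-group one-way ANOVA on log2 expression — F on $1$ and
$n_a + n_b - 2$ degrees of freedom, identical to the squared pooled-variance
t statistic — with an asymptotic p-value from the F distribution, Bonferroni
family-wise correction over the $m$ genes tested within that transition, and
a linear fold-change filter. A gene enters the up (down) DE set $S_j$ of the
transition if its adjusted p-value is below $\alpha$ and its linear fold
change is above (below) 1 and beyond the threshold.

The core construction is a cumulative intersection. With $S_1, \dots, S_K$
the direction-matched DE sets of the $K$ transitions, the *continuing* set at
stage $k$ is

$$C_k = \bigcap_{j=1}^{k} S_j,$$

the genes significantly regulated in the same direction in every comparison
up to transition $k$; the series is nested by construction. The *deviated*
set at the transition from stage $k$ to stage $k+1$ is the complement within
the trend:

$$D_k = C_k \setminus C_{k+1}, \qquad |C_k| = |C_{k+1}| + |D_k|.$$

Deviated genes are the screen's unit of stage-specific biology: they mark
the point in progression at which a gene stops participating in the shared
trend. A deviated set is indexed by the *earlier* stage of its transition —
if 357 genes continue at stage I and 242 at stage II, the 115 deviated genes
sit on the stage-I row. The disjoint-union identity above is enforced by the
`TrajectoryResult` validity method and re-verified by `countTable()` before
any table is emitted.

Continuing sets are then restricted to a subcellular compartment — by
default the extracellular matrix/space (union of two GO CC terms) for the
up screen and the mitochondrion for the down screen — which preserves
nesting, so the filtered family is again a valid trajectory. Deviated sets
are tested for GO biological-process over-representation with the one-sided
hypergeometric upper tail

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

against the background of genes present in both the annotation and the
expression matrix (restricting the universe to the measured genes avoids
inflating enrichment). Bonferroni over the tested terms is the default
correction, matching the correction philosophy of the DE screen;
Benjamini–Hochberg is available.

Finally, the genes of each compartment trajectory are mapped onto a
protein–protein interaction network read from a STRING-dialect edge table,
keeping only edges with positive evidence on a chosen channel
(`experimental` by default, emulating an experimentally-verified-only
network). Two analyses run on the induced graph:

* **Molecular complex detection** re-implements the MCODE procedure: each
  vertex is weighted by $k_{max} \cdot density$ of the highest k-core of its
  closed neighborhood; complexes grow from high-weight seeds, admitting
  neighbors with weight at least $w_{seed}(1 - vwp)$; complexes lacking a
  2-core are discarded; the haircut pass strips degree-1 members; module
  score is $density \times size$.
* **Hub subnetworks** keep the nodes whose parent-graph degree falls in a
  configured band (the published analyses used 8–18 and 8–19), and
  `keyChain()` extracts the simple path through the hub subgraph maximizing
  the summed parent degrees — a deterministic stand-in for reading a signal
  route off a hierarchical layout. It is exhaustive (branch-and-bound) and
  guarded to 25 hubs; ties go to the longer path, then the lexicographically
  smallest sequence. Because the manual layout step it replaces has no
  formal criterion, chain output is reported but never used as a numeric
  benchmark.

## What the synthetic generator emulates

`simulateExpression()` produces already-normalised log2 intensities over a
stage design whose defaults are the study's group sizes
(54, 28, 50, 49, 58, 47, 20). Three gene classes are planted:
`continuous_up` genes whose population mean rises by `effect` log2 units at
every transition up to their drop stage $d$ and is flat after,
`continuous_down` mirrored, and flat `null` genes. The truth table records
class and $d$, so a correct screen puts the gene in $C_d$ and, for $d < K$,
in $D_d$ — the alignment every recovery test relies on.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `effect` | 1.5 log2 units/transition | a strong, clearly detectable per-stage shift at the study's group sizes |
| `sigma` | 0.5 log2 units | typical within-group spread of log-scale array intensities |
| baseline | Normal(8, 1.5) | the intensity scale of a normalised expression microarray |
| class fractions | 0.1 / 0.1 / 0.8 | a minority of trending genes over a null majority |
| drop schedule | uniform over 1..K | no stage is privileged a priori |
| `nGenes` | 1000 | large enough for stable rates, small enough for desk-scale runs |

Class counts are fixed by largest-remainder rounding, gene ids are
lexicographic (`g000001…`), and identical seed plus parameters regenerate
every artifact byte-for-byte; `simulateDataset()` fans one top-level seed
out to per-stage sub-seeds so each component is individually reproducible.

`simulateAnnotations()` plants compartment labels (extracellular on up
genes with probability `pUp`, mitochondrial on down genes with `pDown`,
uniform `background` elsewhere) and BP terms with configurable class
enrichment. `simulateInteractions()` plants near-cliques among non-null
genes over an Erdős–Rényi background and emits a STRING-dialect table with
integer channel scores.

What the generator does **not** emulate: probe-to-gene mapping, array
normalisation, batch effects, heteroscedastic or correlated noise, partial
(fuzzy) continuity, and the GO graph structure (annotations are flat; no
true-path propagation). Passing recovery tests therefore demonstrate the
procedure's correctness under its own assumptions, not robustness to those
real-data complications.

## Numerical and design choices

* **Fold change** is the ratio of group means taken after back-transforming
  each sample to the linear scale. The alternative ($2^{\Delta \bar{x}}$,
  the geometric-mean ratio) differs only by a noise-dependent factor and
  does not change directions; one convention is used everywhere.
* **Fold-change threshold 1** means direction-only filtering; significance
  does the selecting. This matches the regime where inter-stage differences
  are small — a threshold of 2 empties the inter-stage DE sets (and
  `selectDE()` is monotone in both $\alpha$ and the threshold, which the
  suite checks). The threshold is a config knob.
* **Bonferroni scope** is per transition ($m$ = genes tested in that
  comparison), since each stage pair is screened as its own family; the
  correction is a plain multiply-and-cap, so any joint scope can be had by
  rescaling $\alpha$.
* **Degenerate tests are defined, not errors**: zero pooled variance with
  equal means gives $F = 0, p = 1$; with separated means, $F = \infty$ and
  p floored at the smallest positive double (p-values are never reported
  as 0).
* **Effect = 0 is legal** and documented as the generator's global-null
  mode; negative effects are rejected.
* **MCODE specifics**: simple-graph density $2E/(V(V-1))$ without loops,
  defaults vwp = 0.2, haircut on, fluff off, minimum 2-core — the plug-in's
  published defaults. One deliberate deviation: when fluff is enabled, only
  vertices not already assigned join a complex, keeping complexes pairwise
  disjoint (the original allows overlap); fluff is off by default, so the
  default path is unaffected.
* **Ranking ties** (modules: score, then size, then seed id; chains: sum,
  then length, then lexicographic) are fully specified so output is
  deterministic and diffable; gene sets are serialized sorted.
* **Respiratory-chain exclusion** is generalised to `removeTermNodes()` —
  removing all nodes carrying one GO term — so the published step is one
  configuration of a general operation.

## Problem sizes used by the test suite

The suite works at sizes chosen to exercise the asymptotics the methods
rely on while staying desk-scale: the conservation identity on 1,000 random
6-transition instances over 2,000 genes; the $F = t^2$ identity on 10,000
random draws (tolerance 1e-10); family-wise error under the global null
over 2,000 simulated datasets of 20 genes; MCODE weights against a
brute-force closed-neighborhood core-decomposition oracle on 100 random
graphs of up to 200 nodes; planted 6-clique recovery over 20 generator
seeds (top-module Jaccard, mean ≥ 0.8); and trajectory recovery at the
study's sample sizes over 10 seeds with 1,000 genes (≥ 95% of planted genes
recovered, ≥ 90% assigned their exact deviation transition).

## A worked run

```{r, eval = FALSE}
cfg <- defaultConfig(seed = 1)
report <- runPipeline(cfg)
report$trajectory$extracellular_up
```

The report carries per-transition DE counts, the four trajectory count
tables (both directions, full and compartment-filtered), top enriched BP
terms per deviated set, module and hub summaries, and provenance (seed and
config hash), and regenerates identically from the same configuration.

## Known limitations

* The published absolute gene counts from the original microarray study
  (e.g. 3,968 genes up-regulated at stage I) and the database-derived hub
  degrees (FN1/MMP2 at 18, CAV1 at 19) depend on an external accession,
  probe-set curation and an interaction-database version; they are
  replication notes, not things this package can or does reproduce. What
  *is* reproduced exactly is the set arithmetic of the published
  compartment series: continuing counts (357, 242, 131, 79, 21, 10) imply
  deviated counts (115, 111, 52, 58, 11), and (415, 230, 114, 68, 50, 19)
  imply (185, 116, 46, 18, 31).
* Enrichment has no numeric published benchmark (the original analysis
  reports terms qualitatively), so its guarantees are property-based:
  exact agreement with draw enumeration, PMF normalisation, super-uniform
  null p-values, and recovery of planted term/class enrichments.
* No multi-group ANOVA across all stages at once, no moderated variance,
  no paired designs, no fuzzy continuity, no GO propagation, no
  identifier mapping, no layout.
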