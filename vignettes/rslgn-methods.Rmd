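---
title: "Methods: screening, network assembly and topology in rslgn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, network assembly and topology in rslgn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rslgn)
```

## The analysis this package implements

rslgn re-implements, as tested and reusable functions, a liver-transcriptome
analysis of diabetic rats treated with resistant starch (RS) against untreated
diabetic controls (CK). The pipeline has five stages:

1. **Differential-expression screen.** Per-gene linear fold change
   (mean RS intensity / mean CK intensity) combined with a SAM-style
   permutation test: a gene is called regulated when its ratio is `>= 2` or
   `<= 0.5` *and* its permutation Q-value is `<= 5%`. Both thresholds are
   inclusive.
2. **Disease-gene mapping.** The regulated genes are intersected with a
   disease-associated gene list (in the original study, a diabetes query
   against a curated rat genome database; here, any list of symbols).
3. **Local gene network (LGN) assembly.** A typed graph linking the
   disease-associated regulated genes to the pathways that contain them, and
   pathways to each other where they share member genes (or where an explicit
   printed link list says so).
4. **Topology characterization.** Degrees, average shortest-path length and
   clustering coefficient of the main component, component decomposition, and
   a heuristic power-law fit to the degree distribution.
5. **Metabolism-module profiling.** Ordered gene lists for glucose and lipid
   metabolism ("in the order the genes appear in the metabolic process") with
   attached ratios and direction summaries.

A seeded synthetic-data generator stands in for the original microarray data,
which were never deposited; the generator's ground truth is what the test
suite screens against.

## The screening statistic

Fold change is computed on the linear scale, matching the ratio convention of
the published tables; the d-statistic is computed on log2 intensities,
matching the convention of significance analysis of microarrays (SAM). For
gene $g$ with group means $\bar{x}^{RS}_g, \bar{x}^{CK}_g$ on the log2 scale:

$$ d_g = \frac{\bar{x}^{RS}_g - \bar{x}^{CK}_g}{s_g + s_0}, \qquad
   s_g = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
   \frac{\sum_{i}(x_{gi}-\bar x^{CK}_g)^2 + \sum_{j}(x_{gj}-\bar x^{RS}_g)^2}
        {n_1+n_2-2}} $$

an unpaired two-class statistic with equal-variance pooled standard error —
the design is independent control vs treatment animals. The fudge factor
$s_0$ damps the statistic of low-variance genes. It is chosen by a
Tusher-style grid search: candidates are the 0th, 5th, ..., 95th percentiles
of the $s_g$ distribution; genes are split into ten equal-count bins of
$s_g$; within each bin the spread of $d$ is summarized by its median absolute
deviation; the candidate minimizing the coefficient of variation of those
spreads is selected, smallest percentile on ties. The procedure is fully
deterministic given the matrix.

### Permutation Q-values

For every threshold $t$ among the observed $|d|$ values the false-discovery
rate is estimated as

$$ \widehat{FDR}(t) = \pi_0 \cdot
   \frac{\mathrm{median}_b\,\#\{|d^{*}_b| \ge t\}}{\#\{|d| \ge t\}} $$

with $d^{*}_b$ the statistics recomputed under the $b$-th permutation of
group labels ($s_0$ held fixed). A gene's Q-value is the smallest
$\widehat{FDR}(t)$ over all thresholds at which the gene would still be
called ($t \le |d_g|$), clamped to $[0,1]$; this is the usual
min-over-rejection-regions construction and automatically makes Q monotone
nonincreasing in $|d|$.

Two numerical choices matter:

* **$\pi_0 = 1$ by default.** The quartile-based plug-in estimator of the
  null proportion is available (`pi0 = "estimate"`), but with 3–4 replicates
  per group it is noisy; the conservative fixed value is the default.
* **Exhaustive enumeration when feasible.** With $n_1 + n_2$ samples there
  are $\binom{n_1+n_2}{n_1}$ distinct label assignments (20 for 3v3, 70 for
  4v4). Whenever that count is at most `n_permutations` all assignments are
  enumerated, making the Q-values exactly reproducible with no sampling
  noise; otherwise distinct assignments are sampled without replacement under
  the run seed (falling back to independent shuffles only when the assignment
  space is too large to enumerate, above $10^5$).

The screen applies both gates inclusively (`>=`, `<=`) exactly as printed.
When only a table of published ratios is available, the Q gate is waived
(`q_values = NULL`), which reduces the screen to the fold-change rule — this
is how the packaged 17-gene table reproduces its 7 up / 10 down split.

### Hierarchical clustering

The global expression-pattern view uses agglomerative clustering with
distance $1 - r$ (Pearson correlation of log2 profiles) and average (UPGMA)
linkage, via `stats::hclust`. Tie-breaking among equal-height merges follows
the `hclust` convention; ties have probability zero for continuous data and
the test oracle (a naive $O(n^3)$ agglomeration) compares merge heights,
which are tie-invariant. A zero-variance profile would make the correlation
undefined; its correlations are set to 0 with a warning so the item clusters
last rather than aborting the run.

## Network assembly

The LGN is a typed undirected graph: gene nodes carry a `regulation`
attribute (`up`, `down`, or `none` for disease genes that participate in an
included pathway without being regulated), pathway nodes carry display
names; edges are `membership` (gene–pathway) or `pathway_link`
(pathway–pathway). Design choices, made where the source material states no
rule:

* **Inclusion rule.** A pathway enters the network iff it contains at least
  one disease-associated regulated gene — the network is anchored on the
  regulated genes, which is how the published figure is drawn.
* **Derived vs explicit links.** By default two included pathways are linked
  iff they share at least one member gene in the annotation. An explicit link
  list, when supplied, overrides derivation entirely; this is what allows the
  printed forkhead-hub substructure (one pathway linked to eight others) to
  be reconstructed exactly even though the full annotation behind the
  original figure was never published.
* **Undirected throughout.** The source network draws no edge directions.
* **Symbol matching.** Case-insensitive after whitespace trimming, original
  spelling preserved for output. The published tables themselves disagree on
  one spelling (`Cpt1a` vs `Cptla`, a digit-for-letter transcription
  variant); the fixture records the pair as aliases without asserting
  identity, and the lipid-module profile consequently reports `Cptla` as
  unmeasured rather than silently merging it.

Component decomposition orders components by decreasing node count, ties
broken by the lexicographically smallest minimum node id, so "the main
network" is always unique; pathway nodes outside it are the isolated
pathways.

Because the published degree anecdotes mix one-mode views (a gene
participating in ~3 pathways is a bipartite degree; the forkhead hub's
degree of 8 counts pathway–pathway links), topology is always reported for
three views: the full typed graph, the gene–gene projection (genes joined
iff they share a pathway) and the pathway–pathway projection (shared member
or explicit link). One subtlety the tests encode: derived pathway links may
pass through genes that are not themselves in the network, so the gene–gene
projection can have more components than the full graph — what projections
are guaranteed never to disconnect is co-membership.

## Topology metrics

* **Average path length**: mean BFS distance over unordered connected pairs
  *within the main component*; adding an isolated node therefore never
  changes it. Undefined (reported as `null` in JSON) when the main component
  has no edges.
* **Clustering coefficient**: Watts–Strogatz convention; local clustering
  $2\,\Delta_v / (k_v(k_v-1))$ for degree $\ge 2$, nodes of smaller degree
  contribute 0 and are counted; global value is the mean over main-component
  nodes.
* **Scale-free diagnostic**: ordinary least squares of $\log_{10}$ count on
  $\log_{10}$ degree over degrees $\ge 1$; the exponent is minus the slope.
  This is the classic visual diagnostic, not a hypothesis test, and it
  refuses (returns missing) below three distinct degrees. No
  maximum-likelihood power-law machinery is attempted: the claim it supports
  is qualitative.

All graph primitives (components, shortest paths, triangle counts,
projections) are computed with igraph; the test suite checks every metric
against independent brute-force oracles (union-find, vectorized
Floyd–Warshall, explicit triangle enumeration, double-loop projection) to
$10^{-12}$ on random graphs.

## The synthetic-data generator

The generator emulates the study design the pipeline assumes: two groups,
small $n$, log-normal summarized intensities.

| parameter | default | why |
|---|---|---|
| `n_genes` | 1000 | desk-scale stand-in for a genome-wide array; large enough for stable FDR behavior, small enough that the full suite runs in seconds |
| `n_per_group` | 4 | "3 or more biological replications" is the design floor; 4 gives 70 distinct label assignments, enough for exhaustive permutation |
| `frac_up`, `frac_down` | 0.05 each | ~10% regulated genes total keeps both planted and null sets large at $n=1000$ |
| `fc_up`, `fc_down` | 2.5, 0.4 | clearly beyond the 2.0 / 0.5 screen bounds, so recovery is attainable but not trivial at the noise level |
| `noise_sd_log2` | 0.25 | typical replicate-level scatter of RMA-summarized arrays |
| `baseline_log2_mean`, `baseline_log2_sd` | 7, 1.5 | RMA-like intensity range (~2^3–2^11) |
| `n_pathways`, `pathway_size_range` | 38, [3, 15] | mirrors the 38-pathway annotation scale of the original network |
| `frac_disease_genes` | 0.05 | a curated disease query returns a few percent of a genome; at this scale ~3–5% of regulated genes land on the list, proportionally consistent with the original 17 of 370 |

Intensities are $2^{\text{baseline}+\text{noise}}$ with the planted fold
change applied *multiplicatively* to the RS samples. The multiplicative form
is deliberate: for fold changes that are powers of two — exactly the screen's
boundary values 2 and 0.5 — scaling commutes with floating-point rounding, so
the noiseless sample ratio equals the planted value bit-exactly and the
inclusive screen recovers the planted sets exactly, a property the tests
assert. Effects are applied to RS only; CK is the reference, matching the
ratio orientation of the published tables. One integer seed drives all
draws, with fixed offsets per artifact (expression: seed; pathways: seed+1;
disease list: seed+2) so artifacts are individually reproducible; the RNG
state of the caller is saved and restored.

**What the generator does not emulate:** probe-level structure, spatial array
artifacts, normalization residuals, correlated gene blocks, or
intensity-dependent variance. Passing tests therefore demonstrate that the
statistics behave correctly under the stated model, not that they are robust
to every failure mode of real arrays.

## What is reproduced, what is re-derived

The quantities the packaged fixtures support are reproduced exactly: the
17-gene table screens to 7 up / 10 down; the forkhead hub has pathway-link
degree 8; the glucose and lipid modules profile to 13 and 12 genes with
exactly two glucose genes passing the screen (G6pc up, Gck down). The
genome-wide counts (370 regulated of 31,041) and the whole-network metrics
of the original figure (average degree ≈ 3.0, path length 3.68, clustering
0.26, 31 + 7 component split) depend on raw arrays and a full pathway edge
list that were never published; they can only be re-derived on user-supplied
data. In their place the suite checks properties: exhaustive-permutation
equivalence of Q-values on small designs, the pure-null false-call rate
(mean fraction of genes at $Q \le 0.05$ within nominal plus two Monte-Carlo
standard errors over 200 simulations at 1000 genes, 3v3), planted-truth
recovery (sensitivity $\ge 0.8$, FDR $\le 0.15$ under the default
simulation), oracle agreement of every topology metric on random graphs of
up to 50 nodes, and exact noiseless recovery. Problem sizes (1000 genes,
3–4 replicates, 200 null runs, 50 random graphs) are the package's chosen
desk scale: large enough for the Monte-Carlo bounds to be meaningful,
small enough to keep the whole suite interactive.

## Degenerate inputs and edge behavior

* Readers reject rather than repair: duplicate identifiers, non-positive or
  non-numeric intensities and unknown group labels are format errors naming
  the offender. The single documented repair is GMT member deduplication
  (with a warning), since redundant members are common in hand-maintained
  set files.
* A matrix with one replicate per group cannot support the d-statistic; the
  error message directs to fold-change-only screening rather than silently
  degrading.
* An all-zero standard-error distribution (noiseless data) yields $s_0 = 0$
  with a warning; the d-statistic is defined as 0 where the denominator is 0.
* An empty disease intersection is a legitimate result (warning, empty
  network), not an error.
* JSON reports print undefined metrics as `null`, never as a sentinel number.

## Orchestration

`run_pipeline()` executes the stages in order (skipping simulation when real
inputs are given, skipping screening when a pre-screened table is given),
writes every artifact under one output directory, and returns a manifest
with a config fingerprint (FNV-1a over the serialized configuration,
excluding the output path), the seed, per-stage output paths and headline
numbers. A failing stage aborts with the stage name and leaves a
`<stage>.partial` marker. The numbered scripts under `analysis/` are thin
narrative drivers over these same functions; the interface of the package is
its functions, these scripts, and this document.
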