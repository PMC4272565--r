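---
title: "Window co-occurrence PPI prediction: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window co-occurrence PPI prediction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipeppi)
```

## The model and its assumptions

pipeppi predicts physical protein–protein interactions from primary
sequence alone, on the premise that a useful fraction of interactions is
mediated by short linear polypeptide regions. The evidence base is a
database of known interactions: an undirected graph $G$ whose vertices are
proteins and whose edges are independently verified interactions. For a
query pair $(A, B)$, each protein is decomposed into its overlapping
length-$w$ windows. Window pairs are compared with the PAM120 substitution
matrix (ungapped, position-wise sums); two windows *match* when their score
strictly exceeds $\theta_{sim}$. The landscape matrix
$H \in \mathbb{N}^{(|A|-w+1)\times(|B|-w+1)}$ counts, per window pair
$(a_i, b_j)$, across how many database edges $(X, Y)$ the two windows
co-occur — $a_i$ matching somewhere in $X$ and $b_j$ somewhere in $Y$.

Three assumptions are built in. First, interaction evidence is *local in
sequence*: no structural context, no non-contiguous contact patterns.
Second, evidence is *transferable across the database*: a window pair seen
together on any known edge is evidence for any query pair containing
similar windows. Third, the database is *trustworthy*; false edges inject
false co-occurrence signal directly.

### Landscape dimensions and counting

The window-start indexing makes $H$ a $(|A|-w+1)\times(|B|-w+1)$ matrix;
indexing by fragments is the only self-consistent reading of the procedure
(the alternative, $|A| \times |B|$, would leave $w-1$ rows and columns
undefined). Both orientations of every undirected edge are considered —
$X$ against the rows and $Y$ against the columns, and vice versa — which is
exactly what makes $H(A,B) = H(B,A)^\top$ and hence the score symmetric in
the query pair. A per-cell value is therefore bounded by $2\,|E|$. Counting
is *per edge* by default: a matched edge contributes 1 to a cell no matter
how many window occurrences support it on either side. The alternative,
counting every pair of matching window occurrences (`count_mode =
"per_occurrence"`), is retained for sensitivity analysis; it inflates cells
for repetitive sequences.

The candidate list $R_i$ (the union of graph neighbors of all proteins
containing a window similar to $a_i$) is computed per fragment, not
accumulated globally across fragments. A global list would let fragment
$a_1$'s matches license co-occurrence counts for $a_{200}$, inflating the
landscape with cross-fragment evidence that the per-edge definition above
never intends.

### Filter, score and decision

The modified median filter maps $H$ to a binary matrix: a cell becomes 1
exactly when a *strict majority* of its in-bounds Moore neighbors (radius
`filter_radius`, default 1, center excluded) are positive. "Most of the
neighbors" is read as a strict majority; border cells are judged against
their in-bounds neighbors only, so no phantom zero-padding dilutes edges of
the landscape. The filter suppresses isolated co-occurrence cells (noise
from chance window matches) while preserving contiguous diagonal bands, the
signature of a shared motif. The PIPE score is the mean filtered cell — the
fraction of the landscape covered by coherent signal — and the pair is
called interacting when the score strictly exceeds `theta_dec`. All
"above a threshold" comparisons in the package are strict (`>`), applied
uniformly to window similarity, decision thresholds, glom connectivity and
merge overlaps (with one deliberate exception for approximate merging,
below).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `w` | 20 | residues | window length; shorter windows match promiscuously, longer ones miss degenerate motifs |
| `theta_sim` | 35 | PAM120 score | window-match threshold; at $w=20$ a random window pair scores far below 0 on average, while identical motifs score ≈ 100 |
| `filter_radius` | 1 | cells | Moore-neighborhood radius of the median filter |
| `theta_dec` | 0.005 | score fraction | standalone decision threshold; superseded by an operating point in any calibrated use |
| `count_mode` | per_edge | — | landscape increment rule |
| ambiguity score | −8 | PAM120 score | substitution score for letter pairs absent from the matrix (U, O); −8 is in line with PAM120's worst mismatches |

`w` and `theta_sim` are the values used throughout the PIPE method family;
both are explicit, mandatory entries in the CLI configuration so that an
experiment's settings are always recorded in its manifest.

Sequences are uppercased on ingestion and validated against the 20
canonical residues plus `B, Z, X, U, O, *`; anything else is an error
rather than a silent penalty, so scoring is deterministic and typos in
FASTA inputs surface immediately.

## Evaluation: LOO, prevalence adjustment, operating points

Leave-one-out evaluation removes exactly the edge under test from $G$,
scores the pair, and restores the edge; negatives (sampled uniformly from
non-edges) are scored against the full graph. Removing an edge can only
remove co-occurrence evidence, so a LOO score never exceeds the
full-database score of the same pair — a property the tests assert.

Because a test set's positive:negative ratio (e.g. 41,678:100,000) does not
reflect the expected scarcity of true interactions, the confusion matrix's
negative column (FP and TN) is rescaled by
$\text{ratio} \cdot n_{pos} / n_{neg}$ — 100 assumed non-interacting pairs
per interacting pair by default — and rounded to the nearest integer.
Nearest-integer rounding is the only rule that reproduces both published
adjusted cells (50 → 2,084 and 99,950 → 4,165,716) from the raw counts.
The positive column is untouched, so recall is invariant under adjustment.

The operating point is the smallest distinct score threshold whose
specificity reaches the target (default 99.95%); among qualifying
thresholds the smallest is chosen because it maximizes recall. With strict
decisions the highest score always achieves specificity 1, so a target
≤ 1 is always attainable.

## The paraclique decomposition

Initial clusters are all maximal cliques with at least `min_clique_size`
(default 3; a two-protein "complex" is just an edge) members, enumerated by
Bron–Kerbosch with pivoting, degeneracy vertex ordering and bitset
adjacency in compiled code; correctness is judged purely against an
exhaustive subset-enumeration oracle in the tests, never against the
implementation's internals.

Overlap proportion between clusters is $|c_1 \cap c_2| / \min(|c_1|,
|c_2|)$ — the containment-style reading appropriate for merging a small
cluster into a larger one it mostly lies within (Jaccard overlap is
available behind a flag). The exact merge stage unions the pair with the
highest overlap when it exceeds $m$; the approximate stage, used while more
than `switch_count` clusters remain, merges the *first* pair encountered
with overlap **at least** $a$. The inclusive `>=` for the approximation
versus strict `>` for exact merging is implemented verbatim as specified;
the asymmetry is harmless because the approximation is a speed device, not
a definition. All scan orders and tie-breaks follow cluster creation order,
making the decomposition deterministic.

The glom stage absorbs every outside vertex adjacent to strictly more than
proportion $g$ of a cluster, evaluated against the *pre-glom* membership in
a single pass (an iterative variant is exposed as an option through
repeated calls). The first glom pass covers all clusters; later passes only
the cluster newly created by a merge, since the others were already
considered. The loop terminates at `target_count` clusters or at a fixed
point; the tests verify that one further merge step at the fixed point
changes nothing.

Per-cluster annotation enrichment is the one-sided hypergeometric upper
tail, reported raw (one top term per cluster is the reporting convention);
Benjamini–Hochberg correction is available via a flag for users comparing
many terms per cluster.

## What the synthetic generators emulate — and what they do not

`gen_proteome` draws i.i.d. uniform residues: the simplest null, with no
composition bias, repeats or domain architecture. `plant_interactions`
plants each motif pair as a complete bipartite block of edges (default
2×2): every s-side protein receives `motif_s`, every t-side protein
`motif_t` (overwritten at a random non-overlapping position so lengths are
unchanged), and all s×t pairs become true edges. The block design is
deliberate: if edges sharing a motif pair were drawn independently, a
non-edge pair that happens to complete a motif pair would be
sequence-indistinguishable from a true edge, so sampled "negatives" would
contain hidden positives and no benchmark ground truth would exist. With
blocks, motif co-occurrence holds if and only if the pair is a true edge,
and each edge keeps co-occurrence support from its block under
leave-one-out removal (a 2×2 block retains 3 supporting edges).

Consequently the synthetic benchmark is *cleanly separable*: planted
positives score far above ~0-scoring negatives, and the operating-point
precision is typically 1. Passing it demonstrates that the machinery —
window matching, landscape accumulation, filtering, LOO bookkeeping,
thresholding — is correct, not that real proteomes are this easy. Real
sequences have biased composition, repeats and homologous families that
produce chance window matches and inflate false positives; none of that is
modeled. `gen_clustered_graph` similarly produces planted-partition graphs
(within-community edge probability `p_in`, between `p_out`) as a clean test
bed for the decomposition, not a model of real interactome topology.

## Other analysis conventions

Betweenness centrality is summed over unordered endpoint pairs with
endpoints excluded and no normalization: a path's middle vertex scores 1,
the center of a 4-leaf star scores $\binom{4}{2} = 6$, and every vertex of
a 4-cycle scores 0.5. The ordered-pair convention would double every value;
the enumeration oracles in the tests pin the choice. The implementation is
Brandes' accumulation algorithm, validated against two independent oracles
(DFS simple-path enumeration; BFS $\sigma$-products) and cross-checked
against igraph.

Shared-annotation fractions restrict each namespace's denominator to pairs
in which *both* partners are annotated in that namespace, so unannotated
proteins do not masquerade as disagreement; the three-namespace conjunction
column uses pairs annotated in all three. Term-pair co-occurrence divides
observed pair counts by the number of *possible* pairs carrying the two
terms, computed in closed form. Reachability takes the detectable-protein
universe as caller-supplied input — which proteins an experiment could have
seen is a property of the experiment, not of the graph.

## Problem sizes and runtime choices

The oracle suites run exhaustively where exhaustion is feasible — all
labeled graphs on up to 4–5 vertices for betweenness, all $2^{10}$ vertex
subsets for cliques on 10-vertex graphs — and on seeded random instances
(50 × $G(10, 0.4)$, 30 × $G(10, 0.5)$) beyond that. End-to-end recovery
uses ten replicate 60-protein / 40-edge databases with 200 negatives each,
and community recovery uses two planted 8-vertex communities at
$p_{in} = 0.9$, $p_{out} = 0.05$; these sizes exercise every code path in
seconds per replicate while leaving the scores' separation structure
intact. The desk-scale scheduler simulates pull-based workers over measured
per-pair runtimes in one process; its contract — identical prediction sets
for any worker count and packet size, no pair lost or duplicated — is what
the tests pin down, not multi-node deployment.

## Known limitations

* No structural or domain features; motifs assumed contiguous in sequence.
* Database quality bounds prediction quality; false edges propagate.
* Homology is not filtered: families of similar sequences share windows,
  which can make LOO estimates optimistic on real data (a pre-filtered
  input set is the supported route).
* The uniform-residue synthetic null understates real-world false-positive
  rates; calibrate operating points on data that resembles the target
  proteome.
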