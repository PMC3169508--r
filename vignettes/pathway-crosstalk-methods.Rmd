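---
title: "Detecting pathway cross-talk from expression-weighted interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pathway cross-talk from expression-weighted interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biological pathways do not act in isolation: a signalling cascade can
regulate a metabolic pathway, two pathways can compete for a substrate, and
transcription factors downstream of one pathway control members of another.
Such cross-talk is context dependent — whether the P53 and Cell Cycle
pathways talk to each other depends on the cellular condition — so a static
catalogue of pathway relations is not enough. `pathxtalk` detects pathway
interactions that are *active in a given dataset* by combining three
inputs:

* a pathway collection (gene sets, GMT format),
* a protein interaction network (directed and undirected edges from
  curated reactions, functional association databases and
  transcription-factor/target resources), and
* per-gene signed moderated t-statistics from an upstream
  differential-expression analysis (e.g. a limma fit); the tool consumes
  these, it does not compute them.

All identifiers are assumed to live in one namespace ("xrefs"); a plain
two-column mapping table can be applied at read time for inputs that do
not.

## The model

### Unified graph and edge weights

Pathways and proteins become nodes of one directed graph. Undirected
interactions (e.g. binding) are expanded into two directed edges; directed
interactions (e.g. transcription-factor targets) stay single. Every pathway
is connected to each member protein by a *reciprocal* pair of membership
edges — paths must be able to both leave the source pathway and enter the
target pathway; the original description states the connection but not its
direction, and reciprocity is the only choice that allows both.

Each edge takes its weight from its target node:

$$ w(u \to v) = \begin{cases}
  0 & v \text{ is a pathway node} \\
  f(T_v) & v \text{ measured} \\
  1 & v \text{ unmeasured,}
\end{cases}
\qquad
f(T) = \frac{1}{1 + e^{\alpha(|T| - \mu)}} $$

The logistic $f$ is a soft threshold on the absolute t-statistic: it is the
unique standard logistic in $|T|$ that ranges over $(0,1)$, equals exactly
$0.5$ at $|T| = \mu$, has steepness $\alpha$, and gives *lower* weight
(shorter path steps) to more strongly regulated genes. The defaults
$\mu = 3$, $\alpha = 2$ emphasise genes with $|T| \ge 3$ (roughly unadjusted
$p \le 0.004$). With these defaults $f(0) \approx 0.9975$, so a gene with no
signal weighs almost the same as a gene with no data — the method degrades
gracefully under missingness. Edges into pathway nodes are free so that a
path's length does not depend on which membership edge closes it.

### Per-pair path search

For an ordered pair $(P_n, P_m)$:

1. **Neighborhood** — the subgraph $G_{P_n}$ of nodes reachable from $P_n$
   within `nb` *visited edges* (membership steps count). With the default
   `nb = 5`, a path $P_n \to x_1 \to \dots \to x_k \to P_m$ can use at most
   three protein-protein edges; this is primarily a compute bound, and
   longer routes would almost never pass the length cap anyway.
2. **Pair subgraph** — keep $P_n$, $P_m$, their members, and proteins
   annotated to *no* pathway (free intermediates). Proteins belonging to a
   third pathway are excluded: a route through them is better represented
   as two interactions with that pathway in the middle. For proteins shared
   by both pathways the membership edge *into* $P_m$ is removed, so
   membership overlap alone cannot register as an interaction, while a
   shared protein can still bridge towards a distinct partner in the target
   pathway.
3. **Non-redundant shortest paths** — repeatedly extract the weighted
   shortest path (length $l_i$ = sum of edge weights), record it, and
   delete its edges except those incident to $P_n$ or $P_m$; stop when no
   path of length $\le l_{max}$ remains. Successive paths are therefore
   edge-disjoint on their interiors and represent genuinely distinct
   routes. The default cap $l_{max} = 0.9$ means a single unregulated or
   unmeasured step (weight $\approx 1$) already disqualifies a path: only
   routes composed of differentially expressed genes contribute.
4. **Score** — $S_{P_nP_m} = \sum_i 1/l_i$: many short, strongly regulated
   routes give a high score.

### Significance

The score scale depends on pathway size and connectivity, so significance
is empirical. The target pathway $P_m$ is rewired: each member is replaced
by a distinct protein of similar strength (weighted degree over interaction
edges), sampled from the member's quantile stratum (20 strata by default,
nearest-strength fallback when a stratum is exhausted). The whole search is
re-run against each rewired graph, giving null scores $S_{P_nP_r}$, and

$$ p = \frac{\#\{S_{P_nP_r} \ge S_{P_nP_m}\}}{\#\text{permutations}} . $$

Testing runs in two stages: 100 permutations for every scored pair, then
1000 more for pairs with first-stage $p < 0.1$, with $p$ recomputed over the
pooled 1100 draws — cheap overall, with high resolution where it matters.
The pooled count makes the conventional edge threshold $p < 0.001$
attainable. Pairs whose score is 0 are reported with $p = 1$ directly: null
scores are non-negative, so the $\ge$ convention guarantees that outcome
without spending permutations. $p = 0$ is reported as such (the raw
count-over-permutations definition); the per-pair permutation count is
recorded so users can form pseudo-counted versions if they prefer.

Pathway-level enrichment (used to annotate network nodes, not to select
pairs) is the mean $|T|$ over measured members against a null of equal-size
random gene sets drawn without replacement from the measured universe —
10,000 permutations by default, flagged at $p < 0.05$.

## Outputs

Significant pairs (strict $p <$ threshold, default 0.001) form a directed
pathway interaction network; nodes carry in/out degree and betweenness
normalised by $(n-1)(n-2)$, the number of ordered node pairs excluding the
focal node, so the center of a reciprocal star scores exactly 1.
Betweenness is computed on the directed graph by default (the edges are
directed); an undirected variant is available via
`centrality_stats(net, directed = FALSE)`. A detailed network expands the
recorded paths into protein interaction and membership edges, with per-gene
$t$/$q$ annotation. Paths are classified *direct* (every interior protein
belongs to the pair) or *indirect* (one or more free intermediates), and
proteins are ranked by the number of distinct significant pairs whose paths
contain them — candidates for cross-talk hubs. Everything exports to
GraphML and SIF (plus node-attribute TSVs) for Cytoscape.

## Numerical and design choices

* **Tie-breaks.** Equal-length shortest paths are broken deterministically:
  graphs are built with lexically sorted vertices and the search visits
  vertices in index order, so identical inputs give identical paths. With
  continuous weights, exact ties have probability zero.
* **Overlap denominator.** "75% overlap" is read relative to the smaller
  set ($|A \cap B| / \min(|A|,|B|)$) — the most inclusive reading, under
  which a pathway nested in a larger one always merges; `union` (Jaccard)
  and `mean` denominators are available. Merging processes pathways in
  lexical id order within a round, merges each with its most-overlapping
  partner (ties to the lexically smaller id), and repeats to a fixed point;
  the result is independent of input order.
* **Termination.** Every admissible path contains at least one deletable
  interior edge, because the shared-member edge into $P_m$ is removed
  before the search; a guard stops the loop with a warning if that
  invariant is ever violated.
* **Degenerate inputs.** Empty path sets score 0; pathways with no measured
  member get `NA` enrichment; an unreachable target pathway yields score 0
  and $p = 1$ without permutation work.
* **Zero-length paths** are impossible: the first membership step already
  carries the member's $f(T) > 0$, so the inverse-length score is always
  finite.

## The synthetic benchmark

Real inputs at publication scale (hundreds of pathways, $>10^5$
interactions, a full transcriptome) are database-version-bound and too
heavy for routine testing, so the package ships a generator with known
ground truth. It emulates: a heavy-tailed (power-law fitness) interaction
network; pathways as connected modules (breadth-first growth, essentially
disjoint unless an overlap is requested); background statistics
$T \sim N(0, 1)$; and planted cross-talk — vertex-disjoint bridges between
proteins exclusive to the source and target pathway, optionally through a
pathway-free intermediate, with every bridge gene at $|T| = 6$ (a direct
bridge then has length $2 f(6) \approx 0.005 \ll l_{max}$, an effect size a
strong two-group microarray contrast would produce). Effects are expressed
on the $T$ scale so the fixture is explicitly coupled to the sigmoid
parameters.

What the generator does *not* emulate: correlated expression between
interacting genes, hub-biased measurement coverage, pathway annotation
error, and the heavy overlap structure of real curated collections beyond
the configurable pairwise overlaps. Passing the recovery tests therefore
demonstrates the algorithm's correctness and calibration under its own
model, not field performance on any particular organism or platform.

Default validation sizes, chosen to keep full runs interactive on one core:
recovery uses 300 proteins / 12 pathways with three planted pairs (two
bridges each; about 90 s including 1100-permutation testing), and null
calibration uses three seeds at 200 proteins / 8 pathways with no planted
signal. Under the null essentially all pairs score 0 — an admissible
two-step path needs two adjacent genes with $|T| \gtrsim 3$, which is rare
at background $N(0,1)$ — so the pair-level false positive rate sits well
below the nominal level. Note that planting a bridge with *undirected*
edges makes the reverse pair significant too, which is biologically
faithful; directed (tf-target-like) bridges give one-way cross-talk.

## Known limitations

* Pair significance is tested marginally; no multiple-testing correction
  across pairs is applied (the conventional strict threshold $p < 0.001$
  plays that role), and the permutation null randomizes only the target
  pathway, as the score's asymmetry dictates.
* Heterogeneous "context" pathways (e.g. disease signatures aggregating
  generic cascades) can attract interactions driven by a generic sub-module;
  curating the input collection remains the user's responsibility.
* The search is serial; results are exactly reproducible from the seed.
* Hierarchical collections (GO, Reactome) are treated as flat gene sets.
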