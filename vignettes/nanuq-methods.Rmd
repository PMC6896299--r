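---
title: "Inferring level-1 species networks from gene tree quartets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring level-1 species networks from gene tree quartets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanuq)
```

## The model

Species that hybridize are related by a *network* rather than a tree: a
rooted directed acyclic graph in which most nodes are ordinary speciations
(one parent, two children) but *hybrid nodes* have two parents.  Each hybrid
node carries a parameter $\gamma \in (0,1)$: a gene lineage tracing its
ancestry backward through the hybrid node enters one parental population
with probability $\gamma$ and the other with $1-\gamma$.  Edges have lengths
in coalescent units, and within every population lineages coalesce at rate 1
per pair (the Kingman coalescent).  This is the network multispecies
coalescent (NMSC): individual gene trees may have any topology, but their
frequencies are determined by the network's topology, branch lengths and
$\gamma$s.

This package infers *topological features* of such a network from a
collection of unrooted topological gene trees, under two structural
assumptions: the network is binary, and it is **level-1** (no two cycles of
the underlying undirected graph share a vertex).  A level-1 network is a
tree with vertex-disjoint cycles hanging in it; each cycle has a unique
hybrid node.

What is identifiable from gene tree topologies is the network after
contracting all 2- and 3-cycles and forgetting which node of each 4-cycle is
the hybrid; cycles of size 5 or more are recovered together with the
position of their hybrid node.  The pipeline recovers exactly this.

## Quartet concordance factors and the two tests

For four taxa $a<b<c<d$, each gene tree displays one of the three quartets
$ab|cd$, $ac|bd$, $ad|bc$ (or none, if unresolved).  The *concordance
factor* $CF_{abcd}$ is the probability triple of these three outcomes; its
empirical version, the quartet count concordance factor (qcCF)
$(m_1,m_2,m_3)$, is tallied by `tally_quartets()` over all
$\binom{n}{4}$ subsets.  Under the NMSC on a level-1 network, after
contracting small cycles the induced 4-taxon network is either a tree or a
single 4-cycle, and the CF is informative about which:

* a quartet **tree** with internal branch $t$ gives
  $CF = \left(1-\tfrac23 e^{-t},\, \tfrac13 e^{-t},\, \tfrac13 e^{-t}\right)$
  — the two minority entries are equal ("tree-like");
* a **4-cycle** with circular order $(a,b,c,d)$ gives
  $CF_{AB|CD} > CF_{AC|BD}$ and $CF_{AD|BC} > CF_{AC|BD}$: the diagonal
  pairing is the strict minority;
* a **3-cycle whose hybrid node has two descendant taxa** (a $3_2$-cycle)
  is usually tree-like, but not always; see the last section.

`classify_quartets()` applies two likelihood-ratio tests to each qcCF:

1. a *star test* of $H_0: CF = (1/3,1/3,1/3)$, statistic
   $\lambda = 2\left(\sum_i m_i \log(m_i/m) - m\log\tfrac13\right)$ against
   $\chi^2_2$, at level $\beta$; failing to reject leaves the quartet
   unresolved;
2. a *tree-likeness test* of $H_0$: the CF is tree-like, with constrained
   MLE $(m_{\max}/m,\,r,\,r)$, $r = (m-m_{\max})/(2m)$, at level $\alpha$;
   rejection is interpreted as support for a 4-cycle.

If the star test fails to reject, the call is a star regardless of the
second test: evidence for hybridization is held to the strictest standard.
Ties in the maximum (tree call) or minimum (4-cycle call) count are broken
toward the canonical order $(ab|cd, ac|bd, ad|bc)$ and flagged.  A subset
never resolved on any tree is called a star with $p = 1$ and a warning.

The tree-likeness null set (three segments meeting at the simplex centre)
has a singularity at the centre, where the $\chi^2_1$ approximation is
conservative.  The null tail is therefore pluggable
(`tree_test_null` argument); the default is the $\chi^2_1$ upper tail, the
asymptotic law away from the singularity.  Users with a better
finite-sample approximation can supply its tail function.

$\alpha$ and $\beta$ have **no defaults** anywhere in the package:
conventional values such as 0.05 are likely poor choices, the two levels
need not be equal, and sweeping a range of values is part of a careful
analysis.  Smaller $\alpha$ demands stronger evidence for hybridization;
smaller $\beta$ demands stronger evidence of any resolution.

## The network quartet distance

Each call contributes a separation indicator $\rho_{xy}$ for every pair
$x,y$ in its subset: $0$ if the quartet tree joins $x,y$; $1$ if it
separates them; $1/2$ if they are adjacent on a 4-cycle (the average over
the two trees the cycle displays); $1$ across the 4-cycle's diagonal; and
$1$ for every pair of a star (a star separates any two taxa).  The distance

$$ d(x,y) \;=\; 2 \sum_{\{z,w\} \subset X \setminus \{x,y\}}
   \rho_{xy}(Q_{xyzw}) \;+\; 2n-4 $$

(`quartet_distance_matrix()`, sum over *unordered* pairs) is, for the true
calls of a level-1 network $N^-$ with $k$ cycles of size $\ge 4$, exactly
$2^{-k}$ times the distance induced by the network's quartet weight
function $\omega_{N^-}(s) = \sum_{T} w_T(s)$, summed over the $2^k$
displayed trees of the grove, where $w_T$ is the quartet weight of a tree
split ($|X_1||X_2| + |X_3||X_4|$ for an internal edge with adjacent blocks
$X_i$, $|X_1||X_2|$ for a pendant edge).  `theoretical_distances()`
computes both sides by independent routes (grove enumeration vs.
$\rho$-sums) and the identity is verified exactly in the test suite.  This
distance arises from a *circular* weighted split system supported on the
network's splits, which is what makes the next two steps work.

## NeighborNet and split weights

`neighbornet_ordering()` obtains a circular ordering of the taxa by the
NeighborNet agglomeration (delegated to phangorn's implementation of the
published algorithm); orderings are canonicalized up to rotation and
reversal.  `estimate_split_weights()` then fits non-negative weights on all
$n(n-1)/2$ interval splits of that ordering by non-negative least squares
(an active-set solver), minimizing
$\sum_{x<y} (d_\omega(x,y) - D(x,y))^2$.  A circular distance uniquely
determines its weighted split system, so on exact input the residual is
zero and the weights recover $\omega_{N^-}/2^k$; both facts are asserted to
$10^{-8}$ in the tests.  Weights below `eps` ($10^{-10}$ by default, a
numerical threshold) are dropped from the support.

## The splits graph and its construction

A splits graph represents a split system as a planar graph in which each
edge is colored by one split and deleting a color class disconnects the
graph into the split's two sides.  Among outer-labelled planar splits
graphs of a circular system, the *frontier-minimal* ones (fewest edges on
the unbounded face) have exactly $|S_c| + 2|S_i|$ frontier edges, where
$S_c$ are the splits compatible with all others and $S_i$ the rest.

`circular_network()` constructs one incrementally, as the planar dual of a
chord arrangement on a disk.  Taxon $i$ of the circular ordering sits at
boundary position $2i$; a split whose interval is $\{p..q\}$ is a chord
with endpoints in the boundary gaps flanking the interval, with within-gap
offsets chosen so that chords cross **iff** their splits are incompatible.
Inserting a chord routes it along a shortest path of the current graph
between the two boundary windows holding its endpoints — a path that
necessarily crosses each previously inserted incompatible split exactly
once.  Every face along the path is split in two (joined by a new edge
colored by the new split) and every crossed edge is duplicated, producing
the "ladder" structure of the incompatible region.  Rotation systems are
maintained explicitly, so the construction involves no floating-point
geometry; insertion order (decreasing weight, ties lexicographic) is fixed
for reproducibility, and the builder re-verifies the color-class deletion
property of every split.

## Reading the graph

Blobs — maximal 2-edge-connected pieces — correspond one-to-one to the
cycles (size $\ge 4$) of the level-1 network.  `tree_of_blobs()` contracts
each blob to a vertex and returns the resulting multifurcating tree, which
is isomorphic to the network's own tree of blobs.  `detect_darts()`
classifies each blob by its frontier: a cycle of $4(m-3)$ edges whose gaps
between consecutive corners, starting at the *point*, read
$(m-3, 1, 2, \dots, 2, 1, m-3)$.  For $m \ge 5$ the point is the unique
corner $m-3$ frontier edges from its neighbours and marks the hybrid node's
block; for $m = 4$ the blob is a plain quadrilateral and the hybrid node is
not identifiable.  Blobs matching no pattern are reported as
**non-conforming** — a model-fit warning.  The package never coerces a
non-conforming blob into the nearest dart: poor fit to the level-1 NMSC
should be surfaced, not repaired silently.

### Filtering small splits

With noisy calls, the NNLS fit assigns small positive weights to spurious
splits; left in place, they connect or distort blobs.  `nanuq()` therefore
draws only splits of weight at least `min_weight` before interpretation.
The default is $(n-2)/4$: on this distance scale the smallest weight a
genuine level-1 split can carry is $(n-2)/2$ (a cycle split over singleton
blocks appears in half the grove with tree weight $n-2$), so the filter
sits at half the genuine minimum.  This mirrors the common practice of
filtering small-weight splits from a NeighborNet before interpreting it.
Set `min_weight = 0` to see every fitted split.  At small gene-tree sample
sizes the fitted weights of genuine and spurious splits can overlap, and no
fixed threshold separates them; the non-conforming annotations then show
where the signal is equivocal.

## The simulator and what passing tests mean

`simulate_gene_trees()` draws topological gene trees by the exact NMSC:
one lineage per sampled individual, exponential coalescence times at rate
$\binom{j}{2}$ truncated at each edge length, independent $\gamma$-choices
at hybrid nodes, and a single ancestral population above the root.  It is
validated against the closed-form quartet CFs (the tree formula and the
printed $3_2$-cycle formulas) to Monte-Carlo accuracy.

The simulator emulates gene trees produced *without error* under the exact
model: no gene-tree estimation error, no within-population structure, no
continuous migration, every locus independent.  Passing end-to-end tests
therefore demonstrates correctness of the method's implementation under its
own model, not robustness to the additional noise of real data — where
gene trees are themselves estimates and the network need not be level-1.
The per-quartet tests are also applied as if quartets were independent,
which they are not (they share gene trees); this pseudo-likelihood-style
concession is inherited from the method itself.

End-to-end checks use a 16-taxon benchmark network with seven hybrid nodes
(2-, 3-, 4-, 5- and 6-cycles) at 1000 and 300 simulated gene trees with
$\alpha = 0.01$, $\beta = 0.05$, and a Monte-Carlo sample of $10^7$ points
for the $3_2$-cycle tree-likeness measure; combinatorial identities are
checked exactly on that network plus random level-1 fixtures of 6–12 taxa
with up to three cycles.  At 1000 gene trees the full structure (one
4-cycle, a 5-dart and a 6-dart with their hybrid blocks) is recovered; at
300 gene trees recovery succeeds in most but not all replicates, failures
showing up honestly as non-conforming blobs.

## When is a $3_2$-cycle tree-like?

The one ambiguity in interpreting CFs: a $3_2$-cycle quartet network can
produce a *non*-tree-like CF, which the tree-likeness test would read as a
4-cycle.  With transformed lengths $x_i = e^{-t_i}$ ($t_1$ the edge below
the hybrid node, $t_2, t_4$ the hybrid edges, $t_3$ the cycle's tree edge)
the printed CFs (`cf_32cycle()`) give tree-likeness iff
$CF_{AB|CD} \ge CF_{AC|BD}$.  `treelike_region_analysis()` quantifies how
rare the failure is:

* uniformly on the 5-cube, the non-tree-like fraction is about 0.005
  (Monte-Carlo mode);
* $x_1 \le 4/(5-x_3)$ guarantees tree-likeness for all other parameters
  (region of area $4\ln\frac54 \approx 0.89$); in particular
  $t_1 \ge \ln\frac54 \approx 0.2231$ always suffices;
* $\max(x_2,x_4) \le \min(2/x_1 - 3/2,\, 1)$ also guarantees it (about 95%
  of the $(x_1, M)$ square); in particular
  $\min(t_2,t_4) \ge \ln 2 \approx 0.693$ always suffices;
* $CF_{AB|CD} \ge 1/6$ always, with equality at
  $(\gamma, x_1, x_2, x_3, x_4) = (\tfrac12, 1, 1, 0, 1)$.

So hybridization events whose descendant edge is not extremely short cannot
masquerade as 4-cycles.  The package follows the method in treating every
non-tree-like call as a 4-cycle; a dedicated $3_2$-cycle test is out of
scope.

## Numerical and design choices

* $0\log 0 := 0$ throughout; LRT statistics are clamped to $[0,\infty)$ and
  values below $10^{-10}$ snapped to zero (floating-point guard at the
  null, so that counts lying exactly on a null set give $p = 1$).
* Gene-tree quartet extraction uses unit-branch-length path distances (the
  four-point condition with exact integer comparisons), verified against a
  leaf-pruning oracle.
* Hybrid $\gamma$s in extended Newick: paired values summing to 1 are used
  directly; equal repeated values $g$ resolve to $(g, 1-g)$ in string
  order.  Gene-tree metric data are accepted and ignored.
* All randomness is seed-controlled; simulation and pipeline reruns are
  byte-identical given the seed.
* Exact integer/rational structure is preserved where it exists: the
  theoretical $\omega$, $d_\omega$ and $d_Q$ are integer/half-integer
  valued, and the splits-graph construction is purely combinatorial.
  Floats enter only at the NNLS fit.

## Limitations

* Only level-1, binary networks are in scope; non-level-1 signal surfaces
  as non-conforming blobs, not as an inferred network.
* 2- and 3-cycles, 4-cycle hybrid positions, branch lengths and $\gamma$s
  are not identifiable from gene-tree topologies and are not reported.
* The default $\chi^2_1$ tree-test null is conservative near the simplex
  centre; with few gene trees this trades some power against 4-cycles.
* Test levels interact with sample size; results should be reported with
  the $\alpha, \beta$ used, ideally across a range.
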