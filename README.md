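# nanuq

Species that hybridize are related by a **network**, not a tree.  Under the
network multispecies coalescent (NMSC), gene trees formed within a species
network can take any topology, with frequencies determined by the network's
shape, branch lengths (coalescent units) and hybridization parameters γ.
`nanuq` implements the NANUQ algorithm: statistically consistent inference
of the topological features of a **binary level-1** species network from a
collection of unrooted topological gene trees, with no search over network
space.  It is aimed at phylogeneticists who already have gene trees (e.g.
from a multilocus or genomic study) and want a fast, model-based picture of
hybridization, including an honest signal of poor model fit.

## The method

For every 4-taxon subset the gene trees are tallied into a quartet count
concordance factor (qcCF) `(m1, m2, m3)` over the three topologies
`ab|cd, ac|bd, ad|bc`.  Under the NMSC on a level-1 network, the induced
4-taxon network (after contracting 2- and 3-cycles) is a tree or a single
4-cycle, and its CF is either *tree-like* (two smallest entries equal, e.g.
`(1 − (2/3)e^{−t}, (1/3)e^{−t}, (1/3)e^{−t})` for a tree with internal
branch `t`) or has a strict minority at the 4-cycle's diagonal pairing.
Two likelihood-ratio tests classify each qcCF — a star test (χ², 2 df) at
level β and a tree-likeness test (χ², 1 df by default) at level α — and the
calls define a network quartet distance

    d(x,y) = 2 · Σ_{{z,w}} ρ_xy(Q_xyzw) + 2n − 4,

where ρ is 0 / ½ / 1 as x,y are joined, cycle-adjacent, or separated.  For
the true calls this distance comes from a circular weighted split system, so
NeighborNet recovers a circular ordering, non-negative least squares
recovers the split weights, and a frontier-minimal splits graph built from
them displays the network: blobs correspond to cycles, an *m*-dart's point
(m ≥ 5) marks the hybrid node, and the tree of blobs gives the tree-like
part.  Blobs matching no dart pattern are reported as non-conforming rather
than repaired — poor fit to the level-1 NMSC is surfaced, never hidden.

α and β deliberately have no defaults: their choice is part of the analysis
and should be reported.

## Worked example

Simulate 1000 gene trees on the built-in 16-taxon benchmark network (seven
hybrid nodes forming 2-, 3-, 4-, 5- and 6-cycles) and run the pipeline:

```r
library(nanuq)
net <- benchmark_network16()
net
#> Rooted metric binary network: 16 taxa, 7 hybrid nodes, level-1
#> Taxa: a b c d e f g h i j k l m n o p

trees <- simulate_gene_trees(net, m = 1000, seed = 1)
fit <- nanuq(trees, alpha = 0.01, beta = 0.05)
fit
#> NANUQ fit: 16 taxa, 1000 gene trees, 1820 quartets (alpha = 0.01, beta = 0.05)
#> Quartet calls: 0 star, 1542 tree, 278 4-cycle
#> Tree of blobs: (i,(((d,a,(c,b)),(n,j,(p,o),k,(m,l))),e,f,(g,h)));
#> Blobs: 1 four-cycles, 2 darts, 0 non-conforming
#>   6-cycle: blocks (l+m | n | o+p | a+b+c+d+e+f+g+h+i | j | k); hybrid block {l,m}
#>   5-cycle: blocks (g+h | i | a+b+c+d+j+k+l+m+n+o+p | e | f); hybrid block {g,h}
#>   4-cycle: blocks (d | e+f+g+h+i+j+k+l+m+n+o+p | a | b+c)
#> Note: 2- and 3-cycles are unidentifiable; the hybrid node of a 4-cycle is unidentifiable
```

Reading this: every 4-taxon star hypothesis was rejected at β = 0.05; 278
quartets supported a 4-cycle at α = 0.01.  The splits graph contains
exactly three blobs, recovering the benchmark's three identifiable cycles —
the 4-cycle around {b,c} (hybrid node position unidentifiable), the 5-cycle
whose hybrid block is {g,h}, and the 6-cycle whose hybrid block is {l,m} —
which is everything the NMSC can reveal about this network from gene-tree
topologies.  `plot(fit, "simplex")` shows the empirical CFs with their test
outcomes; `plot(fit, "graph")` draws the splits graph; `summary(fit)` lists
the fitted split weights.

The same pipeline runs from the shell over Newick files:

```sh
exec/nanuq pipeline --genetrees trees.nwk --alpha 0.01 --beta 0.05 --out-dir out/
```

writing the qcCF table, per-quartet calls and simplex coordinates (CSV),
the quartet distance (SplitsTree-compatible Nexus + CSV), the fitted splits
(Nexus SPLITS block), the splits graph (DOT) and the interpretation (JSON),
plus a run manifest.  Stage subcommands (`simulate`, `tally`, `test`,
`distance`, `splits`, `interpret`) expose the same files one step at a
time, so an external tool can be injected at the distance boundary.

See the methods vignette (`vignettes/nanuq-methods.Rmd`) for the model,
the construction of the splits graph, all tunable parameters, and known
limitations.

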