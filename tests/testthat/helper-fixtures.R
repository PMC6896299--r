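# shared fixtures and small oracles for the test suite

bench16 <- benchmark_network16()
bench16_un <- unroot(bench16)

# a split system list in the shape estimate_split_weights() returns,
# assembled by hand
make_sw <- function(weights, ordering) {
  list(weights = weights, ordering = ordering, taxa = sort(ordering))
}

# independent displayed-quartet oracle: restrict the tree to the 4 taxa by
# leaf pruning, then read the topology off the pruned tree's bipartitions
oracle_quartet <- function(tree, four) {
  four <- sort(four)
  if (!all(four %in% tree$tip.label)) return("missing")
  sub <- ape::keep.tip(tree, four)
  sub <- ape::unroot(sub)
  bp <- ape::prop.part(sub)
  labs <- attr(bp, "labels")
  for (side in bp) {
    tx <- labs[side]
    if (length(tx) == 2L) {
      if (setequal(tx, four[c(1, 2)])) return("ab|cd")
      if (setequal(tx, four[c(1, 3)])) return("ac|bd")
      if (setequal(tx, four[c(1, 4)])) return("ad|bc")
      if (setequal(tx, four[c(3, 4)])) return("ab|cd")
      if (setequal(tx, four[c(2, 4)])) return("ac|bd")
      if (setequal(tx, four[c(2, 3)])) return("ad|bc")
    }
  }
  "unresolved"
}

# generic multinomial log-likelihood-ratio oracle
lrt_oracle <- function(counts, p0) {
  m <- sum(counts)
  2 * (stats::dmultinom(counts, prob = counts / m, log = TRUE) -
         stats::dmultinom(counts, prob = p0, log = TRUE))
}

# unordered split set of an ape tree, as canonical signatures
tree_split_sigs <- function(tr, taxa) {
  tr <- ape::unroot(tr)
  bp <- ape::prop.part(tr)
  labs <- attr(bp, "labels")
  sigs <- vapply(bp, function(side) {
    tx <- labs[side]
    if (taxa[1] %in% tx) tx <- setdiff(taxa, tx)
    paste(sort(tx), collapse = ",")
  }, character(1))
  # add trivial splits
  triv <- vapply(taxa, function(t) {
    side <- if (identical(t, taxa[1])) setdiff(taxa, t) else t
    paste(sort(side), collapse = ",")
  }, character(1))
  sort(unique(c(sigs[nzchar(sigs)], triv)))
}

# is the index set `i` a circular interval of 1..n?
is_circ_interval <- function(i, n) {
  s <- sort(unique(i))
  gaps <- diff(c(s, s[1] + n))
  sum(gaps > 1L) <= 1L
}
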