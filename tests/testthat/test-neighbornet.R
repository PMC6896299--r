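test_that("tree distances yield orderings consistent with the tree's splits", {
  tr <- ape::read.tree(text = "((a,b),(c,d),e);")
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- ape::cophenetic.phylo(tr)
  ord <- neighbornet_ordering(D)
  # {a,b} and {c,d} must be contiguous in the circular ordering
  for (pair in list(c("a", "b"), c("c", "d"))) {
    i <- match(pair, ord)
    expect_true(abs(diff(i)) == 1L || abs(diff(i)) == length(ord) - 1L)
  }
})

test_that("exact circular distances are fit with zero residual", {
  # quartet tree metric, the hand-solvable 6-split system
  calls4 <- data.frame(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                       class = "tree", topology = 1L)
  D4 <- quartet_distance_matrix(calls4, c("a", "b", "c", "d"))
  sw <- estimate_split_weights(D4, c("a", "b", "c", "d"))
  expect_lt(sw$residual, 1e-10)
  w <- sw$weights
  expect_equal(unname(w[c("b", "c", "d", "b,c,d", "c,d")]), rep(2, 5))
  expect_lt(sum(w) - 10, 1e-8)   # no spurious support

  # level-1 network: recovered weights equal omega / 2^k
  td <- theoretical_distances(bench16_un)
  om <- quartet_weight(bench16_un)
  ord <- neighbornet_ordering(td$d_Q)
  sw2 <- estimate_split_weights(td$d_Q, ord)
  expect_lt(sw2$residual, 1e-8)
  expect_setequal(sw2$support, names(om))
  expect_equal(sw2$weights[names(om)], om / 2^td$k, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("NeighborNet places single-cycle blocks contiguously", {
  un <- random_level1_unrooted(8, 5, seed = 19)
  td <- theoretical_distances(un)
  ord <- neighbornet_ordering(td$d_Q)
  blocks <- cycle_structure(un)[[1]]$blocks
  for (b in blocks)
    expect_true(is_circ_interval(match(b, ord), length(ord)))
  # and the fit is exact
  sw <- estimate_split_weights(td$d_Q, ord)
  expect_lt(sw$residual, 1e-8)
})

test_that("all-zero distances give all-zero weights", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sw <- estimate_split_weights(D, letters[1:4])
  expect_true(all(sw$weights == 0))
  expect_length(sw$support, 0L)
})

test_that("taxon relabelling permutes the fitted system consistently", {
  un <- random_level1_unrooted(7, 4, seed = 23)
  td <- theoretical_distances(un)
  D <- td$d_Q
  perm <- c("t03", "t07", "t01", "t05", "t02", "t06", "t04")
  D2 <- D[perm, perm]
  ord1 <- neighbornet_ordering(D)
  ord2 <- neighbornet_ordering(D2)
  sw1 <- estimate_split_weights(D, ord1)
  sw2 <- estimate_split_weights(D2, ord2)
  w1 <- sw1$weights[sw1$weights > 1e-10]
  w2 <- sw2$weights[sw2$weights > 1e-10]
  expect_equal(sort(names(w1)), sort(names(w2)))
  expect_equal(w2[sort(names(w1))], w1[sort(names(w1))], tolerance = 1e-8)
})

test_that("canonical ordering is rotation- and reversal-invariant", {
  base <- c("c", "a", "d", "b", "e")
  expect_equal(canonical_ordering(base),
               canonical_ordering(rev(base)))
  expect_equal(canonical_ordering(base),
               canonical_ordering(base[c(3, 4, 5, 1, 2)]))
  expect_equal(canonical_ordering(base)[1], "a")
})

test_that("interval splits enumerate n(n-1)/2 distinct splits", {
  ord <- c("a", "c", "b", "e", "d")
  spl <- interval_splits(ord)
  expect_length(spl, 10L)
  expect_false(anyDuplicated(names(spl)) > 0)
})
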