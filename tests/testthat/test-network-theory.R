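test_that("LSA and unrooting reduce to MRCA and unrooted topology on trees", {
  net <- parse_enewick("(((a:1,b:1)u:1,c:2)v:1,d:3)r;")
  expect_equal(net$nodes$type[lsa(net)], "root")
  expect_equal(lsa(net, c("a", "b")),
               net$nodes$id[match("u", net$nodes$label)])
  expect_equal(lsa(net, "a"), net$nodes$id[net$nodes$label == "a" &
                                             net$nodes$type == "leaf"])
  un <- unroot(net)
  expect_equal(un$k, 0L)
  expect_length(cycle_structure(un), 0L)
  expect_equal(length(grove(un)), 1L)
})

test_that("grove size is 2^k and 2-/3-cycle choices deduplicate", {
  expect_length(grove(unroot(quartet_network_41())), 2L)      # one 4-cycle
  expect_length(grove(unroot(quartet_network_32(.3, .1, .2, .4, .3))), 1L)
  expect_length(grove(bench16_un), 8L)                        # k = 3
  expect_equal(bench16_un$k, 3L)
})

test_that("quartet weights on a quartet tree follow the block-size formula", {
  net <- parse_enewick("((a:1,b:1)u:1,(c:1,d:1)v:1)r;")
  om <- quartet_weight(unroot(net))
  expect_equal(sort(names(om)), sort(c("b", "c", "d", "b,c,d", "c,d")))
  expect_true(all(om == 2))   # trivial 1*2, internal 1*1 + 1*1... all 2
})

test_that("omega is blind to 2- and 3-cycles", {
  n32 <- unroot(quartet_network_32(.3, .1, .2, .4, .3))
  tr <- parse_enewick("((a:1,b:1)u:0.4,(c:1,d:1)v:1)r;")
  expect_equal(quartet_weight(n32), quartet_weight(unroot(tr)))
})

test_that("cycle splits of a single cycle follow the interval patterns", {
  un <- random_level1_unrooted(7, 5, seed = 11)
  ss <- split_system(un)
  expect_length(ss$S_i, 2L * (5L - 3L))
  cy <- cycle_structure(un)[[1]]
  blocks <- cy$blocks
  # every cycle split is a union of consecutive blocks containing the
  # hybrid block on one side
  m <- length(blocks)
  for (sig in ss$S_i) {
    side <- strsplit(sig, ",", fixed = TRUE)[[1]]
    if (!all(blocks[[1]] %in% side)) side <- setdiff(un$taxa, side)
    # the hybrid-block side is a union of whole blocks ...
    idx <- which(vapply(blocks, function(b) all(b %in% side), logical(1)))
    expect_setequal(side, unlist(blocks[idx]))
    expect_true(1L %in% idx)
    # ... forming a circular interval through the hybrid block: its
    # complement is a consecutive run of block indices
    comp <- setdiff(seq_len(m), idx)
    expect_true(all(diff(sort(comp)) == 1L))
  }
})

test_that("cut splits are exactly those compatible with all others", {
  for (un in list(bench16_un, random_level1_unrooted(8, c(4, 4), seed = 2))) {
    ss <- split_system(un)
    gr <- grove(un)
    per_tree <- lapply(gr, function(t) attr(t, "splits")$sig)
    on_all <- Reduce(intersect, per_tree)
    expect_setequal(ss$S_c, on_all)
  }
})

test_that("the two distance constructions satisfy d_omega = 2^k d_Q exactly", {
  fixtures <- list(unroot(quartet_network_41()),
                   random_level1_unrooted(6, 5, seed = 4),
                   random_level1_unrooted(9, c(4, 6), seed = 8),
                   bench16_un)
  for (un in fixtures) {
    td <- theoretical_distances(un)
    expect_equal(td$d_omega, 2^td$k * td$d_Q, tolerance = 1e-12)
    expect_true(all(td$d_Q[upper.tri(td$d_Q)] >=
                      2 * length(un$taxa) - 4))
  }
})

test_that("the quartet distance of a tree is the split-weight tree metric", {
  net <- parse_enewick("(((a:1,b:1)u:1,c:1)v:1,(d:1,e:1)w:1)r;")
  un <- unroot(net)
  td <- theoretical_distances(un)
  expect_equal(td$k, 0L)
  expect_equal(td$d_omega, td$d_Q)
  # oracle: explicit split enumeration of w_T
  om <- quartet_weight(un)
  expect_equal(distance_from_splits(om, un$taxa), td$d_Q)
  # n = 4 constants from the single-call definition
  calls4 <- data.frame(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                       class = "tree", topology = 1L)
  D4 <- quartet_distance_matrix(calls4, c("a", "b", "c", "d"))
  expect_equal(D4["a", "b"], 4)
  expect_equal(D4["a", "c"], 6)
  expect_equal(D4["c", "d"], 4)
  calls_star <- data.frame(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                           class = "star", topology = NA_integer_)
  Ds <- quartet_distance_matrix(calls_star, c("a", "b", "c", "d"))
  expect_true(all(Ds[upper.tri(Ds)] == 6))
})

test_that("rho takes the documented values on trees, cycles and stars", {
  tree_call <- list(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                    class = "tree", topology = 1L)
  expect_equal(rho(tree_call, "a", "b"), 0)
  expect_equal(rho(tree_call, "a", "c"), 1)
  cyc_call <- list(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                   class = "cycle4", topology = 2L)  # diagonal ac|bd
  expect_equal(rho(cyc_call, "a", "b"), 0.5)
  expect_equal(rho(cyc_call, "a", "c"), 1)
  star_call <- list(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                    class = "star", topology = NA_integer_)
  for (pr in list(c("a", "b"), c("a", "d"), c("b", "c")))
    expect_equal(rho(star_call, pr[1], pr[2]), 1)
})

test_that("changing one tree call to a star shifts the distance by exactly 2", {
  un <- random_level1_unrooted(6, integer(0), seed = 14)
  calls <- theoretical_calls(un)
  D0 <- quartet_distance_matrix(calls, un$taxa)
  i <- which(calls$class == "tree")[1]
  xy <- switch(calls$topology[i], c(calls$t1[i], calls$t2[i]),
               c(calls$t1[i], calls$t3[i]), c(calls$t1[i], calls$t4[i]))
  calls$class[i] <- "star"; calls$topology[i] <- NA_integer_
  D1 <- quartet_distance_matrix(calls, un$taxa)
  expect_equal(D1[xy[1], xy[2]] - D0[xy[1], xy[2]], 2)
  expect_true(all(abs(D1 - D0) <= 2))
})

test_that("induced quartet classes carry the m_k-cycle inventory", {
  # 4-cycle quartet network: one 4_1-cycle
  iq <- induced_quartet_class(unroot(quartet_network_41()),
                              c("a", "b", "c", "d"))
  expect_equal(iq$class, "cycle4")
  expect_equal(iq$cycles$m, 4L)
  expect_equal(iq$cycles$k, 1L)
  # benchmark: {a,b,c,d} spans the 4-cycle whose hybrid block is {b,c},
  # inducing a 3_2-cycle (hybrid block occupied by two of the four taxa)
  iq2 <- induced_quartet_class(bench16_un, c("a", "b", "c", "d"))
  expect_equal(iq2$class, "tree")
  expect_true(any(iq2$cycles$m == 3L & iq2$cycles$k == 2L))
  # never both a 4_1- and a 3_2-cycle
  set.seed(3)
  subs <- utils::combn(bench16_un$taxa, 4L)
  for (i in sample(ncol(subs), 40L)) {
    iq3 <- induced_quartet_class(bench16_un, subs[, i])
    both <- any(iq3$cycles$m == 4L) && any(iq3$cycles$m == 3L &
                                             iq3$cycles$k == 2L)
    expect_false(both)
    if (any(iq3$cycles$m == 4L)) expect_equal(iq3$class, "cycle4")
  }
})

test_that("theoretical calls match CFs sampled from the coalescent", {
  # a 4_1-cycle quartet network produces the two cyclic topologies in
  # excess of the diagonal (strict inequality pattern)
  net <- quartet_network_41(t1 = 0.4, t2 = 0.4, t4 = 0.3, t5 = 0.3,
                            gamma = 0.5)
  trees <- simulate_gene_trees(net, m = 20000, seed = 17)
  q <- tally_quartets(trees)
  emp <- as.numeric(q[1, c("m1", "m2", "m3")]) / q$m[1]
  # circular order (a,b,c,d): diagonal ac|bd is the minority
  expect_gt(emp[1], emp[2] + 0.02)
  expect_gt(emp[3], emp[2] + 0.02)
  calls <- theoretical_calls(unroot(net))
  expect_equal(calls$class, "cycle4")
  expect_equal(calls$topology, 2L)
})

test_that("tree CF formula behaves at its limits and boundary", {
  expect_equal(as.numeric(cf_tree(0)), rep(1 / 3, 3))
  expect_equal(as.numeric(cf_tree(50)), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(cf_tree(log(4 / 3))[[1]], 0.5)   # majority = 1/2 boundary
})

test_that("3_2-cycle CFs: sum to one, gamma limits, and bound attainment", {
  set.seed(23)
  x <- matrix(runif(5 * 500), ncol = 5)
  cf <- cf_32cycle(x[, 1], x[, 2], x[, 3], x[, 4], x[, 5])
  expect_true(all(abs(rowSums(cf) - 1) < 1e-12))
  expect_true(all(cf >= 0))
  # gamma = 0 collapses to the tree CF with internal length t1 + t2
  cf0 <- cf_32cycle(x[, 1], x[, 2], x[, 3], x[, 4], 0)
  expect_equal(cf0[, 1], 1 - 2 / 3 * x[, 1] * x[, 2], tolerance = 1e-12)
  # the lower bound 1/6 is attained at (gamma, x) = (1/2, 1, 1, 0, 1)
  expect_equal(as.numeric(cf_32cycle(1, 1, 0, 1, 0.5)),
               c(1 / 6, 5 / 12, 5 / 12))
})

test_that("x1 <= 4/(5-x3) guarantees tree-likeness for all other parameters", {
  set.seed(29)
  x3 <- runif(2000); x1 <- runif(2000) * 4 / (5 - x3)
  x2 <- runif(2000); x4 <- runif(2000); g <- runif(2000)
  cf <- cf_32cycle(x1, x2, x3, x4, g)
  expect_true(all(cf[, 1] >= cf[, 2] - 1e-12))
})

test_that("hybrid descendant edges of length log(5/4) force tree-like CFs", {
  set.seed(37)
  n <- 1e5
  x1 <- exp(-(log(5 / 4) + rexp(n)))   # t1 >= log(5/4)
  cf <- cf_32cycle(x1, runif(n), runif(n), runif(n), runif(n))
  expect_equal(sum(cf[, 1] < cf[, 2]), 0L)
})

test_that("region analysis closed forms match their numeric integrals", {
  expect_equal(treelike_region_analysis("area_x1x3"), 4 * log(5 / 4),
               tolerance = 1e-4)
  expect_equal(treelike_region_analysis("area_x1M"), 2 * log(5 / 4) + 0.5,
               tolerance = 1e-4)
  expect_equal(treelike_region_analysis("threshold_t1"), log(5 / 4))
  expect_equal(treelike_region_analysis("threshold_M"), log(2))
})
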