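test_that("a compatible split system builds the tree itself", {
  sw <- make_sw(c("b" = 2, "c" = 2, "d" = 2, "e" = 2, "b,c,d,e" = 2,
                  "d,e" = 1.5, "c,d,e" = 0.7),
                c("a", "b", "c", "d", "e"))
  g <- circular_network(sw)
  # |V| = |E| + 1, every edge is a frontier edge, no blobs
  nv <- length(unique(c(g$edges$v1, g$edges$v2)))
  expect_equal(nrow(g$edges), 7L)
  expect_equal(nv, 8L)
  expect_true(all(g$edges$frontier))
  expect_length(detect_darts(g), 0L)
  tob <- tree_of_blobs(g)
  expect_setequal(tree_split_sigs(tob, g$taxa), sort(names(sw$weights)))
})

test_that("two incompatible splits form one quadrilateral blob", {
  sw <- make_sw(c("b" = 1, "c" = 1, "d" = 1, "b,c,d" = 1,
                  "b,c" = 1, "c,d" = 1), c("a", "b", "c", "d"))
  g <- circular_network(sw)
  expect_equal(sum(g$edges$frontier), 4L + 2L * 2L)   # |S_c| + 2 |S_i|
  darts <- detect_darts(g)
  expect_length(darts, 1L)
  expect_true(darts[[1]]$conforming)
  expect_equal(darts[[1]]$m, 4L)
  expect_null(darts[[1]]$point)
  expect_equal(darts[[1]]$gaps, rep(1L, 4))
})

test_that("frontier counts and coloring follow the frontier-minimal rules", {
  fixtures <- list(random_level1_unrooted(7, 5, seed = 31),
                   random_level1_unrooted(9, c(4, 6), seed = 32),
                   bench16_un)
  for (un in fixtures) {
    ss <- split_system(un)
    om <- quartet_weight(un)
    ord <- neighbornet_ordering(distance_from_splits(om, un$taxa))
    g <- circular_network(make_sw(om, ord))
    expect_equal(sum(g$edges$frontier),
                 length(ss$S_c) + 2L * length(ss$S_i))
    front <- g$edges[g$edges$frontier, ]
    tab <- table(front$sig)
    expect_true(all(tab[ss$S_c] == 1L))
    expect_true(all(tab[ss$S_i] == 2L))
    # cut splits' frontier edges are bridges (not in any blob)
    blobs <- nanuq:::splits_graph_blobs(g)
    blob_edges <- unlist(blobs)
    expect_false(any(g$edges$sig[blob_edges] %in% ss$S_c))
    # incompatible split pairs share a blob
    blob_of_split <- rep(NA_integer_, length(ss$S_i))
    names(blob_of_split) <- ss$S_i
    for (b in seq_along(blobs))
      blob_of_split[unique(g$edges$sig[blobs[[b]]])] <- b
    for (s1 in ss$S_i) for (s2 in ss$S_i)
      if (!splits_compatible(s1, s2, un$taxa))
        expect_equal(blob_of_split[[s1]], blob_of_split[[s2]])
  }
})

test_that("m-darts show the 4(m-3) frontier and its gap pattern", {
  for (m in 5:6) {
    un <- random_level1_unrooted(m + 2, m, seed = 40 + m)
    om <- quartet_weight(un)
    ord <- neighbornet_ordering(distance_from_splits(om, un$taxa))
    g <- circular_network(make_sw(om, ord))
    darts <- Filter(function(d) isTRUE(d$conforming), detect_darts(g))
    darts <- Filter(function(d) d$m == m, darts)
    expect_length(darts, 1L)
    d <- darts[[1]]
    expect_equal(d$frontier_size, 4L * (m - 3L))
    expect_equal(d$gaps, c(m - 3L, 1L, rep(2L, m - 4L), 1L, m - 3L)[1:m])
    # the point is the hybrid block of the cycle
    cy <- cycle_structure(un)[[1]]
    expect_setequal(d$point, cy$blocks[[1]])
  }
})

test_that("theory round trip recovers every cycle of a level-1 network", {
  fixtures <- list(random_level1_unrooted(8, c(4, 5), seed = 51),
                   random_level1_unrooted(12, c(6, 4, 5), seed = 52),
                   bench16_un)
  for (un in fixtures) {
    om <- quartet_weight(un)
    ord <- neighbornet_ordering(distance_from_splits(om, un$taxa))
    g <- circular_network(make_sw(om, ord))
    interp <- interpret_splits_graph(g)
    expect_equal(interp$n_nonconforming, 0L)
    cys <- Filter(function(cy) cy$size >= 4L, cycle_structure(un))
    found <- Filter(function(d) isTRUE(d$conforming), interp$blobs)
    expect_length(found, length(cys))
    key <- function(bl) sort(vapply(bl, function(b)
      paste(sort(b), collapse = "+"), character(1)))
    for (cy in cys) {
      match_d <- Filter(function(d) d$m == cy$size &&
                          identical(key(d$blocks), key(cy$blocks)), found)
      expect_length(match_d, 1L)
      d <- match_d[[1]]
      # circular order agrees (up to rotation/reversal)
      labs <- vapply(cy$blocks, function(b) paste(sort(b), collapse = "+"),
                     character(1))
      dl <- vapply(d$blocks, function(b) paste(sort(b), collapse = "+"),
                   character(1))
      pos <- match(dl, labs)
      steps <- diff(c(pos, pos[1]))
      mm <- length(labs)
      expect_true(all(steps %% mm == 1L) || all(steps %% mm == mm - 1L))
      # dart points mark the hybrid block
      if (cy$size >= 5L) expect_setequal(d$point, cy$blocks[[1]])
    }
  }
})

test_that("tree of blobs displays exactly the cut splits", {
  for (un in list(bench16_un, random_level1_unrooted(8, c(4, 5), seed = 53))) {
    om <- quartet_weight(un)
    ord <- neighbornet_ordering(distance_from_splits(om, un$taxa))
    g <- circular_network(make_sw(om, ord))
    tob <- tree_of_blobs(g)
    ss <- split_system(un)
    got <- tree_split_sigs(tob, un$taxa)
    want <- sort(unique(c(ss$S_c, vapply(un$taxa, function(t) {
      side <- if (identical(t, un$taxa[1])) setdiff(un$taxa, t) else t
      paste(sort(side), collapse = ",")
    }, character(1)))))
    expect_setequal(got, want)
  }
})

test_that("deleting a color class always realizes its split", {
  un <- random_level1_unrooted(10, c(5, 4), seed = 61)
  om <- quartet_weight(un)
  ord <- neighbornet_ordering(distance_from_splits(om, un$taxa))
  g <- circular_network(make_sw(om, ord), validate = FALSE)
  expect_silent(validate_splits_graph(g))
})

test_that("insertion order does not change frontier or blob structure", {
  om <- quartet_weight(bench16_un)
  ord <- neighbornet_ordering(distance_from_splits(om, bench16_un$taxa))
  g1 <- circular_network(make_sw(om, ord))
  g2 <- circular_network(make_sw(rev(om) + 1e-6, ord))
  expect_equal(sum(g1$edges$frontier), sum(g2$edges$frontier))
  i1 <- interpret_splits_graph(g1); i2 <- interpret_splits_graph(g2)
  expect_equal(i1$n_cycle4, i2$n_cycle4)
  expect_equal(i1$n_darts, i2$n_darts)
})

test_that("non-circular input is refused", {
  sw <- make_sw(c("b" = 1, "c" = 1, "b,d" = 1), c("a", "b", "c", "d"))
  expect_error(circular_network(sw), "non-circular")
})
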