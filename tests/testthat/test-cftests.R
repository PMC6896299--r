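test_that("star test statistic matches the trinomial LRT", {
  expect_equal(star_test(c(10, 10, 10))$lambda, 0)
  expect_equal(star_test(c(10, 10, 10))$p, 1)
  expect_equal(star_test(c(300, 0, 0))$lambda, 600 * log(3), tolerance = 1e-12)
  expect_lt(star_test(c(300, 0, 0))$p, 1e-100)
  # cross-check against a generic multinomial LRT on several counts
  for (cnt in list(c(50, 25, 25), c(40, 35, 25), c(120, 3, 77))) {
    expect_equal(star_test(cnt)$lambda, lrt_oracle(cnt, rep(1 / 3, 3)),
                 tolerance = 1e-10)
  }
  expect_equal(star_test(c(50, 25, 25))$lambda, 11.77830, tolerance = 1e-5)
})

test_that("tree-likeness test statistic matches its constrained LRT", {
  expect_equal(treelike_test(c(40, 30, 30))$lambda, 0)
  expect_equal(treelike_test(c(40, 30, 30))$p, 1)
  expect_equal(treelike_test(c(17, 0, 0))$lambda, 0)
  # oracle: constrained MLE (mmax/m, rest/2m, rest/2m)
  for (cnt in list(c(40, 35, 25), c(450, 100, 450), c(7, 5, 2))) {
    m <- sum(cnt); mx <- max(cnt)
    p0 <- c(mx, rep((m - mx) / 2, 2))[order(order(-cnt))] / m
    expect_equal(treelike_test(cnt)$lambda, lrt_oracle(cnt, p0),
                 tolerance = 1e-10)
  }
  expect_equal(treelike_test(c(40, 35, 25))$lambda, 1.674486,
               tolerance = 1e-5)
  # pluggable null distribution
  p_half <- treelike_test(c(40, 35, 25), null_tail = function(q) q * 0 + 0.5)$p
  expect_equal(p_half, 0.5)
})

test_that("both statistics scale linearly in the counts", {
  cnt <- c(40, 35, 25)
  for (cc in c(2, 5, 10)) {
    expect_equal(star_test(cc * cnt)$lambda, cc * star_test(cnt)$lambda,
                 tolerance = 1e-9)
    expect_equal(treelike_test(cc * cnt)$lambda,
                 cc * treelike_test(cnt)$lambda, tolerance = 1e-9)
  }
})

test_that("classification follows the two tests with star priority", {
  expect_equal(classify_quartet(c(334, 333, 333), 0.01, 0.05)$class, "star")
  tr <- classify_quartet(c(900, 50, 50), 0.01, 0.05)
  expect_equal(tr$class, "tree")
  expect_equal(tr$topology, 1L)
  expect_equal(tr$lambda_tree, 0)
  cy <- classify_quartet(c(450, 100, 450), 0.01, 0.05)
  expect_equal(cy$class, "cycle4")
  expect_equal(cy$topology, 2L)      # smallest count names the diagonal

  # priority: p_star >= beta always wins, even when the tree test rejects
  set.seed(31)
  for (i in 1:200) {
    cnt <- as.vector(sample_qccf(c(1, 1, 1) / 3, 60))
    cl <- classify_quartet(cnt, alpha = 0.9, beta = 1e-6)
    if (cl$p_star >= 1e-6) expect_false(cl$class == "cycle4")
  }

  # tie handling is deterministic and flagged: counts rejecting the star
  # but kept tree-like at a small alpha, with the top count tied
  t1 <- classify_quartet(c(130, 130, 80), alpha = 1e-6, beta = 0.05)
  expect_equal(t1$class, "tree")
  expect_true(t1$tie)
  expect_equal(t1$topology, 1L)
  # a tied minimum forces the tree-test statistic to zero, so 4-cycle
  # calls never carry ties on the diagonal
  expect_equal(treelike_test(c(400, 90, 90))$lambda, 0)
  expect_warning(z <- classify_quartet(c(0, 0, 0), 0.01, 0.05), "m = 0")
  expect_equal(z$class, "star")
})

test_that("vectorized classification matches the scalar version", {
  set.seed(5)
  cm <- t(replicate(50, as.vector(sample_qccf(c(.5, .3, .2), 200))))
  q <- structure(data.frame(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                            m1 = cm[, 1], m2 = cm[, 2], m3 = cm[, 3],
                            m = rowSums(cm), unresolved = 0L),
                 class = c("qccf_table", "data.frame"))
  tab <- classify_quartets(q, alpha = 0.05, beta = 0.05)
  for (i in seq_len(nrow(cm))) {
    one <- classify_quartet(cm[i, ], 0.05, 0.05)
    expect_equal(tab$class[i], one$class)
    expect_equal(tab$topology[i], one$topology)
    expect_equal(tab$p_tree[i], one$p_tree)
  }
})

test_that("simplex embedding maps vertices and centroid correctly", {
  m <- 99
  expect_equal(as.vector(simplex_coordinates(c(m, 0, 0))), c(0, 0))
  expect_equal(as.vector(simplex_coordinates(c(0, m, 0))), c(1, 0))
  expect_equal(as.vector(simplex_coordinates(c(0, 0, m))),
               c(0.5, sqrt(3) / 2))
  expect_equal(as.vector(simplex_coordinates(c(m, m, m) / 3)),
               c(0.5, sqrt(3) / 6))
})

test_that("star test type-I error is calibrated at its level", {
  set.seed(1009)
  beta <- 0.05
  nrep <- 1e4
  cm <- sample_qccf(rep(1, 3) / 3, m = 1000, nrep = nrep)
  rate <- mean(star_test(cm)$p < beta)
  se <- sqrt(beta * (1 - beta) / nrep)
  expect_lt(abs(rate - beta), 3 * se)
})

test_that("tree test is conservative for well-separated tree-like CFs", {
  set.seed(1013)
  alpha <- 0.05
  nrep <- 1e4
  cm <- sample_qccf(c(0.6, 0.2, 0.2), m = 1000, nrep = nrep)
  rate <- mean(treelike_test(cm)$p < alpha)
  se <- sqrt(alpha * (1 - alpha) / nrep)
  expect_lt(rate, alpha + 3 * se)
})
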