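# NANUQ Step 2: per-quartet hypothesis tests on qcCFs.
#
# Two likelihood-ratio tests on the trinomial counts (m1, m2, m3):
#   star test     H0: CF = (1/3, 1/3, 1/3)          (chi-square, 2 df)
#   tree test     H0: CF tree-like (two smallest entries equal)
# The tree-test null set has a singularity at the simplex centre, where the
# chi-square(1) approximation is conservative; the null distribution is
# therefore pluggable (default chi-square with 1 df, the asymptotic law away
# from the singularity).

.xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Star-tree likelihood ratio test
#'
#' Tests whether a qcCF is consistent with a 4-taxon star tree, whose
#' theoretical CF is (1/3, 1/3, 1/3).  The statistic is
#' \code{2 (sum_i m_i log(m_i/m) - m log(1/3))}, compared to a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param counts numeric vector (or 3-column matrix) of quartet counts.
#' @return \code{list(lambda, p)} (vectors for matrix input).
#' @export
star_test <- function(counts) {
  cm <- if (is.matrix(counts)) counts else matrix(counts, ncol = 3L)
  m <- rowSums(cm)
  if (any(m < 1)) stop("star test undefined for m = 0")
  lambda <- 2 * (rowSums(.xlogx(cm)) - rowSums(cm * ifelse(m > 0, log(m), 0)) -
                   m * log(1 / 3))
  lambda <- pmax(lambda, 0)
  lambda[lambda < 1e-10] <- 0          # floating-point guard at the null
  list(lambda = lambda, p = stats::pchisq(lambda, df = 2, lower.tail = FALSE))
}

#' Tree-likeness likelihood ratio test
#'
#' Tests whether a qcCF is consistent with a tree-like CF (two smallest
#' entries equal).  With \code{m_max = max(m_i)} the constrained MLE is
#' \code{(m_max/m, (m-m_max)/(2m), (m-m_max)/(2m))} and the statistic is
#' \code{2 (sum_i m_i log(m_i/m) - m_max log(m_max/m)
#' - (m-m_max) log((m-m_max)/(2m)))}.
#'
#' @param counts numeric vector (or 3-column matrix) of quartet counts.
#' @param null_tail function mapping the statistic to an upper-tail
#'   probability; default chi-square with 1 df.
#' @return \code{list(lambda, p)}.
#' @export
treelike_test <- function(counts,
                          null_tail = function(q)
                            stats::pchisq(q, df = 1, lower.tail = FALSE)) {
  cm <- if (is.matrix(counts)) counts else matrix(counts, ncol = 3L)
  m <- rowSums(cm)
  if (any(m < 1)) stop("tree-likeness test undefined for m = 0")
  mmax <- apply(cm, 1L, max)
  ell <- rowSums(.xlogx(cm)) - m * log(m)
  ell0 <- .xlogx(mmax) - mmax * log(m) +
    .xlogx(m - mmax) - (m - mmax) * (log(2) + log(m))
  lambda <- pmax(2 * (ell - ell0), 0)
  lambda[lambda < 1e-10] <- 0          # floating-point guard at the null
  list(lambda = lambda, p = null_tail(lambda))
}

#' Classify one qcCF as star, tree, or 4-cycle
#'
#' Applies the star test at level \code{beta} and the tree-likeness test at
#' level \code{alpha}.  If the star test fails to reject (\code{p >= beta})
#' the call is \code{"star"} regardless of the second test (star priority:
#' evidence for hybridization is held to the strictest standard).  Otherwise
#' \code{p_tree >= alpha} yields a tree with the maximum-likelihood topology
#' (largest count); \code{p_tree < alpha} yields a 4-cycle, recorded by its
#' diagonal pairing (the smallest count: on a 4-cycle in circular order
#' a,b,c,d both cyclic topologies exceed the diagonal one).
#'
#' @param counts numeric vector of 3 counts in canonical order
#'   (\code{ab|cd, ac|bd, ad|bc} for sorted taxa).
#' @param alpha level of the tree-likeness test.
#' @param beta level of the star test.
#' @param null_tail tree-test null tail function (see
#'   \code{\link{treelike_test}}).
#' @return \code{list(class, topology, p_star, p_tree, lambda_star,
#'   lambda_tree, tie)}; \code{topology} indexes the canonical order (for a
#'   tree call, the supported quartet; for a 4-cycle, the diagonal),
#'   \code{NA} for a star.
#' @export
classify_quartet <- function(counts, alpha, beta,
                             null_tail = function(q)
                               stats::pchisq(q, df = 1, lower.tail = FALSE)) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, length(counts) == 3L)
  if (sum(counts) == 0) {
    warning("qcCF with m = 0: classified as star")
    return(list(class = "star", topology = NA_integer_, p_star = 1,
                p_tree = 1, lambda_star = 0, lambda_tree = 0, tie = FALSE))
  }
  st <- star_test(counts)
  tt <- treelike_test(counts, null_tail)
  tie <- FALSE
  if (st$p >= beta) {
    cls <- "star"; top <- NA_integer_
  } else if (tt$p >= alpha) {
    cls <- "tree"
    top <- which(counts == max(counts))
    tie <- length(top) > 1L
    top <- top[1L]
  } else {
    cls <- "cycle4"
    top <- which(counts == min(counts))
    tie <- length(top) > 1L
    top <- top[1L]
  }
  list(class = cls, topology = top, p_star = st$p, p_tree = tt$p,
       lambda_star = st$lambda, lambda_tree = tt$lambda, tie = tie)
}

#' Classify every qcCF row of a table
#'
#' Vectorized \code{\link{classify_quartet}} over a qcCF table.
#'
#' @param qccf a \code{"qccf_table"} (see \code{\link{tally_quartets}}).
#' @inheritParams classify_quartet
#' @return a data.frame of class \code{"quartet_calls"} with columns
#'   \code{t1..t4, class, topology, p_star, p_tree, lambda_star,
#'   lambda_tree, tie}; \code{alpha}, \code{beta} and the taxon set attached
#'   as attributes.
#' @export
classify_quartets <- function(qccf, alpha, beta,
                              null_tail = function(q)
                                stats::pchisq(q, df = 1, lower.tail = FALSE)) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  cm <- as.matrix(qccf[, c("m1", "m2", "m3")])
  m <- rowSums(cm)
  zero <- m == 0
  if (any(zero))
    warning(sprintf("%d qcCFs with m = 0 classified as star", sum(zero)))
  p_star <- p_tree <- rep(1, nrow(cm))
  l_star <- l_tree <- rep(0, nrow(cm))
  if (any(!zero)) {
    st <- star_test(cm[!zero, , drop = FALSE])
    tt <- treelike_test(cm[!zero, , drop = FALSE], null_tail)
    p_star[!zero] <- st$p; l_star[!zero] <- st$lambda
    p_tree[!zero] <- tt$p; l_tree[!zero] <- tt$lambda
  }
  cls <- ifelse(p_star >= beta, "star",
                ifelse(p_tree >= alpha, "tree", "cycle4"))
  top <- rep(NA_integer_, nrow(cm))
  tie <- rep(FALSE, nrow(cm))
  tr <- which(cls == "tree")
  if (length(tr)) {
    top[tr] <- max.col(cm[tr, , drop = FALSE], ties.method = "first")
    tie[tr] <- rowSums(cm[tr, , drop = FALSE] ==
                         apply(cm[tr, , drop = FALSE], 1L, max)) > 1L
  }
  cy <- which(cls == "cycle4")
  if (length(cy)) {
    top[cy] <- max.col(-cm[cy, , drop = FALSE], ties.method = "first")
    tie[cy] <- rowSums(cm[cy, , drop = FALSE] ==
                         apply(cm[cy, , drop = FALSE], 1L, min)) > 1L
  }
  out <- data.frame(t1 = qccf$t1, t2 = qccf$t2, t3 = qccf$t3, t4 = qccf$t4,
                    class = cls, topology = top, p_star = p_star,
                    p_tree = p_tree, lambda_star = l_star,
                    lambda_tree = l_tree, tie = tie,
                    stringsAsFactors = FALSE)
  structure(out, alpha = alpha, beta = beta, taxa = attr(qccf, "taxa"),
            class = c("quartet_calls", "data.frame"))
}

#' Simplex coordinates of normalized qcCFs
#'
#' Embeds each normalized empirical CF in the equilateral triangle with
#' vertices (1,0,0) -> (0,0), (0,1,0) -> (1,0), (0,0,1) -> (1/2, sqrt(3)/2),
#' for simplex plots of test outcomes.
#'
#' @param counts 3-vector or 3-column matrix of counts (each row m >= 1).
#' @return a 2-column matrix of plot coordinates.
#' @export
simplex_coordinates <- function(counts) {
  cm <- if (is.matrix(counts)) counts else matrix(counts, ncol = 3L)
  m <- rowSums(cm)
  if (any(m < 1)) stop("simplex coordinates undefined for m = 0")
  p <- cm / m
  cbind(x = p[, 2L] + p[, 3L] / 2, y = p[, 3L] * sqrt(3) / 2)
}
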