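# The central fitting function: runs the whole quartet-distance pipeline on
# a collection of gene trees and returns a classed object with the fitted
# split system, splits graph and interpretation.

#' Infer species-network features from gene trees
#'
#' Runs the NANUQ pipeline: (1) tally quartet count concordance factors
#' over all 4-taxon subsets; (2) classify each subset as star / resolved
#' tree / 4-cycle by two likelihood-ratio tests at levels \code{beta}
#' (star test) and \code{alpha} (tree-likeness test); (3) assemble the
#' network quartet distance; (4) fit a weighted circular split system by
#' NeighborNet ordering plus non-negative least squares; (5) build a
#' frontier-minimal splits graph and interpret its blobs as the cycles of a
#' level-1 species network.
#'
#' The levels have no defaults: their choice materially affects the
#' inference (small \code{alpha} demands strong evidence of hybridization)
#' and should be reported with any analysis; sweeping a range of levels is
#' part of a careful analysis.
#'
#' @param genetrees a \code{"multiPhylo"} collection of unrooted topological
#'   gene trees (metric annotations ignored), or a path to a Newick file
#'   (one tree per line; \code{#} comments allowed).  Every 4-taxon subset
#'   should occur on at least one tree.
#' @param alpha level of the tree-likeness test (reject = 4-cycle support).
#' @param beta level of the star test (fail to reject = unresolved).
#' @param taxa optional taxon set (default: union of tree leaf labels).
#' @param tree_test_null upper-tail function for the tree-test null
#'   distribution (default chi-square, 1 df).
#' @param eps numerical support threshold for fitted split weights.
#' @param min_weight minimum split weight drawn in the splits graph.  On the
#'   quartet-distance scale the smallest weight a genuine split of a level-1
#'   network can have is \code{(n-2)/2} (a cycle split over singleton
#'   blocks), while weights fitted to test-error noise are much smaller; the
#'   default \code{(n-2)/4} (half the genuine minimum) separates the two.
#'   This mirrors the usual practice of filtering small-weight splits from a
#'   NeighborNet before interpreting it.  Set to 0 to draw every fitted
#'   split.
#' @return an object of class \code{"nanuq"}: list with \code{qccf},
#'   \code{calls}, \code{distance}, \code{ordering}, \code{split_weights},
#'   \code{graph}, \code{interpretation}, \code{alpha}, \code{beta},
#'   \code{taxa}.
#' @examples
#' \donttest{
#' net <- benchmark_network16()
#' trees <- simulate_gene_trees(net, m = 300, seed = 7)
#' fit <- nanuq(trees, alpha = 0.01, beta = 0.05)
#' fit
#' }
#' @export
nanuq <- function(genetrees, alpha, beta, taxa = NULL,
                  tree_test_null = function(q)
                    stats::pchisq(q, df = 1, lower.tail = FALSE),
                  eps = 1e-10, min_weight = NULL) {
  if (is.character(genetrees)) genetrees <- read_gene_trees(genetrees)
  qccf <- tally_quartets(genetrees, taxa)
  calls <- classify_quartets(qccf, alpha, beta, tree_test_null)
  D <- quartet_distance_matrix(calls)
  ord <- neighbornet_ordering(D)
  sw <- estimate_split_weights(D, ord, eps)
  if (is.null(min_weight)) min_weight <- (length(ord) - 2) / 4
  g <- circular_network(sw, eps = max(eps, min_weight))
  interp <- interpret_splits_graph(g)
  structure(list(qccf = qccf, calls = calls, distance = D, ordering = ord,
                 split_weights = sw, graph = g, interpretation = interp,
                 alpha = alpha, beta = beta, taxa = attr(qccf, "taxa")),
            class = "nanuq")
}

#' @export
print.nanuq <- function(x, ...) {
  tb <- table(factor(x$calls$class, levels = c("star", "tree", "cycle4")))
  cat(sprintf("NANUQ fit: %d taxa, %d gene trees, %d quartets (alpha = %g, beta = %g)\n",
              length(x$taxa), attr(x$qccf, "ntrees"), nrow(x$qccf),
              x$alpha, x$beta))
  cat(sprintf("Quartet calls: %d star, %d tree, %d 4-cycle\n",
              tb[["star"]], tb[["tree"]], tb[["cycle4"]]))
  print(x$interpretation)
  invisible(x)
}

#' @export
summary.nanuq <- function(object, ...) {
  structure(list(fit = object), class = "summary.nanuq")
}

#' @export
print.summary.nanuq <- function(x, ...) {
  print(x$fit)
  sw <- x$fit$split_weights
  cat(sprintf("\nCircular ordering: %s\n", paste(sw$ordering, collapse = " ")))
  cat(sprintf("Supported splits: %d (NNLS residual %.3g)\n",
              length(sw$support), sw$residual))
  w <- sort(sw$weights[sw$support], decreasing = TRUE)
  cat("Largest split weights:\n")
  for (i in seq_len(min(5L, length(w))))
    cat(sprintf("  %-40s %.4f\n", names(w)[i], w[i]))
  invisible(x)
}

#' Plot a NANUQ fit
#'
#' \code{type = "simplex"}: empirical CFs of all 4-subsets in the
#' probability simplex, colored by test outcome (star / tree / 4-cycle).
#' \code{type = "graph"}: the splits graph in the equal-angle layout (every
#' edge of one split drawn with the same direction and length equal to its
#' weight).
#'
#' @param x a \code{"nanuq"} object.
#' @param type \code{"simplex"} or \code{"graph"}.
#' @param ... passed to plotting primitives.
#' @return \code{x}, invisibly.
#' @export
plot.nanuq <- function(x, type = c("simplex", "graph"), ...) {
  type <- match.arg(type)
  if (type == "simplex") {
    keep <- x$qccf$m > 0
    xy <- simplex_coordinates(as.matrix(x$qccf[keep, c("m1", "m2", "m3")]))
    cls <- x$calls$class[keep]
    col <- c(star = "tan", tree = "blue", cycle4 = "red")[cls]
    pch <- c(star = 15, tree = 1, cycle4 = 17)[cls]
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, sqrt(3) / 2), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = "Empirical quartet CFs")
    graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
    graphics::points(xy, col = col, pch = pch, ...)
    graphics::legend("topleft", bty = "n", pch = c(15, 1, 17),
                     col = c("tan", "blue", "red"),
                     legend = c("star", "tree", "4-cycle"))
  } else {
    plot(x$graph, ...)
  }
  invisible(x)
}

#' Plot a splits graph in the equal-angle layout
#'
#' @param x a \code{"splits_graph"}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.splits_graph <- function(x, ...) {
  ed <- x$edges
  n <- length(x$ordering)
  verts <- sort(unique(c(ed$v1, ed$v2)))
  # side of each vertex for each split (A = signature side)
  sideA <- matrix(NA, length(verts), nrow(x$splits),
                  dimnames = list(as.character(verts), NULL))
  for (j in seq_len(nrow(x$splits))) {
    keep <- ed$sig != x$splits$sig[j]
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$v1[keep]),
                 to = as.character(ed$v2[keep])),
      directed = FALSE, vertices = data.frame(name = as.character(verts)))
    memb <- igraph::components(ig)$membership[as.character(verts)]
    # which component holds the signature side's taxa?
    sideTx <- strsplit(x$splits$sig[j], ",", fixed = TRUE)[[1L]][1L]
    vhold <- verts[vapply(verts, function(v)
      sideTx %in% x$vertex_taxa[[v]], logical(1))][1L]
    sideA[, j] <- memb == memb[[as.character(vhold)]]
  }
  theta <- pi * (x$splits$p + x$splits$q) / n
  dx <- x$splits$w * cos(theta); dy <- x$splits$w * sin(theta)
  pos <- matrix(NA_real_, length(verts), 2L,
                dimnames = list(as.character(verts), NULL))
  pos[1L, ] <- c(0, 0)
  queue <- verts[1L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    inc <- which(ed$v1 == v | ed$v2 == v)
    for (e in inc) {
      u <- if (ed$v1[e] == v) ed$v2[e] else ed$v1[e]
      if (!is.na(pos[as.character(u), 1L])) next
      j <- match(ed$sig[e], x$splits$sig)
      s <- if (sideA[as.character(v), j]) -1 else 1   # crossing toward A side
      pos[as.character(u), ] <- pos[as.character(v), ] + s * c(dx[j], dy[j])
      queue <- c(queue, u)
    }
  }
  graphics::plot(NA, xlim = range(pos[, 1L]) + c(-1, 1),
                 ylim = range(pos[, 2L]) + c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", ...)
  graphics::segments(pos[as.character(ed$v1), 1L], pos[as.character(ed$v1), 2L],
                     pos[as.character(ed$v2), 1L], pos[as.character(ed$v2), 2L],
                     col = ifelse(ed$frontier, "black", "grey40"))
  for (v in verts) {
    tx <- x$vertex_taxa[[v]]
    if (length(tx))
      graphics::text(pos[as.character(v), 1L], pos[as.character(v), 2L],
                     paste(tx, collapse = ","), col = "red3", cex = 0.8,
                     pos = 4)
  }
  invisible(x)
}

#' Run the NANUQ pipeline and write all stage artifacts
#'
#' File-level front end: reads a gene tree file, runs
#' \code{\link{nanuq}}, and writes the qcCF CSV, the classification CSV,
#' simplex coordinates CSV, the quartet distance (Nexus and CSV), the
#' fitted split system (Nexus SPLITS), the splits graph (DOT), the
#' interpretation (JSON) and a run manifest (JSON) into \code{out_dir}.
#'
#' @param genetrees_path Newick gene tree file (one tree per line).
#' @param alpha,beta test levels (no defaults; see \code{\link{nanuq}}).
#' @param out_dir output directory (created if needed).
#' @param eps split-weight support threshold.
#' @param seed optional seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return the \code{"nanuq"} fit, invisibly.
#' @export
run_pipeline <- function(genetrees_path, alpha, beta, out_dir = ".",
                         eps = 1e-10, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- nanuq(genetrees_path, alpha = alpha, beta = beta, eps = eps)
  p <- function(f) file.path(out_dir, f)
  write_qccf_csv(fit$qccf, p("qccf.csv"))
  keep <- fit$qccf$m > 0
  xy <- simplex_coordinates(as.matrix(fit$qccf[keep, c("m1", "m2", "m3")]))
  utils::write.csv(data.frame(fit$calls[keep, c("t1", "t2", "t3", "t4",
                                                "class")],
                              simplex_x = xy[, 1L], simplex_y = xy[, 2L]),
                   p("simplex.csv"), row.names = FALSE)
  utils::write.csv(data.frame(fit$calls,
                              alpha = alpha, beta = beta),
                   p("calls.csv"), row.names = FALSE)
  write_nexus_distances(fit$distance, p("distance.nex"))
  write_distance_csv(fit$distance, p("distance.csv"))
  write_nexus_splits(fit$split_weights, p("splits.nex"))
  write_dot(fit$graph, p("splitsgraph.dot"))
  interp <- fit$interpretation
  jsonlite::write_json(list(
    tree_of_blobs = interp$tree_of_blobs,
    n_cycle4 = interp$n_cycle4, n_darts = interp$n_darts,
    n_nonconforming = interp$n_nonconforming,
    blobs = lapply(interp$blobs, function(d) list(
      m = d$m, conforming = d$conforming,
      blocks = lapply(d$blocks, as.list),
      point = if (is.null(d$point)) NULL else as.list(d$point))),
    caveat = interp$caveat),
    p("interpretation.json"), auto_unbox = TRUE, null = "null")
  jsonlite::write_json(list(
    input = genetrees_path, alpha = alpha, beta = beta,
    tree_test_null = "chisq1", eps = eps, seed = seed,
    version = tryCatch(as.character(utils::packageVersion("nanuq")),
                       error = function(e) NA_character_),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    p("manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(fit)
}
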