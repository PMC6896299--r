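# Combinatorial operations on rooted and semidirected level-1 networks:
# unrooting, cycle structure, displayed-tree groves, split systems, the
# quartet weight function and the theoretical distances they induce.  These
# are the exact oracles against which the data pipeline is validated.

#' Lowest stable ancestor
#'
#' The unique lowest node lying on every directed path from the root to any
#' taxon in \code{Z}; generalizes the MRCA to networks.
#'
#' @param net a \code{"rooted_network"}.
#' @param Z a character vector of taxon labels (default: all taxa).
#' @return the node id of the LSA.
#' @export
lsa <- function(net, Z = net$taxa) {
  stopifnot(length(Z) >= 1L, all(Z %in% net$taxa))
  ord <- topo_order(net)
  nv <- nrow(net$nodes)
  ed <- net$edges
  # Dom(v) as logical rows: v dominates itself plus intersection of parents'
  dom <- matrix(FALSE, nv, nv)
  for (v in ord) {
    par <- ed$parent[ed$child == v]
    row <- if (length(par) == 0L) rep(FALSE, nv) else {
      r <- dom[par[1L], ]
      for (p in par[-1L]) r <- r & dom[p, ]
      r
    }
    row[v] <- TRUE
    dom[v, ] <- row
  }
  leaf_ids <- net$nodes$id[match(Z, net$nodes$label)]
  common <- dom[leaf_ids[1L], ]
  for (l in leaf_ids[-1L]) common <- common & dom[l, ]
  cand <- which(common)
  # lowest: the candidate dominated by all others (largest dominator set)
  cand[which.max(rowSums(dom[cand, , drop = FALSE]))]
}

#' Unroot a rooted network to its induced semidirected network
#'
#' Deletes everything above the lowest stable ancestor of the full taxon set,
#' undirects tree edges (hybrid edges keep their direction), and suppresses
#' the LSA, summing the lengths of conjoined edges.
#'
#' @param net a \code{"rooted_network"}.
#' @return an object of class \code{"unrooted_network"}: \code{nodes}
#'   (id, label), \code{edges} (v1, v2, directed, length, gamma; when
#'   \code{directed}, \code{v2} is the hybrid child), \code{taxa}, and
#'   \code{k} (number of cycles of size 4 or more).
#' @export
unroot <- function(net) {
  root_lsa <- lsa(net)
  ed <- net$edges
  # descendants of the LSA (inclusive)
  keep <- logical(nrow(net$nodes))
  keep[root_lsa] <- TRUE
  repeat {
    new <- unique(ed$child[keep[ed$parent]])
    if (all(keep[new])) break
    keep[new] <- TRUE
  }
  ed <- ed[keep[ed$parent] & keep[ed$child], , drop = FALSE]
  un <- data.frame(v1 = ed$parent, v2 = ed$child, directed = ed$hybrid,
                   length = ed$length, gamma = ed$gamma)
  # suppress the LSA (degree 2 after deletion of the part above it)
  inc <- which(un$v1 == root_lsa | un$v2 == root_lsa)
  if (length(inc) == 2L) {
    e1 <- un[inc[1L], ]; e2 <- un[inc[2L], ]
    both_hyb <- e1$directed && e2$directed
    if (both_hyb) stop("cannot suppress LSA between two hybrid edges")
    other <- function(e) if (e$v1 == root_lsa) e$v2 else e$v1
    len <- e1$length + e2$length
    if (e1$directed || e2$directed) {
      hy <- if (e1$directed) e1 else e2
      newe <- data.frame(v1 = other(if (e1$directed) e2 else e1),
                         v2 = hy$v2, directed = TRUE, length = len,
                         gamma = hy$gamma)
    } else {
      newe <- data.frame(v1 = other(e1), v2 = other(e2), directed = FALSE,
                         length = len, gamma = NA_real_)
    }
    un <- rbind(un[-inc, ], newe)
  }
  used <- sort(unique(c(un$v1, un$v2)))
  nodes <- net$nodes[net$nodes$id %in% used, c("id", "label")]
  nodes$label[net$nodes$type[match(nodes$id, net$nodes$id)] != "leaf"] <-
    NA_character_
  out <- structure(list(nodes = nodes, edges = un, taxa = net$taxa),
                   class = "unrooted_network")
  out$k <- sum(vapply(cycle_structure(out), function(cy) cy$size >= 4L,
                      logical(1)))
  out
}

#' @export
print.unrooted_network <- function(x, ...) {
  cys <- cycle_structure(x)
  cat(sprintf("Semidirected network: %d taxa, %d cycle%s (sizes: %s)\n",
              length(x$taxa), length(cys), if (length(cys) == 1) "" else "s",
              if (length(cys)) paste(vapply(cys, `[[`, integer(1), "size"),
                                     collapse = ",") else "none"))
  invisible(x)
}

# igraph for an unrooted network (undirected view); edge order preserved
.ug <- function(unet) {
  igraph::graph_from_edgelist(cbind(unet$edges$v1, unet$edges$v2),
                              directed = FALSE)
}

#' Cycle structure of a level-1 semidirected network
#'
#' Finds every cycle (blob) of the undirected graph, its hybrid node (the
#' node with two incoming hybrid edges in the cycle), and the partition of
#' taxa into blocks attached around the cycle, listed in circular order
#' starting from the hybrid node's block.
#'
#' @param unet an \code{"unrooted_network"}.
#' @return a list of cycles, each with \code{size}, \code{nodes} (cycle node
#'   ids in circular order starting at the hybrid node), \code{hybrid}
#'   (node id), and \code{blocks} (list of character vectors of taxa, in the
#'   same circular order).
#' @export
cycle_structure <- function(unet) {
  g <- .ug(unet)
  bc <- igraph::biconnected_components(g)
  ed <- unet$edges
  out <- list()
  for (compE in bc$component_edges) {
    eidx <- as.integer(compE)
    if (length(eidx) <= 1L) next
    cyc_nodes <- unique(c(ed$v1[eidx], ed$v2[eidx]))
    if (length(eidx) != length(cyc_nodes))
      stop("non-cycle blob: network is not level-1")
    # hybrid node: two directed edges of the cycle point into it
    hy_edges <- eidx[ed$directed[eidx]]
    if (length(hy_edges) != 2L || length(unique(ed$v2[hy_edges])) != 1L)
      stop("cycle without a unique hybrid node")
    hybrid <- ed$v2[hy_edges[1L]]
    # order nodes around the cycle starting at the hybrid
    adj <- lapply(cyc_nodes, function(v) {
      nb <- c(ed$v2[eidx][ed$v1[eidx] == v], ed$v1[eidx][ed$v2[eidx] == v])
      nb
    })
    names(adj) <- as.character(cyc_nodes)
    ordn <- hybrid
    prev <- NA_integer_
    while (length(ordn) < length(cyc_nodes)) {
      nb <- adj[[as.character(ordn[length(ordn)])]]
      nxt <- setdiff(nb, prev)
      # 2-cycles: both neighbours equal; pick the single distinct node
      nxt <- nxt[1L]
      prev <- ordn[length(ordn)]
      ordn <- c(ordn, nxt)
    }
    # taxon blocks: components after deleting the cycle's edges
    g2 <- igraph::delete_edges(g, eidx)
    comp <- igraph::components(g2)$membership
    leafv <- unet$nodes$id[!is.na(unet$nodes$label)]
    blocks <- lapply(ordn, function(v) {
      sort(unet$nodes$label[match(leafv[comp[leafv] == comp[v]],
                                  unet$nodes$id)])
    })
    out[[length(out) + 1L]] <- list(size = length(cyc_nodes),
                                    nodes = ordn, hybrid = hybrid,
                                    blocks = blocks)
  }
  out
}

# --- displayed trees ---------------------------------------------------------

# delete one hybrid edge per hybrid node according to `choice` (logical per
# hybrid node: TRUE = delete first of its pair), undirect, suppress degree-2
# nodes; returns a tree as list(edges = 2-col matrix, labels = named chr)
.displayed_tree <- function(unet, choice) {
  ed <- unet$edges
  hyb_nodes <- sort(unique(ed$v2[ed$directed]))
  drop <- integer(0)
  for (i in seq_along(hyb_nodes)) {
    pair <- which(ed$directed & ed$v2 == hyb_nodes[i])
    drop <- c(drop, pair[if (choice[i]) 1L else 2L])
  }
  e <- if (length(drop)) ed[-drop, c("v1", "v2")] else ed[, c("v1", "v2")]
  labs <- stats::setNames(unet$nodes$label, unet$nodes$id)
  leaf_ids <- unet$nodes$id[!is.na(unet$nodes$label)]
  # iteratively suppress internal degree-2 nodes
  repeat {
    deg <- table(c(e$v1, e$v2))
    d2 <- as.integer(names(deg)[deg == 2L])
    d2 <- setdiff(d2, leaf_ids)
    if (!length(d2)) break
    v <- d2[1L]
    inc <- which(e$v1 == v | e$v2 == v)
    nb <- c(e$v1[inc], e$v2[inc])
    nb <- nb[nb != v]
    if (length(inc) != 2L) stop("internal error in suppression")
    e <- rbind(e[-inc, ], data.frame(v1 = nb[1L], v2 = nb[2L]))
  }
  list(edges = as.matrix(e), labels = labs[as.character(leaf_ids)])
}

# canonical split signature: the side not containing the first taxon
# (in sorted order), as a comma-joined sorted string
.split_sig <- function(side, taxa) {
  if (taxa[1L] %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = ",")
}

# splits and quartet weights w_T of an unrooted (binary or not) tree
# returns data.frame(sig, w, pendant)
.tree_splits_w <- function(tree, taxa) {
  e <- tree$edges
  labs <- tree$labels
  verts <- unique(c(e[, 1L], e[, 2L]))
  adj <- lapply(verts, function(v) {
    rows <- which(e[, 1L] == v | e[, 2L] == v)
    nb <- ifelse(e[rows, 1L] == v, e[rows, 2L], e[rows, 1L])
    nb
  })
  names(adj) <- as.character(verts)
  leaf_ids <- as.integer(names(labs))
  memo <- new.env()
  side <- function(u, v) {  # taxa on the v side of edge (u,v)
    key <- paste0(u, "_", v)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (v %in% leaf_ids) labs[[as.character(v)]] else {
      unlist(lapply(setdiff(adj[[as.character(v)]], u),
                    function(w) side(v, w)))
    }
    memo[[key]] <- res
    res
  }
  rows <- list()
  for (i in seq_len(nrow(e))) {
    u <- e[i, 1L]; v <- e[i, 2L]
    B <- side(u, v)
    if (length(B) == 0L || length(B) == length(taxa)) next
    pendant <- (v %in% leaf_ids) || (u %in% leaf_ids)
    if (pendant) {
      leaf_end <- if (v %in% leaf_ids) v else u
      other <- if (v %in% leaf_ids) u else v
      blocks <- lapply(setdiff(adj[[as.character(other)]], leaf_end),
                       function(w) side(other, w))
      w <- prod(vapply(blocks, length, integer(1)))
    } else {
      bu <- lapply(setdiff(adj[[as.character(u)]], v), function(w) side(u, w))
      bv <- lapply(setdiff(adj[[as.character(v)]], u), function(w) side(v, w))
      w <- prod(vapply(bu, length, integer(1))) +
        prod(vapply(bv, length, integer(1)))
    }
    rows[[length(rows) + 1L]] <- data.frame(sig = .split_sig(B, taxa), w = w,
                                            pendant = pendant)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$sig), , drop = FALSE]
}

#' Grove of a level-1 semidirected network
#'
#' The set of distinct unrooted tree topologies displayed on the network:
#' delete one hybrid edge from each pair, undirect, suppress degree-2 nodes.
#' Choices at 2- and 3-cycles yield identical topologies and are
#' de-duplicated, so the grove has size \code{2^k} for \code{k} cycles of
#' size 4 or more.
#'
#' @param unet an \code{"unrooted_network"}.
#' @return a list of trees (each \code{list(edges, labels)}), with the split
#'   signatures of each tree attached as attribute \code{"splits"}.
#' @export
grove <- function(unet) {
  ed <- unet$edges
  hyb_nodes <- sort(unique(ed$v2[ed$directed]))
  H <- length(hyb_nodes)
  seen <- character(0)
  trees <- list()
  combos <- if (H == 0L) list(logical(0)) else
    lapply(seq_len(2^H) - 1L, function(i) as.logical(bitwAnd(
      bitwShiftR(i, seq_len(H) - 1L), 1L)))
  for (ch in combos) {
    tr <- .displayed_tree(unet, ch)
    sw <- .tree_splits_w(tr, unet$taxa)
    key <- paste(sort(sw$sig), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    attr(tr, "splits") <- sw
    trees[[length(trees) + 1L]] <- tr
  }
  trees
}

#' Split system of a level-1 semidirected network
#'
#' The union of the splits of the grove trees, partitioned into cut splits
#' (compatible with every other split; displayed on every grove tree) and
#' cycle splits (incompatible with at least one other).
#'
#' @param unet an \code{"unrooted_network"}.
#' @return \code{list(splits, S_c, S_i)} of canonical split signatures.
#' @export
split_system <- function(unet) {
  gr <- grove(unet)
  sigs <- sort(unique(unlist(lapply(gr, function(t) attr(t, "splits")$sig))))
  inc <- vapply(sigs, function(s1) any(vapply(sigs, function(s2)
    !splits_compatible(s1, s2, unet$taxa), logical(1))), logical(1))
  list(splits = sigs, S_c = sigs[!inc], S_i = sigs[inc])
}

#' Are two splits compatible?
#'
#' Splits \code{A1|B1}, \code{A2|B2} are compatible when at least one of the
#' four pairwise intersections is empty.
#'
#' @param sig1,sig2 canonical split signatures (comma-joined side not
#'   containing the first taxon).
#' @param taxa the full taxon set.
#' @return logical.
#' @export
splits_compatible <- function(sig1, sig2, taxa) {
  a1 <- strsplit(sig1, ",", fixed = TRUE)[[1L]]
  a2 <- strsplit(sig2, ",", fixed = TRUE)[[1L]]
  b1 <- setdiff(taxa, a1); b2 <- setdiff(taxa, a2)
  !length(intersect(a1, a2)) || !length(intersect(a1, b2)) ||
    !length(intersect(b1, a2)) || !length(intersect(b1, b2))
}

#' Quartet weight function of a level-1 network
#'
#' For each split \code{s}, the sum over grove trees \code{T} of the tree
#' quartet weight \code{w_T(s)} (\code{|X1||X2| + |X3||X4|} for an internal
#' edge with adjacent blocks \code{X1..X4}; \code{|X1||X2|} for a pendant
#' edge).  Its support is exactly the network's split system.
#'
#' @param unet an \code{"unrooted_network"}.
#' @return a named numeric vector of weights, names = split signatures.
#' @export
quartet_weight <- function(unet) {
  gr <- grove(unet)
  acc <- list()
  for (t in gr) {
    sw <- attr(t, "splits")
    for (i in seq_len(nrow(sw))) {
      s <- sw$sig[i]
      acc[[s]] <- (if (is.null(acc[[s]])) 0 else acc[[s]]) + sw$w[i]
    }
  }
  unlist(acc)[sort(names(acc))]
}

#' Distance induced by a weighted split system
#'
#' \code{d(x,y)} is the total weight of the splits separating \code{x} and
#' \code{y}.
#'
#' @param omega named numeric vector of split weights (names = canonical
#'   signatures).
#' @param taxa character vector of taxa.
#' @return a symmetric matrix with zero diagonal.
#' @export
distance_from_splits <- function(omega, taxa) {
  n <- length(taxa)
  # membership matrix: does taxon j lie in the signature side of split i
  mem <- t(vapply(names(omega), function(s)
    taxa %in% strsplit(s, ",", fixed = TRUE)[[1L]], logical(n)))
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sep <- xor(mem[, i], mem[, j])
    D[i, j] <- D[j, i] <- sum(omega[sep])
  }
  D
}

# quartet topology of a 4-subset on a tree given its split membership matrix
# mem: splits x taxa logical; cols a<b<c<d (indices into taxa)
# returns 1 (ab|cd), 2 (ac|bd), 3 (ad|bc) or 0 (unresolved)
.quartet_topology_from_mem <- function(mem, a, b, c, d) {
  ma <- mem[, a]; mb <- mem[, b]; mc <- mem[, c]; md <- mem[, d]
  if (any(ma == mb & mc == md & ma != mc)) return(1L)
  if (any(ma == mc & mb == md & ma != mb)) return(2L)
  if (any(ma == md & mb == mc & ma != mb)) return(3L)
  0L
}

#' Theoretical quartet calls of a level-1 network
#'
#' For every 4-subset of taxa, the class of the induced quartet network after
#' contracting 2- and 3-cycles: a resolved quartet tree, or a 4-cycle
#' (recorded by its diagonal pairing, the quartet separating the two pairs
#' across the cycle).  Derived by restricting every grove tree to the four
#' taxa: a tree class displays a single topology; a 4-cycle displays exactly
#' two, and the absent topology is the diagonal.
#'
#' @param unet an \code{"unrooted_network"} (binary, level-1).
#' @return a data.frame with columns \code{t1..t4} (sorted taxa),
#'   \code{class} (\code{"tree"} or \code{"cycle4"}) and \code{topology}
#'   (1 = \code{ab|cd}, 2 = \code{ac|bd}, 3 = \code{ad|bc}; for
#'   \code{cycle4} the diagonal).
#' @export
theoretical_calls <- function(unet) {
  taxa <- unet$taxa
  n <- length(taxa)
  stopifnot(n >= 4L)
  gr <- grove(unet)
  mems <- lapply(gr, function(t) {
    sigs <- attr(t, "splits")$sig
    m <- t(vapply(sigs, function(s)
      taxa %in% strsplit(s, ",", fixed = TRUE)[[1L]], logical(n)))
    m
  })
  subs <- utils::combn(n, 4L)
  res <- vector("list", ncol(subs))
  for (i in seq_len(ncol(subs))) {
    q <- subs[, i]
    tops <- vapply(mems, .quartet_topology_from_mem,
                   integer(1), q[1L], q[2L], q[3L], q[4L])
    u <- sort(unique(tops))
    if (length(u) == 1L) {
      res[[i]] <- list(class = "tree", topology = u)
    } else if (length(u) == 2L) {
      res[[i]] <- list(class = "cycle4", topology = setdiff(1:3, u))
    } else stop("three distinct induced quartet topologies: not level-1")
  }
  data.frame(t1 = taxa[subs[1L, ]], t2 = taxa[subs[2L, ]],
             t3 = taxa[subs[3L, ]], t4 = taxa[subs[4L, ]],
             class = vapply(res, `[[`, character(1), "class"),
             topology = vapply(res, `[[`, integer(1), "topology"),
             stringsAsFactors = FALSE)
}

#' Theoretical quartet distances of a level-1 network
#'
#' Computes by two independent routes the distances attached to a binary
#' level-1 semidirected network: \code{d_omega}, induced by the quartet
#' weight function (grove enumeration), and \code{d_Q}, the quartet distance
#' assembled from the induced quartet networks' separation indicators.  For a
#' network with \code{k} cycles of size 4 or more, \code{d_omega = 2^k d_Q}.
#'
#' @param unet an \code{"unrooted_network"}.
#' @return \code{list(d_omega, d_Q, k)}.
#' @export
theoretical_distances <- function(unet) {
  om <- quartet_weight(unet)
  d_om <- distance_from_splits(om, unet$taxa)
  calls <- theoretical_calls(unet)
  d_q <- quartet_distance_matrix(calls, unet$taxa)
  list(d_omega = d_om, d_Q = d_q, k = unet$k)
}

#' Class of an induced quartet network
#'
#' Restricts a level-1 semidirected network to four taxa and reports the
#' reduced class (tree or 4-cycle, as in \code{\link{theoretical_calls}})
#' together with the inventory of cycle types \code{m_k} present before
#' contraction (\code{m} = induced cycle size, \code{k} = number of the four
#' taxa descended from its hybrid node).
#'
#' @param unet an \code{"unrooted_network"}.
#' @param four character vector of 4 taxa.
#' @return \code{list(class, topology, cycles)} where \code{cycles} is a
#'   data.frame with columns \code{m} and \code{k}.
#' @export
induced_quartet_class <- function(unet, four) {
  stopifnot(length(four) == 4L, all(four %in% unet$taxa))
  four <- sort(four)
  calls <- theoretical_calls(unet)
  row <- calls[calls$t1 == four[1L] & calls$t2 == four[2L] &
                 calls$t3 == four[3L] & calls$t4 == four[4L], ]
  cys <- cycle_structure(unet)
  inv <- list()
  for (cy in cys) {
    occ <- vapply(cy$blocks, function(b) sum(four %in% b), integer(1))
    if (occ[1L] == 0L) next           # hybrid block unoccupied: cycle opens
    j <- sum(occ > 0L)
    if (j < 2L) next                  # cycle contracted away
    inv[[length(inv) + 1L]] <- data.frame(m = j, k = occ[1L])
  }
  cycles <- if (length(inv)) do.call(rbind, inv) else
    data.frame(m = integer(0), k = integer(0))
  list(class = row$class, topology = row$topology, cycles = cycles)
}
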