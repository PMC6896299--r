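# NANUQ Step 5: construct a frontier-minimal, outer-labelled planar splits
# graph from a weighted circular split system, and read off network features
# (tree of blobs, 4-cycles, m-darts and their points).
#
# The construction is the incremental Circular Network Algorithm, realized
# combinatorially as chord insertion into the planar dual of a chord
# arrangement on a disk.  Taxon i of the circular ordering sits at boundary
# position 2i; the split with ordering-interval {p..q} is a chord with ends
# in the boundary gaps (2p-1, 2p) and (2q, 2q+1), with within-gap offsets
# chosen so that two chords cross exactly when their splits are
# incompatible.  Graph vertices are arrangement faces.  Inserting a chord
# routes it along a shortest path between the two boundary windows holding
# its ends; that path crosses exactly the previously inserted incompatible
# splits.  Each path face is split in two (joined by a new edge colored by
# the new split) and each crossed edge is duplicated ("ladder" edges).
# Rotation systems (counter-clockwise) are maintained explicitly, so the
# whole construction is exact integer/rational combinatorics.

#' Construct a frontier-minimal splits graph
#'
#' @param sw a \code{"split_weights"} object (see
#'   \code{\link{estimate_split_weights}}), or any list with
#'   \code{weights} (named by canonical signature), \code{ordering} and
#'   \code{taxa}.
#' @param eps splits with weight below this are ignored.
#' @param validate check, for every split, that deleting its color class
#'   disconnects the graph into exactly the split's two sides.
#' @return an object of class \code{"splits_graph"}: \code{edges}
#'   (data.frame v1, v2, split signature, weight, frontier flag),
#'   \code{vertex_taxa} (list: vertex id -> taxa), \code{ordering},
#'   \code{taxa}, \code{splits} (signature, interval, weight),
#'   \code{boundary} (the circular sequence of frontier edge ids in
#'   boundary order).
#' @export
circular_network <- function(sw, eps = 1e-10, validate = TRUE) {
  ordering <- canonical_ordering(sw$ordering)
  taxa <- sort(ordering)
  n <- length(ordering)
  wts <- sw$weights[sw$weights > eps]
  if (!length(wts)) stop("no splits with positive weight")

  # interval form of each split w.r.t. the ordering
  ivl <- t(vapply(names(wts), function(sig) {
    side <- strsplit(sig, ",", fixed = TRUE)[[1L]]
    if (ordering[1L] %in% side) side <- setdiff(taxa, side)
    pos <- sort(match(side, ordering))
    if (any(diff(pos) != 1L))
      stop(sprintf("split '%s' is not an interval of the ordering: non-circular input", sig))
    c(pos[1L], pos[length(pos)])
  }, integer(2)))
  splits <- data.frame(sig = names(wts), p = ivl[, 1L], q = ivl[, 2L],
                       w = as.numeric(wts), stringsAsFactors = FALSE)
  splits <- splits[order(-splits$w, splits$sig), ]
  rownames(splits) <- NULL
  ns <- nrow(splits)

  # state ---------------------------------------------------------------------
  rot <- list(c(-1L))                 # per-vertex CCW rotation; windows < 0
  win_lo <- 1; win_hi <- 2 * n + 1; win_v <- 1L
  ev1 <- integer(0); ev2 <- integer(0); espl <- integer(0)
  nv <- 1L
  new_vertex <- function() { nv <<- nv + 1L; rot[[nv]] <<- integer(0); nv }
  new_edge <- function(a, b, s) {
    ev1 <<- c(ev1, a); ev2 <<- c(ev2, b); espl <<- c(espl, s)
    length(ev1)
  }
  new_window <- function(lo, hi, v) {
    win_lo <<- c(win_lo, lo); win_hi <<- c(win_hi, hi); win_v <<- c(win_v, v)
    length(win_lo)
  }
  window_at <- function(pos) {
    w <- which(win_lo < pos & pos < win_hi)
    if (length(w) != 1L) stop("internal error: boundary window lookup")
    w
  }
  bfs_path <- function(u, v) {
    if (u == v) return(list(verts = u, edges = integer(0)))
    prev_v <- integer(nv); prev_e <- integer(nv)
    seen <- logical(nv); seen[u] <- TRUE
    frontier <- u
    while (length(frontier)) {
      nxt <- integer(0)
      for (x in frontier) {
        inc <- which(ev1 == x | ev2 == x)
        for (e in inc) {
          y <- if (ev1[e] == x) ev2[e] else ev1[e]
          if (!seen[y]) {
            seen[y] <- TRUE; prev_v[y] <- x; prev_e[y] <- e
            nxt <- c(nxt, y)
          }
        }
      }
      if (seen[v]) break
      frontier <- nxt
    }
    if (!seen[v]) stop("internal error: disconnected splits graph")
    verts <- v; edges <- integer(0)
    while (verts[1L] != u) {
      edges <- c(prev_e[verts[1L]], edges)
      verts <- c(prev_v[verts[1L]], verts)
    }
    list(verts = verts, edges = edges)
  }
  arc_between <- function(items, i_from, i_to) {
    # items strictly between positions i_from and i_to, cyclically forward
    k <- length(items)
    if (k == 0L) return(integer(0))
    idx <- i_from
    out <- integer(0)
    repeat {
      idx <- if (idx == k) 1L else idx + 1L
      if (idx == i_to) break
      out <- c(out, idx)
    }
    items[out]
  }

  for (j in seq_len(ns)) {
    p <- splits$p[j]; q <- splits$q[j]
    szA <- q - p + 1L
    E1 <- (2 * p - 1) + 1 - szA / n
    E2 <- (2 * q + 1) + szA / n
    if (E2 > 2 * n + 1) E2 <- E2 - 2 * n    # wrap past the cut (taxon 1 gap)
    w1 <- window_at(E1); w2 <- window_at(E2)
    u <- win_v[w1]; v <- win_v[w2]
    pth <- bfs_path(u, v)
    L <- length(pth$edges)
    # the path must cross exactly the previously inserted incompatible splits
    if (j > 1L) {
      pp <- splits$p[seq_len(j - 1L)]; qq <- splits$q[seq_len(j - 1L)]
      overlap <- pmax(pp, p) <= pmin(qq, q)
      nested <- (pp <= p & q <= qq) | (p <= pp & qq <= q)
      ninc <- sum(overlap & !nested)
      if (L != ninc) stop("internal error: path length != incompatibility count")
    } else if (L != 0L) stop("internal error: first split must not cross")

    single <- (L == 0L && w1 == w2)
    faces <- pth$verts
    sedge_prev <- NA_integer_
    doorB_prev <- NA_integer_
    for (i in seq_along(faces)) {
      f <- faces[i]
      rotf <- rot[[f]]
      door_in <- if (i == 1L) -w1 else pth$edges[i - 1L]
      door_out <- if (i == length(faces)) -w2 else pth$edges[i]
      fB <- new_vertex()
      se <- new_edge(f, fB, j)
      if (single) {
        # both chord ends inside one window: it splits in three
        i_w <- match(-w1, rotf)
        others <- arc_between(rotf, i_w, i_w)
        if (E1 < E2) {
          # A-arc (E1,E2) lies inside the window; everything else is B-side
          wmid <- new_window(E1, E2, f)
          whi <- new_window(E2, win_hi[w1], fB)
          win_hi[w1] <- E1                     # keeps id, low part (B)
          win_v[w1] <- fB
          rot[[f]] <- c(se, -wmid)
          rot[[fB]] <- c(se, -whi, others, -w1)
          for (e in others[others > 0L]) {
            if (ev1[e] == f) ev1[e] <- fB else ev2[e] <- fB
          }
          for (wd in -others[others < 0L]) win_v[wd] <- fB
        } else {
          # chord wraps the cut: A-arc = (E1,hi) + other items + (lo,E2)
          wA1 <- new_window(E1, win_hi[w1], f)
          wA2 <- new_window(win_lo[w1], E2, f)
          win_lo[w1] <- E2; win_hi[w1] <- E1   # keeps id, (E2,E1) is B
          win_v[w1] <- fB
          rot[[f]] <- c(se, -wA1, others, -wA2)
          rot[[fB]] <- c(se, -w1)
        }
      } else {
        i_in <- match(door_in, rotf)
        i_out <- match(door_out, rotf)
        A_items <- arc_between(rotf, i_in, i_out)
        B_items <- arc_between(rotf, i_out, i_in)
        # door pieces
        if (i == 1L) {
          wA <- new_window(E1, win_hi[w1], f)  # (E1, hi): A side
          win_hi[w1] <- E1                     # (lo, E1): B side
          door_in_A <- -wA
          door_in_B <- -w1
          win_v[w1] <- fB
        } else {
          door_in_A <- door_in                 # old edge id = A copy
          door_in_B <- doorB_prev
        }
        if (i == length(faces)) {
          wB <- new_window(E2, win_hi[w2], fB) # (E2, hi): B side
          win_hi[w2] <- E2                     # (lo, E2): A side
          door_out_A <- -w2
          door_out_B <- -wB
          doorB_cur <- NA_integer_
        } else {
          door_out_A <- door_out
          e <- door_out                        # duplicate for B side later
          to <- if (ev1[e] == f) ev2[e] else ev1[e]
          doorB_cur <- new_edge(fB, NA_integer_, espl[e])
          door_out_B <- doorB_cur
        }
        rot[[f]] <- c(se, door_in_A, A_items, door_out_A)
        rot[[fB]] <- c(se, door_out_B, B_items, door_in_B)
        for (e in B_items[B_items > 0L]) {
          if (ev1[e] == f) ev1[e] <- fB else ev2[e] <- fB
        }
        for (wd in -B_items[B_items < 0L]) win_v[wd] <- fB
        # complete previous B-door edge (its far endpoint is this face's B)
        if (i > 1L) {
          e <- doorB_prev
          if (is.na(ev2[e])) ev2[e] <- fB else ev1[e] <- fB
        }
        doorB_prev <- if (i < length(faces)) doorB_cur else NA_integer_
      }
      sedge_prev <- se
    }
  }

  # assemble ------------------------------------------------------------------
  edges <- data.frame(v1 = ev1, v2 = ev2,
                      sig = splits$sig[espl], weight = splits$w[espl],
                      stringsAsFactors = FALSE)
  # taxa at vertices
  vt <- vector("list", nv)
  for (i in seq_len(n)) {
    w <- window_at(2 * i)
    vtx <- win_v[w]
    vt[[vtx]] <- c(vt[[vtx]], ordering[i])
  }
  # frontier: for each chord end, the split's edge joining the windows on
  # either side of the end position
  endpos <- c((2 * splits$p - 1) + 1 - (splits$q - splits$p + 1) / n,
              (2 * splits$q + 1) + (splits$q - splits$p + 1) / n)
  endpos[endpos > 2 * n + 1] <- endpos[endpos > 2 * n + 1] - 2 * n
  endspl <- rep(seq_len(ns), 2L)
  o <- order(endpos)
  frontier_ids <- integer(0)
  for (k in o) {
    pos <- endpos[k]; s <- endspl[k]
    a <- win_v[which(abs(win_hi - pos) < 1e-12)]
    b <- win_v[which(abs(win_lo - pos) < 1e-12)]
    id <- which(espl == s & ((ev1 == a & ev2 == b) | (ev1 == b & ev2 == a)))
    if (length(id) != 1L) stop("internal error: frontier edge lookup")
    frontier_ids <- c(frontier_ids, id)
  }
  boundary <- frontier_ids              # in boundary circular order
  frontier <- unique(frontier_ids)
  edges$frontier <- seq_len(nrow(edges)) %in% frontier

  g <- structure(list(edges = edges, vertex_taxa = vt, ordering = ordering,
                      taxa = taxa, splits = splits, boundary = boundary),
                 class = "splits_graph")
  if (validate) validate_splits_graph(g)
  g
}

#' Validate the defining property of a splits graph
#'
#' For every split, deleting all edges of its color must leave exactly two
#' connected components whose taxon sets are the split's two sides.
#'
#' @param g a \code{"splits_graph"}.
#' @return \code{g}, invisibly.
#' @export
validate_splits_graph <- function(g) {
  ed <- g$edges
  verts <- sort(unique(c(ed$v1, ed$v2)))
  for (sig in unique(ed$sig)) {
    keep <- ed$sig != sig
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$v1[keep]),
                 to = as.character(ed$v2[keep])),
      directed = FALSE, vertices = data.frame(name = as.character(verts)))
    comp <- igraph::components(ig)
    if (comp$no != 2L)
      stop(sprintf("split '%s': deletion leaves %d components", sig, comp$no))
    memb <- comp$membership[as.character(verts)]
    side1 <- sort(unlist(g$vertex_taxa[verts[memb == 1L]]))
    sideA <- strsplit(sig, ",", fixed = TRUE)[[1L]]
    if (!(setequal(side1, sideA) || setequal(side1, setdiff(g$taxa, sideA))))
      stop(sprintf("split '%s' is not realized by its color class", sig))
  }
  invisible(g)
}

#' @export
print.splits_graph <- function(x, ...) {
  bl <- splits_graph_blobs(x)
  cat(sprintf("Splits graph: %d taxa, %d vertices, %d edges (%d frontier), %d blob%s\n",
              length(x$taxa), length(unique(c(x$edges$v1, x$edges$v2))),
              nrow(x$edges), sum(x$edges$frontier), length(bl),
              if (length(bl) == 1) "" else "s"))
  invisible(x)
}

# blobs: 2-edge-connected components with at least one edge; returns a list
# of integer edge-index vectors
splits_graph_blobs <- function(g) {
  ed <- g$edges
  ig <- igraph::graph_from_edgelist(cbind(ed$v1, ed$v2), directed = FALSE)
  br <- igraph::bridges(ig)
  keep <- setdiff(seq_len(nrow(ed)), as.integer(br))
  if (!length(keep)) return(list())
  sub <- igraph::subgraph_from_edges(ig, keep, delete.vertices = FALSE)
  comp <- igraph::components(sub)$membership
  out <- split(keep, comp[ed$v1[keep]])
  unname(out)
}

#' Tree of blobs of a splits graph
#'
#' Contracts every blob (maximal 2-edge-connected piece) to a single vertex;
#' the remaining cut edges form a tree on the taxa, generally with
#' multifurcations.  Isomorphic to the tree of blobs of the level-1 network
#' whose split system the graph realizes.
#'
#' @param g a \code{"splits_graph"}.
#' @return an \code{ape} \code{"phylo"} tree (possibly multifurcating).
#' @export
tree_of_blobs <- function(g) {
  ed <- g$edges
  verts <- sort(unique(c(ed$v1, ed$v2)))
  blobs <- splits_graph_blobs(g)
  group <- stats::setNames(as.character(verts), verts)
  for (i in seq_along(blobs)) {
    bv <- unique(c(ed$v1[blobs[[i]]], ed$v2[blobs[[i]]]))
    group[as.character(bv)] <- paste0("blob", i)
  }
  bridge_idx <- setdiff(seq_len(nrow(ed)), unlist(blobs))
  # newick via recursive traversal of the contracted tree
  adj <- list()
  addadj <- function(a, b) adj[[a]] <<- c(adj[[a]], b)
  for (e in bridge_idx) {
    a <- group[[as.character(ed$v1[e])]]
    b <- group[[as.character(ed$v2[e])]]
    addadj(a, b); addadj(b, a)
  }
  taxa_of <- function(gid) {
    vs <- verts[group[as.character(verts)] == gid]
    sort(unlist(g$vertex_taxa[vs]))
  }
  all_groups <- unique(group)
  rec <- function(gid, from) {
    here <- taxa_of(gid)
    kids <- setdiff(adj[[gid]], from)
    parts <- c(here, vapply(kids, rec, character(1), from = gid))
    if (length(parts) == 1L) parts else
      paste0("(", paste(parts, collapse = ","), ")")
  }
  start <- all_groups[1L]
  nw <- rec(start, from = NA_character_)
  if (!startsWith(nw, "(")) nw <- paste0("(", nw, ")")
  ape::read.tree(text = paste0(nw, ";"))
}

#' Detect darts and 4-cycles among the blobs of a splits graph
#'
#' For each blob, checks the frontier structure predicted for a
#' frontier-minimal splits graph of a level-1 network: the blob frontier is
#' a cycle of \code{4(m-3)} edges whose corner gaps, starting at the dart's
#' point, are \code{(m-3, 1, 2, ..., 2, 1, m-3)}; for \code{m = 4} a plain
#' quadrilateral (no identifiable point, as the hybrid node of a 4-cycle is
#' not identifiable).  Blobs matching no such pattern are reported as
#' non-conforming (a model-fit warning, never silently repaired).
#'
#' @param g a \code{"splits_graph"}.
#' @return a list of annotations: \code{m}, \code{conforming},
#'   \code{blocks} (list of taxon blocks in circular order; for conforming
#'   blobs with \code{m >= 5} the first block is the dart's point, the
#'   hybrid side), \code{point} (taxa at the point, or NULL),
#'   \code{frontier_size}, \code{gaps}.
#' @export
detect_darts <- function(g) {
  ed <- g$edges
  blobs <- splits_graph_blobs(g)
  bridge_idx <- setdiff(seq_len(nrow(ed)), unlist(blobs))
  out <- list()
  for (bl in blobs) {
    bverts <- unique(c(ed$v1[bl], ed$v2[bl]))
    fr <- bl[ed$frontier[bl]]
    ann <- list(m = NA_integer_, conforming = FALSE, blocks = NULL,
                point = NULL, frontier_size = length(fr), gaps = NULL)
    # frontier must form a single cycle covering its vertices
    deg <- table(c(ed$v1[fr], ed$v2[fr]))
    if (length(fr) >= 3L && all(deg == 2L)) {
      # traverse the frontier cycle
      cyc_v <- integer(0)
      e0 <- fr[1L]
      cur_v <- ed$v1[e0]; cur_e <- e0
      repeat {
        cyc_v <- c(cyc_v, cur_v)
        nxt_v <- if (ed$v1[cur_e] == cur_v) ed$v2[cur_e] else ed$v1[cur_e]
        nxt_e <- setdiff(fr[ed$v1[fr] == nxt_v | ed$v2[fr] == nxt_v], cur_e)
        cur_v <- nxt_v; cur_e <- nxt_e[1L]
        if (cur_v == cyc_v[1L]) break
      }
      if (length(cyc_v) == length(fr)) {
        # corners: frontier vertices with an attachment (bridge or taxa)
        has_att <- vapply(cyc_v, function(v) {
          length(g$vertex_taxa[[v]]) > 0L ||
            any(ed$v1[bridge_idx] == v | ed$v2[bridge_idx] == v)
        }, logical(1))
        corners <- which(has_att)
        if (length(corners) >= 3L) {
          gaps <- diff(c(corners, corners[1L] + length(cyc_v)))
          m <- length(corners)
          F <- length(fr)
          allowed <- setdiff(seq_len(nrow(ed)), bl)
          blocks <- lapply(cyc_v[corners], function(v) {
            reach <- v
            repeat {
              inc <- allowed[ed$v1[allowed] %in% reach |
                               ed$v2[allowed] %in% reach]
              nxt <- unique(c(ed$v1[inc], ed$v2[inc], reach))
              if (length(nxt) == length(reach)) break
              reach <- nxt
            }
            sort(unlist(g$vertex_taxa[reach]))
          })
          ok4 <- (m == 4L && F == 4L && all(gaps == 1L))
          okm <- FALSE
          if (m >= 5L && F == 4L * (m - 3L)) {
            P <- c(m - 3L, 1L, rep(2L, m - 4L), 1L, m - 3L)[seq_len(m)]
            # the closed gap walk starting at the point reads
            # (m-3, 1, 2, ..., 2, 1, m-3); search both traversal
            # directions and all rotations
            for (dirn in 1:2) {
              cseq <- if (dirn == 1L) seq_len(m) else c(1L, m:2L)
              gseq <- if (dirn == 1L) gaps else rev(gaps)
              for (r in seq_len(m)) {
                idx <- ((seq_len(m) + r - 2L) %% m) + 1L
                if (all(gseq[idx] == P)) {
                  okm <- TRUE
                  blocks <- blocks[cseq[idx]]
                  gaps <- gseq[idx]
                  break
                }
              }
              if (okm) break
            }
          }
          if (ok4 || okm) {
            ann <- list(m = m, conforming = TRUE, blocks = blocks,
                        point = if (m >= 5L) blocks[[1L]] else NULL,
                        frontier_size = F, gaps = gaps)
          } else {
            ann$blocks <- blocks
            ann$gaps <- gaps
            ann$m <- m
          }
        }
      }
    }
    out[[length(out) + 1L]] <- ann
  }
  out
}

#' Interpret a splits graph as level-1 network features
#'
#' Applies the splits-graph reading rules in reverse: the tree of blobs, and
#' for each blob its cycle size, the circular order of attached taxon
#' blocks, and (for darts, cycle size 5 or more) the hybrid block at the
#' dart's point.  2- and 3-cycles of the original network, and the hybrid
#' node of a 4-cycle, are not identifiable and are not reported.
#' Non-conforming blobs are flagged, not repaired.
#'
#' @param g a \code{"splits_graph"}.
#' @return an object of class \code{"nanuq_interpretation"}: a list with
#'   \code{tree_of_blobs} (Newick string), \code{blobs} (the
#'   \code{\link{detect_darts}} annotations), and counts by type.
#' @export
interpret_splits_graph <- function(g) {
  tob <- tree_of_blobs(g)
  darts <- detect_darts(g)
  msize <- vapply(darts, function(d)
    if (isTRUE(d$conforming)) d$m else NA_integer_, integer(1))
  structure(list(
    tree_of_blobs = ape::write.tree(tob),
    blobs = darts,
    n_cycle4 = sum(msize == 4L, na.rm = TRUE),
    n_darts = sum(msize >= 5L, na.rm = TRUE),
    n_nonconforming = sum(is.na(msize)),
    caveat = paste("2- and 3-cycles are unidentifiable;",
                   "the hybrid node of a 4-cycle is unidentifiable")),
    class = "nanuq_interpretation")
}

#' @export
print.nanuq_interpretation <- function(x, ...) {
  cat("Tree of blobs:", x$tree_of_blobs, "\n")
  cat(sprintf("Blobs: %d four-cycles, %d darts, %d non-conforming\n",
              x$n_cycle4, x$n_darts, x$n_nonconforming))
  for (d in x$blobs) {
    if (isTRUE(d$conforming)) {
      cat(sprintf("  %d-cycle: blocks (%s)%s\n", d$m,
                  paste(vapply(d$blocks, paste, character(1), collapse = "+"),
                        collapse = " | "),
                  if (!is.null(d$point))
                    paste0("; hybrid block {",
                           paste(d$point, collapse = ","), "}") else ""))
    } else {
      cat(sprintf("  non-conforming blob (frontier %d)\n", d$frontier_size))
    }
  }
  cat("Note:", x$caveat, "\n")
  invisible(x)
}

#' Export a splits graph in DOT format
#'
#' @param g a \code{"splits_graph"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dot <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph splitsgraph {", con)
  verts <- sort(unique(c(g$edges$v1, g$edges$v2)))
  for (v in verts) {
    tx <- g$vertex_taxa[[v]]
    lab <- if (length(tx)) paste(tx, collapse = ",") else ""
    writeLines(sprintf('  n%d [label="%s"];', v, lab), con)
  }
  for (i in seq_len(nrow(g$edges)))
    writeLines(sprintf('  n%d -- n%d [label="%s", weight=%g];',
                       g$edges$v1[i], g$edges$v2[i], g$edges$sig[i],
                       g$edges$weight[i]), con)
  writeLines("}", con)
  invisible(path)
}
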