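# Programmatic network fixtures: the 16-taxon simulation benchmark network,
# parametric single-cycle quartet networks, and random level-1 networks with
# a prescribed cycle-size multiset.

#' The 16-taxon benchmark species network
#'
#' A metric level-1 network on taxa a..p with seven hybrid nodes forming
#' 2-, 3-, 4-, 5- and 6-cycles, used as the standard simulation benchmark:
#' after contracting 2- and 3-cycles its cycles are a 4-cycle with hybrid
#' block \{b,c\}, a 5-cycle with hybrid block \{g,h\}, and a 6-cycle with
#' hybrid block \{l,m\}.  Branch lengths are in coalescent units.
#'
#' @return a \code{"rooted_network"}.
#' @export
benchmark_network16 <- function() {
  parse_enewick(paste0(
    "(((((a:1.5,(((b:.8,h1#.5:.1)x1:.2,(c:.7)h1#.5:.3)x2:.3)h2#.5:.2)",
    "x3:1.5,(h2#.5:.2,d:1.5)x4:1.5)x5:2,h3#.5:1.5)x6:0.5,",
    "(((e:2,(f:1,((g:.25,h:.25)x7:.25)h4#.5:.5)x8:1)x9:1,",
    "(h4#.5:.5,i:1)x10:2)x11:0.5)h3#.5:2)x12:1,",
    "((((j:4.5,(k:3.5,((l:2.75,m:2.75)x13:.25)h5#.3:.5)x14:1)x15:1,",
    "((((n:1)h6#.5:2,h6#.5:2)x16:.5,h5#.3:.5)x17:1,(o:3.5,p:3.5)x18:1)",
    "x19:1)x20:.25)h7#.5:.5,h7#.5:.5)x21:.25)r;"))
}

#' 3_2-cycle quartet network
#'
#' The 4-taxon network whose 3-cycle hybrid node has two descendant taxa
#' (a, b): below the hybrid node an edge of length \code{t1} leads to the
#' cherry (a,b); the hybrid edges have lengths \code{t2} (toward taxon c's
#' side, inherited probability \code{1 - gamma}) and \code{t4} (toward taxon
#' d's side, probability \code{gamma}); \code{t3} is the cycle's tree edge.
#' Its CFs are given in closed form by \code{\link{cf_32cycle}} at
#' \code{x_i = exp(-t_i)}.
#'
#' @param t1,t2,t3,t4 branch lengths in coalescent units.
#' @param gamma hybridization parameter of the \code{t4}-side hybrid edge.
#' @return a \code{"rooted_network"} on taxa a, b, c, d.
#' @export
quartet_network_32 <- function(t1, t2, t3, t4, gamma) {
  stopifnot(t1 >= 0, t3 >= 0, gamma > 0, gamma < 1)
  txt <- sprintf(
    "((c:1,((a:1,b:1)w:%.15g)h#%.15g:%.15g)u:%.15g,(d:1,h#%.15g:%.15g)v:%.15g)r;",
    t1, 1 - gamma, t2, t3 / 2, gamma, t4, t3 / 2)
  parse_enewick(txt)
}

#' 4_1-cycle quartet network
#'
#' The 4-taxon network displaying a 4-cycle with singleton blocks in
#' circular order (a, b, c, d), hybrid node above taxon a; deleting one or
#' the other hybrid edge displays the quartets \code{ab|cd} and
#' \code{ad|bc}.
#'
#' @param t1,t2 lengths of the cycle's tree edges (c-side to b-side and
#'   c-side to d-side).
#' @param t4,t5 lengths of the hybrid edges (b-side, d-side).
#' @param gamma hybridization parameter of the b-side hybrid edge.
#' @return a \code{"rooted_network"} on taxa a, b, c, d.
#' @export
quartet_network_41 <- function(t1 = 1, t2 = 1, t4 = 1, t5 = 1, gamma = 0.5) {
  txt <- sprintf(
    "(c:1,((b:1,(a:1)h#%.15g:%.15g)u1:%.15g,(d:1,h#%.15g:%.15g)u3:%.15g)u2:1)t;",
    gamma, t4, t1, 1 - gamma, t5, t2)
  parse_enewick(txt)
}

#' Random level-1 semidirected network with prescribed cycle sizes
#'
#' Starts from a random unrooted binary tree and expands disjoint connected
#' sets of internal vertices into cycles of the requested sizes (a set of
#' \code{m - 2} internal tree vertices has exactly \code{m} outgoing edges,
#' which become the cycle's attachment edges in random circular order, with
#' a random hybrid position).  Used as a property-test fixture for the
#' combinatorial oracles; edge lengths are set to 1 and gammas to 1/2.
#'
#' @param n number of taxa (labels t01, t02, ...).
#' @param cycle_sizes integer vector of cycle sizes (each at least 3).
#' @param seed integer seed.
#' @return an \code{"unrooted_network"}.
#' @export
random_level1_unrooted <- function(n, cycle_sizes = integer(0), seed) {
  stopifnot(n >= 4L, all(cycle_sizes >= 3L))
  # cycle growth can dead-end on an unlucky draw; retry deterministically
  for (attempt in 0:99) {
    out <- tryCatch(.random_level1_once(n, cycle_sizes,
                                        seed + 7919L * attempt),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
  }
  stop(out)
}

.random_level1_once <- function(n, cycle_sizes, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, rooted = TRUE, br = NULL))
  labs <- sprintf("t%02d", seq_len(n))
  tr$tip.label <- sample(labs)
  nt <- length(tr$tip.label)
  ed <- data.frame(v1 = tr$edge[, 1L], v2 = tr$edge[, 2L], directed = FALSE,
                   length = 1, gamma = NA_real_)
  node_lab <- rep(NA_character_, max(ed$v1, ed$v2))
  node_lab[seq_len(nt)] <- tr$tip.label
  used <- logical(max(ed$v1, ed$v2) + sum(cycle_sizes))
  next_id <- max(ed$v1, ed$v2)
  for (m in cycle_sizes) {
    internal <- setdiff(unique(c(ed$v1, ed$v2)), which(!is.na(node_lab)))
    deg <- table(c(ed$v1, ed$v2))
    internal <- internal[deg[as.character(internal)] == 3L & !used[internal]]
    if (!length(internal)) stop("tree too small for requested cycles")
    S <- sample(internal, 1L)
    while (length(S) < m - 2L) {
      nb <- unique(c(ed$v2[ed$v1 %in% S], ed$v1[ed$v2 %in% S]))
      nb <- intersect(setdiff(nb, S), internal)
      if (!length(nb)) stop("could not grow cycle: try another seed")
      S <- c(S, if (length(nb) == 1L) nb else sample(nb, 1L))
    }
    used[S] <- TRUE
    inside <- which(ed$v1 %in% S & ed$v2 %in% S)
    outside <- setdiff(which(ed$v1 %in% S | ed$v2 %in% S), inside)
    stopifnot(length(outside) == m)
    # new cycle nodes c_1..c_m in random attachment order; hybrid at c_1
    ord <- sample(outside)
    cyc <- next_id + seq_len(m)
    next_id <- next_id + m
    used[cyc] <- TRUE
    for (i in seq_len(m)) {
      e <- ord[i]
      if (ed$v1[e] %in% S) ed$v1[e] <- cyc[i] else ed$v2[e] <- cyc[i]
    }
    ed <- ed[-inside, , drop = FALSE]
    # cycle edges: hybrid c_1 receives directed edges from c_2 and c_m
    newe <- data.frame(
      v1 = c(cyc[2L], cyc[m], cyc[2:(m - 1L)]),
      v2 = c(cyc[1L], cyc[1L], cyc[3:m]),
      directed = c(TRUE, TRUE, rep(FALSE, m - 2L)),
      length = 1, gamma = c(0.5, 0.5, rep(NA_real_, m - 2L)))
    newe <- newe[seq_len(m), , drop = FALSE]   # m edges total
    ed <- rbind(ed, newe)
  }
  ids <- sort(unique(c(ed$v1, ed$v2)))
  nodes <- data.frame(id = ids, label = node_lab[ids],
                      stringsAsFactors = FALSE)
  out <- structure(list(nodes = nodes, edges = ed, taxa = sort(labs)),
                   class = "unrooted_network")
  out$k <- sum(cycle_sizes >= 4L)
  out
}
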