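#' Parse a rooted metric level-1 network from extended Newick
#'
#' Reads the extended-Newick dialect in which a hybrid node is written as a
#' token \code{name#g:len} appearing exactly twice: once as a "leaf"
#' placeholder and once carrying the subtree below the hybrid node.  \code{g}
#' is a hybridization parameter and \code{len} the length of that hybrid edge
#' in coalescent units.  The two occurrences are merged into a single hybrid
#' node with two parent (hybrid) edges.
#'
#' Hybridization parameters: if the two occurrences of a hybrid token carry
#' values summing to 1, they are used directly; if they carry equal values
#' \code{g}, the occurrence appearing first in the string receives
#' \code{gamma = g} and the second \code{1 - g}.  Any other pattern is an
#' error, as the parameters of paired hybrid edges must sum to 1.
#'
#' @param text a single extended-Newick string (whitespace is ignored; the
#'   terminating \code{";"} is optional).
#' @param validate check the degree/parameter invariants of a binary rooted
#'   network (root outdegree 2; tree nodes in 1 / out 2; hybrid nodes in 2 /
#'   out 1; leaves labelled; gamma in (0,1) summing to 1 per hybrid node).
#' @return an object of class \code{"rooted_network"}: a list with
#'   \code{nodes} (id, label, type), \code{edges} (parent, child, length,
#'   gamma, hybrid), \code{taxa}, and \code{level1} (logical: no two cycles of
#'   the underlying undirected graph share a vertex).
#' @examples
#' net <- parse_enewick("((a:1,(b:1)h1#0.4:1)x:1,(h1#0.6:1,c:1)y:1)r;")
#' net$taxa
#' @export
parse_enewick <- function(text, validate = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  if (!nzchar(s)) stop("empty extended-Newick string")

  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop(sprintf("eNewick parse error at offset %d: %s", pos, msg))

  # temp occurrence records
  occ <- list()   # each: label, gamma, length, children (indices), start
  new_occ <- function(label, gamma, len, children, start) {
    occ[[length(occ) + 1L]] <<- list(label = label, gamma = gamma,
                                     length = len, children = children,
                                     start = start)
    length(occ)
  }

  read_token <- function() {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% c("(", ")", ",", ":", ";")))
      advance()
    substr(s, start, pos - 1L)
  }
  read_number <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9.eE+-]", substr(s, pos, pos))) advance()
    val <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
    if (is.na(val)) fail("expected a number")
    val
  }

  parse_suffix <- function(children) {
    start <- pos
    tok <- read_token()
    gamma <- NA_real_
    label <- tok
    if (grepl("#", tok)) {
      parts <- strsplit(tok, "#", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) fail("malformed hybrid token")
      label <- parts[1L]
      if (!nzchar(label)) fail("hybrid token requires a name")
      gamma <- suppressWarnings(as.numeric(parts[2L]))
      if (is.na(gamma)) fail("malformed hybrid parameter")
    }
    len <- NA_real_
    if (peek() == ":") { advance(); len <- read_number() }
    new_occ(if (nzchar(label)) label else NA_character_, gamma, len, children, start)
  }

  parse_clade <- function() {
    if (peek() == "(") {
      advance()
      children <- c(parse_clade())
      while (peek() == ",") { advance(); children <- c(children, parse_clade()) }
      if (peek() != ")") fail("expected ')'")
      advance()
      parse_suffix(children)
    } else {
      if (peek() %in% c(")", ",", ":", "")) fail("expected a label or '('")
      parse_suffix(integer(0))
    }
  }

  root_occ <- parse_clade()
  if (pos <= n) fail("trailing characters")

  # merge hybrid occurrences --------------------------------------------------
  is_hyb <- vapply(occ, function(o) !is.na(o$gamma), logical(1))
  hyb_labels <- unique(vapply(occ[is_hyb], `[[`, character(1), "label"))
  occ_of <- function(lbl) which(is_hyb & vapply(occ, function(o)
    identical(o$label, lbl), logical(1)))

  # final node table; map occurrence index -> final node id
  node_id_of_occ <- integer(length(occ))
  nodes <- list()
  add_node <- function(label, type) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, label = label, type = type)
    id
  }
  hyb_node_of <- new.env()
  for (lbl in hyb_labels) {
    idx <- occ_of(lbl)
    if (length(idx) != 2L)
      stop(sprintf("hybrid token '%s' appears %d times (must be exactly 2)",
                   lbl, length(idx)))
    assign(lbl, add_node(lbl, "hybrid"), envir = hyb_node_of)
  }
  for (i in seq_along(occ)) {
    o <- occ[[i]]
    if (is_hyb[i]) {
      node_id_of_occ[i] <- get(o$label, envir = hyb_node_of)
    } else {
      type <- if (length(o$children) == 0L) "leaf" else "tree"
      node_id_of_occ[i] <- add_node(o$label, type)
    }
  }
  node_id_of_occ[root_occ] -> root_id
  nodes[[root_id]]$type <- "root"

  # resolve gammas per hybrid label
  gamma_of_occ <- rep(NA_real_, length(occ))
  for (lbl in hyb_labels) {
    idx <- occ_of(lbl)
    idx <- idx[order(vapply(occ[idx], `[[`, numeric(1), "start"))]
    g <- vapply(occ[idx], `[[`, numeric(1), "gamma")
    if (abs(sum(g) - 1) < 1e-8) {
      gg <- g
    } else if (abs(g[1] - g[2]) < 1e-12) {
      gg <- c(g[1], 1 - g[1])
    } else {
      stop(sprintf("hybrid '%s': parameters %g, %g neither sum to 1 nor are equal",
                   lbl, g[1], g[2]))
    }
    if (any(gg <= 0 | gg >= 1))
      stop(sprintf("hybrid '%s': hybridization parameter outside (0,1)", lbl))
    gamma_of_occ[idx] <- gg
    # hybrid child subtree: exactly one occurrence may carry children
    kids <- vapply(occ[idx], function(o) length(o$children), integer(1))
    if (sum(kids > 0) != 1L)
      stop(sprintf("hybrid '%s': exactly one occurrence must carry the subtree",
                   lbl))
  }

  # edges ---------------------------------------------------------------------
  edges <- list()
  add_edge <- function(parent, child, len, gamma, hybrid) {
    edges[[length(edges) + 1L]] <<- list(parent = parent, child = child,
                                         length = len, gamma = gamma,
                                         hybrid = hybrid)
  }
  for (i in seq_along(occ)) {
    o <- occ[[i]]
    for (ch in o$children) {
      co <- occ[[ch]]
      add_edge(node_id_of_occ[i], node_id_of_occ[ch],
               if (is.na(co$length)) 0 else co$length,
               gamma_of_occ[ch], is_hyb[ch])
    }
  }

  nodes_df <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    label = vapply(nodes, function(x) if (is.null(x$label) || is.na(x$label))
      NA_character_ else x$label, character(1)),
    type = vapply(nodes, `[[`, character(1), "type"),
    stringsAsFactors = FALSE)
  edges_df <- data.frame(
    parent = vapply(edges, `[[`, integer(1), "parent"),
    child = vapply(edges, `[[`, integer(1), "child"),
    length = vapply(edges, `[[`, numeric(1), "length"),
    gamma = vapply(edges, `[[`, numeric(1), "gamma"),
    hybrid = vapply(edges, `[[`, logical(1), "hybrid"),
    stringsAsFactors = FALSE)

  taxa <- nodes_df$label[nodes_df$type == "leaf"]
  if (anyNA(taxa)) stop("unlabelled leaf in network")
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1])

  net <- structure(list(nodes = nodes_df, edges = edges_df,
                        taxa = sort(taxa)), class = "rooted_network")
  if (validate) validate_rooted_network(net)
  net$level1 <- is_level1(net)
  net
}

#' Validate the structural invariants of a rooted binary network
#'
#' Checks the defining degree constraints (root in 0 / out 2, leaves in 1 /
#' out 0, tree nodes in 1 / out 2, hybrid nodes in 2 / out 1), positivity of
#' tree edge lengths, the gamma-sum condition on paired hybrid edges, and
#' acyclicity.  Errors on the first violation.
#'
#' @param net a \code{"rooted_network"}.
#' @return \code{net}, invisibly.
#' @export
validate_rooted_network <- function(net) {
  nd <- net$nodes; ed <- net$edges
  indeg <- tabulate(ed$child, nbins = nrow(nd))
  outdeg <- tabulate(ed$parent, nbins = nrow(nd))
  expect <- list(root = c(0, 2), leaf = c(1, 0), tree = c(1, 2), hybrid = c(2, 1))
  for (i in seq_len(nrow(nd))) {
    e <- expect[[nd$type[i]]]
    if (indeg[i] != e[1] || outdeg[i] != e[2])
      stop(sprintf("node %d (%s): indegree %d / outdegree %d violates type",
                   i, nd$type[i], indeg[i], outdeg[i]))
  }
  if (any(!ed$hybrid & ed$length <= 0))
    stop("tree edge with non-positive length")
  if (any(ed$length < 0)) stop("negative edge length")
  hy <- ed[ed$hybrid, , drop = FALSE]
  if (any(is.na(hy$gamma)) || any(hy$gamma <= 0 | hy$gamma >= 1))
    stop("hybrid edge with gamma outside (0,1)")
  for (h in unique(hy$child)) {
    g <- hy$gamma[hy$child == h]
    if (length(g) != 2L || abs(sum(g) - 1) > 1e-8)
      stop(sprintf("hybrid node %d: gammas do not sum to 1", h))
  }
  # acyclicity via topological sort
  if (is.null(topo_order(net))) stop("directed cycle in network")
  invisible(net)
}

# topological order of node ids (children after parents); NULL if cyclic
topo_order <- function(net) {
  ed <- net$edges
  nv <- nrow(net$nodes)
  indeg <- tabulate(ed$child, nbins = nv)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    ch <- ed$child[ed$parent == v]
    for (c2 in ch) {
      indeg[c2] <- indeg[c2] - 1L
      if (indeg[c2] == 0L) queue <- c(queue, c2)
    }
  }
  if (length(out) != nv) NULL else out
}

#' Test whether a network is level-1
#'
#' A binary network is level-1 when no two cycles of its underlying
#' undirected (multi)graph share a vertex; equivalently every biconnected
#' component is a single edge or a simple cycle.
#'
#' @param net a \code{"rooted_network"} or \code{"unrooted_network"}.
#' @return logical.
#' @export
is_level1 <- function(net) {
  ed <- net$edges
  if (inherits(net, "rooted_network")) {
    el <- cbind(ed$parent, ed$child)
  } else {
    el <- cbind(ed$v1, ed$v2)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  bc <- igraph::biconnected_components(g)
  for (compE in bc$component_edges) {
    if (length(compE) <= 1L) next
    sub <- igraph::subgraph_from_edges(g, compE, delete.vertices = TRUE)
    if (any(igraph::degree(sub) != 2L)) return(FALSE)
    if (igraph::ecount(sub) != igraph::vcount(sub)) return(FALSE)
  }
  TRUE
}

#' @export
print.rooted_network <- function(x, ...) {
  nh <- sum(x$nodes$type == "hybrid")
  cat(sprintf("Rooted metric binary network: %d taxa, %d hybrid node%s%s\n",
              length(x$taxa), nh, if (nh == 1) "" else "s",
              if (isTRUE(x$level1)) ", level-1" else ""))
  cat("Taxa:", paste(x$taxa, collapse = " "), "\n")
  invisible(x)
}

#' Write a rooted network in extended Newick
#'
#' Inverse of \code{\link{parse_enewick}}: hybrid nodes are emitted as paired
#' \code{name#gamma:len} tokens (subtree on the first-written occurrence).
#'
#' @param net a \code{"rooted_network"}.
#' @return a single extended-Newick string terminated by \code{";"}.
#' @export
write_enewick <- function(net) {
  nd <- net$nodes; ed <- net$edges
  hyb_seen <- new.env()
  fmt_num <- function(x) sprintf("%.10g", x)
  rec <- function(v, elen, egam, ehyb) {
    lab <- nd$label[v]
    if (ehyb) {
      tok <- sprintf("%s#%s", if (is.na(lab)) paste0("H", v) else lab,
                     fmt_num(egam))
      first <- !exists(as.character(v), envir = hyb_seen)
      if (first) assign(as.character(v), TRUE, envir = hyb_seen)
      inner <- if (first) {
        ch <- which(ed$parent == v)
        paste0("(", paste(vapply(ch, function(e)
          rec(ed$child[e], ed$length[e], ed$gamma[e], ed$hybrid[e]),
          character(1)), collapse = ","), ")")
      } else ""
      return(paste0(inner, tok, ":", fmt_num(elen)))
    }
    ch <- which(ed$parent == v)
    body <- if (length(ch) == 0L) {
      lab
    } else {
      paste0("(", paste(vapply(ch, function(e)
        rec(ed$child[e], ed$length[e], ed$gamma[e], ed$hybrid[e]),
        character(1)), collapse = ","),
        ")", if (!is.na(lab)) lab else "")
    }
    if (is.na(elen)) body else paste0(body, ":", fmt_num(elen))
  }
  root <- nd$id[nd$type == "root"]
  paste0(rec(root, NA_real_, NA_real_, FALSE), ";")
}

#' Read unrooted topological gene trees from a Newick file
#'
#' One tree per line; lines starting with \code{#} and blank lines are
#' skipped.  Metric annotations are accepted and ignored downstream (the
#' pipeline uses topologies only).  Trees with duplicate leaf labels are
#' rejected; trees with fewer than 4 leaves are accepted and simply
#' contribute no quartets.
#'
#' @param path file of Newick strings, or a character vector of Newick
#'   strings via \code{text}.
#' @param text optional character vector of Newick strings (overrides
#'   \code{path}).
#' @return an \code{ape} \code{"multiPhylo"} list.
#' @export
read_gene_trees <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(file.exists(path))
    text <- readLines(path, warn = FALSE)
  }
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  if (!length(text)) stop("no gene trees found")
  trees <- ape::read.tree(text = paste(text, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  for (i in seq_along(trees)) {
    labs <- trimws(trees[[i]]$tip.label)
    if (anyDuplicated(labs))
      stop(sprintf("tree %d: duplicate leaf label '%s'", i,
                   labs[duplicated(labs)][1]))
    trees[[i]]$tip.label <- labs
  }
  trees
}
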