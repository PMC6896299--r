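# Gene tree simulation under the network multispecies coalescent (NMSC).
# Lineages are traced backward in time through the species network; within
# an edge of length t (coalescent units) j lineages coalesce as a Kingman
# process at rate choose(j,2); at a hybrid node each lineage independently
# chooses a parent edge with probability gamma / 1-gamma; above the root a
# single infinite population guarantees coalescence to one lineage.

#' Simulate topological gene trees on a species network
#'
#' @param net a \code{"rooted_network"} (binary, metric; branch lengths in
#'   coalescent units, hybridization parameters gamma on hybrid edges).
#' @param m number of gene trees.
#' @param individuals individuals sampled per taxon (default 1; with more,
#'   leaf labels are \code{taxon_1, taxon_2, ...}).
#' @param seed integer seed (required: simulations are reproducible by
#'   construction).
#' @param missing_rate probability that each taxon is deleted from each gene
#'   independently (default 0).
#' @return a \code{"multiPhylo"} list of gene trees (arbitrarily rooted at
#'   the final coalescence; downstream analysis ignores rooting), with the
#'   configuration attached as attribute \code{"config"}.
#' @examples
#' net <- parse_enewick("((a:1,(b:1)h#0.4:1)x:1,(h#0.6:1,c:1)y:1)r;")
#' trees <- simulate_gene_trees(net, m = 5, seed = 1)
#' @export
simulate_gene_trees <- function(net, m, individuals = 1L, seed,
                                missing_rate = 0) {
  stopifnot(m >= 1L, individuals >= 1L, missing_rate >= 0, missing_rate < 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  ord <- topo_order(net)
  ed <- net$edges
  nd <- net$nodes
  root <- nd$id[nd$type == "root"]

  newick <- character(m)
  for (g in seq_len(m)) {
    # per-lineage newick fragments, keyed by lineage id
    frag <- list()
    nlin <- 0L
    new_lineage <- function(label) {
      nlin <<- nlin + 1L
      frag[[nlin]] <<- label
      nlin
    }
    coalesce_in <- function(lins, t_avail) {
      # Kingman within a population for duration t_avail (Inf above root)
      while (length(lins) > 1L) {
        j <- length(lins)
        w <- stats::rexp(1L, rate = j * (j - 1) / 2)
        if (w > t_avail) break
        t_avail <- t_avail - w
        pick <- sample.int(j, 2L)
        nlin <<- nlin + 1L
        frag[[nlin]] <<- paste0("(", frag[[lins[pick[1L]]]], ",",
                                frag[[lins[pick[2L]]]], ")")
        lins <- c(lins[-pick], nlin)
      }
      lins
    }
    taxa_present <- if (missing_rate > 0)
      net$taxa[stats::runif(length(net$taxa)) >= missing_rate] else net$taxa
    if (length(taxa_present) < 2L) { newick[g] <- NA_character_; next }

    edge_out <- vector("list", nrow(ed))   # lineages exiting each edge (top)
    for (v in rev(ord)) {                  # leaves first
      if (nd$type[v] == "leaf") {
        lab <- nd$label[v]
        enter <- if (!lab %in% taxa_present) integer(0)
        else if (individuals == 1L) new_lineage(lab)
        else vapply(seq_len(individuals), function(i)
          new_lineage(paste0(lab, "_", i)), integer(1))
      } else {
        below <- which(ed$parent == v)
        enter <- unlist(lapply(below, function(e) edge_out[[e]]))
        if (is.null(enter)) enter <- integer(0)
      }
      if (v == root) {
        if (length(enter) == 0L) { newick[g] <- NA_character_; break }
        final <- coalesce_in(enter, Inf)
        newick[g] <- paste0(frag[[final]], ";")
        next
      }
      parents <- which(ed$child == v)
      if (length(parents) == 1L) {
        edge_out[[parents]] <- coalesce_in(enter, ed$length[parents])
      } else {
        # hybrid node: each lineage chooses a parent edge independently
        g1 <- ed$gamma[parents[1L]]
        take1 <- stats::runif(length(enter)) < g1
        edge_out[[parents[1L]]] <-
          coalesce_in(enter[take1], ed$length[parents[1L]])
        edge_out[[parents[2L]]] <-
          coalesce_in(enter[!take1], ed$length[parents[2L]])
      }
    }
  }
  keep <- !is.na(newick)
  if (!any(keep)) stop("all gene trees empty (missing rate too high?)")
  trees <- ape::read.tree(text = paste(newick[keep], collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  attr(trees, "config") <- list(m = m, individuals = individuals,
                                seed = seed, missing_rate = missing_rate)
  trees
}

#' Draw a multinomial qcCF from a CF triple
#'
#' A qcCF for a sample of \code{m} independent gene trees is a multinomial
#' sample from the theoretical CF.
#'
#' @param cf probability 3-vector summing to 1.
#' @param m sample size.
#' @param seed optional integer seed.
#' @param nrep number of replicate draws (default 1).
#' @return an \code{nrep x 3} matrix of counts.
#' @export
sample_qccf <- function(cf, m, seed = NULL, nrep = 1L) {
  stopifnot(length(cf) == 3L, all(cf >= 0), abs(sum(cf) - 1) < 1e-9, m >= 1L)
  if (!is.null(seed)) set.seed(seed)
  t(stats::rmultinom(nrep, m, cf))
}
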