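# NANUQ Step 1: tally displayed quartets across gene trees into quartet
# count concordance factors (qcCFs), one row per 4-taxon subset.

# unit-branch-length cophenetic distances of a tree over the global taxon
# order; absent taxa give NA rows/columns
.unit_cophenetic <- function(tree, taxa) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  Dt <- ape::cophenetic.phylo(tree)
  n <- length(taxa)
  D <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  idx <- match(rownames(Dt), taxa)
  if (anyNA(idx)) stop("tree contains a taxon absent from the taxon set")
  D[idx, idx] <- Dt
  D
}

#' Quartet displayed by a gene tree on four taxa
#'
#' The induced unrooted tree on the four taxa: one of the three resolved
#' quartets, \code{"unresolved"} (the restriction is a star, from a
#' polytomy), or \code{"missing"} (some taxon absent from the tree).
#'
#' @param tree an \code{ape} \code{"phylo"} tree (topology; edge lengths
#'   ignored).
#' @param four character vector of four distinct taxon names.
#' @return one of \code{"ab|cd"}, \code{"ac|bd"}, \code{"ad|bc"} (with
#'   \code{a<b<c<d} the sorted input taxa), \code{"unresolved"},
#'   \code{"missing"}.
#' @export
displayed_quartet <- function(tree, four) {
  stopifnot(length(four) == 4L, !anyDuplicated(four))
  four <- sort(four)
  if (!all(four %in% tree$tip.label)) return("missing")
  D <- .unit_cophenetic(tree, sort(tree$tip.label))
  i <- match(four, rownames(D))
  s <- c(D[i[1], i[2]] + D[i[3], i[4]], D[i[1], i[3]] + D[i[2], i[4]],
         D[i[1], i[4]] + D[i[2], i[3]])
  top <- which(s == min(s))
  if (length(top) > 1L) return("unresolved")
  c("ab|cd", "ac|bd", "ad|bc")[top]
}

#' Tally quartet count concordance factors across gene trees
#'
#' For every 4-subset of the global taxon set, counts how many gene trees
#' display each of the three resolved quartet topologies on those taxa
#' (canonical order \code{ab|cd, ac|bd, ad|bc} for sorted taxa
#' \code{a<b<c<d}).  Trees missing any of the four taxa do not contribute;
#' trees containing all four but unresolved on them (polytomies) are counted
#' separately.
#'
#' @param trees a \code{"multiPhylo"} list (or list of \code{"phylo"}).
#' @param taxa optional global taxon set; default is the sorted union of
#'   leaf labels.
#' @return an object of class \code{"qccf_table"}: a data.frame with columns
#'   \code{t1..t4}, counts \code{m1,m2,m3}, total \code{m} and
#'   \code{unresolved}; attributes \code{taxa} and \code{ntrees}.
#' @export
tally_quartets <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  for (i in seq_along(trees))
    if (anyDuplicated(trees[[i]]$tip.label))
      stop(sprintf("tree %d: duplicate leaf label '%s'", i,
                   trees[[i]]$tip.label[duplicated(trees[[i]]$tip.label)][1]))
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(trees, `[[`,
                                                       "tip.label"))))
  n <- length(taxa)
  if (n < 4L) stop("fewer than 4 distinct taxa across gene trees")
  subs <- utils::combn(n, 4L)
  ns <- ncol(subs)
  lin <- function(i, j) (subs[j, ] - 1L) * n + subs[i, ]  # linear indices
  i12 <- lin(1L, 2L); i34 <- lin(3L, 4L)
  i13 <- lin(1L, 3L); i24 <- lin(2L, 4L)
  i14 <- lin(1L, 4L); i23 <- lin(2L, 3L)
  counts <- matrix(0L, ns, 3L)
  unres <- integer(ns)
  for (tr in trees) {
    D <- .unit_cophenetic(tr, taxa)
    s1 <- D[i12] + D[i34]; s2 <- D[i13] + D[i24]; s3 <- D[i14] + D[i23]
    ok <- !is.na(s1)
    w1 <- ok & s1 < s2 & s1 < s3
    w2 <- ok & s2 < s1 & s2 < s3
    w3 <- ok & s3 < s1 & s3 < s2
    counts[w1, 1L] <- counts[w1, 1L] + 1L
    counts[w2, 2L] <- counts[w2, 2L] + 1L
    counts[w3, 3L] <- counts[w3, 3L] + 1L
    u <- ok & !(w1 | w2 | w3)
    unres[u] <- unres[u] + 1L
  }
  out <- data.frame(t1 = taxa[subs[1L, ]], t2 = taxa[subs[2L, ]],
                    t3 = taxa[subs[3L, ]], t4 = taxa[subs[4L, ]],
                    m1 = counts[, 1L], m2 = counts[, 2L], m3 = counts[, 3L],
                    m = rowSums(counts), unresolved = unres,
                    stringsAsFactors = FALSE)
  if (any(out$m == 0L))
    warning(sprintf("%d of %d 4-taxon subsets have no resolved quartet on any gene tree",
                    sum(out$m == 0L), ns))
  structure(out, taxa = taxa, ntrees = length(trees),
            class = c("qccf_table", "data.frame"))
}

#' Write / read a qcCF table as CSV
#'
#' Interchange format between the tally and testing stages: columns
#' \code{taxon1..taxon4, count_ab_cd, count_ac_bd, count_ad_bc, m,
#' unresolved} with a header row.
#'
#' @param qccf a \code{"qccf_table"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly (writer); a \code{"qccf_table"} (reader).
#' @export
write_qccf_csv <- function(qccf, path) {
  out <- data.frame(taxon1 = qccf$t1, taxon2 = qccf$t2, taxon3 = qccf$t3,
                    taxon4 = qccf$t4, count_ab_cd = qccf$m1,
                    count_ac_bd = qccf$m2, count_ad_bc = qccf$m3,
                    m = qccf$m, unresolved = qccf$unresolved)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qccf_csv
#' @export
read_qccf_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(t1 = x$taxon1, t2 = x$taxon2, t3 = x$taxon3,
                    t4 = x$taxon4, m1 = x$count_ab_cd, m2 = x$count_ac_bd,
                    m3 = x$count_ad_bc, m = x$m, unresolved = x$unresolved,
                    stringsAsFactors = FALSE)
  taxa <- sort(unique(c(out$t1, out$t2, out$t3, out$t4)))
  structure(out, taxa = taxa, ntrees = NA_integer_,
            class = c("qccf_table", "data.frame"))
}
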