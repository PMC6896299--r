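# NANUQ Step 4: fit a weighted circular split system to the quartet
# distance.  The circular ordering comes from the NeighborNet agglomeration
# (net-divergence-adjusted neighbor selection with node reduction, as
# implemented in phangorn); split weights are then estimated by non-negative
# least squares over all interval splits of the ordering, whose optimum is
# unique because a circular distance determines its weighted split system.

#' NeighborNet circular ordering of a distance matrix
#'
#' @param D symmetric distance matrix with zero diagonal and taxon dimnames.
#' @return a character vector of taxa: a circular ordering, canonicalized to
#'   start at the lexicographically least taxon and proceed toward the
#'   smaller of its two neighbours.
#' @export
neighbornet_ordering <- function(D) {
  taxa <- rownames(D)
  n <- length(taxa)
  stopifnot(n >= 4L, isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  ord <- phangorn:::getOrderingNN(stats::as.dist(D))
  canonical_ordering(taxa[ord])
}

#' Canonical form of a circular ordering
#'
#' Circular orderings are identified up to rotation and reversal; the
#' canonical representative starts at the lexicographically least taxon and
#' proceeds toward the smaller of its two neighbours.
#'
#' @param ordering character vector of taxa.
#' @return character vector of the same taxa.
#' @export
canonical_ordering <- function(ordering) {
  n <- length(ordering)
  i <- which(ordering == min(ordering))[1L]
  rot <- ordering[((seq_len(n) + i - 2L) %% n) + 1L]
  if (rot[2L] > rot[n]) rot <- c(rot[1L], rev(rot[-1L]))
  rot
}

#' All interval splits of a circular ordering
#'
#' The \code{n(n-1)/2} splits whose sides are intervals of the ordering
#' (every split of a circular split system on this ordering is of this
#' form).
#'
#' @param ordering character vector of taxa (circular).
#' @return a list of character vectors (the side not containing the first
#'   taxon in sorted order), named by canonical signature.
#' @export
interval_splits <- function(ordering) {
  n <- length(ordering)
  taxa <- sort(ordering)
  out <- list()
  for (p in 2L:n) for (q in p:n) {
    side <- ordering[p:q]
    sig <- .split_sig(side, taxa)
    out[[sig]] <- sort(if (taxa[1L] %in% side) setdiff(taxa, side) else side)
  }
  out
}

#' Estimate non-negative split weights for a circular ordering
#'
#' Least-squares fit of the distance induced by interval-split weights to
#' \code{D}: minimize \code{sum_(x<y) (d_w(x,y) - D(x,y))^2} over weights
#' \code{w >= 0} on the interval splits of the ordering (active-set NNLS).
#' Splits with fitted weight below \code{eps} are dropped from the support.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param ordering circular ordering of the taxa.
#' @param eps support threshold for fitted weights (default 1e-10).
#' @return an object of class \code{"split_weights"}: a list with
#'   \code{weights} (named vector over all interval splits),
#'   \code{support} (signatures with weight > eps), \code{ordering},
#'   \code{residual} (the fitted-distance RMS error), \code{taxa}.
#' @export
estimate_split_weights <- function(D, ordering, eps = 1e-10) {
  taxa <- sort(rownames(D))
  stopifnot(setequal(ordering, taxa))
  n <- length(taxa)
  spl <- interval_splits(ordering)
  ns <- length(spl)
  mem <- vapply(spl, function(s) taxa %in% s, logical(n))   # n x ns
  pairs <- utils::combn(n, 2L)
  A <- matrix(0, ncol(pairs), ns)
  for (j in seq_len(ns))
    A[, j] <- xor(mem[pairs[1L, ], j], mem[pairs[2L, ], j])
  Ds <- D[taxa, taxa]
  d <- Ds[cbind(pairs[1L, ], pairs[2L, ])]
  fit <- pracma::lsqnonneg(A, d)
  w <- stats::setNames(pmax(fit$x, 0), names(spl))
  resid <- sqrt(mean((as.vector(A %*% w) - d)^2))
  structure(list(weights = w, support = names(w)[w > eps],
                 ordering = canonical_ordering(ordering),
                 residual = resid, taxa = taxa),
            class = "split_weights")
}

#' @export
print.split_weights <- function(x, ...) {
  cat(sprintf("Weighted circular split system: %d taxa, %d supported splits (RMS residual %.3g)\n",
              length(x$taxa), length(x$support), x$residual))
  cat("Circular ordering:", paste(x$ordering, collapse = " "), "\n")
  invisible(x)
}

#' Write a split system as a SplitsTree-compatible Nexus SPLITS block
#'
#' TAXA block plus an \code{st_splits}-style SPLITS block with the CYCLE
#' statement (circular ordering) and a MATRIX of weight + split-set rows, so
#' the fitted system can be inspected in SplitsTree4.
#'
#' @param sw a \code{"split_weights"} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_splits <- function(sw, path) {
  taxa <- sw$taxa
  n <- length(taxa)
  sup <- sw$support
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#NEXUS")
  w("BEGIN TAXA;")
  w("DIMENSIONS NTAX=%d;", n)
  w("TAXLABELS")
  for (t in taxa) w("  '%s'", t)
  w(";")
  w("END;")
  w("BEGIN ST_SPLITS;")
  w("DIMENSIONS NTAX=%d NSPLITS=%d;", n, length(sup))
  w("FORMAT LABELS=NO WEIGHTS=YES;")
  w("CYCLE %s;", paste(match(sw$ordering, taxa), collapse = " "))
  w("MATRIX")
  for (i in seq_along(sup)) {
    side <- strsplit(sup[i], ",", fixed = TRUE)[[1L]]
    w("  [%d] %g %s,", i, sw$weights[[sup[i]]],
      paste(match(side, taxa), collapse = " "))
  }
  w(";")
  w("END;")
  invisible(path)
}
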