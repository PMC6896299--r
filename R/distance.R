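# NANUQ Step 3: the network quartet distance assembled from per-quartet
# calls.  For each 4-subset the separation indicator rho_xy is 0 when x,y
# are together on a quartet tree, 1 when separated, 1/2 when adjacent on a
# 4-cycle (the average over the two trees the cycle displays), and 1 for a
# star (a star separates any two taxa).

# rho contributions of one call over its 6 unordered taxon pairs, in the
# order (12, 13, 14, 23, 24, 34) of the sorted 4-subset
.rho6 <- function(class, topology) {
  if (class == "star") return(rep(1, 6L))
  if (class == "tree") {
    r <- rep(1, 6L)
    pair <- switch(topology, c(1L, 6L), c(2L, 5L), c(3L, 4L))
    r[pair] <- 0
    return(r)
  }
  # cycle4: topology is the diagonal pairing
  r <- rep(0.5, 6L)
  pair <- switch(topology, c(1L, 6L), c(2L, 5L), c(3L, 4L))
  r[pair] <- 1
  r
}

#' Separation indicator of a quartet call
#'
#' @param call a single-row list/data.frame with \code{t1..t4},
#'   \code{class}, \code{topology} (see \code{\link{classify_quartets}} and
#'   \code{\link{theoretical_calls}}).
#' @param x,y two distinct taxa of the call's 4-subset.
#' @return 0, 1/2, or 1.
#' @export
rho <- function(call, x, y) {
  four <- c(call$t1, call$t2, call$t3, call$t4)
  stopifnot(x %in% four, y %in% four, x != y)
  i <- sort(match(c(x, y), four))
  pairidx <- c(`12` = 1L, `13` = 2L, `14` = 3L, `23` = 4L, `24` = 5L,
               `34` = 6L)[[paste0(i[1L], i[2L])]]
  .rho6(call$class, call$topology)[pairidx]
}

#' Network quartet distance matrix from quartet calls
#'
#' \code{d(x,y) = 2 sum rho_xy over the 4-subsets containing x,y, plus
#' 2n - 4}.  With calls all trees displayed on one binary tree this is the
#' tree's quartet-weight metric; with the theoretical calls of a level-1
#' network it equals the network quartet distance \code{d_Q}.
#'
#' @param calls a \code{"quartet_calls"} data.frame (or the output of
#'   \code{\link{theoretical_calls}}) with one row per 4-subset.
#' @param taxa taxon set (default from attributes or the calls).
#' @return a symmetric distance matrix with zero diagonal.
#' @export
quartet_distance_matrix <- function(calls, taxa = NULL) {
  if (is.null(taxa)) taxa <- attr(calls, "taxa")
  if (is.null(taxa)) taxa <- sort(unique(c(calls$t1, calls$t2, calls$t3,
                                           calls$t4)))
  n <- length(taxa)
  stopifnot(n >= 4L)
  if (nrow(calls) != choose(n, 4L))
    stop("calls must cover every 4-subset exactly once")
  acc <- matrix(0, n, n, dimnames = list(taxa, taxa))
  i1 <- match(calls$t1, taxa); i2 <- match(calls$t2, taxa)
  i3 <- match(calls$t3, taxa); i4 <- match(calls$t4, taxa)
  pr <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
              c(3L, 4L))
  im <- cbind(i1, i2, i3, i4)
  for (r in seq_len(nrow(calls))) {
    rr <- .rho6(calls$class[r], calls$topology[r])
    for (p in 1:6) {
      a <- im[r, pr[p, 1L]]; b <- im[r, pr[p, 2L]]
      acc[a, b] <- acc[a, b] + rr[p]
    }
  }
  acc <- acc + t(acc)
  D <- 2 * acc + (2 * n - 4)
  diag(D) <- 0
  D
}

#' Write a distance matrix as a SplitsTree-compatible Nexus file
#'
#' Emits a TAXA block and a DISTANCES block (\code{TRIANGLE=BOTH}, labels on
#' rows), loadable by SplitsTree4.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_distances <- function(D, path) {
  taxa <- rownames(D)
  n <- length(taxa)
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
  w("BEGIN DISTANCES;")
  w("DIMENSIONS NTAX=%d;", n)
  w("FORMAT TRIANGLE=BOTH DIAGONAL LABELS;")
  w("MATRIX")
  for (i in seq_len(n))
    w("  '%s' %s", taxa[i], paste(format(D[i, ], trim = TRUE),
                                  collapse = " "))
  w(";")
  w("END;")
  invisible(path)
}

#' Write a distance matrix as CSV
#'
#' @param D symmetric matrix with taxon dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_csv <- function(D, path) {
  utils::write.csv(data.frame(taxon = rownames(D), D, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
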