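# Closed-form quartet concordance factors under the NMSC, and the
# tree-likeness analysis of the 3_2-cycle quartet network.  Parameters are
# branch lengths t_i in coalescent units or their transforms x_i = exp(-t_i).

#' CF of a resolved quartet tree
#'
#' For four taxa related by the quartet tree \code{ab|cd} with internal
#' branch length \code{t} (coalescent units), the standard multispecies
#' coalescent result: the matching topology has probability
#' \code{1 - (2/3) exp(-t)} and each alternative \code{(1/3) exp(-t)}.
#'
#' @param t internal branch length, \code{t >= 0}.
#' @return a CF triple \code{(CF_ab|cd, CF_ac|bd, CF_ad|bc)}.
#' @export
cf_tree <- function(t) {
  stopifnot(all(t >= 0))
  e <- exp(-t)
  out <- cbind(`CF_ab|cd` = 1 - 2 / 3 * e, `CF_ac|bd` = e / 3,
               `CF_ad|bc` = e / 3)
  if (length(t) == 1L) out[1L, ] else out
}

#' CF of the 3_2-cycle quartet network
#'
#' The quartet network whose 3-cycle hybrid node has two descendant taxa
#' (a, b below an edge of transformed length \code{x1 = exp(-t1)}), hybrid
#' edges of transformed lengths \code{x2}, \code{x4} with hybridization
#' parameter \code{gamma} on the \code{x4} side, and \code{x3} the
#' transformed length of the cycle's tree edge:
#' \deqn{CF_{AB|CD} = (1-g)^2 (1 - 2/3 x1 x2) + 2 g (1-g)(1 - x1 + 1/3 x1 x3)
#'       + g^2 (1 - 2/3 x1 x4)}
#' \deqn{CF_{AC|BD} = CF_{AD|BC} = (1-g)^2 (1/3 x1 x2)
#'       + g(1-g) x1 (1 - 1/3 x3) + g^2 (1/3 x1 x4).}
#' Parameters are tree-like when \code{CF_AB|CD >= CF_AC|BD}.
#'
#' @param x1,x2,x3,x4 transformed branch lengths in (0, 1] (vectors
#'   recycled); the boundary 0 (infinite branch) is accepted.
#' @param gamma hybridization parameter in [0, 1].
#' @return a matrix with columns \code{CF_ab|cd, CF_ac|bd, CF_ad|bc}.
#' @export
cf_32cycle <- function(x1, x2, x3, x4, gamma) {
  stopifnot(all(x1 >= 0 & x1 <= 1), all(x2 >= 0 & x2 <= 1),
            all(x3 >= 0 & x3 <= 1), all(x4 >= 0 & x4 <= 1),
            all(gamma >= 0 & gamma <= 1))
  g <- gamma
  maj <- (1 - g)^2 * (1 - 2 / 3 * x1 * x2) +
    2 * g * (1 - g) * (1 - x1 + x1 * x3 / 3) +
    g^2 * (1 - 2 / 3 * x1 * x4)
  minr <- (1 - g)^2 * (x1 * x2 / 3) +
    g * (1 - g) * x1 * (1 - x3 / 3) +
    g^2 * (x1 * x4 / 3)
  cbind(`CF_ab|cd` = maj, `CF_ac|bd` = minr, `CF_ad|bc` = minr)
}

#' Tree-likeness analysis of 3_2-cycle parameters
#'
#' Quantifies how much of the 3_2-cycle parameter space yields tree-like
#' CFs (\code{CF_AB|CD >= CF_AC|BD}).
#'
#' Modes:
#' \describe{
#'   \item{\code{mc_nontreelike_fraction}}{Monte-Carlo measure of the
#'     non-tree-like region of the unit 5-cube
#'     \code{(x1,x2,x3,x4,gamma)}.}
#'   \item{\code{area_x1x3}}{area of \code{x1 <= 4/(5-x3)} in the unit
#'     square: parameters there are tree-like for all \code{x2, x4, gamma};
#'     closed form \code{4 log(5/4)}.}
#'   \item{\code{area_x1M}}{area of
#'     \code{M <= min(2/x1 - 3/2, 1)}, \code{M = max(x2, x4)}: tree-like
#'     for all \code{x3, gamma}; closed form \code{2 log(5/4) + 1/2}.}
#'   \item{\code{threshold_t1}}{\code{log(5/4)}: \code{t1} at least this
#'     guarantees tree-likeness regardless of all other parameters.}
#'   \item{\code{threshold_M}}{\code{log 2}: hybrid branch lengths
#'     \code{t2, t4} at least this guarantee tree-likeness.}
#' }
#'
#' @param mode one of the modes above.
#' @param n_samples Monte-Carlo sample count (mc mode).
#' @param seed integer seed (mc mode).
#' @param n_grid grid resolution for the numeric area integrals.
#' @return a scalar.
#' @export
treelike_region_analysis <- function(mode = c("mc_nontreelike_fraction",
                                              "area_x1x3", "area_x1M",
                                              "threshold_t1", "threshold_M"),
                                     n_samples = 1e7, seed = 1,
                                     n_grid = 4000L) {
  mode <- match.arg(mode)
  switch(mode,
    mc_nontreelike_fraction = {
      set.seed(seed)
      block <- 1e6
      hits <- 0
      done <- 0
      while (done < n_samples) {
        b <- min(block, n_samples - done)
        x1 <- stats::runif(b); x2 <- stats::runif(b)
        x3 <- stats::runif(b); x4 <- stats::runif(b)
        g <- stats::runif(b)
        cf <- cf_32cycle(x1, x2, x3, x4, g)
        hits <- hits + sum(cf[, 1L] < cf[, 2L])
        done <- done + b
      }
      hits / n_samples
    },
    area_x1x3 = {
      # integral over x3 of min(4/(5-x3), 1); midpoint rule
      x3 <- (seq_len(n_grid) - 0.5) / n_grid
      mean(pmin(4 / (5 - x3), 1))
    },
    area_x1M = {
      x1 <- (seq_len(n_grid) - 0.5) / n_grid
      mean(pmin(pmax(2 / x1 - 1.5, 0), 1))
    },
    threshold_t1 = log(5 / 4),
    threshold_M = log(2))
}
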