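#' @include AllClasses.R utils.R ensemble-aggregate.R
NULL

# Coerce SignedNetwork / igraph / adjacency matrix to a symmetric 0/1
# adjacency matrix (unsigned skeleton; self-loops dropped).
.asAdjacency <- function(graph) {
  if (is(graph, "SignedNetwork")) {
    g <- asIgraph(graph)
    a <- as.matrix(igraph::as_adjacency_matrix(g))
  } else if (igraph::is_igraph(graph)) {
    a <- as.matrix(igraph::as_adjacency_matrix(graph))
  } else if (is.matrix(graph)) {
    a <- graph
  } else stop("expected a SignedNetwork, igraph graph, or adjacency matrix")
  a <- (a != 0) * 1
  a <- pmax(a, t(a))
  diag(a) <- 0
  a
}

#' Natural connectivity of a graph
#'
#' The natural connectivity is the log of the average of the exponentials of
#' the adjacency eigenvalues, ln((1/N) sum_i exp(lambda_i)) — a spectral
#' measure of the redundancy of alternative paths that increases strictly
#' with every added edge. Edge signs and weights are ignored (presence
#' only). An empty node set returns 0 by convention.
#'
#' @param graph a [SignedNetwork-class], \pkg{igraph} graph, or adjacency
#'   matrix.
#' @return natural connectivity (>= 0; 0 for an edgeless graph).
#' @examples
#' naturalConnectivity(igraph::make_full_graph(3))  # ~0.9963
#' @export
naturalConnectivity <- function(graph) {
  a <- .asAdjacency(graph)
  n <- nrow(a)
  if (n == 0L) return(0)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  # log-sum-exp for numerical stability on large graphs
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

#' Normalized natural connectivity
#'
#' Natural connectivity divided by N - ln N, which bounds it by the complete
#' graph's value so that networks of different sizes are comparable.
#' Networks with fewer than 2 nodes return 0.
#'
#' @inheritParams naturalConnectivity
#' @return normalized natural connectivity in [0, 1].
#' @export
normalizedNaturalConnectivity <- function(graph) {
  a <- .asAdjacency(graph)
  n <- nrow(a)
  if (n <= 1L) return(0)
  naturalConnectivity(a) / (n - log(n))
}

.nncOfSubset <- function(a, keep) {
  if (length(keep) <= 1L) return(0)
  normalizedNaturalConnectivity(a[keep, keep, drop = FALSE])
}

#' Random-attack robustness trajectory
#'
#' For every removal count k in 1..N-1, draws \code{nAttacks} independent
#' uniform node subsets of size k and records the normalized natural
#' connectivity of each remaining induced subgraph.
#'
#' @inheritParams naturalConnectivity
#' @param nAttacks repetitions per removal count (the study convention is
#'   1000).
#' @param seed integer seed.
#' @return an [AttackTrajectory-class] in \code{"random"} mode.
#' @export
randomAttack <- function(graph, nAttacks = 1000L, seed = 1L) {
  a <- .asAdjacency(graph)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 nodes to attack")
  if (nAttacks < 1L) stop("nAttacks must be >= 1")
  set.seed(seed)
  conn <- matrix(NA_real_, n - 1L, nAttacks,
                 dimnames = list(seq_len(n - 1L), NULL))
  for (k in seq_len(n - 1L)) {
    for (t in seq_len(nAttacks)) {
      keep <- sample.int(n, n - k)
      conn[k, t] <- .nncOfSubset(a, keep)
    }
  }
  new("AttackTrajectory", connectivity = conn, mode = "random",
      nNodes = n, seed = as.integer(seed))
}

#' Compare attack robustness between two networks
#'
#' Per removal count k (over the common range of the two trajectories) the
#' two samples of normalized natural connectivity are compared with a
#' two-sided Wilcoxon rank-sum test; the per-k p-values are merged with the
#' weighted Simes combination using the number of remaining nodes of the
#' larger network as the weight, so early attack steps (large remaining
#' networks) dominate. Identical samples at a step give p = 1.
#'
#' @param trajA,trajB random-mode [AttackTrajectory-class] objects.
#' @return list with \code{perK} (data.frame: k, weight, medianA, medianB,
#'   p), \code{mergedP}, and \code{direction} (\code{"A"}, \code{"B"} or
#'   \code{"tie"}: the network with the higher summed median connectivity
#'   over the common range).
#' @export
compareGroupRobustness <- function(trajA, trajB) {
  stopifnot(is(trajA, "AttackTrajectory"), is(trajB, "AttackTrajectory"))
  if (trajA@mode != "random" || trajB@mode != "random")
    stop("robustness comparison requires random-mode trajectories")
  kMax <- min(nrow(trajA@connectivity), nrow(trajB@connectivity))
  if (kMax < 1L) stop("no common removal counts")
  nBig <- max(trajA@nNodes, trajB@nNodes)
  perK <- data.frame(k = seq_len(kMax), weight = nBig - seq_len(kMax),
                     medianA = NA_real_, medianB = NA_real_, p = NA_real_)
  for (k in seq_len(kMax)) {
    x <- trajA@connectivity[k, ]
    y <- trajB@connectivity[k, ]
    perK$medianA[k] <- stats::median(x)
    perK$medianB[k] <- stats::median(y)
    if (length(unique(c(x, y))) == 1L) {
      perK$p[k] <- 1
    } else {
      exact <- length(x) < 20L && length(y) < 20L
      perK$p[k] <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    }
  }
  keep <- perK$weight > 0
  merged <- weightedSimes(pmin(pmax(perK$p[keep], .Machine$double.xmin), 1),
                          weights = perK$weight[keep])
  dm <- sum(perK$medianA) - sum(perK$medianB)
  direction <- if (dm > 0) "A" else if (dm < 0) "B" else "tie"
  list(perK = perK, mergedP = merged, direction = direction)
}

#' Negative-interaction subnetwork
#'
#' Restricts a signed network to its negative edges; nodes without any
#' negative edge are dropped.
#'
#' @param net a [SignedNetwork-class].
#' @return a [SignedNetwork-class] containing only negative edges.
#' @export
negativeSubnetwork <- function(net) {
  stopifnot(is(net, "SignedNetwork"))
  ed <- net@edges[net@edges$sign == -1, , drop = FALSE]
  rownames(ed) <- NULL
  keep <- unique(c(ed$taxon_a, ed$taxon_b))
  nodes <- net@nodes[net@nodes$taxon %in% keep, , drop = FALSE]
  rownames(nodes) <- NULL
  new("SignedNetwork", nodes = nodes, edges = ed)
}
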