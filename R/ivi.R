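#' @include AllClasses.R utils.R connectivity.R
NULL

# Node H-index over neighbour degrees: largest h such that the node has at
# least h neighbours of degree >= h.
.hIndex <- function(vals) {
  if (!length(vals)) return(0)
  s <- sort(vals, decreasing = TRUE)
  sum(s >= seq_along(s))
}

#' Integrated value of influence (IVI) of every node
#'
#' Composite node-influence score combining six centralities. Components:
#' degree; ClusterRank \code{10^(-c_i) * sum_\{j in N(i)\} (deg(j) + 1)}
#' with c_i the local clustering coefficient (taken as 0 for degree < 2);
#' neighbourhood connectivity (mean neighbour degree); local H-index
#' \code{h(i) + sum_\{j in N(i)\} h(j)} with h the node H-index over
#' neighbour degrees; shortest-path betweenness; and collective influence
#' \code{(deg(i) - 1) * sum_\{j at distance 2\} (deg(j) - 1)}. Each
#' component is min-max scaled to [1, 100] (a constant component maps every
#' node to 100); then hubness = scaled degree + scaled local H-index,
#' spreading = (scaled ClusterRank + scaled neighbourhood connectivity) *
#' (scaled betweenness + scaled collective influence), and IVI is
#' hubness * spreading rescaled to [1, 100].
#'
#' @param graph a [SignedNetwork-class], \pkg{igraph} graph, or adjacency
#'   matrix (signs/weights ignored); at least 2 nodes.
#' @return data.frame, one row per node: \code{node}, the six raw
#'   components, \code{hubness}, \code{spreading}, and \code{ivi} in
#'   [1, 100], ordered by decreasing IVI (ties by node id).
#' @export
ivi <- function(graph) {
  a <- .asAdjacency(graph)
  n <- nrow(a)
  if (n < 2L) stop("IVI needs at least 2 nodes")
  if (is.null(rownames(a)))
    dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  neighborList <- lapply(seq_len(n), function(i) which(a[i, ] > 0))

  clusterRank <- vapply(seq_len(n), function(i)
    10^(-cc[i]) * sum(deg[neighborList[[i]]] + 1), 1)
  neighConn <- vapply(seq_len(n), function(i) {
    nb <- neighborList[[i]]
    if (!length(nb)) 0 else mean(deg[nb])
  }, 1)
  h <- vapply(seq_len(n), function(i) .hIndex(deg[neighborList[[i]]]), 1)
  localH <- vapply(seq_len(n), function(i)
    h[i] + sum(h[neighborList[[i]]]), 1)
  a2 <- a %*% a
  dist2 <- (a2 > 0) & (a == 0)
  diag(dist2) <- FALSE
  collInf <- vapply(seq_len(n), function(i)
    (deg[i] - 1) * sum(pmax(deg[dist2[i, ]] - 1, 0)), 1)

  sDeg <- .minmax1_100(deg)
  sCR <- .minmax1_100(clusterRank)
  sNC <- .minmax1_100(neighConn)
  sLH <- .minmax1_100(localH)
  sBtw <- .minmax1_100(btw)
  sCI <- .minmax1_100(collInf)
  hubness <- sDeg + sLH
  spreading <- (sCR + sNC) * (sBtw + sCI)
  iviScore <- .minmax1_100(hubness * spreading)

  out <- data.frame(node = rownames(a), degree = unname(deg),
                    clusterrank = clusterRank,
                    neighborhood_connectivity = neighConn,
                    local_h_index = localH, betweenness = unname(btw),
                    collective_influence = collInf, hubness = hubness,
                    spreading = spreading, ivi = iviScore,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ivi, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutational keystone-taxon detection
#'
#' Nodes are removed cumulatively in decreasing-IVI order (ties broken by
#' node id) and the normalized natural connectivity of the remainder is
#' recorded at every prefix. The null model repeats the same recording for
#' \code{nPermutations} uniformly random removal orders. The per-prefix
#' empirical p-value uses the midpoint rule,
#' (1 + #\{null strictly more damaging\} + 0.5 #\{null tied\}) /
#' (nPermutations + 1), where a tie is a null order reaching the same
#' connectivity (typically by removing the same node set); the keystone set
#' is the maximal initial prefix of the IVI order significant at every step
#' (empty if the first step is not significant).
#'
#' Note the structural floor of this test: a random order removes the same
#' first node as the targeted attack with probability 1/N, so the first
#' prefix's p-value cannot fall below about 1/(2N) however many
#' permutations are used. \code{alpha} must therefore exceed 1/(2N); with
#' small toy networks use e.g. alpha = 0.05.
#'
#' @param net a [SignedNetwork-class], \pkg{igraph} graph, or adjacency
#'   matrix; its unsigned skeleton is attacked.
#' @param nPermutations random removal orders (the study convention is
#'   1000).
#' @param alpha per-prefix significance level (study convention 0.001; must
#'   be reachable, i.e. \code{nPermutations >= 1/alpha - 1}).
#' @param seed integer seed.
#' @return list with \code{keystones} (character, IVI-ordered), \code{table}
#'   (data.frame: node, ivi, targeted connectivity, prefix p),
#'   \code{nPermutations}, \code{alpha}.
#' @export
keystoneDetection <- function(net, nPermutations = 1000L, alpha = 0.001,
                              seed = 1L) {
  a <- .asAdjacency(net)
  n <- nrow(a)
  if (is.null(rownames(a)))
    dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  if (n < 3L || sum(a) == 0) stop("need >= 3 nodes with at least one edge")
  if (nPermutations < 1 / alpha - 1)
    stop(sprintf("alpha %.4g unreachable with %d permutations (need >= %d)",
                 alpha, nPermutations, ceiling(1 / alpha - 1)))
  iviTab <- ivi(a)
  ord <- match(iviTab$node, rownames(a))   # already IVI-desc, ties by id

  trajectoryOf <- function(order) {
    vapply(seq_len(n - 1L), function(k)
      .nncOfSubset(a, order[(k + 1L):n]), 1)
  }
  targeted <- trajectoryOf(ord)

  set.seed(seed)
  lower <- numeric(n - 1L)
  for (t in seq_len(nPermutations)) {
    nullTraj <- trajectoryOf(sample.int(n))
    # midpoint rule: a null order visiting the same node set produces the
    # same connectivity (up to eigensolver noise, hence the tolerance) and
    # counts half, so ties neither prove nor refute the target's influence
    lower <- lower + (nullTraj < targeted - 1e-9) +
      0.5 * (abs(nullTraj - targeted) <= 1e-9)
  }
  prefixP <- (1 + lower) / (nPermutations + 1)
  sig <- prefixP < alpha
  nKeystone <- if (!sig[1L]) 0L else {
    r <- rle(sig)
    if (r$values[1L]) r$lengths[1L] else 0L
  }
  keystones <- iviTab$node[seq_len(nKeystone)]
  tab <- data.frame(node = iviTab$node[seq_len(n - 1L)],
                    ivi = iviTab$ivi[seq_len(n - 1L)],
                    connectivity = targeted, prefix_p = prefixP,
                    stringsAsFactors = FALSE)
  list(keystones = keystones, table = tab,
       nPermutations = as.integer(nPermutations), alpha = alpha)
}

#' Spearman correlation between IVI and mean relative abundance
#'
#' @param iviTable output of [ivi()] (or any data.frame with \code{node} and
#'   \code{ivi} columns).
#' @param meanAbundances named numeric vector of per-taxon mean relative
#'   abundances covering the IVI nodes.
#' @return list with \code{rho} and \code{p} from a Spearman rank test.
#' @export
iviAbundanceCorrelation <- function(iviTable, meanAbundances) {
  stopifnot(all(c("node", "ivi") %in% colnames(iviTable)))
  common <- intersect(iviTable$node, names(meanAbundances))
  if (length(common) < 3L) stop("need at least 3 matching taxa")
  x <- iviTable$ivi[match(common, iviTable$node)]
  y <- meanAbundances[common]
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
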