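#' @include AllClasses.R utils.R ensemble-methods.R
NULL

.ensembleMethods <- c("coat", "sparse_graph", "mutual_information",
                      "bray_curtis")

# Statistic closures mapping a relative taxon x sample matrix to a score
# matrix, with tuning fixed from the observed table so that bootstrap and
# permutation recomputations measure sampling variation only. Each method
# contributes two statistics: `score` (the reported edge strength; averaged
# over bootstraps) and `test` (the permutation-test statistic; a smooth,
# atom-free statistic so that exceedance p-values are calibrated - COAT
# tests its unthresholded CLR correlation and the sparse graph tests its
# densest-penalty fit, because hard-thresholded/selected statistics put
# point mass at zero and cannot yield uniform null p-values).
.methodStatistic <- function(method, v, soft, nlambda, bins, pseudocount,
                             seed, nSubsamples, instabilityTarget) {
  if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(v)
  if (is.null(bins)) bins <- max(2L, min(10L, floor(sqrt(ncol(v)))))
  switch(method,
    coat = list(
      score = function(m) .coatScores(clrTransform(m, pseudocount), soft)$R,
      test = function(m) .coatScores(clrTransform(m, pseudocount), 0)$R),
    sparse_graph = {
      clr0 <- clrTransform(v, pseudocount)
      grid <- .lambdaGrid(scale(t(clr0)), nlambda)
      lam <- .starsSelectLambda(t(clr0), grid, seed = seed,
                                nSubsamples = nSubsamples,
                                instabilityTarget = instabilityTarget)$lambda
      list(
        score = function(m) .mbScores(t(clrTransform(m, pseudocount)), lam),
        test = function(m) .ridgePartialCor(clrTransform(m, pseudocount)))
    },
    mutual_information = {
      f <- function(m) .miScores(m, bins)
      list(score = f, test = f)
    },
    bray_curtis = {
      f <- function(m) .bcScores(m)
      list(score = f, test = f)
    },
    stop("unknown method: ", method))
}

#' ReBoot-style empirical edge p-values for one ensemble member
#'
#' Compositionality-aware significance and score stabilization for one
#' ensemble method. Two resampling layers are used:
#' \itemize{
#'   \item \emph{Bootstrap}: the reported raw score of every taxon pair is
#'     the mean of the method's score over \code{nBootstraps} resamplings of
#'     the samples (with replacement, columns re-closed to sum 1), which
#'     stabilizes the edge strengths and signs.
#'   \item \emph{Permutation}: the null distribution of the method's test
#'     statistic comes from \code{nPermutations} datasets in which every
#'     taxon's values are independently shuffled across samples and the
#'     composition re-closed per sample, so the null carries the
#'     compositional artifact. The p-value of a pair is
#'     (1 + #\{null |stat| >= |observed stat|\}) / (nPermutations + 1), with
#'     the observed statistic computed on the full data — the standard
#'     permutation-test comparison, which keeps null p-values uniform
#'     (plug-in estimator biases appear identically in both terms).
#' }
#' COAT is tested through its unthresholded CLR correlation and the sparse
#' graph through a ridge-regularized CLR partial correlation;
#' thresholded/selected statistics have an atom at zero that would put point
#' mass at p = 1 and cannot be uniform under the null.
#'
#' For the sparse-graph member the StARS penalty is selected once on the
#' observed data and held fixed across all resamples.
#'
#' @param table relative-mode [AbundanceTable-class].
#' @param method one of \code{"coat"}, \code{"sparse_graph"},
#'   \code{"mutual_information"}, \code{"bray_curtis"}.
#' @param nBootstraps,nPermutations resampling counts (defaults 100; the
#'   p-value floor is 1/(nPermutations + 1)).
#' @param seed integer seed.
#' @param soft COAT soft-threshold multiplier (default 0.2).
#' @param nlambda sparse-graph penalty path length (default 100).
#' @param bins MI bin count (default as in [mutualInformationMatrix()]).
#' @param pseudocount CLR pseudocount (default as in [clrTransform()]).
#' @param nSubsamples,instabilityTarget StARS parameters.
#' @return [MethodScoreMatrix-class]: \code{raw} holds the bootstrap-mean
#'   scores, \code{signs} their signs, \code{pvalues} the permutation
#'   p-values.
#' @export
rebootEdgePvalues <- function(table, method = .ensembleMethods,
                              nBootstraps = 100L, nPermutations = 100L,
                              seed = 1L, soft = 0.2, nlambda = 100L,
                              bins = NULL, pseudocount = NULL,
                              nSubsamples = 20L, instabilityTarget = 0.05) {
  method <- match.arg(method)
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceMode(table) != "relative")
    stop("ReBoot requires a relative-mode table")
  if (nPermutations < 19L)
    warning("fewer than 19 permutations: the p-value floor exceeds 0.05")
  v <- assay(table, "abundance")
  p <- nrow(v); n <- ncol(v)
  f <- .methodStatistic(method, v, soft = soft, nlambda = nlambda,
                        bins = bins, pseudocount = pseudocount,
                        seed = .stageSeed(seed, "stars"),
                        nSubsamples = nSubsamples,
                        instabilityTarget = instabilityTarget)
  obsTest <- abs(f$test(v))
  obsTest[is.na(obsTest)] <- 0

  set.seed(.stageSeed(seed, "reboot"))
  bootSum <- matrix(0, p, p)
  for (b in seq_len(nBootstraps)) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- v[, idx, drop = FALSE]
    m <- sweep(m, 2, colSums(m), "/")
    sc <- f$score(m)
    sc[is.na(sc)] <- 0
    bootSum <- bootSum + sc
  }
  raw <- bootSum / nBootstraps
  dimnames(raw) <- dimnames(v)[c(1L, 1L)]

  exceed <- if (method == "sparse_graph") {
    .allRowNullExceed(v, f$test, obsTest, nPermutations)
  } else {
    pc <- if (is.null(pseudocount)) .defaultPseudocount(v) else pseudocount
    bn <- if (is.null(bins)) max(2L, min(10L, floor(sqrt(n)))) else
      as.integer(bins)
    switch(method,
      coat = .coatNullExceed(v, pc, obsTest, nPermutations),
      mutual_information = .miNullExceed(v, bn, obsTest, nPermutations),
      bray_curtis = .bcNullExceed(v, obsTest, nPermutations))
  }
  pmat <- (1 + exceed) / (nPermutations + 1)
  diag(pmat) <- NA_real_
  dimnames(pmat) <- dimnames(raw)
  .newMSM(method, raw, .msmSigns(raw), pmat)
}

# Null scheme shared by the exceedance routines below: for every pair (i, j)
# with i < j, the null shuffles the values of the lower-indexed endpoint i
# across samples (the other taxa keep their observed alignment) and, where
# the statistic is not scale-invariant, the composition is re-closed per
# sample so that the null carries the compositional artifact.

# Ridge-regularized partial correlations on the CLR scale: the significance
# statistic of the sparse-graph member. Lasso-selected statistics have an
# atom at zero (point mass at p = 1) and near-unpenalized fits are unstable
# under collinearity, both of which break null uniformity; a fixed moderate
# ridge gives a smooth, stable conditional-dependence statistic.
.ridgePartialCor <- function(clr, ridge = 0.3) {
  S <- stats::cov(t(clr))
  p <- nrow(S)
  O <- solve(S + ridge * mean(diag(S)) * diag(p))
  pc <- -O / sqrt(outer(diag(O), diag(O)))
  diag(pc) <- 1
  dimnames(pc) <- dimnames(clr)[c(1L, 1L)]
  pc
}

# Whole-matrix fallback: every row shuffled independently, then re-closed.
# Used for the sparse-graph member, whose joint fit cannot be updated per
# endpoint at acceptable cost.
.allRowNullExceed <- function(v, testFun, obsTest, nPerm) {
  p <- nrow(v); n <- ncol(v)
  exceed <- matrix(0, p, p)
  for (t in seq_len(nPerm)) {
    m <- v
    for (i in seq_len(p)) m[i, ] <- m[i, sample.int(n)]
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2, cs, "/")
    sc <- testFun(m)
    sc[is.na(sc)] <- 0
    exceed <- exceed + (abs(sc) >= obsTest)
  }
  exceed
}

# One-endpoint null for the (unthresholded) CLR correlation. CLR is
# invariant to per-sample rescaling, so re-closure drops out; shuffling row
# i only shifts every row's geometric-mean centering, which is updated
# exactly.
.coatNullExceed <- function(v, pseudocount, obsTest, nPerm) {
  p <- nrow(v); n <- ncol(v)
  x <- v + pseudocount
  x <- sweep(x, 2, colSums(x), "/")
  L <- log(x)
  clr <- sweep(L, 2, colMeans(L), "-")
  exceed <- matrix(0, p, p)
  for (t in seq_len(nPerm)) {
    for (i in seq_len(p - 1L)) {
      Li2 <- L[i, sample.int(n)]
      delta <- (Li2 - L[i, ]) / p
      xi <- Li2 - colMeans(L) - delta        # shuffled row's new CLR
      rows <- (i + 1L):p
      Y <- clr[rows, , drop = FALSE] -
        matrix(delta, length(rows), n, byrow = TRUE)
      xc <- xi - mean(xi)
      Yc <- Y - rowMeans(Y)
      r <- as.vector(Yc %*% xc) /
        sqrt(rowSums(Yc^2) * sum(xc^2))
      r[!is.finite(r)] <- 0
      hit <- abs(r) >= obsTest[rows, i]
      exceed[rows, i] <- exceed[rows, i] + hit
      exceed[i, rows] <- exceed[i, rows] + hit
    }
  }
  exceed
}

# One-endpoint null for binned mutual information: shuffling a taxon's
# values permutes its (rank-based) bin labels, so the null is an exact
# within-pair permutation of the discretized data.
.miNullExceed <- function(v, bins, obsTest, nPerm) {
  p <- nrow(v); n <- ncol(v)
  d <- .discretizeRows(v, bins)
  exceed <- matrix(0, p, p)
  miPair <- function(di, dj) {
    joint <- tabulate(di + (dj - 1L) * bins, bins * bins) / n
    pj <- matrix(joint, bins, bins)
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  }
  for (t in seq_len(nPerm)) {
    for (i in seq_len(p - 1L)) {
      di <- d[i, sample.int(n)]
      for (j in (i + 1L):p) {
        hit <- miPair(di, d[j, ]) >= obsTest[i, j]
        exceed[i, j] <- exceed[i, j] + hit
        exceed[j, i] <- exceed[j, i] + hit
      }
    }
  }
  exceed
}

# One-endpoint null for the Bray-Curtis member: plain permutation of the
# endpoint row. Re-closing the composition after the shuffle would add a
# second layer of common-denominator coupling that the observed statistic
# does not carry (making the null conservative), so the null keeps the
# remaining rows untouched; the compositional adjustment of the ensemble
# lives in the CLR-based members.
.bcNullExceed <- function(v, obsTest, nPerm) {
  p <- nrow(v); n <- ncol(v)
  exceed <- matrix(0, p, p)
  for (t in seq_len(nPerm)) {
    for (i in seq_len(p - 1L)) {
      b <- v[i, sample.int(n)]
      rows <- (i + 1L):p
      A <- v[rows, , drop = FALSE]
      num <- rowSums(abs(sweep(A, 2, b, "-")))
      den <- rowSums(sweep(A, 2, b, "+"))
      s <- 1 - num / den
      s[!is.finite(s)] <- 0
      hit <- abs(s) >= obsTest[rows, i]
      exceed[rows, i] <- exceed[rows, i] + hit
      exceed[i, rows] <- exceed[i, rows] + hit
    }
  }
  exceed
}

#' Weighted Simes combination of p-values
#'
#' Sorts the p-values ascending and returns
#' min_i (sum(w) * p_(i) / sum_\{j <= i\} w_(j)), capped at 1. With equal
#' weights this reduces to the classic Simes combination
#' min_i (m * p_(i) / i).
#'
#' @param p numeric p-values in (0, 1].
#' @param weights positive weights, same length as \code{p} (default equal).
#' @return a single combined p-value in (0, 1].
#' @examples
#' weightedSimes(c(0.01, 0.04, 0.03))            # 0.03
#' weightedSimes(c(0.05, 0.01), weights = c(2, 1))  # 0.03
#' @export
weightedSimes <- function(p, weights = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (is.null(weights)) weights <- rep(1, length(p))
  stopifnot(length(weights) == length(p), all(weights > 0),
            all(p > 0), all(p <= 1))
  o <- order(p)
  ps <- p[o]
  ws <- weights[o]
  min(1, min(sum(ws) * ps / cumsum(ws)))
}

#' Aggregate the four-method ensemble into scores, signs and merged p-values
#'
#' Per method, the absolute raw scores are min-max normalized to [0, 1] over
#' all taxon pairs; the aggregate score is their weighted mean. The edge
#' sign comes from the two sign-bearing members (COAT and the sparse graph):
#' if both are nonzero and agree the shared sign is used; if exactly one is
#' nonzero its sign is used; if they conflict the edge is excluded (sign NA,
#' merged p forced to 1, and flagged). The merged p-value is the weighted
#' Simes combination of the per-method ReBoot p-values.
#'
#' @param methodMatrices list of the four [MethodScoreMatrix-class] objects
#'   (any order), each with p-values computed.
#' @param weights per-method weights, named by method or in the canonical
#'   order coat, sparse_graph, mutual_information, bray_curtis (default
#'   equal).
#' @param conflictRule \code{"exclude"} (default) or \code{"magnitude"}: on
#'   a COAT/sparse-graph sign conflict either drop the edge or let the
#'   member with the larger normalized magnitude decide.
#' @return list with matrices \code{score}, \code{sign}, \code{mergedP},
#'   \code{conflict}, and the per-method \code{normalized} scores.
#' @export
aggregateEnsemble <- function(methodMatrices, weights = NULL,
                              conflictRule = c("exclude", "magnitude")) {
  conflictRule <- match.arg(conflictRule)
  methods <- vapply(methodMatrices, function(m) m@method, "")
  names(methodMatrices) <- methods
  missing <- setdiff(.ensembleMethods, methods)
  if (length(missing))
    stop("missing ensemble method(s): ", paste(missing, collapse = ", "))
  mm <- methodMatrices[.ensembleMethods]
  if (is.null(weights)) weights <- rep(1, 4L)
  if (!is.null(names(weights))) weights <- weights[.ensembleMethods]
  stopifnot(length(weights) == 4L, all(weights > 0))
  weights <- weights / sum(weights)

  taxa <- rownames(mm[[1L]]@raw)
  p <- length(taxa)
  for (m in mm) {
    if (!identical(rownames(m@raw), taxa))
      stop("method matrices disagree on taxa")
    if (!length(m@pvalues))
      stop("method '", m@method, "' lacks p-values; run rebootEdgePvalues()")
  }

  normalized <- lapply(mm, function(m) {
    a <- abs(m@raw)
    ut <- upper.tri(a)
    sc <- a
    sc[ut] <- .minmax0_1(a[ut])
    sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
    sc[is.na(sc)] <- 0
    diag(sc) <- NA_real_
    sc
  })
  score <- Reduce(`+`, Map(function(w, s) w * s, weights, normalized))

  sCoat <- mm$coat@signs
  sGraph <- mm$sparse_graph@signs
  sgn <- ifelse(!is.na(sCoat), sCoat, sGraph)
  both <- !is.na(sCoat) & !is.na(sGraph)
  conflict <- both & (sCoat != sGraph)
  if (conflictRule == "magnitude") {
    useCoat <- normalized$coat >= normalized$sparse_graph
    sgn[conflict] <- ifelse(useCoat[conflict], sCoat[conflict],
                            sGraph[conflict])
    conflict[] <- FALSE
  } else {
    sgn[conflict] <- NA_real_
  }

  mergedP <- matrix(NA_real_, p, p, dimnames = list(taxa, taxa))
  pv <- lapply(mm, function(m) m@pvalues)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ps <- vapply(pv, function(x) x[i, j], 1)
      mergedP[i, j] <- mergedP[j, i] <- weightedSimes(ps, weights)
    }
  }
  mergedP[conflict] <- 1

  list(score = score, sign = sgn, mergedP = mergedP, conflict = conflict,
       normalized = normalized)
}

#' Build a SignedNetwork from aggregated ensemble output
#'
#' Keeps taxon pairs with merged p-value strictly below \code{threshold} and
#' a defined sign. Isolated taxa remain in the node table. The default
#' threshold 1e-3 matches strict network construction; 0.01 is a common
#' laxer preset.
#'
#' @param aggregate output of [aggregateEnsemble()].
#' @param threshold edge p-value threshold in (0, 1).
#' @param domains named per-taxon kingdom labels (e.g. [taxonDomains()] of
#'   the merged table).
#' @return a [SignedNetwork-class].
#' @export
buildNetwork <- function(aggregate, threshold = 1e-3, domains) {
  stopifnot(threshold > 0, threshold < 1)
  taxa <- rownames(aggregate$mergedP)
  stopifnot(all(taxa %in% names(domains)))
  keep <- which(upper.tri(aggregate$mergedP) &
                aggregate$mergedP < threshold &
                !is.na(aggregate$sign), arr.ind = TRUE)
  edges <- data.frame(
    taxon_a = taxa[keep[, 1L]], taxon_b = taxa[keep[, 2L]],
    sign = aggregate$sign[keep], score = aggregate$score[keep],
    p = aggregate$mergedP[keep], stringsAsFactors = FALSE)
  if (nrow(edges)) {
    swap <- edges$taxon_a > edges$taxon_b
    tmp <- edges$taxon_a[swap]
    edges$taxon_a[swap] <- edges$taxon_b[swap]
    edges$taxon_b[swap] <- tmp
    edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- data.frame(taxon = taxa, domain = unname(domains[taxa]),
                      stringsAsFactors = FALSE)
  new("SignedNetwork", nodes = nodes, edges = edges)
}

#' Split a network into within- and cross-kingdom sub-networks
#'
#' Partitions edges by endpoint domains into bacteria-bacteria,
#' fungi-fungi, and bacteria-fungi sub-networks; the three edge counts sum
#' to the original.
#'
#' @param net a [SignedNetwork-class] with domain-labelled nodes.
#' @return named list of three [SignedNetwork-class] objects
#'   (\code{bacteria}, \code{fungi}, \code{cross}).
#' @export
splitSubnetworks <- function(net) {
  stopifnot(is(net, "SignedNetwork"))
  nd <- net@nodes
  if (anyNA(nd$domain)) stop("all nodes must carry a domain label")
  dom <- stats::setNames(nd$domain, nd$taxon)
  ed <- net@edges
  da <- dom[ed$taxon_a]; db <- dom[ed$taxon_b]
  mk <- function(edges, nodes) new("SignedNetwork",
                                   nodes = nodes,
                                   edges = {rownames(edges) <- NULL; edges})
  list(
    bacteria = mk(ed[da == "bacteria" & db == "bacteria", , drop = FALSE],
                  nd[nd$domain == "bacteria", , drop = FALSE]),
    fungi = mk(ed[da == "fungi" & db == "fungi", , drop = FALSE],
               nd[nd$domain == "fungi", , drop = FALSE]),
    cross = mk(ed[da != db, , drop = FALSE], nd))
}

#' Infer a signed co-occurrence network from a merged profile
#'
#' End-to-end ensemble inference for one sample group: runs the four
#' ensemble members with ReBoot significance on the merged relative table,
#' aggregates scores, signs, and weighted-Simes merged p-values, and builds
#' the thresholded signed network.
#'
#' @param table merged relative-mode [AbundanceTable-class] (one group's
#'   samples).
#' @param threshold network edge p threshold (default 1e-3).
#' @param weights per-method ensemble weights (default equal).
#' @param conflictRule see [aggregateEnsemble()].
#' @param ... tuning passed to [rebootEdgePvalues()] (\code{nBootstraps},
#'   \code{nPermutations}, \code{soft}, \code{nlambda}, \code{bins},
#'   \code{pseudocount}, \code{seed}, ...).
#' @return list with \code{network} ([SignedNetwork-class]),
#'   \code{aggregate} (see [aggregateEnsemble()]) and the per-method
#'   \code{methods} list.
#' @export
inferNetwork <- function(table, threshold = 1e-3, weights = NULL,
                         conflictRule = "exclude", ...) {
  msms <- lapply(.ensembleMethods, function(m)
    rebootEdgePvalues(table, method = m, ...))
  agg <- aggregateEnsemble(msms, weights = weights,
                           conflictRule = conflictRule)
  net <- buildNetwork(agg, threshold = threshold,
                      domains = taxonDomains(table))
  list(network = net, aggregate = agg,
       methods = stats::setNames(msms, .ensembleMethods))
}
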