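#' @include AllClasses.R utils.R abundance.R
NULL

#' Bray-Curtis sample similarity from a relative-abundance profile
#'
#' S_ij = 1 - BC(sample_i, sample_j), with unit diagonal.
#'
#' @param table relative-mode [AbundanceTable-class] with >= 2 samples.
#' @return a [SimilarityMatrix-class] of kind
#'   \code{"bray_curtis_similarity"}.
#' @export
similarityFromProfile <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceMode(table) != "relative")
    stop("similarity requires a relative-mode table")
  v <- assay(table, "abundance")
  if (ncol(v) < 2L) stop("need at least 2 samples")
  zero <- colSums(v) == 0
  if (any(zero))
    stop("all-zero sample profile(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(v), method = "bray"))
  s <- 1 - d
  diag(s) <- 1
  new("SimilarityMatrix", matrix = s, kind = "bray_curtis_similarity")
}

#' Richness-based fusion weights
#'
#' Each kingdom's weight is its retained taxon count divided by the total
#' over kingdoms, so a richer biome contributes proportionally more to the
#' fused similarity. With the study's 122 bacteria and 131 fungi the weights
#' are 122/253 and 131/253.
#'
#' @param tables named list of filtered [AbundanceTable-class] objects.
#' @return named numeric weights summing to 1.
#' @export
richnessWeights <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, TRUE, "AbundanceTable")))
  rich <- vapply(tables, nrow, 1L)
  if (sum(rich) == 0L) stop("all tables are empty; cannot derive weights")
  w <- rich / sum(rich)
  if (is.null(names(w)))
    names(w) <- vapply(tables, function(t) rowData(t)$domain[1L], "")
  w
}

# Full-kernel row normalization (SNF convention): off-diagonal mass 1/2,
# diagonal 1/2.
.snfNormalize <- function(s) {
  p <- s
  diag(p) <- 0
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / (2 * rs)
  diag(p) <- 0.5
  p
}

# Sparse k-nearest-neighbour kernel: each row keeps its k largest
# off-diagonal similarities, renormalized to sum 1.
.snfKernel <- function(s, k) {
  n <- nrow(s)
  out <- matrix(0, n, n, dimnames = dimnames(s))
  for (i in seq_len(n)) {
    sims <- s[i, ]
    sims[i] <- -Inf
    nn <- order(sims, decreasing = TRUE)[seq_len(k)]
    w <- s[i, nn]
    if (sum(w) == 0) w <- rep(1, k)
    out[i, nn] <- w / sum(w)
  }
  out
}

#' Weighted similarity network fusion
#'
#' Standard SNF cross-diffusion with per-data-type weights: every input
#' similarity is row-normalized into a full kernel P and a sparse k-NN
#' kernel S; each iteration updates P_d <- S_d (sum_{e != d} w~_e P_e) S_d'
#' where w~ renormalizes the weights over the partner matrices, followed by
#' symmetrization and renormalization. The fused matrix is the weighted mean
#' of the diffused kernels, rescaled so its maximum (the diagonal) is 1.
#' With a single input matrix no diffusion partner exists and the normalized
#' input is returned.
#'
#' @param similarities list of [SimilarityMatrix-class] objects over the
#'   same samples.
#' @param kNeighbors neighbourhood size of the sparse kernel
#'   (1 <= k < n samples).
#' @param iterations number of cross-diffusion steps (default 20).
#' @param weights per-matrix nonnegative weights (default equal); typically
#'   [richnessWeights()].
#' @return a [SimilarityMatrix-class] of kind \code{"fused"}.
#' @export
snfFuse <- function(similarities, kNeighbors, iterations = 20L,
                    weights = NULL) {
  stopifnot(length(similarities) >= 1L,
            all(vapply(similarities, is, TRUE, "SimilarityMatrix")),
            iterations >= 1L)
  ids <- rownames(similarities[[1L]]@matrix)
  n <- length(ids)
  if (kNeighbors >= n || kNeighbors < 1L)
    stop("kNeighbors must satisfy 1 <= k < n (n = ", n, ")")
  mats <- lapply(similarities, function(s) {
    if (!setequal(rownames(s@matrix), ids))
      stop("similarity matrices must share one sample set")
    s@matrix[ids, ids]
  })
  m <- length(mats)
  if (is.null(weights)) weights <- rep(1 / m, m)
  stopifnot(length(weights) == m, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)

  P <- lapply(mats, .snfNormalize)
  if (m > 1L) {
    S <- lapply(mats, .snfKernel, k = kNeighbors)
    for (it in seq_len(iterations)) {
      Pnew <- vector("list", m)
      for (d in seq_len(m)) {
        wPartner <- weights[-d]
        if (sum(wPartner) == 0) {
          Pnew[[d]] <- P[[d]]        # no weighted partner: stays put
          next
        }
        wPartner <- wPartner / sum(wPartner)
        avg <- Reduce(`+`, Map(function(w, pp) w * pp, wPartner, P[-d]))
        upd <- S[[d]] %*% avg %*% t(S[[d]])
        upd <- (upd + t(upd)) / 2
        Pnew[[d]] <- .snfNormalize(upd)
      }
      P <- Pnew
    }
  }
  fused <- Reduce(`+`, Map(function(w, pp) w * pp, weights, P))
  fused <- (fused + t(fused)) / 2
  fused <- fused / max(fused)
  dimnames(fused) <- list(ids, ids)
  new("SimilarityMatrix", matrix = fused, kind = "fused")
}

#' Choose the number of clusters by the eigengap heuristic
#'
#' Builds the symmetric normalized graph Laplacian of the similarity matrix
#' and returns the k in [2, kMax] maximizing the gap between the k-th and
#' (k+1)-th smallest eigenvalues. When all gaps are numerically zero (e.g.
#' an identity or constant similarity) the boundary kMax is returned with a
#' warning.
#'
#' @param fused a [SimilarityMatrix-class].
#' @param kMax largest k considered (default 10; 2 <= kMax < n).
#' @return list with \code{k} (integer) and \code{gaps} (numeric, named by
#'   candidate k).
#' @export
eigengapNClusters <- function(fused, kMax = 10L) {
  stopifnot(is(fused, "SimilarityMatrix"))
  w <- fused@matrix
  n <- nrow(w)
  kMax <- as.integer(min(kMax, n - 1L))
  if (kMax < 2L) stop("need kMax >= 2 and n > 2")
  ev <- .laplacianEigen(w)$values
  gaps <- ev[3L:(kMax + 1L)] - ev[2L:kMax]
  names(gaps) <- as.character(2L:kMax)
  if (max(gaps) < 1e-9) {
    warning("degenerate spectrum: all eigen-gaps ~0; returning kMax")
    return(list(k = kMax, gaps = gaps))
  }
  list(k = as.integer(names(gaps)[which.max(gaps)]), gaps = gaps)
}

# Symmetric normalized Laplacian eigen-decomposition, eigenvalues ascending.
.laplacianEigen <- function(w) {
  diag(w) <- 0
  d <- rowSums(w)
  d[d == 0] <- 1
  dInv <- 1 / sqrt(d)
  L <- diag(nrow(w)) - (dInv * w) %*% diag(dInv)
  L <- (L + t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  list(values = rev(e$values),
       vectors = e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE])
}

#' Normalized spectral clustering of a similarity matrix
#'
#' Ng-Jordan-Weiss style: rows of the first \code{nClusters} eigenvectors of
#' the symmetric normalized Laplacian are unit-normalized and clustered with
#' k-means (20 restarts, seeded).
#'
#' @param fused a [SimilarityMatrix-class].
#' @param nClusters number of clusters (2 <= nClusters <= n).
#' @param seed integer seed for the k-means restarts.
#' @param eigengapValues optional gap vector to store in the result.
#' @param silhouetteByK optional silhouette-by-k vector to store.
#' @return a [ClusterAssignment-class].
#' @export
spectralCluster <- function(fused, nClusters, seed = 1L,
                            eigengapValues = numeric(),
                            silhouetteByK = numeric()) {
  stopifnot(is(fused, "SimilarityMatrix"))
  w <- fused@matrix
  n <- nrow(w)
  if (nClusters > n) stop("nClusters exceeds sample count")
  stopifnot(nClusters >= 2L)
  if (nClusters == n) {         # singleton clusters; k-means degenerate
    labels <- stats::setNames(seq_len(n), rownames(w))
    return(new("ClusterAssignment", labels = labels,
               nClusters = as.integer(n),
               eigengapValues = eigengapValues,
               silhouetteByK = silhouetteByK))
  }
  eig <- .laplacianEigen(w)
  U <- eig$vectors[, seq_len(nClusters), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  set.seed(seed)
  km <- stats::kmeans(U, centers = nClusters, nstart = 20L, iter.max = 100L)
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(w)
  new("ClusterAssignment", labels = labels,
      nClusters = as.integer(nClusters),
      eigengapValues = eigengapValues, silhouetteByK = silhouetteByK)
}

#' Select the k-nearest-neighbour parameter by silhouette width
#'
#' For every candidate k the similarities are fused, the cluster count is
#' chosen by the eigengap, samples are spectrally clustered, and the mean
#' silhouette width is computed on the distance 1 - fused similarity. The k
#' with the largest silhouette wins; ties go to the smallest k.
#'
#' @param similarities list of [SimilarityMatrix-class].
#' @param kGrid integer candidates (within [1, n-1]).
#' @param weights per-matrix fusion weights.
#' @param iterations diffusion steps per fuse.
#' @param kMax eigengap search bound.
#' @param seed seed for the clustering step.
#' @return list with \code{k}, \code{silhouetteByK}, and the winning
#'   \code{fused} matrix.
#' @export
selectKNeighbors <- function(similarities, kGrid, weights = NULL,
                             iterations = 20L, kMax = 10L, seed = 1L) {
  if (!length(kGrid)) stop("empty kNeighbors grid")
  sil <- stats::setNames(rep(NA_real_, length(kGrid)), as.character(kGrid))
  fusedBy <- vector("list", length(kGrid))
  for (i in seq_along(kGrid)) {
    fused <- snfFuse(similarities, kNeighbors = kGrid[i],
                     iterations = iterations, weights = weights)
    kc <- suppressWarnings(eigengapNClusters(fused, kMax = kMax)$k)
    cl <- spectralCluster(fused, kc, seed = seed)
    dmat <- 1 - fused@matrix
    diag(dmat) <- 0
    s <- cluster::silhouette(cl@labels, dmatrix = dmat)
    sil[i] <- mean(s[, "sil_width"])
    fusedBy[[i]] <- fused
  }
  best <- which(sil == max(sil))[1L]      # ties: smallest k (grid order)
  list(k = kGrid[best], silhouetteByK = sil, fused = fusedBy[[best]])
}

#' End-to-end WSNF clustering of a multi-kingdom cohort
#'
#' Convenience wrapper: per-kingdom Bray-Curtis similarities, richness
#' weights, silhouette-based k-NN selection, eigengap cluster count (unless
#' fixed by \code{nClusters}), spectral clustering.
#'
#' @param tables named list of filtered relative-mode
#'   [AbundanceTable-class] objects (one per kingdom).
#' @param kGrid candidate k-NN values; default \{5, 10, 15, 20\} capped at
#'   n/5 (and always >= 2).
#' @param nClusters optional fixed cluster count (skips the eigengap).
#' @param iterations diffusion steps (default 20).
#' @param kMax eigengap bound (default 10).
#' @param seed integer seed.
#' @return list with \code{assignment} ([ClusterAssignment-class]),
#'   \code{fused} ([SimilarityMatrix-class]), \code{weights}, and
#'   \code{kNeighbors}.
#' @export
wsnfCluster <- function(tables, kGrid = NULL, nClusters = NULL,
                        iterations = 20L, kMax = 10L, seed = 1L) {
  sims <- lapply(tables, similarityFromProfile)
  w <- richnessWeights(tables)
  n <- nrow(sims[[1L]]@matrix)
  if (is.null(kGrid)) {
    kGrid <- unique(pmax(2L, pmin(c(5L, 10L, 15L, 20L),
                                  max(2L, floor(n / 5)))))
  }
  sel <- selectKNeighbors(sims, kGrid, weights = w, iterations = iterations,
                          kMax = kMax, seed = seed)
  fused <- sel$fused
  gap <- suppressWarnings(eigengapNClusters(fused, kMax = kMax))
  kc <- if (is.null(nClusters)) gap$k else as.integer(nClusters)
  cl <- spectralCluster(fused, kc, seed = seed,
                        eigengapValues = gap$gaps,
                        silhouetteByK = sel$silhouetteByK)
  list(assignment = cl, fused = fused, weights = w, kNeighbors = sel$k)
}
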