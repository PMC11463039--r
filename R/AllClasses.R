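#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' AbundanceTable: a taxon-by-sample abundance matrix with domain labels
#'
#' Container for multi-kingdom microbiome profiles. Extends
#' \linkS4class{SummarizedExperiment}: the single assay \code{"abundance"}
#' holds a nonnegative taxon x sample matrix, \code{rowData()$domain} tags
#' every taxon as \code{"bacteria"} or \code{"fungi"}, and an optional
#' \code{colData()$group} carries per-sample group labels. The \code{mode}
#' slot records whether entries are raw counts or relative abundances
#' (columns summing to 1; after taxon filtering, an open subcomposition
#' with column sums at most 1).
#'
#' @slot mode character, \code{"counts"} or \code{"relative"}.
#' @seealso [abundanceTable()] for construction,
#'   [readAbundanceTable()] to read from TSV.
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  representation(mode = "character"))

.validAbundanceTable <- function(object) {
  msg <- character()
  v <- assay(object, "abundance")
  if (!is.numeric(v))
    msg <- c(msg, "abundance assay must be numeric")
  if (anyNA(v))
    msg <- c(msg, "abundance assay contains NA")
  else if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("negative abundance at taxon '%s', sample '%s'",
                          rownames(v)[idx[1L]], colnames(v)[idx[2L]]))
  }
  if (nrow(v) > 0L && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msg <- c(msg, "taxon ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!object@mode %in% c("counts", "relative"))
    msg <- c(msg, "mode must be 'counts' or 'relative'")
  if (!"domain" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'domain' column")
  else if (!all(rowData(object)$domain %in% c("bacteria", "fungi")))
    msg <- c(msg, "domain labels must be 'bacteria' or 'fungi'")
  if (object@mode == "relative" && ncol(v) > 0L && nrow(v) > 0L && !anyNA(v)) {
    # filtered tables are open subcompositions: sums may fall below 1 but
    # never exceed it
    cs <- colSums(v)
    bad <- which(cs - 1 > 1e-9 | cs <= 0)
    if (length(bad))
      msg <- c(msg, sprintf(
        "relative-mode columns must sum to at most 1 and be positive (first offender: sample '%s', sum %.6g)",
        colnames(v)[bad[1L]], cs[bad[1L]]))
  }
  if (length(msg)) msg else TRUE
}
setValidity("AbundanceTable", .validAbundanceTable)

#' MethodScoreMatrix: per-method taxon-pair association scores
#'
#' Holds one ensemble member's output: raw pairwise scores, signs where the
#' method defines them (\code{NA} for magnitude-only methods such as mutual
#' information), and, once computed, ReBoot empirical p-values. Matrices are
#' symmetric with an undefined (NA) diagonal.
#'
#' @slot method one of \code{"coat"}, \code{"sparse_graph"},
#'   \code{"mutual_information"}, \code{"bray_curtis"}.
#' @slot raw symmetric numeric matrix of raw scores.
#' @slot signs symmetric matrix in \{-1, +1, NA\}.
#' @slot pvalues symmetric matrix of empirical p-values in (0, 1], or a
#'   0 x 0 matrix before [rebootEdgePvalues()] has been run.
#' @export
setClass("MethodScoreMatrix",
  representation(method = "character", raw = "matrix",
                 signs = "matrix", pvalues = "matrix"))

.validMethodScoreMatrix <- function(object) {
  msg <- character()
  ok_methods <- c("coat", "sparse_graph", "mutual_information", "bray_curtis")
  if (!object@method %in% ok_methods)
    msg <- c(msg, sprintf("method must be one of: %s",
                          paste(ok_methods, collapse = ", ")))
  r <- object@raw
  if (nrow(r) != ncol(r)) msg <- c(msg, "raw score matrix must be square")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8, check.attributes = FALSE)))
    msg <- c(msg, "raw score matrix must be symmetric")
  if (!identical(dim(object@signs), dim(r)))
    msg <- c(msg, "signs matrix must match raw dimensions")
  s <- object@signs
  if (!all(s[!is.na(s)] %in% c(-1, 1)))
    msg <- c(msg, "signs must be -1, +1 or NA")
  if (length(object@pvalues)) {
    p <- object@pvalues
    if (!identical(dim(p), dim(r)))
      msg <- c(msg, "pvalues matrix must match raw dimensions")
    pv <- p[upper.tri(p)]
    if (any(!is.na(pv) & (pv <= 0 | pv > 1)))
      msg <- c(msg, "pvalues must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MethodScoreMatrix", .validMethodScoreMatrix)

#' SignedNetwork: an undirected signed co-occurrence network
#'
#' Nodes are taxa with a kingdom (domain) tag; edges are unordered taxon
#' pairs carrying a sign (+1 co-presence / -1 exclusion), an aggregate
#' ensemble score and a merged p-value. Isolated nodes are kept in the node
#' table so that network size reflects the input taxa, not just the
#' connected part.
#'
#' @slot nodes data.frame with columns \code{taxon}, \code{domain}.
#' @slot edges data.frame with columns \code{taxon_a}, \code{taxon_b},
#'   \code{sign}, \code{score}, \code{p}.
#' @seealso [buildNetwork()], [splitSubnetworks()], [asIgraph()]
#' @export
setClass("SignedNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

.validSignedNetwork <- function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("taxon", "domain") %in% colnames(nd)))
    msg <- c(msg, "nodes must have 'taxon' and 'domain' columns")
  else if (anyDuplicated(nd$taxon))
    msg <- c(msg, "node taxa must be unique")
  need <- c("taxon_a", "taxon_b", "sign", "score", "p")
  if (!all(need %in% colnames(ed)))
    msg <- c(msg, sprintf("edges must have columns: %s",
                          paste(need, collapse = ", ")))
  else if (nrow(ed)) {
    if (any(ed$taxon_a == ed$taxon_b)) msg <- c(msg, "self-loops not allowed")
    if (!all(ed$sign %in% c(-1, 1))) msg <- c(msg, "edge signs must be -1/+1")
    key <- paste(pmin(ed$taxon_a, ed$taxon_b), pmax(ed$taxon_a, ed$taxon_b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
    if (!all(c(ed$taxon_a, ed$taxon_b) %in% nd$taxon))
      msg <- c(msg, "edge endpoints must be listed nodes")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SignedNetwork", .validSignedNetwork)

#' SimilarityMatrix: pairwise sample similarity
#'
#' Symmetric sample-by-sample similarity, either a Bray-Curtis similarity
#' (1 - dissimilarity, entries in [0, 1], unit diagonal) or the output of
#' weighted similarity network fusion (rescaled so that the diagonal is the
#' row maximum).
#'
#' @slot matrix symmetric numeric matrix with sample ids as dimnames.
#' @slot kind \code{"bray_curtis_similarity"} or \code{"fused"}.
#' @export
setClass("SimilarityMatrix",
  representation(matrix = "matrix", kind = "character"))

.validSimilarityMatrix <- function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9,
                        check.attributes = FALSE)))
    msg <- c(msg, "matrix must be symmetric (tolerance 1e-9)")
  if (!object@kind %in% c("bray_curtis_similarity", "fused"))
    msg <- c(msg, "kind must be 'bray_curtis_similarity' or 'fused'")
  if (object@kind == "bray_curtis_similarity" &&
      (any(m < -1e-12) || any(m > 1 + 1e-12)))
    msg <- c(msg, "Bray-Curtis similarity entries must lie in [0, 1]")
  if (nrow(m) && any(abs(diag(m) - apply(m, 1L, max)) > 1e-9))
    msg <- c(msg, "diagonal must be the row maximum")
  if (is.null(rownames(m)))
    msg <- c(msg, "sample ids required as dimnames")
  if (length(msg)) msg else TRUE
}
setValidity("SimilarityMatrix", .validSimilarityMatrix)

#' PlantedNetwork: ground-truth interaction network of a synthetic group
#'
#' The generator plants conditional dependencies through a sparse symmetric
#' positive-definite precision matrix on the latent log-abundance scale. The
#' ground-truth interaction sign of an edge is \code{-sign} of the precision
#' entry, i.e. the sign of the latent partial correlation.
#'
#' @slot taxa character taxon ids (row/col order of \code{precision}).
#' @slot domains per-taxon kingdom labels.
#' @slot precision symmetric positive-definite numeric matrix.
#' @slot edges data.frame(\code{taxon_a}, \code{taxon_b}, \code{sign}).
#' @export
setClass("PlantedNetwork",
  representation(taxa = "character", domains = "character",
                 precision = "matrix", edges = "data.frame"))

.validPlantedNetwork <- function(object) {
  msg <- character()
  P <- object@precision
  if (nrow(P) != ncol(P) || nrow(P) != length(object@taxa))
    msg <- c(msg, "precision must be square and match taxa")
  if (!isTRUE(all.equal(P, t(P), tolerance = 1e-10,
                        check.attributes = FALSE)))
    msg <- c(msg, "precision must be symmetric")
  if (any(diag(P) <= 0)) msg <- c(msg, "precision diagonal must be positive")
  ev <- tryCatch(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) NA_real_)
  if (!is.na(ev) && ev <= 0)
    msg <- c(msg, sprintf("precision not positive definite (min eigenvalue %.3g)", ev))
  if (length(object@domains) != length(object@taxa))
    msg <- c(msg, "domains must match taxa")
  if (length(msg)) msg else TRUE
}
setValidity("PlantedNetwork", .validPlantedNetwork)

#' SimulationConfig: parameters of the synthetic two-group cohort generator
#'
#' Defaults emulate the nasal-microbiome study conditions that motivate this
#' package: 122 bacterial and 131 fungal taxa after filtering, a strongly
#' dominance-skewed abundance distribution (top-10 taxa near 75 percent
#' cumulative mean relative abundance), and two sample groups whose planted
#' interaction networks share a common backbone. See the package vignette
#' for the rationale behind each default.
#'
#' @slot nSamples integer(2), samples per group.
#' @slot nBacteria,nFungi taxa per kingdom.
#' @slot edgeDensity fraction of possible taxon pairs given a planted edge.
#' @slot fractionNegativeEdges fraction of planted edges with sign -1.
#' @slot groupSpecificEdgeFraction fraction of each group's edges that are
#'   unique to that group (the rest form the shared backbone).
#' @slot dominance standard deviation of the log-normal baseline means;
#'   larger values concentrate abundance in fewer taxa.
#' @slot sequencingDepth multinomial total count per sample.
#' @slot zeroInflationProb probability of independently zeroing a count cell
#'   after sampling (sequencing dropout).
#' @slot differentialTaxa data.frame(\code{taxon}, \code{logFold}) of
#'   group-2 mean shifts on the latent log scale.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nSamples = "integer", nBacteria = "integer",
                 nFungi = "integer", edgeDensity = "numeric",
                 fractionNegativeEdges = "numeric",
                 groupSpecificEdgeFraction = "numeric",
                 dominance = "numeric", sequencingDepth = "numeric",
                 zeroInflationProb = "numeric",
                 differentialTaxa = "data.frame", seed = "integer"))

.validSimulationConfig <- function(object) {
  msg <- character()
  fr <- c(edgeDensity = object@edgeDensity,
          fractionNegativeEdges = object@fractionNegativeEdges,
          groupSpecificEdgeFraction = object@groupSpecificEdgeFraction,
          zeroInflationProb = object@zeroInflationProb)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad))
    msg <- c(msg, sprintf("must lie in [0,1]: %s", paste(bad, collapse = ", ")))
  if (any(object@nSamples < 1L)) msg <- c(msg, "nSamples must be >= 1")
  if (length(object@nSamples) != 2L) msg <- c(msg, "nSamples must have length 2")
  if (object@nBacteria + object@nFungi < 2L)
    msg <- c(msg, "need at least 2 taxa in total")
  if (object@sequencingDepth <= 0) msg <- c(msg, "sequencingDepth must be > 0")
  if (object@dominance < 0) msg <- c(msg, "dominance must be >= 0")
  dt <- object@differentialTaxa
  if (nrow(dt) && !all(c("taxon", "logFold") %in% colnames(dt)))
    msg <- c(msg, "differentialTaxa needs 'taxon' and 'logFold' columns")
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' SyntheticCohort: a generated two-group multi-kingdom cohort
#'
#' Bundle of everything [simulateCohort()] produces: per-kingdom counts and
#' relative-abundance tables (group labels in \code{colData()$group}), the
#' per-group planted ground-truth networks, and the differential-taxa list.
#'
#' @slot counts named list of counts-mode [AbundanceTable-class] objects,
#'   one per kingdom.
#' @slot relative same tables in relative mode.
#' @slot networks named list of [PlantedNetwork-class], one per group.
#' @slot differentialTaxa data.frame(\code{taxon}, \code{logFold}).
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SyntheticCohort",
  representation(counts = "list", relative = "list", networks = "list",
                 differentialTaxa = "data.frame",
                 config = "SimulationConfig"))

#' ClusterAssignment: sample clustering with model-selection diagnostics
#'
#' @slot labels named integer vector of cluster labels in 1..nClusters.
#' @slot nClusters integer.
#' @slot eigengapValues numeric vector of Laplacian eigen-gaps indexed by k.
#' @slot silhouetteByK numeric vector of mean silhouette widths by candidate
#'   k-nearest-neighbour values (empty when k was fixed by the caller).
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", nClusters = "integer",
                 eigengapValues = "numeric", silhouetteByK = "numeric"))

.validClusterAssignment <- function(object) {
  msg <- character()
  lb <- object@labels
  k <- object@nClusters
  if (any(lb < 1L | lb > k)) msg <- c(msg, "labels must lie in 1..nClusters")
  if (!setequal(unique(lb), seq_len(k)))
    msg <- c(msg, "every cluster must be nonempty")
  if (length(msg)) msg else TRUE
}
setValidity("ClusterAssignment", .validClusterAssignment)

#' AttackTrajectory: natural connectivity under progressive node removal
#'
#' Row k of \code{connectivity} holds the normalized natural connectivity of
#' the network after removing k nodes; random attacks store one column per
#' repetition, the IVI-targeted attack a single column.
#'
#' @slot connectivity numeric matrix, (N-1) x n_attacks.
#' @slot mode \code{"random"} or \code{"ivi_targeted"}.
#' @slot nNodes node count of the attacked network.
#' @slot seed integer seed used (NA for deterministic targeted mode).
#' @export
setClass("AttackTrajectory",
  representation(connectivity = "matrix", mode = "character",
                 nNodes = "integer", seed = "integer"))

.validAttackTrajectory <- function(object) {
  msg <- character()
  if (!object@mode %in% c("random", "ivi_targeted"))
    msg <- c(msg, "mode must be 'random' or 'ivi_targeted'")
  cn <- object@connectivity
  if (any(cn < -1e-12, na.rm = TRUE))
    msg <- c(msg, "connectivity values must be nonnegative")
  if (object@mode == "ivi_targeted" && ncol(cn) != 1L)
    msg <- c(msg, "targeted mode records a single trajectory")
  if (nrow(cn) != object@nNodes - 1L)
    msg <- c(msg, "trajectory must cover removals 1..N-1")
  if (length(msg)) msg else TRUE
}
setValidity("AttackTrajectory", .validAttackTrajectory)
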