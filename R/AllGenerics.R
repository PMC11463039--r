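#' @include AllClasses.R
NULL

#' Accessors for CrossKingdomNet classes
#'
#' Small accessor family: \code{abundanceMode()} returns \code{"counts"} or
#' \code{"relative"}; \code{taxonDomains()} the per-taxon kingdom labels;
#' \code{sampleGroups()} the per-sample group labels (or NULL);
#' \code{edgeTable()} / \code{nodeTable()} the edge and node data.frames of a
#' network; \code{asIgraph()} converts a network to an \pkg{igraph} object
#' with \code{domain} vertex and \code{sign}, \code{score}, \code{p} edge
#' attributes.
#'
#' @param x an object of the documented class.
#' @param ... further arguments for methods.
#' @return see Description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundanceMode", function(x) standardGeneric("abundanceMode"))

#' @rdname accessors
#' @export
setGeneric("taxonDomains", function(x) standardGeneric("taxonDomains"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @param signedOnly for \code{asIgraph}: drop edges without a defined sign.
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setMethod("abundanceMode", "AbundanceTable", function(x) x@mode)

#' @rdname accessors
#' @export
setMethod("taxonDomains", "AbundanceTable", function(x) {
  stats::setNames(as.character(rowData(x)$domain), rownames(x))
})

#' @rdname accessors
#' @export
setMethod("sampleGroups", "AbundanceTable", function(x) {
  if (!"group" %in% colnames(colData(x))) return(NULL)
  stats::setNames(as.character(colData(x)$group), colnames(x))
})

#' @rdname accessors
#' @export
setMethod("edgeTable", "SignedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nodeTable", "SignedNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "PlantedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("asIgraph", "SignedNetwork", function(x, signedOnly = FALSE) {
  ed <- x@edges
  g <- igraph::graph_from_data_frame(
    d = ed[, c("taxon_a", "taxon_b", "sign", "score", "p")],
    directed = FALSE,
    vertices = data.frame(name = x@nodes$taxon, domain = x@nodes$domain,
                          stringsAsFactors = FALSE))
  g
})

setMethod("show", "AbundanceTable", function(object) {
  v <- assay(object, "abundance")
  dom <- table(rowData(object)$domain)
  cat(sprintf("AbundanceTable (%s mode): %d taxa x %d samples\n",
              object@mode, nrow(v), ncol(v)))
  cat("  domains:", paste(sprintf("%s=%d", names(dom), dom), collapse = ", "),
      "\n")
  gr <- sampleGroups(object)
  if (!is.null(gr)) {
    gt <- table(gr)
    cat("  groups: ", paste(sprintf("%s=%d", names(gt), gt), collapse = ", "),
        "\n")
  }
  invisible(object)
})

setMethod("show", "MethodScoreMatrix", function(object) {
  cat(sprintf("MethodScoreMatrix '%s': %d taxa (%d pairs)%s\n",
              object@method, nrow(object@raw),
              choose(nrow(object@raw), 2),
              if (length(object@pvalues)) ", with ReBoot p-values" else ""))
  invisible(object)
})

setMethod("show", "SignedNetwork", function(object) {
  ed <- object@edges
  cat(sprintf("SignedNetwork: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(object@nodes), nrow(ed),
              sum(ed$sign > 0), sum(ed$sign < 0)))
  invisible(object)
})

setMethod("show", "PlantedNetwork", function(object) {
  cat(sprintf("PlantedNetwork: %d taxa, %d planted edges (%d negative)\n",
              length(object@taxa), nrow(object@edges),
              sum(object@edges$sign < 0)))
  invisible(object)
})

setMethod("show", "SyntheticCohort", function(object) {
  ns <- object@config@nSamples
  cat(sprintf(
    "SyntheticCohort: %d bacteria + %d fungi, groups of %d and %d samples\n",
    object@config@nBacteria, object@config@nFungi, ns[1L], ns[2L]))
  cat(sprintf("  planted edges: %s\n",
              paste(vapply(object@networks,
                           function(n) nrow(n@edges), 1L), collapse = " / ")))
  invisible(object)
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d samples in %d clusters (sizes: %s)\n",
              length(object@labels), object@nClusters,
              paste(tabulate(object@labels, object@nClusters),
                    collapse = ", ")))
  invisible(object)
})

setMethod("show", "AttackTrajectory", function(object) {
  cat(sprintf("AttackTrajectory (%s): N=%d, removals 1..%d, %d repetition%s\n",
              object@mode, object@nNodes, nrow(object@connectivity),
              ncol(object@connectivity),
              if (ncol(object@connectivity) == 1L) "" else "s"))
  invisible(object)
})
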