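#' @include AllClasses.R synthetic.R wsnf.R ensemble-aggregate.R connectivity.R ivi.R
NULL

#' Summary table of per-group network characteristics
#'
#' @param nets named list of [SignedNetwork-class] objects.
#' @return data.frame, one row per network: node and edge counts, positive
#'   and negative edge counts, and the within-bacteria, within-fungi and
#'   cross-kingdom edge counts.
#' @export
summarizeNetworks <- function(nets) {
  stopifnot(length(nets) >= 1L,
            all(vapply(nets, is, TRUE, "SignedNetwork")))
  rows <- lapply(names(nets), function(nm) {
    net <- nets[[nm]]
    ed <- net@edges
    sub <- splitSubnetworks(net)
    data.frame(network = nm, nodes = nrow(net@nodes), edges = nrow(ed),
               positive = sum(ed$sign > 0), negative = sum(ed$sign < 0),
               bacteria_bacteria = nrow(sub$bacteria@edges),
               fungi_fungi = nrow(sub$fungi@edges),
               bacteria_fungi = nrow(sub$cross@edges),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.writeNetwork <- function(net, prefix) {
  tsv <- paste0(prefix, "_edges.tsv")
  utils::write.table(net@edges, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(asIgraph(net), gml, format = "graphml")
  c(tsv, gml)
}

#' Run the full multi-kingdom network ecology pipeline
#'
#' Stages: (1) obtain per-kingdom profiles, either by simulation
#' (\code{simulation}) or from TSV inputs (\code{inputs}); (2)
#' prevalence/abundance filtering per kingdom and cross-kingdom merge with
#' renormalization; (3) WSNF clustering of all samples; (4) per-group
#' ensemble network inference with ReBoot significance; (5) attack
#' robustness comparison between the two groups (overall and negative-only);
#' (6) permutational keystone detection per group. All stage seeds are
#' derived deterministically from \code{seed}.
#'
#' @param outputDir directory for all outputs (created if needed).
#' @param simulation a [SimulationConfig-class], or NULL when reading files.
#' @param inputs named list with paths \code{bacteria}, \code{fungi} (TSV
#'   abundance tables) and \code{metadata} (sample_id, group); exactly one
#'   of \code{simulation} / \code{inputs} must be given.
#' @param filters per-kingdom filter settings: list with elements
#'   \code{bacteria} and \code{fungi}, each
#'   \code{c(minAbundance, minPrevalence)}. Defaults: 1e-4 / 0.1 for
#'   bacteria, 1e-3 / 0.1 for fungi.
#' @param ensemble list of [rebootEdgePvalues()] /
#'   [inferNetwork()] settings: \code{nBootstraps}, \code{nPermutations},
#'   \code{soft}, \code{nlambda}, \code{threshold}, ...
#' @param robustness list: \code{nAttacks} (default 1000),
#'   \code{nPermutations} (default 1000), \code{alpha} (default 0.001).
#'   The reduced smoke preset used in examples is 100/100 with alpha 0.01.
#' @param cluster logical: run the WSNF clustering stage (default TRUE).
#' @param seed global integer seed.
#' @return the run manifest (named list; also written as
#'   \code{manifest.json}), containing the configuration echo, per-stage
#'   outputs, the network summary table, robustness comparison and keystone
#'   reports.
#' @export
runPipeline <- function(outputDir, simulation = NULL, inputs = NULL,
                        filters = list(bacteria = c(1e-4, 0.1),
                                       fungi = c(1e-3, 0.1)),
                        ensemble = list(), robustness = list(),
                        cluster = TRUE, seed = 1L) {
  if (is.null(simulation) == is.null(inputs))
    stop("give exactly one of 'simulation' or 'inputs'")
  if (!dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  manifest <- list(seed = as.integer(seed), stages = list(),
                   files = character())

  # -- stage 1: profiles ----------------------------------------------------
  if (!is.null(simulation)) {
    cohort <- simulateCohort(simulation)
    gt <- exportGroundTruth(cohort, file.path(outputDir, "ground_truth"))
    manifest$files <- c(manifest$files, unname(gt))
    tables <- cohort@relative
    groups <- sampleGroups(tables$bacteria)
    manifest$stages$profiles <- list(source = "simulation",
                                     seed = simulation@seed)
  } else {
    for (nm in c("bacteria", "fungi", "metadata"))
      if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]]))
        stop("missing input file for '", nm, "': ",
             if (is.null(inputs[[nm]])) "(not given)" else inputs[[nm]])
    md <- readSampleMetadata(inputs$metadata)
    groups <- stats::setNames(md$group, md$sample_id)
    tables <- list(
      bacteria = toRelative(readAbundanceTable(inputs$bacteria, "bacteria")),
      fungi = toRelative(readAbundanceTable(inputs$fungi, "fungi")))
    for (nm in c("bacteria", "fungi")) {
      v <- assay(tables[[nm]], "abundance")
      if (!all(colnames(v) %in% names(groups)))
        stop("metadata lacks group labels for some samples")
      tables[[nm]] <- abundanceTable(v, nm, mode = "relative",
                                     group = groups[colnames(v)])
    }
    manifest$stages$profiles <- list(source = "files", inputs = inputs)
  }

  # -- stage 2: filter + merge ----------------------------------------------
  filtered <- lapply(names(tables), function(nm) {
    f <- filters[[nm]]
    prevalenceAbundanceFilter(tables[[nm]], f[1L], f[2L])
  })
  names(filtered) <- names(tables)
  merged <- mergeDomainsRenormalize(filtered)
  mergedPath <- file.path(outputDir, "merged_profile.tsv")
  writeAbundanceTable(merged, mergedPath)
  manifest$files <- c(manifest$files, mergedPath)
  manifest$stages$filter <- list(
    retained = vapply(filtered, nrow, 1L), filters = filters)

  # -- stage 3: WSNF clustering ---------------------------------------------
  if (cluster) {
    cl <- wsnfCluster(filtered, seed = .stageSeed(seed, "cluster"))
    labPath <- file.path(outputDir, "clusters.tsv")
    utils::write.table(
      data.frame(sample_id = names(cl$assignment@labels),
                 cluster = cl$assignment@labels),
      labPath, sep = "\t", quote = FALSE, row.names = FALSE)
    fusedPath <- file.path(outputDir, "fused_similarity.tsv")
    utils::write.table(cl$fused@matrix, fusedPath, sep = "\t", quote = FALSE)
    manifest$files <- c(manifest$files, labPath, fusedPath)
    manifest$stages$cluster <- list(
      nClusters = cl$assignment@nClusters, kNeighbors = cl$kNeighbors,
      weights = as.list(cl$weights),
      silhouetteByK = as.list(cl$assignment@silhouetteByK))
  }

  # -- stage 4: per-group networks ------------------------------------------
  grpLevels <- sort(unique(groups))
  if (length(grpLevels) != 2L)
    stop("pipeline expects exactly 2 sample groups, got ",
         length(grpLevels))
  ens <- utils::modifyList(
    list(nBootstraps = 100L, nPermutations = 100L, soft = 0.2,
         nlambda = 100L, threshold = 1e-3), ensemble)
  nets <- list()
  for (g in grpLevels) {
    sub <- merged[, names(groups)[groups == g]]
    sub <- new("AbundanceTable", sub, mode = "relative")
    res <- inferNetwork(toRelative(sub),
                        threshold = ens$threshold,
                        nBootstraps = ens$nBootstraps,
                        nPermutations = ens$nPermutations,
                        soft = ens$soft, nlambda = ens$nlambda,
                        seed = .stageSeed(seed, "network"))
    nets[[g]] <- res$network
    manifest$files <- c(manifest$files,
                        .writeNetwork(res$network,
                                      file.path(outputDir,
                                                paste0("network_", g))))
    subs <- splitSubnetworks(res$network)
    for (s in names(subs))
      manifest$files <- c(
        manifest$files,
        .writeNetwork(subs[[s]],
                      file.path(outputDir,
                                paste0("network_", g, "_", s))))
  }
  summary <- summarizeNetworks(nets)
  sumPath <- file.path(outputDir, "network_summary.tsv")
  utils::write.table(summary, sumPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$files <- c(manifest$files, sumPath)
  manifest$stages$networks <- list(summary = summary)

  # -- stage 5: robustness --------------------------------------------------
  rob <- utils::modifyList(
    list(nAttacks = 1000L, nPermutations = 1000L, alpha = 0.001),
    robustness)
  robReport <- list()
  canAttack <- function(net) {
    g <- igraph::subgraph(asIgraph(net),
                          which(igraph::degree(asIgraph(net)) > 0))
    if (igraph::vcount(g) >= 2L) g else NULL
  }
  skel <- lapply(nets, canAttack)
  if (!any(vapply(skel, is.null, TRUE))) {
    tr <- lapply(skel, randomAttack, nAttacks = rob$nAttacks,
                 seed = .stageSeed(seed, "attack"))
    cmp <- compareGroupRobustness(tr[[1L]], tr[[2L]])
    robReport$overall <- list(
      mergedP = cmp$mergedP,
      moreRobust = switch(cmp$direction, A = grpLevels[1L],
                          B = grpLevels[2L], "tie"),
      perK = cmp$perK)
    negs <- lapply(nets, negativeSubnetwork)
    negSkel <- lapply(negs, canAttack)
    if (!any(vapply(negSkel, is.null, TRUE))) {
      trN <- lapply(negSkel, randomAttack, nAttacks = rob$nAttacks,
                    seed = .stageSeed(seed, "attack"))
      cmpN <- compareGroupRobustness(trN[[1L]], trN[[2L]])
      robReport$negativeOnly <- list(
        mergedP = cmpN$mergedP,
        moreRobust = switch(cmpN$direction, A = grpLevels[1L],
                            B = grpLevels[2L], "tie"),
        perK = cmpN$perK)
    }
  }
  robPath <- file.path(outputDir, "robustness.json")
  jsonlite::write_json(robReport, robPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  manifest$files <- c(manifest$files, robPath)
  manifest$stages$robustness <- robReport[setdiff(names(robReport), "perK")]

  # -- stage 6: keystones ---------------------------------------------------
  keyReports <- list()
  for (g in grpLevels) {
    if (is.null(skel[[g]])) next
    kr <- keystoneDetection(skel[[g]], nPermutations = rob$nPermutations,
                            alpha = rob$alpha,
                            seed = .stageSeed(seed, "keystone"))
    keyPath <- file.path(outputDir, paste0("keystones_", g, ".tsv"))
    utils::write.table(kr$table, keyPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$files <- c(manifest$files, keyPath)
    keyReports[[g]] <- list(keystones = kr$keystones,
                            alpha = kr$alpha,
                            nPermutations = kr$nPermutations)
  }
  manifest$stages$keystones <- keyReports

  stopifnot(all(file.exists(manifest$files)))
  manPath <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
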