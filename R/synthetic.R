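#' @include AllClasses.R utils.R abundance.R
NULL

#' Create a SimulationConfig
#'
#' Defaults reproduce the study conditions the generator emulates: a
#' two-group cohort (439 and 807 samples), 122 bacterial and 131 fungal
#' taxa, and a dominance-skewed abundance profile in which the top-10 taxa
#' carry roughly three quarters of the total mean relative abundance
#' (dominance sd 2.5 at 253 taxa). Tests and examples use much smaller
#' cohorts by overriding these.
#'
#' @param nSamples integer(2), samples per group.
#' @param nBacteria,nFungi taxa per kingdom.
#' @param edgeDensity fraction of taxon pairs carrying a planted edge.
#' @param fractionNegativeEdges fraction of planted edges with negative
#'   interaction sign.
#' @param groupSpecificEdgeFraction fraction of each group's edges unique to
#'   the group.
#' @param dominance sd of the log-normal baseline means (log scale).
#' @param sequencingDepth multinomial total count per sample.
#' @param zeroInflationProb post-sampling dropout probability per cell.
#' @param differentialTaxa data.frame(\code{taxon}, \code{logFold}): latent
#'   log-scale mean shifts applied to group 2.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nSamples = c(439L, 807L),
                             nBacteria = 122L, nFungi = 131L,
                             edgeDensity = 0.05,
                             fractionNegativeEdges = 0.35,
                             groupSpecificEdgeFraction = 0.3,
                             dominance = 2.5,
                             sequencingDepth = 1e6,
                             zeroInflationProb = 0.02,
                             differentialTaxa = data.frame(
                               taxon = character(), logFold = numeric()),
                             seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nBacteria = as.integer(nBacteria),
      nFungi = as.integer(nFungi), edgeDensity = edgeDensity,
      fractionNegativeEdges = fractionNegativeEdges,
      groupSpecificEdgeFraction = groupSpecificEdgeFraction,
      dominance = dominance, sequencingDepth = sequencingDepth,
      zeroInflationProb = zeroInflationProb,
      differentialTaxa = differentialTaxa, seed = as.integer(seed))
}

.taxonIds <- function(config) {
  c(sprintf("bac%03d", seq_len(config@nBacteria)),
    sprintf("fun%03d", seq_len(config@nFungi)))
}

.taxonDomainsOf <- function(config) {
  c(rep("bacteria", config@nBacteria), rep("fungi", config@nFungi))
}

#' Sample the planted per-group precision matrices
#'
#' Draws a sparse symmetric precision matrix for each of the two groups. The
#' groups share a common edge backbone; \code{groupSpecificEdgeFraction} of
#' each group's edges are unique to it. Off-diagonal magnitudes are uniform
#' in [0.2, 0.4]; the interaction sign of an edge is \code{-sign} of the
#' precision entry, and a \code{fractionNegativeEdges} share of edges is
#' negative. Positive definiteness is enforced by diagonal dominance:
#' \code{diag_i = 1 + sum_j |omega_ij|}.
#'
#' @param config a [SimulationConfig-class].
#' @param rngSeed integer seed (defaults to \code{config@seed}).
#' @return named list of two [PlantedNetwork-class] objects
#'   (\code{group1}, \code{group2}).
#' @export
samplePlantedNetwork <- function(config, rngSeed = config@seed) {
  validObject(config)
  set.seed(rngSeed)
  p <- config@nBacteria + config@nFungi
  ids <- .taxonIds(config)
  doms <- .taxonDomainsOf(config)
  maxEdges <- p * (p - 1L) / 2L
  nEdges <- round(config@edgeDensity * maxEdges)
  nSpecific <- round(config@groupSpecificEdgeFraction * nEdges)
  nBackbone <- nEdges - nSpecific
  if (nBackbone + 2L * nSpecific > maxEdges)
    stop(sprintf(
      "infeasible density: need %d distinct pairs but only %d exist",
      nBackbone + 2L * nSpecific, maxEdges))

  allPairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pick <- sample.int(nrow(allPairs), nBackbone + 2L * nSpecific)
  backbone <- pick[seq_len(nBackbone)]
  spec1 <- pick[nBackbone + seq_len(nSpecific)]
  spec2 <- pick[nBackbone + nSpecific + seq_len(nSpecific)]

  drawEdgeValues <- function(k) {
    mag <- stats::runif(k, 0.2, 0.4)
    sgn <- ifelse(stats::runif(k) < config@fractionNegativeEdges, -1, 1)
    list(mag = mag, sign = sgn)
  }
  vBack <- drawEdgeValues(nBackbone)
  v1 <- drawEdgeValues(nSpecific)
  v2 <- drawEdgeValues(nSpecific)

  buildGroup <- function(idxShared, vShared, idxOwn, vOwn) {
    omega <- matrix(0, p, p, dimnames = list(ids, ids))
    fill <- function(idx, v) {
      if (!length(idx)) return()
      ij <- allPairs[idx, , drop = FALSE]
      # interaction sign s => precision entry -s * magnitude
      omega[cbind(ij[, 1L], ij[, 2L])] <<- -v$sign * v$mag
      omega[cbind(ij[, 2L], ij[, 1L])] <<- -v$sign * v$mag
    }
    fill(idxShared, vShared)
    fill(idxOwn, vOwn)
    diag(omega) <- 1 + rowSums(abs(omega))
    idx <- c(idxShared, idxOwn)
    if (length(idx)) {
      ij <- allPairs[idx, , drop = FALSE]
      edges <- data.frame(
        taxon_a = pmin(ids[ij[, 1L]], ids[ij[, 2L]]),
        taxon_b = pmax(ids[ij[, 1L]], ids[ij[, 2L]]),
        sign = c(vShared$sign, vOwn$sign),
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
      rownames(edges) <- NULL
    } else {
      edges <- data.frame(taxon_a = character(), taxon_b = character(),
                          sign = numeric(), stringsAsFactors = FALSE)
    }
    new("PlantedNetwork", taxa = ids, domains = doms, precision = omega,
        edges = edges)
  }
  list(group1 = buildGroup(backbone, vBack, spec1, v1),
       group2 = buildGroup(backbone, vBack, spec2, v2))
}

#' Simulate a two-group multi-kingdom cohort with planted ground truth
#'
#' Latent log-abundances are multivariate normal with covariance equal to
#' the inverse of the group's planted precision matrix; per-taxon means are
#' drawn log-normal with sd \code{dominance} (shared across groups), with
#' \code{differentialTaxa} log-fold shifts added to group 2. Latent values
#' are exponentiated, closed to a composition, sampled into counts with a
#' per-sample multinomial at \code{sequencingDepth}, and finally thinned by
#' independent per-cell dropout with probability \code{zeroInflationProb}.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' cfg <- simulationConfig(nSamples = c(20L, 20L), nBacteria = 10L,
#'                         nFungi = 8L, sequencingDepth = 1e4, seed = 7L)
#' simulateCohort(cfg)
#' @export
simulateCohort <- function(config) {
  validObject(config)
  networks <- samplePlantedNetwork(config, rngSeed = config@seed)
  set.seed(.stageSeed(config@seed, "simulate"))
  p <- config@nBacteria + config@nFungi
  ids <- .taxonIds(config)
  doms <- .taxonDomainsOf(config)

  baseMu <- stats::rnorm(p, 0, config@dominance)
  names(baseMu) <- ids
  dt <- config@differentialTaxa
  if (nrow(dt)) {
    unknown <- setdiff(dt$taxon, ids)
    if (length(unknown))
      stop("differentialTaxa not in cohort: ", paste(unknown, collapse = ", "))
  }

  sampleGroup <- function(g) {
    n <- config@nSamples[g]
    mu <- baseMu
    if (g == 2L && nrow(dt)) mu[dt$taxon] <- mu[dt$taxon] + dt$logFold
    sigma <- solve(networks[[g]]@precision)
    sigma <- (sigma + t(sigma)) / 2
    z <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
    z <- matrix(z, nrow = n)               # n = 1 safety
    x <- exp(z)
    probs <- x / rowSums(x)
    counts <- apply(probs, 1L, function(pr)
      stats::rmultinom(1L, size = config@sequencingDepth, prob = pr))
    counts <- matrix(as.numeric(counts), nrow = p)
    if (config@zeroInflationProb > 0) {
      drop <- matrix(stats::runif(length(counts)) < config@zeroInflationProb,
                     nrow = p)
      counts[drop] <- 0
    }
    dimnames(counts) <- list(ids, sprintf("g%d_s%03d", g, seq_len(n)))
    counts
  }
  c1 <- sampleGroup(1L)
  c2 <- sampleGroup(2L)
  counts <- cbind(c1, c2)
  groups <- rep(c("group1", "group2"), times = config@nSamples)

  kingdoms <- intersect(c("bacteria", "fungi"), unique(doms))
  countsTables <- lapply(stats::setNames(kingdoms, kingdoms), function(d)
    abundanceTable(counts[doms == d, , drop = FALSE], d, mode = "counts",
                   group = groups))
  relTables <- lapply(countsTables, toRelative)

  new("SyntheticCohort", counts = countsTables, relative = relTables,
      networks = networks, differentialTaxa = dt, config = config)
}

#' Export a cohort's ground truth to plain-text files
#'
#' Writes \code{planted_edges.tsv} (taxon_a, taxon_b, sign, group),
#' \code{differential_taxa.tsv}, a YAML echo of the configuration (including
#' the seed), and the per-kingdom count tables in the TSV dialect
#' [readAbundanceTable()] reads.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
exportGroundTruth <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- c(edges = file.path(dir, "planted_edges.tsv"),
             differential = file.path(dir, "differential_taxa.tsv"),
             config = file.path(dir, "config.yaml"),
             stats::setNames(
               file.path(dir, sprintf("counts_%s.tsv", names(cohort@counts))),
               names(cohort@counts)))
  edges <- do.call(rbind, lapply(names(cohort@networks), function(g) {
    e <- cohort@networks[[g]]@edges
    if (nrow(e)) cbind(e, group = g)
    else cbind(e, group = character())
  }))
  utils::write.table(edges, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort@differentialTaxa, paths[["differential"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort@config
  yaml::write_yaml(list(
    nSamples = cfg@nSamples, nBacteria = cfg@nBacteria, nFungi = cfg@nFungi,
    edgeDensity = cfg@edgeDensity,
    fractionNegativeEdges = cfg@fractionNegativeEdges,
    groupSpecificEdgeFraction = cfg@groupSpecificEdgeFraction,
    dominance = cfg@dominance, sequencingDepth = cfg@sequencingDepth,
    zeroInflationProb = cfg@zeroInflationProb,
    differentialTaxa = if (nrow(cfg@differentialTaxa))
      as.list(cfg@differentialTaxa) else list(),
    seed = cfg@seed), paths[["config"]])
  for (d in names(cohort@counts))
    writeAbundanceTable(cohort@counts[[d]], paths[[d]])
  invisible(paths)
}
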