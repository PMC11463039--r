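suppressPackageStartupMessages(library(SummarizedExperiment))

test_that("planted precision matrices are positive definite with mixed signs", {
  cfg <- simulationConfig(nSamples = c(20L, 20L), nBacteria = 15L,
                          nFungi = 15L, edgeDensity = 0.1, seed = 3L)
  nets <- samplePlantedNetwork(cfg)
  for (pn in nets) {
    ev <- eigen(pn@precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(pn@precision, t(pn@precision))
    expect_true(all(pn@edges$sign %in% c(-1, 1)))
    # planted interaction sign is the sign of the latent partial correlation
    for (k in seq_len(min(5, nrow(pn@edges)))) {
      i <- pn@edges$taxon_a[k]; j <- pn@edges$taxon_b[k]
      expect_equal(pn@edges$sign[k], -sign(pn@precision[i, j]))
    }
  }
})

test_that("edge density, backbone sharing and degenerate settings behave", {
  cfg0 <- simulationConfig(nSamples = c(5L, 5L), nBacteria = 10L,
                           nFungi = 0L, edgeDensity = 0, seed = 1L)
  nets0 <- samplePlantedNetwork(cfg0)
  expect_equal(nrow(nets0$group1@edges), 0L)
  expect_true(all(nets0$group1@precision[upper.tri(diag(10))] == 0))

  cfgShared <- simulationConfig(nSamples = c(5L, 5L), nBacteria = 12L,
                                nFungi = 0L, edgeDensity = 0.2,
                                groupSpecificEdgeFraction = 0, seed = 2L)
  netsS <- samplePlantedNetwork(cfgShared)
  expect_identical(netsS$group1@edges, netsS$group2@edges)

  cfgBad <- simulationConfig(nSamples = c(5L, 5L), nBacteria = 6L,
                             nFungi = 0L, edgeDensity = 1,
                             groupSpecificEdgeFraction = 1, seed = 2L)
  expect_error(samplePlantedNetwork(cfgBad), "infeasible")
})

test_that("cohorts are reproducible, closed, and at depth before dropout", {
  cfg <- simulationConfig(nSamples = c(8L, 12L), nBacteria = 10L,
                          nFungi = 6L, sequencingDepth = 5e4,
                          zeroInflationProb = 0, seed = 7L)
  ch1 <- simulateCohort(cfg)
  ch2 <- simulateCohort(cfg)
  expect_identical(assay(ch1@counts$bacteria, "abundance"),
                   assay(ch2@counts$bacteria, "abundance"))
  expect_identical(ch1@networks$group1@precision,
                   ch2@networks$group1@precision)

  allCounts <- rbind(assay(ch1@counts$bacteria, "abundance"),
                     assay(ch1@counts$fungi, "abundance"))
  expect_true(all(colSums(allCounts) == 5e4))
  expect_equal(unname(colSums(assay(ch1@relative$bacteria, "abundance"))),
               rep(1, 20), tolerance = 1e-9)
  expect_equal(unname(sampleGroups(ch1@relative$fungi)),
               rep(c("group1", "group2"), c(8, 12)))
})

test_that("single-sample groups and differential effects work", {
  dt <- data.frame(taxon = "bac001", logFold = 2)
  cfg <- simulationConfig(nSamples = c(1L, 1L), nBacteria = 5L, nFungi = 3L,
                          differentialTaxa = dt, seed = 5L)
  ch <- simulateCohort(cfg)
  expect_equal(ncol(ch@counts$bacteria), 2L)

  cfg2 <- simulationConfig(nSamples = c(150L, 150L), nBacteria = 20L,
                           nFungi = 0L, dominance = 1,
                           differentialTaxa = dt, sequencingDepth = 1e5,
                           seed = 6L)
  ch2 <- simulateCohort(cfg2)
  rel <- assay(ch2@relative$bacteria, "abundance")
  grp <- sampleGroups(ch2@relative$bacteria)
  expect_gt(mean(rel["bac001", grp == "group2"]),
            mean(rel["bac001", grp == "group1"]))
})

test_that("default dominance reproduces a strongly dominance-skewed profile", {
  cfg <- simulationConfig(nSamples = c(60L, 60L), seed = 9L)  # 253 taxa
  ch <- simulateCohort(cfg)
  merged <- mergeDomainsRenormalize(ch@relative)
  mra <- rowMeans(assay(merged, "abundance"))
  top10 <- sum(sort(mra, decreasing = TRUE)[1:10])
  expect_gt(top10, 0.5)
})

test_that("ground-truth export round-trips edges and config", {
  cfg <- simulationConfig(nSamples = c(6L, 6L), nBacteria = 8L, nFungi = 6L,
                          edgeDensity = 0.15, sequencingDepth = 1e4,
                          seed = 11L)
  ch <- simulateCohort(cfg)
  dir <- withr::local_tempdir()
  paths <- exportGroundTruth(ch, dir)
  expect_true(all(file.exists(paths)))

  edges <- read.delim(paths[["edges"]])
  g1 <- edges[edges$group == "group1", c("taxon_a", "taxon_b", "sign")]
  rownames(g1) <- NULL
  expect_equal(g1, ch@networks$group1@edges)

  cfgEcho <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfgEcho$seed, 11L)
  expect_equal(cfgEcho$nBacteria, 8L)

  back <- readAbundanceTable(paths[["bacteria"]], "bacteria")
  expect_equal(assay(back, "abundance"),
               assay(ch@counts$bacteria, "abundance"))

  # empty edge set -> header-only file
  cfg0 <- simulationConfig(nSamples = c(3L, 3L), nBacteria = 5L,
                           nFungi = 0L, edgeDensity = 0,
                           sequencingDepth = 1e3, seed = 2L)
  p0 <- exportGroundTruth(simulateCohort(cfg0), withr::local_tempdir())
  expect_equal(nrow(read.delim(p0[["edges"]])), 0L)
})

test_that("latent CLR correlations track the planted basis correlations", {
  cfg <- simulationConfig(nSamples = c(400L, 5L), nBacteria = 30L,
                          nFungi = 0L, edgeDensity = 0.1,
                          sequencingDepth = 1e7, zeroInflationProb = 0,
                          dominance = 1, seed = 13L)
  ch <- simulateCohort(cfg)
  tab <- ch@relative$bacteria
  g1 <- names(which(sampleGroups(tab) == "group1"))
  clr <- clrTransform(toRelative(tab[, g1]))
  emp <- cor(t(clr))
  truth <- cov2cor(solve(ch@networks$group1@precision))
  ut <- upper.tri(truth)
  # strong pairs (planted edges and their propagation) must be recovered in
  # order: rank correlation restricted to informative pairs
  strong <- abs(truth[ut]) > 0.05
  expect_gt(cor(emp[ut][strong], truth[ut][strong], method = "spearman"),
            0.7)
  # and planted edges separate from null pairs
  keys <- pairKeys(rownames(truth))
  isEdge <- keys %in% plantedKeys(ch@networks$group1)
  expect_gt(auroc(abs(emp[ut]), isEdge), 0.75)
})
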