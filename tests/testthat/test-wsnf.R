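suppressPackageStartupMessages(library(SummarizedExperiment))

test_that("Bray-Curtis sample similarity matches hand arithmetic", {
  m <- cbind(s1 = c(0.5, 0.5), s2 = c(0.25, 0.75), s3 = c(0.5, 0.5))
  rownames(m) <- c("t1", "t2")
  s <- similarityFromProfile(relTable(m))
  expect_equal(s@matrix["s1", "s2"], 0.75)
  expect_equal(s@matrix["s1", "s3"], 1)
  expect_equal(diag(s@matrix), c(s1 = 1, s2 = 1, s3 = 1))

  disjoint <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(disjoint) <- c("t1", "t2")
  expect_equal(similarityFromProfile(relTable(disjoint))@matrix["s1", "s2"],
               0)
})

test_that("richness weights are proportional retained taxon counts", {
  bac <- relTable(randomRelMatrix(122, 4, seed = 1), "bacteria")
  fun <- relTable(randomRelMatrix(131, 4, seed = 2), "fungi")
  w <- richnessWeights(list(bacteria = bac, fungi = fun))
  expect_equal(unname(w), c(122, 131) / 253)
  expect_equal(sum(w), 1)
  expect_equal(unname(richnessWeights(list(bac))), 1)
  w2 <- richnessWeights(list(bac, relTable(randomRelMatrix(122, 4, 3),
                                           "fungi")))
  expect_equal(unname(w2), c(0.5, 0.5))
})

test_that("fusion is the normalization identity for one input and respects weights", {
  s <- blockSimilarity(2, blockSize = 6)
  fused1 <- snfFuse(list(s), kNeighbors = 3)
  norm <- CrossKingdomNet:::.snfNormalize(s@matrix)
  expect_equal(fused1@matrix, norm / max(norm), tolerance = 1e-12)

  # weight (1, 0): fused structure equals the single-input run
  set.seed(4)
  noise <- matrix(runif(144, 0, 0.3), 12, 12)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 1
  dimnames(noise) <- dimnames(s@matrix)
  s2 <- new("SimilarityMatrix", matrix = noise,
            kind = "bray_curtis_similarity")
  fusedW <- snfFuse(list(s, s2), kNeighbors = 3, weights = c(1, 0))
  expect_lt(norm(fusedW@matrix - fused1@matrix, "F"), 1e-6)
})

test_that("fusing two block-structured views preserves the block structure", {
  s <- blockSimilarity(2, blockSize = 6)
  jitter <- s@matrix
  set.seed(8)
  jitter[jitter == 0] <- runif(sum(jitter == 0), 0, 0.1)
  jitter <- (jitter + t(jitter)) / 2; diag(jitter) <- 1
  s2 <- new("SimilarityMatrix", matrix = jitter,
            kind = "bray_curtis_similarity")
  fused <- snfFuse(list(s, s2), kNeighbors = 4)
  f <- fused@matrix
  within <- c(f[1:6, 1:6][upper.tri(diag(6))],
              f[7:12, 7:12][upper.tri(diag(6))])
  between <- as.vector(f[1:6, 7:12])
  expect_gt(mean(within), mean(between))
  expect_equal(f, t(f), tolerance = 1e-9)
})

test_that("fusion commutes with sample permutation", {
  # generic (tie-free) similarities: k-NN tie-breaking is undefined on ties
  sA <- similarityFromProfile(relTable(randomRelMatrix(8, 10, seed = 9)))
  sB <- similarityFromProfile(relTable(randomRelMatrix(8, 10, seed = 10)))
  dimnames(sB@matrix) <- dimnames(sA@matrix)
  fused <- snfFuse(list(sA, sB), kNeighbors = 3, weights = c(0.6, 0.4))
  perm <- sample(rownames(sA@matrix))
  permute <- function(s) new("SimilarityMatrix",
                             matrix = s@matrix[perm, perm], kind = s@kind)
  fusedP <- snfFuse(list(permute(sA), permute(sB)), kNeighbors = 3,
                    weights = c(0.6, 0.4))
  expect_equal(fusedP@matrix, fused@matrix[perm, perm], tolerance = 1e-9)
})

test_that("eigengap recovers exact block counts and warns on degenerate spectra", {
  for (k in 2:5) {
    expect_equal(eigengapNClusters(blockSimilarity(k), kMax = 8)$k, k)
  }
  n <- 10
  ones <- matrix(1, n, n, dimnames = list(paste0("s", 1:n),
                                          paste0("s", 1:n)))
  sm <- new("SimilarityMatrix", matrix = ones,
            kind = "bray_curtis_similarity")
  expect_warning(res <- eigengapNClusters(sm, kMax = 6), "degenerate")
  expect_equal(res$k, 6L)
})

test_that("spectral clustering separates blocks exactly and is deterministic", {
  s <- blockSimilarity(3, blockSize = 5)
  fused <- snfFuse(list(s), kNeighbors = 4)
  cl <- spectralCluster(fused, 3, seed = 2)
  truth <- rep(1:3, each = 5)
  expect_equal(ari(cl@labels, truth), 1)
  cl2 <- spectralCluster(fused, 3, seed = 2)
  expect_identical(cl@labels, cl2@labels)

  clN <- spectralCluster(fused, nrow(s@matrix), seed = 2)
  expect_equal(clN@nClusters, 15L)
  expect_equal(sort(unique(clN@labels)), 1:15)
  expect_error(spectralCluster(fused, 16), "exceeds")
})

test_that("k-neighbour selection maximizes silhouette with smallest-k ties", {
  s <- blockSimilarity(2, blockSize = 8)
  sel <- selectKNeighbors(list(s), kGrid = c(3L, 5L), seed = 1)
  expect_true(sel$k %in% c(3L, 5L))
  # the distance 1 - fused is diagonal-dominant, so silhouette magnitudes
  # are modest; what matters is that they are positive and that the blocks
  # are recovered exactly
  expect_gt(max(sel$silhouetteByK), 0.05)
  kc <- suppressWarnings(eigengapNClusters(sel$fused)$k)
  cl <- spectralCluster(sel$fused, kc, seed = 1)
  expect_equal(ari(cl@labels, rep(1:2, each = 8)), 1)
  # a grid of one returns that k; exact ties return the first (smallest)
  sel1 <- selectKNeighbors(list(s), kGrid = 4L, seed = 1)
  expect_equal(sel1$k, 4L)
  expect_error(selectKNeighbors(list(s), kGrid = integer()), "empty")
})

test_that("WSNF recovers planted groups from strong composition effects", {
  p <- 40L
  dt <- data.frame(taxon = c(sprintf("bac%03d", 1:8),
                             sprintf("fun%03d", 1:8)),
                   logFold = rep(c(2, -2), 8))
  cfg <- simulationConfig(nSamples = c(60L, 60L), nBacteria = p, nFungi = p,
                          edgeDensity = 0.05, sequencingDepth = 1e6,
                          zeroInflationProb = 0.02, dominance = 1.5,
                          differentialTaxa = dt, seed = 42L)
  ch <- simulateCohort(cfg)
  res <- wsnfCluster(ch@relative, nClusters = 2L, seed = 9L)
  truth <- sampleGroups(ch@relative$bacteria)
  expect_gte(ari(res$assignment@labels[names(truth)], truth), 0.9)
  expect_equal(sum(res$weights), 1)
})
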