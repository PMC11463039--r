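suppressPackageStartupMessages(library(SummarizedExperiment))

test_that("CLR transform matches hand arithmetic and is scale invariant", {
  x <- c(1, 10, 100) / 111
  m <- matrix(x, 3, dimnames = list(paste0("t", 1:3), "s1"))
  clr <- clrTransform(m, pseudocount = 0)
  expect_equal(unname(clr[, 1]), c(-log(10), 0, log(10)), tolerance = 1e-12)

  m5 <- matrix(5 * c(1, 10, 100), 3,
               dimnames = list(paste0("t", 1:3), "s1"))
  expect_equal(clrTransform(m5, pseudocount = 0), clr, tolerance = 1e-12)

  u <- matrix(rep(0.25, 4), 4, dimnames = list(paste0("t", 1:4), "s1"))
  expect_equal(unname(clrTransform(u, 0)[, 1]), rep(0, 4))

  expect_equal(unname(colMeans(clrTransform(randomRelMatrix(6, 5)))),
               rep(0, 5), tolerance = 1e-12)
  withZero <- randomRelMatrix(4, 3); withZero[1, 1] <- 0
  withZero <- sweep(withZero, 2, colSums(withZero), "/")
  expect_error(clrTransform(withZero, pseudocount = 0), "pseudocount")
})

test_that("COAT shrinks to zero at large soft and separates a planted pair", {
  clr <- t(scale(matrix(rnorm(200 * 10), 200, 10), scale = FALSE))
  dimnames(clr) <- list(paste0("t", 1:10), paste0("s", 1:200))
  hard <- coatCorrelation(clr, soft = 1e6)
  expect_true(all(hard@raw[upper.tri(hard@raw)] == 0))

  # independent taxa: small average off-diagonal magnitude
  set.seed(21)
  big <- t(matrix(rnorm(1000 * 10), 1000, 10))
  dimnames(big) <- list(paste0("t", 1:10), paste0("s", 1:1000))
  co <- coatCorrelation(big, soft = 0.2)
  expect_lt(mean(abs(co@raw[upper.tri(co@raw)])), 0.1)

  # two strongly co-varying latent taxa dominate a 10-taxon simplex
  set.seed(22)
  z <- matrix(rnorm(300 * 10), 300, 10)
  z[, 2] <- z[, 1] + rnorm(300, sd = 0.1)
  comp <- exp(z); comp <- comp / rowSums(comp)
  m2 <- t(comp)
  dimnames(m2) <- list(paste0("t", 1:10), paste0("s", 1:300))
  co2 <- coatCorrelation(clrTransform(m2, pseudocount = 0), soft = 0.2)
  sc <- abs(co2@raw); diag(sc) <- NA
  idx <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(sc)[idx], c("t1", "t2"))
  expect_equal(co2@signs["t1", "t2"], 1)
})

test_that("COAT flags constant taxa", {
  clr <- t(scale(matrix(rnorm(50 * 5), 50, 5), scale = FALSE))
  clr[3, ] <- 0
  dimnames(clr) <- list(paste0("t", 1:5), paste0("s", 1:50))
  expect_warning(co <- coatCorrelation(clr), "t3")
  expect_true(all(is.na(co@raw["t3", -3])))
})

test_that("sparse graph is near-empty on independent data and ranks a chain", {
  set.seed(4)
  X <- matrix(rnorm(500 * 10), 500, 10)
  clr <- t(X)
  dimnames(clr) <- list(paste0("t", 1:10), paste0("s", 1:500))
  sg <- sparseGraphPartialCorrelation(clr, seed = 2)
  expect_lte(sum(sg@raw[upper.tri(sg@raw)] != 0, na.rm = TRUE), 2)

  p <- 10
  Om <- diag(p)
  for (i in 1:(p - 1)) Om[i, i + 1] <- Om[i + 1, i] <- -0.45
  set.seed(5)
  Z <- MASS::mvrnorm(500, rep(0, p), solve(Om))
  clr2 <- t(Z)
  dimnames(clr2) <- list(paste0("t", 1:p), paste0("s", 1:500))
  sg2 <- sparseGraphPartialCorrelation(clr2, seed = 2)
  sc <- abs(sg2@raw)
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  chain <- ut[, 2] - ut[, 1] == 1
  topIdx <- order(-sc[upper.tri(sc)])[seq_len(p - 1)]
  expect_equal(sort(topIdx), which(chain))
  # chain partial correlations are positive (precision entries negative)
  expect_true(all(sg2@signs[cbind(1:9, 2:10)] == 1))

  expect_identical(sparseGraphPartialCorrelation(clr2, seed = 2)@raw,
                   sg2@raw)
})

test_that("mutual information matches the plug-in formula on 2x2 designs", {
  X <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_equal(mutualInformationMatrix(X, bins = 2)@raw["a", "b"], log(2))

  Y <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_equal(mutualInformationMatrix(Y, bins = 2)@raw["a", "b"], 0)

  m <- randomRelMatrix(6, 60, seed = 5)
  mi <- mutualInformationMatrix(relTable(m))
  expect_true(all(mi@raw[upper.tri(mi@raw)] >= 0))
  expect_true(all(is.na(mi@signs[upper.tri(mi@signs)])))
  expect_error(mutualInformationMatrix(relTable(randomRelMatrix(3, 4)),
                                       bins = 10), "samples")
})

test_that("Bray-Curtis association is similarity-oriented", {
  m <- rbind(a = c(2, 1), b = c(1, 2), c = c(2, 1), d = c(0, 0))
  m <- m / 5
  colnames(m) <- c("s1", "s2")
  bc <- brayCurtisAssociation(m)
  expect_equal(bc@raw["a", "c"], 1)
  expect_equal(bc@raw["a", "b"], 2 / 3)
  expect_true(is.na(bc@raw["d", "d"]))
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(brayCurtisAssociation(disj)@raw["a", "b"], 0)
})

test_that("weighted Simes equals enumeration and classic Simes, and is monotone", {
  expect_equal(weightedSimes(0.2), 0.2)
  expect_equal(weightedSimes(c(0.01, 0.04, 0.03)), 0.03)
  expect_equal(weightedSimes(c(0.05, 0.01), weights = c(2, 1)), 0.03)
  expect_equal(weightedSimes(c(0.01, 0.04, 0.03, 1)), 0.04)
  expect_error(weightedSimes(numeric()), "empty")

  set.seed(31)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    p <- runif(k)^2
    w <- runif(k, 0.1, 3)
    expect_equal(weightedSimes(p, w), simesOracle(p, w), tolerance = 1e-12)
    # equal weights reduce to classic Simes
    expect_equal(weightedSimes(p), min(1, min(k * sort(p) / seq_len(k))),
                 tolerance = 1e-12)
  }
  # monotone nondecreasing in each input and bounded by (0, 1]
  set.seed(32)
  for (i in 1:200) {
    p <- runif(4); w <- runif(4, 0.5, 2)
    s0 <- weightedSimes(p, w)
    j <- sample(4, 1)
    p2 <- p; p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(weightedSimes(p2, w) + 1e-12, s0)
    expect_gt(s0, 0); expect_lte(s0, 1)
  }
})

test_that("ReBoot p-values hit the floor for a planted pair and are reproducible", {
  set.seed(41)
  z <- matrix(rnorm(300 * 8), 300, 8)
  z[, 2] <- z[, 1] + rnorm(300, sd = 0.15)
  comp <- exp(z); comp <- comp / rowSums(comp)
  m <- t(comp)
  dimnames(m) <- list(paste0("t", 1:8), paste0("s", 1:300))
  tab <- relTable(m)
  r <- rebootEdgePvalues(tab, "coat", nBootstraps = 10L,
                         nPermutations = 49L, seed = 3L)
  expect_equal(r@pvalues["t1", "t2"], 1 / 50)
  expect_equal(r@signs["t1", "t2"], 1)
  r2 <- rebootEdgePvalues(tab, "coat", nBootstraps = 10L,
                          nPermutations = 49L, seed = 3L)
  expect_identical(r@pvalues, r2@pvalues)
  expect_identical(r@raw, r2@raw)
  expect_warning(
    rebootEdgePvalues(tab, "bray_curtis", nBootstraps = 2L,
                      nPermutations = 5L, seed = 1L), "19")
})

test_that("ensemble aggregation combines scores, signs, and merged p-values", {
  taxa <- c("a", "b", "c")
  mk <- function(method, raw, signs = NULL, p = NULL) {
    dimnames(raw) <- list(taxa, taxa)
    if (!is.null(signs)) dimnames(signs) <- list(taxa, taxa)
    if (!is.null(p)) dimnames(p) <- list(taxa, taxa)
    CrossKingdomNet:::.newMSM(method, raw, signs, p)
  }
  sym <- function(ab, ac, bc, diag = 1) {
    m <- matrix(diag, 3, 3)
    m[1, 2] <- m[2, 1] <- ab; m[1, 3] <- m[3, 1] <- ac
    m[2, 3] <- m[3, 2] <- bc
    m
  }
  pv <- sym(0.01, 0.04, 0.5, diag = NA)
  sgn <- function(ab, ac, bc) {
    m <- sym(ab, ac, bc, diag = NA)
    m[!is.na(m) & m == 0] <- NA
    m
  }
  msms <- list(
    mk("coat", sym(0.9, -0.5, 0.1), sgn(1, -1, 1), pv),
    mk("sparse_graph", sym(0.5, 0.4, 0), sgn(1, 1, 0), pv),
    mk("mutual_information", sym(0.8, 0.3, 0.05), p = pv),
    mk("bray_curtis", sym(0.7, 0.2, 0.1), p = pv))
  agg <- aggregateEnsemble(msms)
  # strongest pair everywhere -> normalized 1 in all methods -> aggregate 1
  expect_equal(agg$score["a", "b"], 1)
  # coat and sparse_graph conflict on (a, c): excluded
  expect_true(agg$conflict["a", "c"])
  expect_equal(agg$mergedP["a", "c"], 1)
  expect_true(is.na(agg$sign["a", "c"]))
  # (b, c): only coat carries a sign
  expect_equal(agg$sign["b", "c"], 1)
  # merged p via equal-weight Simes of (0.01, 0.04, 0.5, 0.01 ...) per pair
  expect_equal(agg$mergedP["a", "b"],
               simesOracle(rep(0.01, 4) * c(1, 1, 1, 1)))

  # magnitude rule resolves the conflict instead of excluding: on (a, c)
  # the sparse graph's min-max normalized magnitude (0.8) beats COAT's
  # (0.5), so its sign wins
  agg2 <- aggregateEnsemble(msms, conflictRule = "magnitude")
  expect_false(any(agg2$conflict))
  expect_equal(agg2$sign["a", "c"], 1)

  expect_error(aggregateEnsemble(msms[1:3]), "missing")
})

test_that("network building thresholds edges and splitting partitions them", {
  taxa <- c("b1", "b2", "f1", "f2")
  doms <- c(b1 = "bacteria", b2 = "bacteria", f1 = "fungi", f2 = "fungi")
  p <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  p["b1", "b2"] <- p["b2", "b1"] <- 1e-4
  p["b1", "f1"] <- p["f1", "b1"] <- 5e-4
  p["f1", "f2"] <- p["f2", "f1"] <- 2e-3
  s <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  sgn <- matrix(NA_real_, 4, 4, dimnames = list(taxa, taxa))
  sgn["b1", "b2"] <- sgn["b2", "b1"] <- 1
  sgn["b1", "f1"] <- sgn["f1", "b1"] <- -1
  sgn["f1", "f2"] <- sgn["f2", "f1"] <- 1
  agg <- list(score = s, sign = sgn, mergedP = p)

  net <- buildNetwork(agg, threshold = 1e-3, domains = doms)
  expect_equal(nrow(edgeTable(net)), 2L)
  expect_equal(nrow(nodeTable(net)), 4L)       # isolated nodes retained
  netAll <- buildNetwork(agg, threshold = 0.999, domains = doms)
  expect_equal(nrow(edgeTable(netAll)), 3L)

  subs <- splitSubnetworks(netAll)
  expect_equal(nrow(edgeTable(subs$bacteria)), 1L)
  expect_equal(nrow(edgeTable(subs$fungi)), 1L)
  expect_equal(nrow(edgeTable(subs$cross)), 1L)
  expect_equal(sum(vapply(subs, function(n) nrow(edgeTable(n)), 1L)),
               nrow(edgeTable(netAll)))
  expect_equal(edgeTable(subs$cross)$taxon_a, "b1")

  neg <- negativeSubnetwork(netAll)
  expect_equal(nrow(edgeTable(neg)), 1L)
  expect_setequal(nodeTable(neg)$taxon, c("b1", "f1"))
})
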