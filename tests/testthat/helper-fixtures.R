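# Shared fixture builders and small independent oracles.

# taxon x sample relative table with dimnames
relTable <- function(values, domain = "bacteria", group = NULL) {
  abundanceTable(values, domain = domain, mode = "relative", group = group)
}

randomRelMatrix <- function(p, n, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(p * n), p, n,
              dimnames = list(sprintf("t%02d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  sweep(m, 2, colSums(m), "/")
}

# Adjusted Rand index, computed from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Rank-based AUROC of score against a logical truth vector.
auroc <- function(score, truth) {
  score[is.na(score)] <- 0
  r <- rank(score)
  (mean(r[truth]) - (sum(truth) + 1) / 2) / sum(!truth)
}

# Brute-force weighted Simes: scan every candidate bound.
simesOracle <- function(p, w = rep(1, length(p))) {
  o <- order(p)
  ps <- p[o]; ws <- w[o]
  best <- Inf
  for (i in seq_along(ps))
    best <- min(best, sum(ws) * ps[i] / sum(ws[seq_len(i)]))
  min(1, best)
}

# Upper-triangle pair keys "a b" with a < b for a symmetric matrix.
pairKeys <- function(taxa) {
  ut <- which(upper.tri(diag(length(taxa))), arr.ind = TRUE)
  paste(pmin(taxa[ut[, 1]], taxa[ut[, 2]]),
        pmax(taxa[ut[, 1]], taxa[ut[, 2]]))
}

plantedKeys <- function(pn) paste(pn@edges$taxon_a, pn@edges$taxon_b)

# Exact block-diagonal similarity matrix toy.
blockSimilarity <- function(nBlocks, blockSize = 6, within = 0.9) {
  n <- nBlocks * blockSize
  m <- matrix(0, n, n)
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1) * blockSize + 1):(b * blockSize)
    m[idx, idx] <- within
  }
  diag(m) <- 1
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  new("SimilarityMatrix", matrix = m, kind = "bray_curtis_similarity")
}

# Group-1 relative table of a single-kingdom recovery cohort.
recoveryCohort <- function(seed, p = 30L, n = 500L, density = 0.1) {
  cfg <- simulationConfig(nSamples = c(n, n), nBacteria = p, nFungi = 0L,
                          edgeDensity = density, sequencingDepth = 1e6,
                          zeroInflationProb = 0, dominance = 1, seed = seed)
  ch <- simulateCohort(cfg)
  tab <- ch@relative$bacteria
  g1 <- names(which(sampleGroups(tab) == "group1"))
  list(table = toRelative(tab[, g1]), truth = ch@networks$group1,
       cohort = ch)
}
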