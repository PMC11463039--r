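#' @include AllClasses.R utils.R abundance.R
NULL

.defaultPseudocount <- function(v) {
  nz <- v[v > 0]
  if (!length(nz)) stop("table has no nonzero entries")
  min(nz) / 2
}

#' Centered log-ratio transform of a relative-abundance table
#'
#' Per sample: a pseudocount is added, the column re-closed to sum 1, and
#' the log abundances are centered by their mean over taxa (equivalently,
#' divided by the geometric mean). Output columns therefore have mean zero,
#' and the transform is invariant to sample-wise rescaling of the input.
#'
#' @param table relative-mode [AbundanceTable-class], or a nonnegative
#'   taxon x sample matrix.
#' @param pseudocount added before taking logs; default is half the smallest
#'   nonzero relative abundance in the table. May be 0 only for zero-free
#'   tables.
#' @return taxon x sample numeric matrix of CLR values.
#' @export
clrTransform <- function(table, pseudocount = NULL) {
  v <- if (is(table, "AbundanceTable")) {
    if (abundanceMode(table) != "relative")
      stop("CLR requires a relative-mode table")
    assay(table, "abundance")
  } else as.matrix(table)
  if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(v)
  if (pseudocount <= 0 && any(v == 0))
    stop("pseudocount must be > 0 when the table contains zeros")
  x <- v + pseudocount
  x <- sweep(x, 2, colSums(x), "/")
  lg <- log(x)
  sweep(lg, 2, colMeans(lg), "-")
}

.msmSigns <- function(scores) {
  s <- sign(scores)
  s[s == 0] <- NA
  diag(s) <- NA
  s
}

.newMSM <- function(method, raw, signs = NULL, pvalues = NULL) {
  diag(raw) <- NA_real_
  if (is.null(signs)) {
    signs <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  }
  new("MethodScoreMatrix", method = method, raw = raw, signs = signs,
      pvalues = if (is.null(pvalues))
        matrix(numeric(), 0L, 0L) else pvalues)
}

# Core COAT estimator on a CLR matrix (taxa x samples): CLR covariance with
# entry-adaptive soft thresholding, returned as a correlation matrix.
.coatScores <- function(clr, soft) {
  p <- nrow(clr); n <- ncol(clr)
  X <- clr - rowMeans(clr)
  S <- tcrossprod(X) / n
  M2 <- tcrossprod(X^2) / n
  theta <- pmax(M2 - S^2, 0)
  lambda <- soft * sqrt(theta * log(p) / n)
  Tm <- sign(S) * pmax(abs(S) - lambda, 0)
  diag(Tm) <- diag(S)
  dg <- diag(Tm)
  sdv <- sqrt(dg)
  R <- Tm / outer(sdv, sdv)
  R <- pmin(pmax(R, -1), 1)
  constant <- dg <= .Machine$double.eps
  if (any(constant)) {
    R[constant, ] <- NA_real_
    R[, constant] <- NA_real_
  }
  diag(R) <- 1
  dimnames(R) <- dimnames(clr)[c(1L, 1L)]
  list(R = R, constant = constant)
}

#' Composition-adjusted thresholding (COAT) correlations
#'
#' Treats the CLR sample covariance as the estimate of the basis covariance
#' of the composition and applies entry-adaptive soft thresholding: entry
#' sigma_ij is shrunk by lambda_ij = soft * sqrt(theta_ij * log(p) / n),
#' where theta_ij is the empirical variance of the per-sample centered
#' cross-products. The thresholded covariance is converted to a correlation
#' matrix, which carries both the score magnitude and the sign.
#'
#' @param clr taxon x sample CLR matrix (see [clrTransform()]).
#' @param soft soft-thresholding multiplier (default 0.2).
#' @return [MethodScoreMatrix-class] with \code{method = "coat"}.
#' @export
coatCorrelation <- function(clr, soft = 0.2) {
  stopifnot(nrow(clr) >= 4L, ncol(clr) >= 4L, soft >= 0)
  res <- .coatScores(clr, soft)
  if (any(res$constant))
    warning("constant taxon row(s); their correlations are undefined: ",
            paste(rownames(clr)[res$constant], collapse = ", "))
  .newMSM("coat", res$R, .msmSigns(res$R))
}

# Common log-spaced penalty grid for neighbourhood selection.
.lambdaGrid <- function(X, nlambda, minRatio = 0.01) {
  n <- nrow(X)
  C <- abs(crossprod(X)) / n
  diag(C) <- 0
  lmax <- max(C)
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nlambda))
}

# Meinshausen-Buhlmann neighbourhood selection over a fixed lambda grid.
# Returns a p x p x nlambda coefficient array (beta[j, i, l]: coefficient of
# predictor i in the lasso regression of node j).
.mbPath <- function(X, lambdas) {
  p <- ncol(X)
  beta <- array(0, dim = c(p, p, length(lambdas)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                          lambda = lambdas, standardize = FALSE,
                          intercept = FALSE)
    cf <- as.matrix(fit$beta)      # (p-1) x n_fitted
    nf <- ncol(cf)
    if (nf < length(lambdas))      # path stopped early: pad with last column
      cf <- cbind(cf, cf[, rep(nf, length(lambdas) - nf), drop = FALSE])
    beta[j, -j, ] <- cf[, seq_along(lambdas)]
  }
  beta
}

# StARS: pick the penalty by edge-selection instability over subsamples.
.starsSelectLambda <- function(X, lambdas, nSubsamples = 20L,
                               subsampleRatio = 0.8,
                               instabilityTarget = 0.05, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  m <- floor(subsampleRatio * n)
  nl <- length(lambdas)
  xi <- matrix(0, p * p, nl)
  set.seed(seed)
  for (b in seq_len(nSubsamples)) {
    idx <- sample.int(n, m)
    beta <- .mbPath(scale(X[idx, , drop = FALSE]), lambdas)
    for (l in seq_len(nl)) {
      adj <- (beta[, , l] != 0) | t(beta[, , l] != 0)   # OR rule
      xi[, l] <- xi[, l] + as.numeric(adj)
    }
  }
  xi <- xi / nSubsamples
  inst <- colSums(2 * xi * (1 - xi)) / (p * (p - 1L))
  instMono <- cummax(inst)                  # lambdas ordered decreasing
  ok <- which(instMono <= instabilityTarget)
  sel <- if (length(ok)) max(ok) else 1L    # densest graph within target
  list(lambda = lambdas[sel], index = sel, instability = inst)
}

# Symmetrized partial-correlation-style scores from an MB fit at one lambda.
.mbScores <- function(X, lambda) {
  Xs <- scale(X)
  beta <- .mbPath(Xs, lambda)[, , 1L]
  b1 <- beta; b2 <- t(beta)
  score <- matrix(0, ncol(X), ncol(X))
  both <- (b1 != 0) & (b2 != 0)
  agree <- both & (sign(b1) == sign(b2))
  score[agree] <- sign(b1[agree]) * sqrt(abs(b1[agree] * b2[agree]))
  oneOnly <- xor(b1 != 0, b2 != 0)
  score[oneOnly] <- (b1 + b2)[oneOnly]      # the single nonzero coefficient
  dimnames(score) <- list(colnames(X), colnames(X))
  (score + t(score)) / 2
}

#' Sparse-graph partial correlations (neighbourhood selection + StARS)
#'
#' Estimates a sparse conditional-dependence graph on the CLR scale by
#' Meinshausen-Buhlmann neighbourhood selection (node-wise lasso via
#' \pkg{glmnet}) over a log-spaced path of \code{nlambda} penalties. The
#' penalty is chosen by StARS stability selection (default 20 subsamples of
#' 80 percent of the samples, total-instability target 0.05). Scores are
#' signed symmetrized coefficients: sqrt(|beta_ij * beta_ji|) when both
#' directions agree in sign, the single nonzero coefficient when only one
#' direction selects the edge, and 0 on sign conflict or no selection.
#'
#' @param clr taxon x sample CLR matrix.
#' @param nlambda length of the penalty path (default 100).
#' @param seed integer seed for the StARS subsamples.
#' @param lambda optional fixed penalty; skips StARS when given.
#' @param nSubsamples,subsampleRatio,instabilityTarget StARS parameters.
#' @return [MethodScoreMatrix-class] with \code{method = "sparse_graph"};
#'   the selected penalty is attached as attribute \code{"lambda"} of the
#'   raw score matrix so that resampling schemes can reuse it.
#' @export
sparseGraphPartialCorrelation <- function(clr, nlambda = 100L, seed = 1L,
                                          lambda = NULL, nSubsamples = 20L,
                                          subsampleRatio = 0.8,
                                          instabilityTarget = 0.05) {
  X <- t(clr)
  if (nrow(X) < 10L) stop("need at least 10 samples")
  if (is.null(lambda)) {
    grid <- .lambdaGrid(scale(X), nlambda)
    lambda <- .starsSelectLambda(X, grid, nSubsamples = nSubsamples,
                                 subsampleRatio = subsampleRatio,
                                 instabilityTarget = instabilityTarget,
                                 seed = seed)$lambda
  }
  score <- .mbScores(X, lambda)
  msm <- .newMSM("sparse_graph", score, .msmSigns(score))
  attr(msm@raw, "lambda") <- lambda
  msm
}

#' Pairwise mutual information of taxa
#'
#' Each taxon's abundances are discretized into equal-frequency bins and the
#' plug-in mutual information (natural log, nats) is computed for every
#' pair. MI is magnitude-only: the signs slot is all-NA.
#'
#' @param table relative-mode [AbundanceTable-class] or taxon x sample
#'   matrix.
#' @param bins number of bins (default \code{floor(sqrt(n))} capped at 10,
#'   minimum 2).
#' @return [MethodScoreMatrix-class] with
#'   \code{method = "mutual_information"}.
#' @export
mutualInformationMatrix <- function(table, bins = NULL) {
  v <- if (is(table, "AbundanceTable")) assay(table, "abundance")
       else as.matrix(table)
  n <- ncol(v)
  if (is.null(bins)) bins <- max(2L, min(10L, floor(sqrt(n))))
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  if (n < bins) stop("need at least as many samples as bins")
  raw <- .miScores(v, bins)
  .newMSM("mutual_information", raw)
}

.discretizeRows <- function(v, bins) {
  n <- ncol(v)
  t(apply(v, 1L, function(x) {
    b <- ceiling(rank(x, ties.method = "average") * bins / n)
    pmin(pmax(b, 1L), bins)
  }))
}

.miScores <- function(v, bins) {
  d <- .discretizeRows(v, bins)
  p <- nrow(v); n <- ncol(v)
  raw <- .pairApply(p, function(i, j) {
    joint <- tabulate(d[i, ] + (d[j, ] - 1L) * bins, bins * bins) / n
    pj <- matrix(joint, bins, bins)
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  }, dimnames = dimnames(v)[c(1L, 1L)])
  raw
}

#' Bray-Curtis association between taxa
#'
#' Similarity-oriented ensemble member: score = 1 - BC dissimilarity between
#' the two taxa's abundance vectors across samples, so that larger means
#' stronger for every method before normalization. Pairs of two all-zero
#' taxa are undefined (NA). Magnitude-only (no signs).
#'
#' @param table relative-mode [AbundanceTable-class] or taxon x sample
#'   matrix.
#' @return [MethodScoreMatrix-class] with \code{method = "bray_curtis"}.
#' @export
brayCurtisAssociation <- function(table) {
  v <- if (is(table, "AbundanceTable")) assay(table, "abundance")
       else as.matrix(table)
  raw <- .bcScores(v)
  .newMSM("bray_curtis", raw)
}

.bcScores <- function(v) {
  rs <- rowSums(v)
  d <- suppressWarnings(as.matrix(vegan::vegdist(v, method = "bray")))
  s <- 1 - d
  bothZero <- outer(rs == 0, rs == 0, `&`)
  s[bothZero] <- NA_real_
  dimnames(s) <- dimnames(v)[c(1L, 1L)]
  s
}
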