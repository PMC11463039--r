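#' @include AllClasses.R
NULL

#' Construct an AbundanceTable
#'
#' @param values nonnegative numeric matrix, taxa as rows, samples as
#'   columns; dimnames required.
#' @param domain per-taxon kingdom label(s), \code{"bacteria"} or
#'   \code{"fungi"}; recycled if length 1.
#' @param mode \code{"auto"} (default; relative if every column sums to 1
#'   within 1e-6, counts otherwise), \code{"counts"} or \code{"relative"}.
#' @param group optional per-sample group labels.
#' @return an [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(.2, .3, .5, .1, .4, .5), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' abundanceTable(m, domain = "bacteria")
#' @export
abundanceTable <- function(values, domain, mode = "auto", group = NULL) {
  values <- as.matrix(values)
  if (length(domain) == 1L) domain <- rep(domain, nrow(values))
  if (identical(mode, "auto")) {
    cs <- colSums(values)
    mode <- if (ncol(values) && all(abs(cs - 1) < 1e-6)) "relative" else "counts"
  }
  if (mode == "relative" && ncol(values)) {
    cs <- colSums(values)
    # snap near-1 column sums so tables rebuilt from rounded TSVs validate
    ok <- abs(cs - 1) < 1e-6 & abs(cs - 1) > 0
    if (any(ok)) values[, ok] <- sweep(values[, ok, drop = FALSE], 2,
                                       cs[ok], "/")
  }
  cd <- if (is.null(group)) DataFrame(row.names = colnames(values))
        else DataFrame(group = as.character(group),
                       row.names = colnames(values))
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    rowData = DataFrame(domain = domain, row.names = rownames(values)),
    colData = cd)
  new("AbundanceTable", se, mode = mode)
}

#' Read a taxon-by-sample abundance table from TSV
#'
#' Expects a UTF-8, tab-delimited file with a header row of sample ids and a
#' first column of taxon ids. Counts vs relative mode is auto-detected from
#' the column sums.
#'
#' @param path file path.
#' @param domain kingdom label for all taxa in the file.
#' @return an [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, domain = c("bacteria", "fungi")) {
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expected a taxon-id column plus >=1 sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate taxon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(ids, colnames(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at taxon '%s' (row %d), sample '%s'",
                 ids[idx[1L]], idx[1L], colnames(num)[idx[2L]]))
  }
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 ids[idx[1L]], colnames(num)[idx[2L]]))
  }
  abundanceTable(num, domain = domain, mode = "auto")
}

#' Write an AbundanceTable to TSV (the dialect readAbundanceTable reads)
#'
#' @param table an [AbundanceTable-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(table, path) {
  v <- assay(table, "abundance")
  df <- data.frame(taxon_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table (sample_id, group, ...)
#'
#' @param path TSV path with at least columns \code{sample_id} and
#'   \code{group}.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(md)))
    stop("metadata must contain 'sample_id' and 'group' columns")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  md
}

#' Convert a table to relative abundances
#'
#' Divides each sample column by its sum. Idempotent on relative tables.
#'
#' @param table an [AbundanceTable-class].
#' @return relative-mode [AbundanceTable-class].
#' @export
toRelative <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  v <- assay(table, "abundance")
  cs <- colSums(v)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(v)[cs == 0], collapse = ", "))
  out <- sweep(v, 2, cs, "/")
  abundanceTable(out, domain = taxonDomains(table), mode = "relative",
                 group = sampleGroups(table))
}

#' Prevalence/abundance filtering of taxa
#'
#' Keeps taxa whose mean relative abundance (zeros included) strictly
#' exceeds \code{minAbundance} and whose prevalence — the fraction of samples
#' with a strictly positive entry — strictly exceeds \code{minPrevalence}.
#' The strict ">" on both criteria follows the conventional reading of
#' "greater than"; a taxon at exactly 10 percent prevalence is dropped.
#' Typical thresholds in nasal-microbiome profiling are 1e-4 (bacteria) or
#' 1e-3 (fungi) abundance with 0.1 prevalence.
#'
#' @param table relative-mode [AbundanceTable-class].
#' @param minAbundance minimum mean relative abundance, in (0, 1).
#' @param minPrevalence minimum prevalence fraction, in (0, 1).
#' @return filtered [AbundanceTable-class] (taxon order preserved). Columns
#'   are \emph{not} renormalized; renormalization happens when domains are
#'   merged.
#' @seealso [mergeDomainsRenormalize()]
#' @export
prevalenceAbundanceFilter <- function(table, minAbundance, minPrevalence) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceMode(table) != "relative")
    stop("filtering requires a relative-mode table; call toRelative() first")
  stopifnot(minAbundance > 0, minAbundance < 1,
            minPrevalence > 0, minPrevalence < 1)
  v <- assay(table, "abundance")
  keep <- rowMeans(v) > minAbundance &
          rowMeans(v > 0) > minPrevalence
  if (!any(keep)) {
    warning("no taxa pass the filter; returning an empty table")
  }
  sub <- table[keep, ]
  new("AbundanceTable", sub, mode = "relative")
}

#' Merge per-kingdom profiles and renormalize
#'
#' Row-concatenates filtered per-kingdom relative tables over a common
#' sample set and renormalizes every sample column to sum to 1, yielding the
#' merged cross-kingdom profile used for network inference.
#'
#' @param tables list of relative-mode [AbundanceTable-class] objects with
#'   identical sample sets and disjoint taxon ids.
#' @return merged relative-mode [AbundanceTable-class].
#' @export
mergeDomainsRenormalize <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, TRUE, "AbundanceTable")))
  if (any(vapply(tables, abundanceMode, "") != "relative"))
    stop("all tables must be in relative mode")
  samp <- lapply(tables, colnames)
  ref <- samp[[1L]]
  for (i in seq_along(samp)[-1L]) {
    if (!setequal(samp[[i]], ref)) {
      d <- union(setdiff(samp[[i]], ref), setdiff(ref, samp[[i]]))
      stop("sample sets differ between tables: ", paste(d, collapse = ", "))
    }
  }
  mats <- lapply(tables, function(t) assay(t, "abundance")[, ref, drop = FALSE])
  ids <- unlist(lapply(mats, rownames), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("taxon ids must be disjoint across tables: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  merged <- do.call(rbind, mats)
  cs <- colSums(merged)
  if (any(cs == 0))
    stop("all-zero merged sample column(s): ",
         paste(ref[cs == 0], collapse = ", "))
  merged <- sweep(merged, 2, cs, "/")
  dom <- unlist(lapply(tables, taxonDomains), use.names = FALSE)
  grp <- sampleGroups(tables[[1L]])
  abundanceTable(merged, domain = dom, mode = "relative",
                 group = if (is.null(grp)) NULL else grp[ref])
}

#' Alpha diversity of a single relative-abundance profile
#'
#' Shannon H = -sum p log p (natural log, zero entries skipped), Simpson =
#' 1 - sum p^2, Pielou evenness = H / log(S) with S the number of taxa with
#' nonzero abundance. Pielou is undefined (NaN, with a warning) when S = 1.
#'
#' @param p nonnegative numeric vector summing to 1 (tolerance 1e-9).
#' @param index one of \code{"shannon"}, \code{"simpson"}, \code{"pielou"}.
#' @return a single numeric value.
#' @examples
#' alphaDiversity(rep(0.25, 4), "shannon")  # log(4)
#' @export
alphaDiversity <- function(p, index = c("shannon", "simpson", "pielou")) {
  index <- match.arg(index)
  stopifnot(is.numeric(p), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9)
    stop("profile must sum to 1 (got ", format(sum(p)), ")")
  nz <- p[p > 0]
  H <- -sum(nz * log(nz))
  switch(index,
    shannon = H,
    simpson = 1 - sum(p^2),
    pielou = {
      S <- length(nz)
      if (S < 2L) {
        warning("Pielou evenness undefined for a single-taxon profile")
        NaN
      } else H / log(S)
    })
}

#' Bray-Curtis dissimilarity between two nonnegative vectors
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in [0, 1].
#'
#' @param x,y nonnegative numeric vectors of equal length, not both zero.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / tot
}

#' pN/pS ratio from SNV and site counts
#'
#' (nonsynonymous SNVs / nonsynonymous sites) /
#' (synonymous SNVs / synonymous sites). Values below 1 indicate purifying
#' selection. When no synonymous SNVs were observed the ratio is undefined
#' and NaN is returned with a warning (not infinity).
#'
#' @param nonsynSnvs,nonsynSites,synSnvs,synSites nonnegative counts; site
#'   counts must be positive.
#' @return the ratio, or NaN when \code{synSnvs == 0}.
#' @export
pnPsRatio <- function(nonsynSnvs, nonsynSites, synSnvs, synSites) {
  stopifnot(nonsynSites > 0, synSites > 0, nonsynSnvs >= 0, synSnvs >= 0)
  if (synSnvs == 0) {
    warning("no synonymous SNVs: pN/pS undefined, returning NaN")
    return(NaN)
  }
  (nonsynSnvs / nonsynSites) / (synSnvs / synSites)
}
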