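#' @include AllClasses.R
NULL

# Min-max scale to [1, 100]; a constant vector maps to all-100 (every node
# equally influential), matching the convention used for IVI components.
.minmax1_100 <- function(x) {
  rng <- range(x)
  if (!is.finite(rng[1L]) || rng[2L] - rng[1L] < .Machine$double.eps)
    return(rep(100, length(x)))
  1 + 99 * (x - rng[1L]) / (rng[2L] - rng[1L])
}

# Min-max scale to [0, 1]; constant maps to all-1.
.minmax0_1 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[2L] - rng[1L] < .Machine$double.eps) {
    out <- ifelse(is.na(x), NA_real_, 1)
    return(out)
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

# Deterministic fan-out of one global seed into stage-specific seeds, so a
# stage re-run in isolation with its own seed reproduces the pipeline run.
# Kept below 2^31 - 1.
.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 101L, cluster = 211L, network = 307L,
               robustness = 401L, keystone = 503L, attack = 601L,
               reboot = 701L, stars = 809L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

# Symmetric matrix from the upper triangle of f applied pairwise.
.pairApply <- function(p, f, dimnames = NULL) {
  m <- matrix(NA_real_, p, p, dimnames = dimnames)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      m[i, j] <- m[j, i] <- f(i, j)
    }
  }
  m
}

.upperVals <- function(m) m[upper.tri(m)]
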