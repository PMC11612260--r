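# Independent oracles used across tests.

# Brute-force checkerboard count for one taxon pair: the number of ordered
# site pairs (a, b) with taxon i present only at a and taxon j present only
# at b. Counting loop, no algebra shared with the implementation.
brute_pair_cu <- function(m, i, j) {
  cu <- 0L
  for (a in seq_len(ncol(m))) {
    for (b in seq_len(ncol(m))) {
      if (a != b &&
          m[i, a] == 1 && m[j, a] == 0 &&
          m[j, b] == 1 && m[i, b] == 0) cu <- cu + 1L
    }
  }
  cu
}

brute_cscore <- function(m) {
  M <- nrow(m)
  total <- 0
  for (i in seq_len(M - 1))
    for (j in (i + 1):M) total <- total + brute_pair_cu(m, i, j)
  total / (M * (M - 1) / 2)
}

# random 0/1 matrix, redrawn until non-degenerate (no all-zero margin)
random_binary_matrix <- function(nr, nc, p = 0.5) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# one-way Euclidean pseudo-F computed from first principles (distance-free
# sums of squares), independent of the package implementation
oracle_pseudo_f <- function(X, g) {
  X <- as.matrix(X)
  g <- as.factor(g)
  n <- nrow(X)
  grand <- colMeans(X)
  ssw <- 0; ssb <- 0
  for (lev in levels(g)) {
    sub <- X[g == lev, , drop = FALSE]
    cen <- colMeans(sub)
    ssw <- ssw + sum(t(t(sub) - cen)^2)
    ssb <- ssb + nrow(sub) * sum((cen - grand)^2)
  }
  (ssb / (nlevels(g) - 1)) / (ssw / (n - nlevels(g)))
}

# tiny occurrence table used by several community_data tests
toy_occurrence_csv <- function(path, extra_rows = NULL) {
  lines <- c(
    "site_id,taxon_id,abundance,year,ecoregion,vegetation",
    "s1,chironomus,17,2011,LHW,bulrush",
    "s2,chironomus,3,2011,LHW,bulrush",
    "s2,gyraulus,5,2011,LHW,bulrush",
    extra_rows)
  writeLines(lines, path)
  path
}
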